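# Expression filtering, differential-expression selection, temporal
# clustering and cluster-median profiles.
#
# An expression matrix is a tibble with a `gene_id` column plus one numeric
# column per sample (log2 intensities). Sample metadata is a tibble with
# columns `sample` (matching the column names) and `time` (hours).

expr_matrix <- function(expr, samples) {
  missing <- setdiff(samples$sample, names(expr))
  if (length(missing) > 0) {
    abort(paste0("samples not found in expression columns: ",
                 paste(missing, collapse = ", ")))
  }
  m <- as.matrix(expr[, samples$sample, drop = FALSE])
  rownames(m) <- expr$gene_id
  if (any(!is.finite(m))) abort("expression values must be finite")
  m
}

#' Filter to expressed genes
#'
#' Keeps genes whose maximum log2 intensity across all samples reaches
#' `min_log2` (default 6, i.e. intensity 64). The retained set defines the
#' expressed-gene background universe used by motif enrichment and the
#' random-gene-set ChIP test.
#'
#' @param expr Expression tibble (`gene_id` + sample columns, log2 scale).
#' @param samples Sample metadata tibble (`sample`, `time`).
#' @param min_log2 Minimum log2 intensity (default 6); the comparison is `>=`.
#' @return The filtered expression tibble.
#' @export
filter_expressed <- function(expr, samples, min_log2 = 6) {
  m <- expr_matrix(expr, samples)
  keep <- apply(m, 1, max) >= min_log2
  if (!any(keep)) abort("no genes pass the expression filter")
  expr[keep, , drop = FALSE]
}

row_f_stats <- function(m, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- ncol(m)
  ind <- stats::model.matrix(~ 0 + groups)          # n x k indicator
  sizes <- colSums(ind)
  gmeans <- (m %*% ind) %*% diag(1 / sizes, k)      # G x k group means
  grand <- rowMeans(m)
  ssb <- rowSums(sweep(gmeans, 2, sizes, "*") * gmeans) - n * grand^2
  sst <- rowSums(m * m) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssw == 0 & ssb > 0] <- Inf
  f[ssw == 0 & ssb <= 1e-12] <- 0
  f
}

#' Per-gene one-way ANOVA with permutation q-values
#'
#' Computes a one-way ANOVA F statistic across time points for every gene,
#' then builds a null F distribution from `n_perm` balanced permutations of
#' the sample-to-time-point labels (each permutation reassigns whole samples,
#' preserving group sizes, and is applied to all genes at once). The per-gene
#' permutation p-value is `(1 + #{permuted F >= observed F}) / (n_perm + 1)`.
#' The q-value is the plug-in empirical FDR: at threshold `F_g`, the mean
#' number of null exceedances per permutation divided by the number of
#' observed exceedances, monotonized to be nonincreasing in F and capped at 1.
#'
#' With a single replicate per time point the F statistic is undefined; all
#' statistics are returned as `NA` with a warning, and downstream selection
#' falls back to the fold-change criterion alone.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param samples Sample metadata tibble (`sample`, `time`).
#' @param n_perm Number of balanced label permutations (default 1000).
#' @param seed Optional integer seed for the permutations.
#' @return A tibble `gene_id`, `f`, `p`, `q`.
#' @export
anova_permutation_q <- function(expr, samples, n_perm = 1000, seed = NULL) {
  m <- expr_matrix(expr, samples)
  groups <- as.factor(samples$time)
  if (nlevels(groups) < 2) abort("need at least two time points")
  if (max(table(groups)) < 2) {
    warn(paste("single replicate per time point: F undefined,",
               "selection degrades to fold-change only"))
    return(tibble(gene_id = expr$gene_id, f = NA_real_, p = NA_real_,
                  q = NA_real_))
  }
  if (n_perm < 100) warn("fewer than 100 permutations: q-values are coarse")
  f_obs <- row_f_stats(m, groups)
  run_perms <- function() {
    vapply(seq_len(n_perm), function(b) {
      row_f_stats(m, sample(groups))
    }, numeric(nrow(m)))
  }
  f_null <- if (is.null(seed)) run_perms() else {
    withr::with_seed(seed, run_perms())
  }
  # per-gene permutation p (floor 1/(n_perm+1))
  f_obs <- unname(f_obs)
  p <- (1 + unname(rowSums(f_null >= f_obs))) / (n_perm + 1)
  # plug-in empirical FDR against the pooled null, monotonized in F
  ord <- order(f_obs, decreasing = TRUE)
  null_sorted <- sort(as.vector(f_null))
  n_null <- length(null_sorted)
  exceed_null <- n_null -
    findInterval(f_obs[ord] - .Machine$double.eps^0.5, null_sorted)
  q_ord <- (exceed_null / n_perm) / seq_along(ord)
  q_ord <- pmin(cummax(q_ord), 1)   # nonincreasing in F = nondecreasing in rank
  q <- numeric(length(f_obs))
  q[ord] <- q_ord
  tibble(gene_id = expr$gene_id, f = f_obs, p = p, q = q)
}

#' Per-gene log2 fold changes versus the unstimulated baseline
#'
#' Fold change is the difference of per-time-point mean log2 intensity from
#' the 0 h mean, for every time point (0 h itself gives 0).
#'
#' @inheritParams anova_permutation_q
#' @return A long tibble `gene_id`, `time`, `log2fc`.
#' @export
fold_changes <- function(expr, samples) {
  m <- expr_matrix(expr, samples)
  times <- sort(unique(samples$time))
  if (!0 %in% times) abort("the 0 h baseline time point is required")
  means <- vapply(times, function(t) {
    rowMeans(m[, samples$sample[samples$time == t], drop = FALSE])
  }, numeric(nrow(m)))
  fc <- means - means[, which(times == 0)]
  tibble(
    gene_id = rep(expr$gene_id, times = length(times)),
    time = rep(times, each = nrow(m)),
    log2fc = as.vector(fc)
  )
}

#' Select differentially expressed genes
#'
#' A gene is kept when its ANOVA permutation q-value is at most `q_cut` and
#' its maximum absolute log2 fold change over stimulated time points reaches
#' `log2(fc_cut)`. Direction is the sign of the maximum-magnitude fold
#' change. `NA` q-values (single-replicate mode) pass the q criterion.
#'
#' @param stats Output of [anova_permutation_q()].
#' @param fc Output of [fold_changes()].
#' @param q_cut q-value cutoff (default 0.01).
#' @param fc_cut Linear fold-change cutoff (default 5); applied as
#'   `|log2fc| >= log2(fc_cut)`.
#' @return A tibble `gene_id`, `q`, `max_abs_log2fc`, `direction`
#'   (`"up"`/`"down"`) for the selected genes.
#' @export
select_de <- function(stats, fc, q_cut = 0.01, fc_cut = 5) {
  if (fc_cut < 1) abort("`fc_cut` must be >= 1")
  peak <- fc |>
    filter(.data$time > 0) |>
    group_by(.data$gene_id) |>
    summarise(
      max_abs_log2fc = max(abs(.data$log2fc)),
      direction = if_else(.data$log2fc[which.max(abs(.data$log2fc))] > 0,
                          "up", "down"),
      .groups = "drop"
    )
  stats |>
    inner_join(peak, by = "gene_id") |>
    filter(is.na(.data$q) | .data$q <= q_cut,
           .data$max_abs_log2fc >= log2(fc_cut)) |>
    select("gene_id", "q", "max_abs_log2fc", "direction")
}

zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  if (any(s == 0)) {
    abort(paste0("zero-variance profile(s): ",
                 paste(rownames(m)[s == 0], collapse = ", ")))
  }
  (m - mu) / s
}

kmeans_cor_once <- function(z, k) {
  n <- nrow(z); tt <- ncol(z)
  centers <- z[sample.int(n, k), , drop = FALSE]
  assign_old <- rep(0L, n)
  for (iter in seq_len(100)) {
    # correlation between z-scored rows: r = (x . c) / (T - 1)
    r <- tcrossprod(z, centers) / (tt - 1)
    assign_new <- max.col(r, ties.method = "first")
    if (all(assign_new == assign_old)) break
    assign_old <- assign_new
    for (j in seq_len(k)) {
      members <- z[assign_new == j, , drop = FALSE]
      if (nrow(members) == 0) {            # re-seed an emptied cluster
        centers[j, ] <- z[sample.int(n, 1), ]
      } else {
        cm <- colMeans(members)
        s <- sd(cm)
        centers[j, ] <- if (s > 0) (cm - mean(cm)) / s else cm
      }
    }
  }
  r <- tcrossprod(z, centers) / (tt - 1)
  obj <- sum(1 - r[cbind(seq_len(n), assign_old)])
  list(assignment = assign_old, objective = obj)
}

#' Cluster temporal fold-change profiles by correlation distance
#'
#' k-means under the distance `1 - Pearson r`: profiles are z-scored across
#' time, each is assigned to the most correlated centroid, and centroids are
#' re-standardized member means. Random restarts are run and the solution
#' with the lowest total within-cluster `1 - r` is kept.
#'
#' @param fc Long fold-change tibble (`gene_id`, `time`, `log2fc`).
#' @param k Number of clusters.
#' @param n_start Number of random restarts (default 20).
#' @param seed Optional integer seed.
#' @return An object of class `tf_clusters` with elements `membership`
#'   (tibble `gene_id`, `cluster`), `medians` (tibble `cluster`, `time`,
#'   `median`, `iqr`), `objective` and `k`. Supports [tidy()] and [glance()].
#' @export
cluster_profiles <- function(fc, k, n_start = 20, seed = NULL) {
  wide <- tidyr::pivot_wider(fc, id_cols = "gene_id",
                             names_from = "time", values_from = "log2fc")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene_id
  if (k > nrow(m)) abort("k exceeds the number of profiles")
  z <- zscore_rows(m)
  run <- function() {
    best <- NULL
    for (s in seq_len(n_start)) {
      fit <- kmeans_cor_once(z, k)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    best
  }
  best <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  membership <- tibble(gene_id = rownames(m),
                       cluster = best$assignment)
  medians <- fc |>
    inner_join(membership, by = "gene_id") |>
    group_by(.data$cluster, .data$time) |>
    summarise(median = median(.data$log2fc),
              iqr = stats::IQR(.data$log2fc), .groups = "drop")
  structure(
    list(membership = membership, medians = medians,
         objective = best$objective, k = k),
    class = "tf_clusters"
  )
}

#' Cluster up- and down-regulated genes separately
#'
#' Splits the differentially expressed genes by direction and clusters each
#' set independently, labelling clusters `UC1..UCk_up` and `DC1..DCk_down`
#' in decreasing order of size.
#'
#' @param fc Long fold-change tibble for all genes.
#' @param de Output of [select_de()].
#' @param k_up,k_down Cluster counts (defaults 5 and 3).
#' @param n_start,seed Passed to [cluster_profiles()].
#' @return A `tf_clusters` object whose cluster labels are the `UC*`/`DC*`
#'   strings; `medians` carries the per-label median and IQR profile.
#' @export
cluster_de_profiles <- function(fc, de, k_up = 5, k_down = 3, n_start = 20,
                                seed = NULL) {
  relabel <- function(fit, prefix) {
    sizes <- table(fit$membership$cluster)
    new <- setNames(paste0(prefix, seq_along(sizes)),
                    names(sort(sizes, decreasing = TRUE)))
    fit$membership$cluster <- unname(new[as.character(fit$membership$cluster)])
    fit$medians$cluster <- unname(new[as.character(fit$medians$cluster)])
    fit
  }
  seeds <- if (is.null(seed)) c(NA, NA) else seed + c(0L, 1L)
  pick <- function(i) if (is.null(seed)) NULL else seeds[i]
  fits <- list()
  for (dir in c("up", "down")) {
    ids <- de$gene_id[de$direction == dir]
    k <- if (dir == "up") k_up else k_down
    if (length(ids) == 0) next
    fit <- cluster_profiles(filter(fc, .data$gene_id %in% ids), k = k,
                            n_start = n_start,
                            seed = pick(if (dir == "up") 1 else 2))
    fits[[dir]] <- relabel(fit, if (dir == "up") "UC" else "DC")
  }
  structure(
    list(
      membership = bind_rows(lapply(fits, `[[`, "membership")),
      medians = bind_rows(lapply(fits, `[[`, "medians")),
      objective = sum(vapply(fits, `[[`, numeric(1), "objective")),
      k = c(up = k_up, down = k_down)
    ),
    class = "tf_clusters"
  )
}

#' @export
tidy.tf_clusters <- function(x, ...) x$membership

#' @export
glance.tf_clusters <- function(x, ...) {
  tibble(
    n_genes = nrow(x$membership),
    n_clusters = length(unique(x$membership$cluster)),
    objective = x$objective
  )
}

#' @export
print.tf_clusters <- function(x, ...) {
  cat("Temporal expression clustering (1 - r distance)\n")
  print(glance(x))
  invisible(x)
}

#' Median and interquartile-range profile of a gene set
#'
#' @param fc Long fold-change tibble.
#' @param gene_ids Genes forming the cluster.
#' @return A tibble `time`, `median`, `iqr`.
#' @export
median_profile <- function(fc, gene_ids) {
  sub <- filter(fc, .data$gene_id %in% gene_ids)
  if (nrow(sub) == 0) abort("empty cluster")
  sub |>
    group_by(.data$time) |>
    summarise(median = median(.data$log2fc), iqr = stats::IQR(.data$log2fc),
              .groups = "drop")
}

#' Piecewise-linear interpolation of a temporal profile
#'
#' @param times Knot times (strictly increasing).
#' @param values Profile values at the knots.
#' @param t_query Query times; must lie within `range(times)` (no
#'   extrapolation).
#' @return Interpolated values at `t_query`.
#' @export
interp_profile <- function(times, values, t_query) {
  if (any(t_query < min(times) | t_query > max(times))) {
    abort("interpolation query outside the measured time range")
  }
  approx(times, values, xout = t_query, method = "linear")$y
}
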