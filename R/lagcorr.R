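# Time-lagged correlation of motif score series with cluster-median
# expression. Motif scores live on the ChIP time grid (default 0/1/2/4 h)
# and are never interpolated; expression medians (default grid 0/2/4/12 h)
# are linearly interpolated at shifted times.

#' Time-lagged Pearson correlation at a single lag
#'
#' Correlates motif raw scores at their native time points with the
#' cluster-median expression linearly interpolated at `times + tau`.
#'
#' @param scores Motif raw scores (one per score time point).
#' @param score_times Time points of the scores, hours.
#' @param expr_times,expr_values Measured cluster-median expression profile.
#' @param tau Lag in hours (added to the score times before interpolating the
#'   expression).
#' @return Pearson R, or `NA` if either series has zero variance.
#' @export
lagged_cor <- function(scores, score_times, expr_times, expr_values, tau) {
  e <- interp_profile(expr_times, expr_values, score_times + tau)
  if (sd(scores) == 0 || sd(e) == 0) return(NA_real_)
  cor(scores, e)
}

lag_grid <- function(lag_range = c(0, 2), grid_step = 0.001) {
  seq(lag_range[1], lag_range[2], by = grid_step)
}

# correlation of one fixed score vector with the expression interpolated at
# every grid lag; returns a vector over the grid (NA where degenerate)
lag_cor_curve <- function(scores, score_times, expr_times, expr_values,
                          taus) {
  q <- outer(taus, score_times, `+`)
  e <- matrix(interp_profile(expr_times, expr_values, as.vector(q)),
              nrow = length(taus))
  mc <- scores - mean(scores)
  ec <- e - rowMeans(e)
  den <- sqrt(sum(mc^2) * rowSums(ec^2))
  r <- as.vector(ec %*% mc) / den
  r[den == 0] <- NA_real_
  r
}

#' Fit time-lagged correlations for motif/cluster score series
#'
#' For every (motif, cluster) series, computes Pearson R under three lag
#' policies: no lag (tau = 0), a fixed per-cluster lag (the grid lag
#' maximizing the summed squared R over the cluster's retained motifs), and
#' a per-motif optimal lag (the grid lag maximizing |R|, with its signed R).
#' Lags are searched on a dense grid; exact objective ties resolve to the
#' smallest lag.
#'
#' @param series Score series tibble (`motif_id`, `cluster`, `time`,
#'   `raw_score`, `retained`), e.g. from [score_motif_series()].
#' @param medians Cluster-median expression (`cluster`, `time`, `median`).
#' @param lag_range Allowed lag interval in hours (default `c(0, 2)`).
#' @param grid_step Lag grid step in hours (default 0.001).
#' @param retained_only Use only retained series (default `TRUE`).
#' @return An object of class `tf_lagfit`: a list with `results` (tibble
#'   `motif_id`, `cluster`, `r_nolag`, `tau_fixed`, `r_fixed`, `tau_opt`,
#'   `r_opt`), `cluster_lags` (tibble `cluster`, `tau_fixed`), and the grid
#'   settings. Supports [tidy()] and [glance()].
#' @export
fit_lag_correlations <- function(series, medians, lag_range = c(0, 2),
                                 grid_step = 0.001, retained_only = TRUE) {
  if (retained_only && "retained" %in% names(series)) {
    series <- filter(series, .data$retained)
  }
  series <- filter(series, !is.na(.data$raw_score))
  if (nrow(series) == 0) abort("no retained motif series to fit")
  taus <- lag_grid(lag_range, grid_step)
  med <- medians |> group_by(.data$cluster) |> arrange(.data$time,
                                                       .by_group = TRUE)
  med_split <- split(as_tibble(med), med$cluster)
  # guard: every grid query must be interpolable
  for (m in med_split) {
    tmax <- max(series$time) + max(taus)
    if (tmax > max(m$time) || min(series$time) + min(taus) < min(m$time)) {
      abort("lag range would require extrapolating the expression profile")
    }
  }
  per_series <- series |>
    group_by(.data$motif_id, .data$cluster) |>
    arrange(.data$time, .by_group = TRUE) |>
    summarise(times = list(.data$time), scores = list(.data$raw_score),
              .groups = "drop")
  curves <- purrr::pmap(per_series, function(motif_id, cluster, times,
                                             scores) {
    m <- med_split[[as.character(cluster)]]
    if (is.null(m)) return(NULL)
    r <- lag_cor_curve(scores, times, m$time, m$median, taus)
    list(motif_id = motif_id, cluster = cluster, r = r)
  })
  curves <- purrr::compact(curves)
  # fixed per-cluster lag: argmax of the summed squared R over the grid
  cluster_lags <- purrr::map_dfr(split(curves, vapply(curves, `[[`,
                                                      character(1),
                                                      "cluster")),
    function(cs) {
      obj <- Reduce(`+`, lapply(cs, function(x) {
        r2 <- x$r^2
        r2[is.na(r2)] <- 0
        r2
      }))
      if (all(obj == 0)) {
        abort("all motif series degenerate: fixed cluster lag undefined")
      }
      tibble(cluster = cs[[1]]$cluster, tau_fixed = taus[which.max(obj)])
    })
  results <- purrr::map_dfr(curves, function(x) {
    tf <- cluster_lags$tau_fixed[cluster_lags$cluster == x$cluster]
    i_opt <- if (all(is.na(x$r))) NA_integer_ else which.max(abs(x$r))
    tibble(
      motif_id = x$motif_id, cluster = x$cluster,
      r_nolag = x$r[which.min(abs(taus - 0))],
      tau_fixed = tf,
      r_fixed = x$r[which.min(abs(taus - tf))],
      tau_opt = if (is.na(i_opt)) NA_real_ else taus[i_opt],
      r_opt = if (is.na(i_opt)) NA_real_ else x$r[i_opt]
    )
  })
  structure(
    list(results = results, cluster_lags = cluster_lags,
         lag_range = lag_range, grid_step = grid_step),
    class = "tf_lagfit"
  )
}

#' @export
tidy.tf_lagfit <- function(x, ...) x$results

#' @export
glance.tf_lagfit <- function(x, ...) {
  tibble(
    n_series = nrow(x$results),
    n_clusters = nrow(x$cluster_lags),
    lag_min = x$lag_range[1], lag_max = x$lag_range[2],
    grid_step = x$grid_step
  )
}

#' @export
print.tf_lagfit <- function(x, ...) {
  cat("Time-lagged motif/expression correlation fit\n")
  print(glance(x))
  print(x$cluster_lags)
  invisible(x)
}

#' Association report for motif/cluster pairs
#'
#' Combines the score series, enrichment p-values, lag-correlation results
#' under all three lag policies, the chosen ranking, and a putative role
#' annotation (activator when the optimal-lag R is positive, repressor when
#' negative).
#'
#' @param lagfit A `tf_lagfit` object.
#' @param series The score series tibble used to fit it.
#' @param method Ranking statistic passed to [rank_motifs()].
#' @param medians Cluster medians (needed for `method = "score_at_peak"`).
#' @return A tibble with one row per (motif, cluster): score and p columns
#'   spread by time point, `retained`, R under each lag policy, `rank`, and
#'   `role`.
#' @export
report_associations <- function(lagfit, series, method = "score_range",
                                medians = NULL) {
  ranks <- rank_motifs(series, method = method, medians = medians,
                       lag_results = lagfit$results)
  wide <- series |>
    select("motif_id", "cluster", "time", "raw_score", "p", "retained") |>
    tidyr::pivot_wider(names_from = "time",
                       values_from = c("raw_score", "p"),
                       names_glue = "{.value}_t{time}")
  wide |>
    inner_join(lagfit$results, by = c("motif_id", "cluster")) |>
    left_join(select(ranks, "motif_id", "cluster", "statistic", "rank"),
              by = c("motif_id", "cluster")) |>
    mutate(role = case_when(
      is.na(.data$r_opt) ~ NA_character_,
      .data$r_opt > 0 ~ "activator",
      TRUE ~ "repressor"
    )) |>
    arrange(.data$cluster, .data$rank)
}
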