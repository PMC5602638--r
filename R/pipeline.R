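# End-to-end orchestration: coverage -> valleys -> APRs -> expression
# clustering -> motif scoring -> lag correlation -> ChIP validation.

#' Pipeline parameters
#'
#' Defaults are the reference analysis settings: 10 bp grid, 40 bp smoothing
#' sigma, 50-500 bp flanking windows, 0.70 dip rule, +/-5 kbp APR radius,
#' -1500/+500 promoter window, -2000/+500 ChIP window, motif retention
#' p <= 0.01, DE cuts q <= 0.01 and fold change >= 5, 5 up / 3 down
#' clusters, lags 0-2 h on a 0.001 h grid, 1000 background draws and random
#' sets, 122 bp read extension, log2 intensity filter at 6.
#'
#' @param ... Named overrides of any default listed above.
#' @return A named list of parameters.
#' @export
run_params <- function(...) {
  p <- list(
    step = 10, sigma = 40, near = 50, far = 500, dip_fraction = 0.70,
    extension = 122, apr_radius = 5000,
    promoter_upstream = 1500, promoter_downstream = 500,
    chip_upstream = 2000, chip_downstream = 500,
    min_log2 = 6, q_cut = 0.01, fc_cut = 5, n_perm = 1000,
    k_up = 5, k_down = 3, n_start = 20,
    p_cut = 0.01, n_draws = 1000, length_tol = 0.1,
    lag_range = c(0, 2), grid_step = 0.001,
    n_sets = 1000, ranking = "score_range"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0) {
    abort(paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")))
  }
  p[names(dots)] <- dots
  p
}

#' Run the full valley-guided TF discovery pipeline
#'
#' Executes every stage on in-memory inputs: valley calling on each time
#' point's coverage track, expression filtering / DE selection / temporal
#' clustering, APR assignment and sequence extraction, motif enrichment
#' scoring per cluster and time point, time-lagged correlation, and (when
#' TF reads are provided) the random-gene-set ChIP enrichment test.
#'
#' @param data A list with elements `genes` (gene models), `tracks`
#'   (coverage tibble with a `time` column), `expr` and `samples`
#'   (expression matrix and sample sheet), `motifs` (motif tibble), `genome`
#'   (DNAStringSet or FASTA path), and optionally `tf_reads` and
#'   `tf_motifs`; [simulate_dataset()] output has this shape.
#' @param params A [run_params()] list.
#' @param seed Integer seed governing every stochastic stage.
#' @return An object of class `valleytf_run`: a list with `valleys`, `de`,
#'   `clusters` (a `tf_clusters`), `aprs`, `series`, `lagfit` (a
#'   `tf_lagfit`), `associations` and `chip` (or `NULL`).
#' @export
run_valley_tf <- function(data, params = run_params(), seed = 1) {
  withr::with_seed(seed, run_valley_tf_impl(data, params))
}

run_valley_tf_impl <- function(data, p) {
  for (nm in c("genes", "tracks", "expr", "samples", "motifs", "genome")) {
    if (is.null(data[[nm]])) abort(paste0("input `", nm, "` is missing"))
  }
  # -- valleys per time point
  valleys <- data$tracks |>
    group_by(.data$time) |>
    group_modify(function(tr, key) {
      sm <- smooth_coverage(tr, sigma = p$sigma, step = p$step)
      call_valleys(sm, near = p$near, far = p$far,
                   dip_fraction = p$dip_fraction, step = p$step)
    }) |>
    ungroup() |>
    select("chrom", "start", "end", "score", "time")

  # -- expression: filter, DE, clusters
  expr_f <- filter_expressed(data$expr, data$samples, min_log2 = p$min_log2)
  expressed <- expr_f$gene_id
  stats <- anova_permutation_q(expr_f, data$samples, n_perm = p$n_perm)
  fc <- fold_changes(expr_f, data$samples)
  de <- select_de(stats, fc, q_cut = p$q_cut, fc_cut = p$fc_cut)
  clusters <- cluster_de_profiles(fc, de, k_up = p$k_up, k_down = p$k_down,
                                  n_start = p$n_start)

  # -- APR sequences per cluster and time point
  genes_expr <- filter(data$genes, .data$gene_id %in% expressed)
  aprs <- assign_aprs(valleys, genes_expr, radius = p$apr_radius)
  apr_members <- inner_join(aprs, clusters$membership, by = "gene_id")
  apr_seqs <- extract_sequences(apr_members, data$genome) |>
    select("cluster", "time", "gene_id", "seq")

  # -- background: promoters of all expressed genes
  bg_seqs <- extract_sequences(
    promoter_windows(genes_expr, upstream = p$promoter_upstream,
                     downstream = p$promoter_downstream),
    data$genome)$seq

  # -- motif enrichment series and lagged correlation
  series <- score_motif_series(data$motifs, apr_seqs, bg_seqs,
                               n_draws = p$n_draws, p_cut = p$p_cut,
                               length_tol = p$length_tol)
  lagfit <- fit_lag_correlations(series, clusters$medians,
                                 lag_range = p$lag_range,
                                 grid_step = p$grid_step)
  associations <- report_associations(lagfit, series, method = p$ranking,
                                      medians = clusters$medians)

  # -- ChIP validation (optional)
  chip <- NULL
  if (!is.null(data$tf_reads)) {
    chip <- validate_chip(
      data$tf_reads, clusters$membership, data$genes, expressed,
      series = series, tf_motifs = data$tf_motifs,
      upstream = p$chip_upstream, downstream = p$chip_downstream,
      n_sets = p$n_sets, p_cut = p$p_cut)
  }

  structure(
    list(valleys = valleys, de = de, clusters = clusters, aprs = aprs,
         series = series, lagfit = lagfit, associations = associations,
         chip = chip, params = p),
    class = "valleytf_run"
  )
}

#' @export
glance.valleytf_run <- function(x, ...) {
  tibble(
    n_valleys = nrow(x$valleys),
    n_de = nrow(x$de),
    n_clusters = length(unique(x$clusters$membership$cluster)),
    n_retained_series = nrow(distinct(filter(x$series, .data$retained),
                                      .data$motif_id, .data$cluster)),
    chip_tested = !is.null(x$chip)
  )
}

#' @export
print.valleytf_run <- function(x, ...) {
  cat("valleytf pipeline run\n")
  print(glance(x))
  invisible(x)
}

#' Write pipeline results to a directory
#'
#' Emits the stage outputs as plain-text files: valley calls (BED6 with the
#' valley score in the score field, one file per time point), DE gene table,
#' cluster memberships and medians, the motif score series, the association
#' table, the ChIP validation table when present, and a JSON run manifest
#' with the parameters used.
#'
#' @param run A `valleytf_run`.
#' @param dir Output directory (created if needed).
#' @param seed The seed the run was executed with (recorded in the manifest).
#' @return The directory, invisibly.
#' @export
write_run <- function(run, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in unique(run$valleys$time)) {
    v <- filter(run$valleys, .data$time == t)
    write_bed(mutate(v, name = "valley"),
              file.path(dir, sprintf("valleys_t%g.bed", t)))
  }
  readr::write_tsv(run$de, file.path(dir, "de_genes.tsv"), progress = FALSE)
  readr::write_tsv(run$clusters$membership,
                   file.path(dir, "cluster_membership.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$clusters$medians,
                   file.path(dir, "cluster_medians.tsv"), progress = FALSE)
  readr::write_tsv(run$series, file.path(dir, "motif_series.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$associations, file.path(dir, "associations.tsv"),
                   progress = FALSE)
  if (!is.null(run$chip)) {
    readr::write_tsv(run$chip, file.path(dir, "chip_validation.tsv"),
                     progress = FALSE)
  }
  manifest <- list(package_version = as.character(utils::packageVersion("valleytf")),
                   seed = seed, params = run$params,
                   cluster_lags = as.data.frame(run$lagfit$cluster_lags))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

match_clusters <- function(membership, truth_members) {
  found <- split(membership$gene_id, membership$cluster)
  planted <- split(truth_members$gene_id, truth_members$cluster)
  purrr::map_dfr(names(planted), function(tc) {
    jac <- vapply(found, function(g) {
      length(intersect(g, planted[[tc]])) / length(union(g, planted[[tc]]))
    }, numeric(1))
    tibble(true_cluster = tc, found_cluster = names(found)[which.max(jac)],
           jaccard = max(jac))
  })
}

#' Evaluate a pipeline run against simulation ground truth
#'
#' Matches each planted cluster to the recovered cluster with maximal
#' membership Jaccard index, then reports whether the planted regulator
#' motif ranks first by the max-minus-min score-range statistic in that
#' cluster and whether the sign of its optimal-lag correlation matches the
#' planted activator/repressor role.
#'
#' @param run A `valleytf_run`.
#' @param truth The `truth` element of [simulate_dataset()] output.
#' @return A tibble with one row per planted cluster: `true_cluster`,
#'   `found_cluster`, `jaccard`, `motif_id`, `rank`, `rank1` (logical),
#'   `r_opt`, `sign_ok`.
#' @export
evaluate_run <- function(run, truth) {
  matches <- match_clusters(run$clusters$membership, truth$members)
  ranks <- rank_motifs(run$series, method = "score_range")
  purrr::pmap_dfr(matches, function(true_cluster, found_cluster, jaccard) {
    info <- filter(truth$clusters, .data$cluster == true_cluster)
    rk <- ranks |>
      filter(.data$cluster == found_cluster,
             .data$motif_id == info$motif_id)
    res <- run$lagfit$results |>
      filter(.data$cluster == found_cluster,
             .data$motif_id == info$motif_id)
    r_opt <- if (nrow(res) == 1) res$r_opt else NA_real_
    tibble(
      true_cluster = true_cluster, found_cluster = found_cluster,
      jaccard = jaccard, motif_id = info$motif_id,
      rank = if (nrow(rk) == 1) rk$rank else NA_integer_,
      rank1 = !is.na(rank) && rank == 1,
      r_opt = r_opt,
      sign_ok = !is.na(r_opt) &&
        sign(r_opt) == if (info$role == "activator") 1 else -1
    )
  })
}
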