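# Validation of motif -> cluster predictions against TF ChIP-seq read
# counts, using a random-gene-set null distribution.

#' Count reads overlapping each gene's promoter window
#'
#' @param reads Read-interval tibble (`chrom`, `start`, `end`, 0-based
#'   half-open; strand ignored for counting).
#' @param genes Gene-model tibble.
#' @param upstream,downstream Strand-aware window relative to the TSS
#'   (defaults 2000 and 500).
#' @return A tibble `gene_id`, `count`.
#' @export
count_promoter_reads <- function(reads, genes, upstream = 2000,
                                 downstream = 500) {
  win <- promoter_windows(genes, upstream = upstream, downstream = downstream)
  if (nrow(reads) == 0) return(tibble(gene_id = win$gene_id, count = 0L))
  wgr <- GenomicRanges::GRanges(
    win$chrom, IRanges::IRanges(start = win$start + 1, end = win$end))
  rgr <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(start = reads$start + 1, end = reads$end))
  tibble(gene_id = win$gene_id,
         count = GenomicRanges::countOverlaps(wgr, rgr))
}

#' Count reads in valley regions near each gene's TSS
#'
#' Region-provider variant of [count_promoter_reads()]: reads are counted in
#' the gene's assigned valley (APR) intervals instead of a fixed promoter
#' window.
#'
#' @param reads Read-interval tibble.
#' @param aprs APR tibble (`gene_id`, `chrom`, `start`, `end`), e.g. from
#'   [assign_aprs()].
#' @param gene_ids Genes to report (defaults to all genes in `aprs`; genes
#'   without APRs get count 0).
#' @return A tibble `gene_id`, `count`.
#' @export
count_valley_reads <- function(reads, aprs, gene_ids = unique(aprs$gene_id)) {
  counts <- setNames(integer(length(gene_ids)), gene_ids)
  aprs <- filter(aprs, .data$gene_id %in% gene_ids)
  if (nrow(aprs) > 0 && nrow(reads) > 0) {
    agr <- GenomicRanges::GRanges(
      aprs$chrom, IRanges::IRanges(start = aprs$start + 1, end = aprs$end))
    rgr <- GenomicRanges::GRanges(
      reads$chrom, IRanges::IRanges(start = reads$start + 1, end = reads$end))
    per_region <- GenomicRanges::countOverlaps(agr, rgr)
    agg <- tapply(per_region, aprs$gene_id, sum)
    counts[names(agg)] <- as.integer(agg)
  }
  tibble(gene_id = gene_ids, count = as.integer(counts))
}

#' Build the random-gene-set null distribution of promoter read counts
#'
#' Draws `n_sets` random gene sets of size `set_size` (without replacement)
#' from the expressed-gene universe; each set's statistic is
#' `log2(1 + sum of counts)`. Returns the mean and standard deviation of the
#' statistic over the sets.
#'
#' @param counts Per-gene count tibble (`gene_id`, `count`).
#' @param universe Gene ids forming the expressed background universe.
#' @param set_size Size of each random set (the cluster size).
#' @param n_sets Number of random sets (default 1000).
#' @param seed Optional integer seed.
#' @return A list with `mu`, `sd`, `n_sets` and `degenerate` (`TRUE` when
#'   sd is 0, in which case z-scores are undefined).
#' @export
build_chip_null <- function(counts, universe, set_size, n_sets = 1000,
                            seed = NULL) {
  if (n_sets < 2) abort("`n_sets` must be at least 2")
  cnt <- setNames(counts$count, counts$gene_id)[universe]
  if (anyNA(cnt)) abort("universe contains genes without counts")
  if (length(universe) < set_size) {
    abort("universe smaller than the set size")
  }
  run <- function() {
    vapply(seq_len(n_sets), function(i) {
      log2(1 + sum(cnt[sample.int(length(cnt), set_size)]))
    }, numeric(1))
  }
  stat <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  s <- sd(stat)
  list(mu = mean(stat), sd = s, n_sets = n_sets, degenerate = s == 0)
}

#' Z-score enrichment of a gene set against a random-set null
#'
#' @param cluster_genes Gene ids in the cluster.
#' @param counts Per-gene count tibble.
#' @param null A null distribution from [build_chip_null()].
#' @return A tibble with `observed` (`log2(1 + sum counts)`), `mu`, `sd`,
#'   `z` and the two-tailed normal `p = 2 * (1 - pnorm(|z|))`; `z` and `p`
#'   are `NA` for a degenerate null.
#' @export
chip_enrichment_z <- function(cluster_genes, counts, null) {
  cnt <- setNames(counts$count, counts$gene_id)[cluster_genes]
  if (anyNA(cnt)) abort("cluster contains genes without counts")
  obs <- log2(1 + sum(cnt))
  if (null$degenerate) {
    return(tibble(observed = obs, mu = null$mu, sd = null$sd,
                  z = NA_real_, p = NA_real_))
  }
  z <- (obs - null$mu) / null$sd
  tibble(observed = obs, mu = null$mu, sd = null$sd, z = z,
         p = 2 * (1 - pnorm(abs(z))))
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p A vector of p-values.
#' @return The BH-adjusted q-values (same order as `p`).
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Validate motif predictions against TF ChIP-seq read counts
#'
#' For every TF, time point and cluster, compares the cluster's summed
#' promoter read counts with a random-gene-set null, yielding z, p and BH q.
#' The `predicted` flag marks (TF, time, cluster) cells where the TF's motif
#' was retained as enriched at that time point. The FDR family is all
#' non-degenerate tests in the run.
#'
#' @param tf_reads A tibble of TF ChIP reads with columns `tf`, `time`,
#'   `chrom`, `start`, `end`.
#' @param clusters A membership tibble (`gene_id`, `cluster`).
#' @param genes Gene-model tibble.
#' @param universe Expressed-gene ids for the null draws.
#' @param series Motif score series with `motif_id`, `cluster`, `time`, `p`
#'   (to derive `predicted`); may be `NULL`.
#' @param tf_motifs A tibble mapping `tf` to `motif_id`; required when
#'   `series` is given.
#' @param upstream,downstream Promoter window (defaults 2000/500).
#' @param n_sets Random sets per null (default 1000).
#' @param p_cut Motif-enrichment cutoff defining `predicted` (default 0.01).
#' @param aprs Optional APR tibble; when supplied, reads are counted in
#'   valley regions (see [count_valley_reads()]) instead of promoter windows.
#' @param seed Optional integer seed.
#' @return A tibble `tf`, `time`, `cluster`, `observed`, `mu`, `sd`, `z`,
#'   `p`, `q`, `predicted`.
#' @export
validate_chip <- function(tf_reads, clusters, genes, universe,
                          series = NULL, tf_motifs = NULL,
                          upstream = 2000, downstream = 500,
                          n_sets = 1000, p_cut = 0.01, aprs = NULL,
                          seed = NULL) {
  cluster_sets <- split(clusters$gene_id, clusters$cluster)
  combos <- distinct(tf_reads, .data$tf, .data$time)
  run <- function() {
    out <- list()
    for (i in seq_len(nrow(combos))) {
      tf_i <- combos$tf[i]; time_i <- combos$time[i]
      reads <- filter(tf_reads, .data$tf == tf_i, .data$time == time_i)
      counts <- if (is.null(aprs)) {
        count_promoter_reads(reads, genes, upstream, downstream)
      } else {
        count_valley_reads(reads, filter(aprs, .data$time == time_i),
                           gene_ids = genes$gene_id)
      }
      nulls <- list()
      for (cl in names(cluster_sets)) {
        sz <- length(cluster_sets[[cl]])
        key <- as.character(sz)
        if (is.null(nulls[[key]])) {
          nulls[[key]] <- build_chip_null(counts, universe, sz, n_sets)
        }
        res <- chip_enrichment_z(cluster_sets[[cl]], counts, nulls[[key]])
        out[[length(out) + 1]] <- bind_cols(
          tibble(tf = tf_i, time = time_i, cluster = cl), res)
      }
    }
    bind_rows(out)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  res$q <- NA_real_
  ok <- !is.na(res$p)
  res$q[ok] <- bh_adjust(res$p[ok])
  if (!is.null(series)) {
    if (is.null(tf_motifs)) abort("`tf_motifs` is required with `series`")
    pred <- series |>
      inner_join(tf_motifs, by = "motif_id",
                 relationship = "many-to-many") |>
      group_by(.data$tf, .data$cluster, .data$time) |>
      summarise(predicted = any(.data$p <= p_cut, na.rm = TRUE),
                .groups = "drop")
    res <- left_join(res, pred, by = c("tf", "cluster", "time")) |>
      mutate(predicted = tidyr::replace_na(.data$predicted, FALSE))
  }
  res
}

#' Concordance between motif scores and observed TF binding
#'
#' For each TF, computes the Pearson correlation between the motif raw score
#' and the observed `log2(1 + count)` statistic over (cluster, time) cells,
#' split by whether the cell was predicted (motif retained/enriched).
#'
#' @param chip_results Output of [validate_chip()] (with `predicted`).
#' @param series Motif score series tibble.
#' @param tf_motifs Mapping tibble `tf`, `motif_id`.
#' @return A tibble `tf`, `predicted`, `n_cells`, `r`.
#' @export
concordance_report <- function(chip_results, series, tf_motifs) {
  joined <- chip_results |>
    inner_join(tf_motifs, by = "tf", relationship = "many-to-many") |>
    inner_join(select(series, "motif_id", "cluster", "time", "raw_score"),
               by = c("motif_id", "cluster", "time"))
  joined |>
    group_by(.data$tf, .data$predicted) |>
    summarise(
      n_cells = dplyr::n(),
      r = if (dplyr::n() >= 3 && sd(.data$raw_score) > 0 &&
                sd(.data$observed) > 0) {
        cor(.data$raw_score, .data$observed)
      } else NA_real_,
      .groups = "drop"
    )
}
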