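# Generator checks run on a reduced-scale configuration so the full suite
# stays fast; the reference-scale run is exercised by the acceptance tests.
small_cfg <- function(...) {
  sim_config(n_chrom = 1, chrom_length = 6e5, n_genes = 30,
             n_unexpressed = 4, members_per_cluster = 5, n_motifs = 6, ...)
}

test_that("genome simulation is deterministic with disjoint TSS windows and
           the requested base composition", {
  cfg <- small_cfg()
  g1 <- simulate_genome(cfg, seed = 11)
  g2 <- simulate_genome(cfg, seed = 11)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$genes, g2$genes)
  g3 <- simulate_genome(cfg, seed = 12)
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))

  # disjoint +/-5 kbp windows
  tss <- sort(g1$genes$tss)
  expect_true(all(diff(tss) >= 10000))

  # base composition within 3 sigma of multinomial expectation
  f <- base_frequencies(as.character(g1$genome))
  n <- sum(Biostrings::width(g1$genome))
  expect_true(all(abs(f - 0.25) < 3 * sqrt(0.25 * 0.75 / n)))

  expect_error(sim_config(n_genes = 5000, chrom_length = 1e6),
               "too small")
})

test_that("noiseless synthetic tracks are recovered perfectly by the valley
           caller", {
  cfg <- small_cfg(signal_noise_sd = 0)
  sim <- simulate_dataset(cfg, seed = 21)
  tr0 <- dplyr::filter(sim$tracks, time == 0)
  sm <- smooth_coverage(tr0)
  calls <- call_valleys(sm)
  planted <- open_positions <- dplyr::bind_rows(
    dplyr::inner_join(sim$truth$sites,
                      dplyr::filter(sim$truth$levels, time == 0),
                      by = "cluster") |>
      dplyr::filter(site <= level) |> dplyr::select(chrom, pos),
    dplyr::select(sim$truth$empty_sites, chrom, pos))
  # recall: every planted open dip center is inside a call
  hit <- vapply(seq_len(nrow(planted)), function(i) {
    any(calls$chrom == planted$chrom[i] & calls$start <= planted$pos[i] &
          planted$pos[i] < calls$end)
  }, logical(1))
  expect_equal(mean(hit), 1)
  # precision: every call contains a planted center
  used <- vapply(seq_len(nrow(calls)), function(i) {
    any(planted$chrom == calls$chrom[i] & planted$pos >= calls$start[i] &
          planted$pos < calls$end[i])
  }, logical(1))
  expect_equal(mean(used), 1)
})

test_that("planted motif occupancy raises the target cluster's raw score at
           active times only", {
  cfg <- small_cfg(signal_noise_sd = 0)
  sim <- simulate_dataset(cfg, seed = 31)
  truth <- sim$truth
  cl <- truth$clusters$cluster[1]
  motif <- truth$motifs$mat[[which(truth$motifs$motif_id ==
                                     truth$clusters$motif_id[1])]]
  lev <- dplyr::filter(truth$levels, cluster == cl)
  t_hi <- lev$time[which.max(lev$level)]
  t_lo <- lev$time[which.min(lev$level)]
  members <- truth$members$gene_id[truth$members$cluster == cl]
  apr_seq_at <- function(t) {
    open <- dplyr::filter(valleytf:::open_sites(truth, t), gene_id %in% members)
    regions <- tibble::tibble(chrom = open$chrom, start = open$pos - 80,
                              end = open$pos + 80)
    extract_sequences(regions, sim$genome)$seq
  }
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  expect_gt(motif_raw_score(motif, apr_seq_at(t_hi), bg),
            motif_raw_score(motif, apr_seq_at(t_lo), bg))
  # embedded instances sit wholly inside their dip regions
  w <- ncol(motif)
  cons <- truth$motifs$consensus[[1]]
  site_seqs <- apr_seq_at(t_hi)
  expect_true(any(grepl(cons, site_seqs)))
})

test_that("simulated expression recovers DE members with high sensitivity
           and keeps filler genes null", {
  cfg <- small_cfg()
  sim <- simulate_dataset(cfg, seed = 41)
  st <- anova_permutation_q(sim$expr, sim$samples, n_perm = 200, seed = 1)
  fc <- fold_changes(sim$expr, sim$samples)
  de <- select_de(st, fc)
  members <- sim$truth$members$gene_id
  expect_gte(mean(members %in% de$gene_id), 0.95)
  filler <- setdiff(sim$genes$gene_id,
                    c(members, sim$truth$unexpressed))
  expect_lte(mean(filler %in% de$gene_id), 0.02)
  # unexpressed genes fall below the filter
  kept <- filter_expressed(sim$expr, sim$samples)$gene_id
  expect_false(any(sim$truth$unexpressed %in% kept))
})

test_that("TF read sets are enriched over target promoters at active
           times in proportion to occupancy", {
  cfg <- small_cfg()
  sim <- simulate_dataset(cfg, seed = 51)
  truth <- sim$truth
  cl <- truth$clusters$cluster[1]
  tf <- truth$clusters$tf[1]
  lev <- dplyr::filter(truth$levels, cluster == cl,
                       time %in% cfg$chip_times)
  t_hi <- lev$time[which.max(lev$level)]
  members <- truth$members$gene_id[truth$members$cluster == cl]
  reads <- dplyr::filter(sim$tf_reads, tf == !!tf, time == t_hi)
  counts <- count_promoter_reads(reads, sim$genes)
  in_cl <- counts$count[counts$gene_id %in% members]
  out_cl <- counts$count[!counts$gene_id %in% members]
  if (max(lev$level) > 0) {
    expect_gt(mean(in_cl), 1.5 * mean(out_cl))
  }
})

test_that("dataset writing emits readable pipeline formats with a
           ground-truth manifest", {
  cfg <- small_cfg(signal_noise_sd = 0)
  sim <- simulate_dataset(cfg, seed = 61)
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  expect_true(file.exists(file.path(dir, "genome.fa")))
  expect_true(file.exists(file.path(dir, "truth.json")))

  genes_back <- read_gene_models(file.path(dir, "genes.bed"))
  expect_equal(genes_back$tss, sim$genes$tss)
  expect_equal(genes_back$strand, sim$genes$strand)

  tr_back <- read_bedgraph(file.path(dir, "hac_t0.bedgraph"))
  tr0 <- dplyr::filter(sim$tracks, time == 0) |>
    dplyr::select(chrom, pos, value)
  merged <- dplyr::inner_join(tr_back, tr0, by = c("chrom", "pos"))
  expect_equal(nrow(merged), nrow(tr0))
  expect_equal(merged$value.x, merged$value.y, tolerance = 1e-9)

  motifs_back <- read_motifs(file.path(dir, "motifs.transfac"),
                             pseudocount = 0)
  expect_equal(motifs_back$motif_id, sim$motifs$motif_id)
  expect_equal(motifs_back$mat[[1]], sim$motifs$mat[[1]], tolerance = 2e-3,
               ignore_attr = TRUE)

  truth_back <- jsonlite::read_json(file.path(dir, "truth.json"),
                                    simplifyVector = TRUE)
  expect_setequal(truth_back$members$gene_id, sim$truth$members$gene_id)

  # full round trip into pipeline inputs
  data_back <- read_dataset(dir)
  expect_setequal(sort(unique(data_back$tracks$time)), cfg$signal_times)
  expect_equal(data_back$genes$gene_id, sim$genes$gene_id)
  expect_equal(dim(data_back$expr), dim(sim$expr))
  expect_setequal(unique(data_back$tf_reads$tf), sim$truth$clusters$tf)
  expect_equal(data_back$tf_motifs, sim$tf_motifs)
})
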