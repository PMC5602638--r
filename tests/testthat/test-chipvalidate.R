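test_that("promoter read counting is half-open and matches brute force", {
  g <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 2000,
                      strand = "+")
  # + strand window [0, 2500)
  r_in <- tibble::tibble(chrom = "chr1", start = 100, end = 150)
  expect_equal(count_promoter_reads(r_in, g)$count, 1)
  r_edge <- tibble::tibble(chrom = "chr1", start = 2500, end = 2550)
  expect_equal(count_promoter_reads(r_edge, g)$count, 0)

  withr::with_seed(121, {
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:15),
      chrom = sample(c("chr1", "chr2"), 15, replace = TRUE),
      tss = sample(3000:50000, 15),
      strand = sample(c("+", "-"), 15, replace = TRUE)
    )
    reads <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 300, replace = TRUE),
      start = sample(0:52000, 300, replace = TRUE)
    ) |> dplyr::mutate(end = start + 36)
  })
  got <- count_promoter_reads(reads, genes)
  win <- promoter_windows(genes, 2000, 500)
  brute <- vapply(seq_len(nrow(win)), function(i) {
    sum(reads$chrom == win$chrom[i] & reads$start < win$end[i] &
          reads$end > win$start[i])
  }, numeric(1))
  expect_equal(got$count, brute, ignore_attr = TRUE)
})

test_that("valley-restricted counting aggregates per gene", {
  aprs <- tibble::tibble(gene_id = c("g1", "g1", "g2"), chrom = "chr1",
                         start = c(100, 500, 900), end = c(200, 600, 1000))
  reads <- tibble::tibble(chrom = "chr1", start = c(120, 150, 950),
                          end = c(156, 186, 986))
  got <- count_valley_reads(reads, aprs)
  expect_equal(got$count[got$gene_id == "g1"], 2L)
  expect_equal(got$count[got$gene_id == "g2"], 1L)
})

test_that("the random-set null is centered where expected and degenerates
           on constant counts", {
  universe <- sprintf("g%03d", 1:200)
  const <- tibble::tibble(gene_id = universe, count = 5L)
  null_c <- build_chip_null(const, universe, set_size = 10, n_sets = 50,
                            seed = 1)
  expect_true(null_c$degenerate)
  res <- chip_enrichment_z(universe[1:10], const, null_c)
  expect_true(is.na(res$z))

  withr::with_seed(7, {
    counts <- tibble::tibble(gene_id = universe,
                             count = rpois(200, 20))
  })
  null_d <- build_chip_null(counts, universe, set_size = 20, n_sets = 400,
                            seed = 2)
  expect_equal(null_d$mu, log2(1 + 20 * mean(counts$count)),
               tolerance = 2 * null_d$sd / sqrt(400) / null_d$mu + 0.01)
  # relabeling invariance (same seed, shuffled gene ids)
  shuffled <- counts[withr::with_seed(3, sample(200)), ]
  null_e <- build_chip_null(shuffled, universe, set_size = 20, n_sets = 400,
                            seed = 2)
  expect_equal(null_e$mu, null_d$mu, tolerance = 3 * null_d$sd / sqrt(400))
})

test_that("z-scores convert to two-tailed normal p-values", {
  null <- list(mu = 10, sd = 1, n_sets = 100, degenerate = FALSE)
  counts <- tibble::tibble(gene_id = c("a", "b"), count = c(511, 512))
  res <- chip_enrichment_z("a", counts, null)  # log2(512) = 9 -> z = -1
  expect_equal(res$z, -1)
  expect_equal(res$p, 2 * (1 - pnorm(1)))
  # z = 1.959964 -> p ~ 0.05
  null2 <- list(mu = 0, sd = 1, n_sets = 100, degenerate = FALSE)
  counts2 <- tibble::tibble(gene_id = "a", count = 2^1.959964 - 1)
  expect_equal(chip_enrichment_z("a", counts2, null2)$p, 0.05,
               tolerance = 1e-6)
  # observed equal to mu -> z = 0, p = 1
  counts3 <- tibble::tibble(gene_id = "a", count = 2^10 - 1)
  res3 <- chip_enrichment_z("a", counts3, null)
  expect_equal(res3$z, 0)
  expect_equal(res3$p, 1)
})

test_that("BH adjustment equals the hand step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  withr::with_seed(131, {
    for (i in 1:20) {
      p <- runif(sample(1:50, 1))
      q <- bh_adjust(p)
      expect_equal(q, oracle_bh(p))
      expect_true(all(q >= p))
      expect_true(all(diff(q[order(p)]) >= -1e-15))
    }
  })
})

test_that("planted read enrichment yields large z and small q; uniform
           reads do not", {
  withr::with_seed(141, {
    genes <- tibble::tibble(
      gene_id = sprintf("g%03d", 1:100),
      chrom = "chr1",
      tss = 5000 + (0:99) * 10000,
      strand = "+"
    )
    cluster_genes <- genes$gene_id[1:15]
    # uniform reads everywhere
    n_reads <- 20000
    reads_u <- tibble::tibble(
      chrom = "chr1", start = sample(0:1e6, n_reads, replace = TRUE)
    ) |> dplyr::mutate(end = start + 36)
    # double the reads over the cluster promoters
    win <- promoter_windows(genes[1:15, ], 2000, 500)
    extra <- purrr::map_dfr(seq_len(nrow(win)), function(i) {
      tibble::tibble(chrom = "chr1",
                     start = round(runif(50, win$start[i], win$end[i] - 36)))
    }) |> dplyr::mutate(end = start + 36)
  })
  counts_u <- count_promoter_reads(reads_u, genes)
  null <- build_chip_null(counts_u, genes$gene_id, 15, n_sets = 500,
                          seed = 4)
  res_u <- chip_enrichment_z(cluster_genes, counts_u, null)
  expect_lt(abs(res_u$z), 4)

  counts_e <- count_promoter_reads(dplyr::bind_rows(reads_u, extra), genes)
  null_e <- build_chip_null(counts_e, genes$gene_id, 15, n_sets = 500,
                            seed = 4)
  res_e <- chip_enrichment_z(cluster_genes, counts_e, null_e)
  expect_gt(res_e$z, 4)
  expect_lt(res_e$p, 0.01)
})

test_that("validate_chip produces one row per TF x time x cluster with
           concordance by prediction status", {
  withr::with_seed(151, {
    genes <- tibble::tibble(
      gene_id = sprintf("g%03d", 1:60), chrom = "chr1",
      tss = 5000 + (0:59) * 11000, strand = "+")
    clusters <- tibble::tibble(gene_id = genes$gene_id[1:20],
                               cluster = rep(c("UC1", "DC1"), each = 10))
    tf_reads <- purrr::map_dfr(c(0, 2), function(t) {
      tibble::tibble(tf = "TF_X", time = t, chrom = "chr1",
                     start = sample(0:6.5e5, 3000, replace = TRUE)) |>
        dplyr::mutate(end = start + 36, strand = "+")
    })
    series <- tidyr::expand_grid(motif_id = "V$X", cluster = c("UC1", "DC1"),
                                 time = c(0, 2)) |>
      dplyr::mutate(raw_score = runif(4, 0, 2),
                    p = c(0.001, 0.5, 0.001, 0.5), retained = TRUE)
  })
  tf_motifs <- tibble::tibble(tf = "TF_X", motif_id = "V$X")
  res <- validate_chip(tf_reads, clusters, genes, genes$gene_id,
                       series = series, tf_motifs = tf_motifs,
                       n_sets = 200, seed = 6)
  expect_equal(nrow(res), 1 * 2 * 2)   # TFs x times x clusters
  expect_true(all(c("observed", "mu", "sd", "z", "p", "q", "predicted") %in%
                    names(res)))
  expect_true(all(res$q >= res$p - 1e-12))
  conc <- concordance_report(res, series, tf_motifs)
  expect_true(all(conc$n_cells >= 1))
})
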