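uniform_bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

test_that("TRANSFAC parsing applies the pseudocount and round-trips", {
  path <- withr::local_tempfile(fileext = ".dat")
  writeLines(c(
    "AC  M00001", "XX", "ID  V$TEST_01", "XX",
    "P0      A      C      G      T",
    "01     10      0      0      0 A",
    "02      0      5      5      0 S",
    "XX", "//"
  ), path)
  m <- read_motifs(path, "transfac", pseudocount = 0.25)
  expect_equal(m$motif_id, "V$TEST_01")
  expect_equal(m$width, 2L)
  expect_equal(unname(m$mat[[1]]["A", 1]), 10.25 / 11)  # (10+0.25)/(10+1)
  expect_equal(colSums(m$mat[[1]]), c(1, 1), ignore_attr = TRUE)

  # round trip through the writer
  out <- withr::local_tempfile(fileext = ".dat")
  write_motifs_transfac(m, out, scale = 44)  # 44 * probs are integers
  back <- read_motifs(out, "transfac", pseudocount = 0)
  expect_equal(back$mat[[1]], m$mat[[1]], tolerance = 1e-12)
})

test_that("MEME and TRANSFAC encodings of the same motif agree", {
  counts <- matrix(c(8, 1, 1, 0,
                     0, 9, 0, 1), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  tf_path <- withr::local_tempfile(fileext = ".dat")
  writeLines(c(
    "AC  V$X", "XX", "P0      A      C      G      T",
    sprintf("01  %d %d %d %d", counts[1, 1], counts[2, 1], counts[3, 1],
            counts[4, 1]),
    sprintf("02  %d %d %d %d", counts[1, 2], counts[2, 2], counts[3, 2],
            counts[4, 2]),
    "//"), tf_path)
  meme_path <- withr::local_tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", "",
    "MOTIF V$X",
    "letter-probability matrix: alength= 4 w= 2 nsites= 10 E= 0",
    paste(counts[, 1] / 10, collapse = " "),
    paste(counts[, 2] / 10, collapse = " ")), meme_path)
  a <- read_motifs(tf_path, "transfac")
  b <- read_motifs(meme_path, "meme")
  expect_equal(a$mat[[1]], b$mat[[1]], tolerance = 1e-12)
  expect_error(read_motifs(withr::local_tempfile(fileext = ".x",
                                                 lines = "nothing"),
                           "meme"), "MOTIF")
})

test_that("the average likelihood ratio enumerates both strands", {
  # w = 1, P(A) = 1, uniform background, "AAAA": forward LR 4 each,
  # reverse-strand placements score 0 -> (4*4 + 0) / 8 = 2
  pwm_a <- make_pwm(c(1, 0, 0, 0))
  expect_equal(sequence_alr(pwm_a, "AAAA", uniform_bg), 2)
  expect_equal(motif_raw_score(pwm_a, "AAAA", uniform_bg), log(2))

  # background-equal PWM scores exactly 1 / 0 on anything
  pwm_bg <- make_pwm(rep(0.25, 4), rep(0.25, 4), rep(0.25, 4))
  expect_equal(sequence_alr(pwm_bg, "ACGTTGCA", uniform_bg), 1)
  expect_equal(motif_raw_score(pwm_bg, c("ACGTTGCA", "TTTTGGGA"),
                               uniform_bg), 0)

  # strand symmetry: ALR(seq) == ALR(reverse complement)
  pwm <- make_pwm(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.1, 0.7, 0.1),
                  c(0.25, 0.25, 0.25, 0.25))
  s <- "ACGTAGGCTAAC"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(sequence_alr(pwm, s, uniform_bg),
               sequence_alr(pwm, rc, uniform_bg), tolerance = 1e-12)
})

test_that("raw scores equal exhaustive placement enumeration", {
  withr::with_seed(71, {
    for (rep in 1:6) {
      w <- sample(2:12, 1)
      counts <- matrix(rpois(4 * w, 5), nrow = 4)
      rownames(counts) <- c("A", "C", "G", "T")
      mat <- sweep(counts + 0.375, 2, colSums(counts + 0.375), "/")
      bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
      seqs <- vapply(1:4, function(i) {
        paste(sample(c("A", "C", "G", "T"), sample(w:50, 1),
                     replace = TRUE), collapse = "")
      }, character(1))
      expect_equal(motif_raw_score(mat, seqs, bg),
                   oracle_raw_score(mat, seqs, bg), tolerance = 1e-9)
    }
  })
})

test_that("ambiguous bases are neutral and short sequences are skipped", {
  pwm_a <- make_pwm(c(1, 0, 0, 0), c(1, 0, 0, 0))
  # "NN" contributes LR 1 per placement on both strands
  expect_equal(sequence_alr(pwm_a, "NN", uniform_bg), 1)
  expect_warning(
    sc <- motif_raw_score(pwm_a, c("A", "AAA"), uniform_bg), "skipped")
  expect_equal(sc, motif_raw_score(pwm_a, "AAA", uniform_bg))
  # duplicating every sequence leaves the mean score unchanged
  seqs <- c("AATTGC", "GGAATC")
  expect_equal(motif_raw_score(pwm_a, c(seqs, seqs), uniform_bg),
               motif_raw_score(pwm_a, seqs, uniform_bg))
})

test_that("enrichment p-values hit the floor when the target dominates and
           are invariant to background relabeling", {
  withr::with_seed(81, {
    bg_seqs <- vapply(1:40, function(i) {
      paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    }, character(1))
  })
  pwm <- make_pwm(c(0.97, 0.01, 0.01, 0.01), c(0.01, 0.01, 0.01, 0.97),
                  c(0.97, 0.01, 0.01, 0.01))
  target <- c("GGATAGGGATAGGGATAGGGATAGGGATAG",
              "ATAGGATAGGATAGGATAGGATAGGATAGG")
  res <- motif_enrichment(pwm, target, bg_seqs, n_draws = 200, seed = 4)
  expect_equal(res$p, 1 / 201)
  res2 <- motif_enrichment(pwm, target, rev(bg_seqs), n_draws = 200,
                           seed = 4)
  expect_equal(res2$p, res$p)
  expect_error(motif_enrichment(pwm, bg_seqs, target), "smaller")
})

test_that("score series flag planted temporal enrichment and rank it by
           score range", {
  withr::with_seed(91, {
    bg_seqs <- vapply(1:60, function(i) {
      paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    }, character(1))
    rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")
    planted <- "GGATACCGAT"
    apr <- purrr::map_dfr(c(0, 1, 2, 4), function(t) {
      n_inst <- c(`0` = 0, `1` = 2, `2` = 4, `4` = 4)[[as.character(t)]]
      seqs <- vapply(1:8, function(i) {
        s <- rand_seq(60)
        if (i <= n_inst) {
          substr(s, 20, 29) <- planted
        }
        s
      }, character(1))
      tibble::tibble(cluster = "C1", time = t, seq = seqs)
    })
  })
  consensus_pwm <- make_pwm(
    c(0.01, 0.01, 0.97, 0.01), c(0.01, 0.01, 0.97, 0.01),
    c(0.97, 0.01, 0.01, 0.01), c(0.01, 0.01, 0.01, 0.97),
    c(0.97, 0.01, 0.01, 0.01), c(0.01, 0.97, 0.01, 0.01),
    c(0.01, 0.97, 0.01, 0.01), c(0.01, 0.01, 0.97, 0.01),
    c(0.97, 0.01, 0.01, 0.01), c(0.01, 0.01, 0.01, 0.97))
  decoy <- make_pwm(
    c(0.01, 0.97, 0.01, 0.01), c(0.01, 0.01, 0.01, 0.97),
    c(0.01, 0.97, 0.01, 0.01), c(0.97, 0.01, 0.01, 0.01),
    c(0.01, 0.01, 0.01, 0.97), c(0.01, 0.97, 0.01, 0.01),
    c(0.97, 0.01, 0.01, 0.01), c(0.01, 0.01, 0.97, 0.01),
    c(0.01, 0.01, 0.01, 0.97), c(0.01, 0.97, 0.01, 0.01))
  motifs <- tibble::tibble(motif_id = c("PLANTED", "DECOY"), width = 10L,
                           mat = list(consensus_pwm, decoy))
  series <- score_motif_series(motifs, apr, bg_seqs, n_draws = 200, seed = 5)
  planted_series <- dplyr::filter(series, motif_id == "PLANTED")
  expect_true(all(planted_series$retained))
  expect_gt(planted_series$raw_score[planted_series$time == 4],
            planted_series$raw_score[planted_series$time == 0])
  expect_false(any(dplyr::filter(series, motif_id == "DECOY")$retained))

  ranked <- rank_motifs(dplyr::mutate(series, retained = TRUE),
                        method = "score_range")
  expect_equal(ranked$motif_id[ranked$rank == 1], "PLANTED")
  # score_range oracle: direct max - min
  direct <- max(planted_series$raw_score) - min(planted_series$raw_score)
  expect_equal(ranked$statistic[ranked$motif_id == "PLANTED"], direct)
})

test_that("constant series rank last and ranking methods validate input", {
  series <- tibble::tibble(
    motif_id = rep(c("A_var", "B_const"), each = 2),
    cluster = "C1", time = rep(c(0, 4), 2),
    raw_score = c(0, 3, 1, 1), p = 0.001, retained = TRUE
  )
  rk <- rank_motifs(series, "score_range")
  expect_equal(rk$rank[rk$motif_id == "B_const"], 2)
  expect_error(rank_motifs(series, "score_at_peak"), "medians")
  expect_error(rank_motifs(series, "lag_correlation"), "lag_results")
})

test_that("base frequencies sum to one and reflect composition", {
  f <- base_frequencies(c("AACC", "GGTT"))
  expect_equal(sum(f), 1)
  expect_equal(unname(f["A"]), 0.25)
})
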