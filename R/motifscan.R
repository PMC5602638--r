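# PWM handling and Clover-style log-average-likelihood enrichment scoring.
#
# A motif set is a tibble with columns motif_id, width, and a list-column
# `mat` of 4 x w probability matrices (rows A, C, G, T; columns sum to 1).

DNA_BASES <- c("A", "C", "G", "T")

pwm_from_counts <- function(counts, pseudocount = 0.375) {
  counts <- counts + pseudocount
  sweep(counts, 2, colSums(counts), "/")
}

check_pwm <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) != 4 || ncol(mat) < 1) {
    abort("a PWM must be a 4 x w matrix")
  }
  if (any(abs(colSums(mat) - 1) > 1e-9)) {
    abort("PWM columns must sum to 1")
  }
  invisible(mat)
}

#' Read position-weight matrices
#'
#' Parses TRANSFAC flat files or MEME minimal files into a motif tibble.
#' Count matrices (TRANSFAC, or MEME probabilities scaled back by `nsites`)
#' are converted to probabilities after adding `pseudocount` to every cell.
#'
#' @param path Path to the motif file.
#' @param format `"transfac"` or `"meme"`.
#' @param pseudocount Count added to every matrix cell before normalization
#'   (default 0.375).
#' @return A tibble with columns `motif_id`, `width`, `mat` (list of 4 x w
#'   probability matrices, rows A/C/G/T).
#' @export
read_motifs <- function(path, format = c("transfac", "meme"),
                        pseudocount = 0.375) {
  format <- match.arg(format)
  switch(format,
         transfac = read_motifs_transfac(path, pseudocount),
         meme = read_motifs_meme(path, pseudocount))
}

read_motifs_transfac <- function(path, pseudocount = 0.375) {
  lines <- readLines(path)
  out <- list()
  id <- NULL; ac <- NULL; rows <- list(); in_matrix <- FALSE
  flush <- function() {
    if (length(rows) == 0) return(NULL)
    counts <- t(do.call(rbind, rows))
    rownames(counts) <- DNA_BASES
    mid <- if (!is.null(id)) id else ac
    if (is.null(mid)) abort("TRANSFAC block without ID or AC line")
    list(motif_id = mid, mat = pwm_from_counts(counts, pseudocount))
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    tag <- substr(ln, 1, 2)
    if (tag == "AC") ac <- trimws(substr(ln, 3, nchar(ln)))
    if (tag == "ID") id <- trimws(substr(ln, 3, nchar(ln)))
    if (tag == "P0" || tag == "PO") { in_matrix <- TRUE; next }
    if (grepl("^[0-9]+\\s", ln) && in_matrix) {
      fields <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(fields) < 5) {
        abort(sprintf("malformed TRANSFAC matrix row for motif %s at line %d",
                      if (is.null(id)) ac else id, i))
      }
      vals <- suppressWarnings(as.numeric(fields[2:5]))
      if (any(is.na(vals))) {
        abort(sprintf("non-numeric TRANSFAC counts for motif %s at line %d",
                      if (is.null(id)) ac else id, i))
      }
      rows[[length(rows) + 1]] <- vals
    }
    if (tag == "//") {
      m <- flush()
      if (!is.null(m)) out[[length(out) + 1]] <- m
      id <- NULL; ac <- NULL; rows <- list(); in_matrix <- FALSE
    }
  }
  m <- flush()
  if (!is.null(m)) out[[length(out) + 1]] <- m
  if (length(out) == 0) abort("no motifs found in TRANSFAC file")
  tibble(
    motif_id = vapply(out, `[[`, character(1), "motif_id"),
    width = vapply(out, function(x) ncol(x$mat), integer(1)),
    mat = lapply(out, `[[`, "mat")
  )
}

read_motifs_meme <- function(path, pseudocount = 0.375) {
  lines <- readLines(path)
  motif_starts <- grep("^MOTIF\\s", lines)
  if (length(motif_starts) == 0) abort("no MOTIF blocks in MEME file")
  out <- list()
  for (s in motif_starts) {
    mid <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr_i <- s + which(grepl("^letter-probability matrix",
                             lines[(s + 1):length(lines)]))[1]
    if (is.na(hdr_i)) {
      abort(sprintf("motif %s: missing letter-probability header near line %d",
                    mid, s))
    }
    hdr <- lines[hdr_i]
    w <- as.integer(sub(".*w=\\s*([0-9]+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr)) {
      as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr))
    } else 20
    rows <- lines[(hdr_i + 1):(hdr_i + w)]
    counts <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]) * nsites
    }, numeric(4), USE.NAMES = FALSE))
    counts <- t(counts)
    rownames(counts) <- DNA_BASES
    out[[length(out) + 1]] <- list(motif_id = mid,
                                   mat = pwm_from_counts(counts, pseudocount))
  }
  tibble(
    motif_id = vapply(out, `[[`, character(1), "motif_id"),
    width = vapply(out, function(x) ncol(x$mat), integer(1)),
    mat = lapply(out, `[[`, "mat")
  )
}

#' Write motifs as a TRANSFAC flat file
#'
#' Writes integer-scaled count matrices (probabilities scaled by `scale`)
#' so files round-trip through [read_motifs()].
#'
#' @param motifs A motif tibble (`motif_id`, `mat`).
#' @param path Output path.
#' @param scale Total count per column (default 1000).
#' @export
write_motifs_transfac <- function(motifs, path, scale = 1000) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(motifs))) {
    mat <- motifs$mat[[i]]
    writeLines(c(sprintf("AC  %s", motifs$motif_id[i]),
                 "XX",
                 sprintf("ID  %s", motifs$motif_id[i]),
                 "XX",
                 "P0      A      C      G      T"), con)
    counts <- round(mat * scale)
    for (j in seq_len(ncol(mat))) {
      cons <- DNA_BASES[which.max(mat[, j])]
      writeLines(sprintf("%02d  %6d %6d %6d %6d %s", j,
                         counts[1, j], counts[2, j], counts[3, j],
                         counts[4, j], cons), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

encode_dna <- function(seq) {
  v <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  v[is.na(v)] <- 5L  # ambiguity code: neutral
  v
}

#' Base frequencies of a sequence set
#'
#' @param seqs Character vector of DNA sequences.
#' @return Named numeric vector of A/C/G/T frequencies (ambiguous bases
#'   excluded).
#' @export
base_frequencies <- function(seqs) {
  tab <- table(factor(unlist(strsplit(toupper(paste(seqs, collapse = "")),
                                      "")), levels = DNA_BASES))
  f <- as.numeric(tab) / sum(tab)
  setNames(f, DNA_BASES)
}

# log likelihood-ratio lookup with a neutral 5th row for N
lr_table <- function(mat, bg) {
  rbind(log(mat) - log(bg), rep(0, ncol(mat)))
}

revcomp_pwm <- function(mat) {
  mat[4:1, rev(seq_len(ncol(mat))), drop = FALSE]
}

alr_one <- function(lr_fwd, lr_rev, enc) {
  w <- ncol(lr_fwd)
  np <- length(enc) - w + 1
  if (np < 1) return(NA_real_)
  sf <- numeric(np); sr <- numeric(np)
  for (j in seq_len(w)) {
    b <- enc[j:(j + np - 1)]
    sf <- sf + lr_fwd[b, j]
    sr <- sr + lr_rev[b, j]
  }
  (sum(exp(sf)) + sum(exp(sr))) / (2 * np)
}

#' Average likelihood ratio of a PWM over one sequence
#'
#' The mean, over all placements of the motif on both strands, of the
#' likelihood ratio of the PWM against the background base composition
#' (the pre-log per-sequence quantity behind the Clover-style raw score).
#' Ambiguous bases (N) contribute a neutral likelihood ratio of 1 at their
#' position.
#'
#' @param mat 4 x w probability matrix (rows A/C/G/T).
#' @param seq A DNA string of length >= w.
#' @param bg Background base frequencies (length-4, A/C/G/T order).
#' @return The average likelihood ratio (a positive real), or `NA` if the
#'   sequence is shorter than the motif.
#' @export
sequence_alr <- function(mat, seq, bg) {
  check_pwm(mat)
  # reverse-strand placements read the complemented bases, so their
  # background likelihood uses the complemented frequencies (bg is in
  # A/C/G/T order; complementation reverses it)
  lr_fwd <- lr_table(mat, bg)
  lr_rev <- lr_table(revcomp_pwm(mat), rev(as.numeric(bg)))
  alr_one(lr_fwd, lr_rev, encode_dna(seq))
}

alr_set <- function(mat, seqs, bg) {
  lr_fwd <- lr_table(mat, bg)
  lr_rev <- lr_table(revcomp_pwm(mat), rev(as.numeric(bg)))
  vapply(seqs, function(s) alr_one(lr_fwd, lr_rev, encode_dna(s)),
         numeric(1), USE.NAMES = FALSE)
}

#' Log-average-likelihood raw enrichment score of a motif on a sequence set
#'
#' The natural log of the mean [sequence_alr()] over the set. Sequences
#' shorter than the motif are skipped with a warning; regions are always
#' scored independently (no placements across region boundaries).
#'
#' @param mat 4 x w probability matrix.
#' @param seqs Character vector of region sequences.
#' @param bg Background base frequencies.
#' @return The raw score (0 for a PWM equal to the background composition).
#' @export
motif_raw_score <- function(mat, seqs, bg) {
  alr <- alr_set(mat, seqs, bg)
  if (any(is.na(alr))) {
    warn(sprintf("%d sequence(s) shorter than the motif were skipped",
                 sum(is.na(alr))))
    alr <- alr[!is.na(alr)]
  }
  if (length(alr) == 0) return(NA_real_)
  log(mean(alr))
}

# Total-length matching is only attempted when a size-n background subset
# can reach the target total within tolerance (e.g. promoter-vs-promoter
# draws); when the length distributions are structurally disjoint (short
# valley regions versus full-length promoters) plain subsets are drawn.
draw_matched_subset <- function(bg_lengths, n, target_total, tol = 0.1,
                                max_tries = 50) {
  reachable <- target_total >= (1 - tol) * n * min(bg_lengths) &&
    target_total <= (1 + tol) * n * max(bg_lengths)
  if (!reachable) return(sample.int(length(bg_lengths), n))
  best <- NULL; best_diff <- Inf
  for (tr in seq_len(max_tries)) {
    idx <- sample.int(length(bg_lengths), n)
    tot <- sum(bg_lengths[idx])
    d <- abs(tot - target_total) / target_total
    if (d <= tol) return(idx)
    if (d < best_diff) { best_diff <- d; best <- idx }
  }
  best
}

#' Resampling enrichment p-value of a motif in a target sequence set
#'
#' Compares the observed raw score on the target set to raw scores of
#' `n_draws` random background subsets of the same size (total length
#' matched within `length_tol`), giving
#' `p = (1 + #{draws >= observed}) / (n_draws + 1)`.
#'
#' @param mat 4 x w probability matrix.
#' @param target_seqs Target region sequences.
#' @param bg_seqs Background sequences (at least as many as targets).
#' @param bg Background base frequencies (defaults to frequencies of
#'   `bg_seqs`).
#' @param n_draws Number of background draws (default 1000).
#' @param length_tol Relative tolerance for total-length matching of draws
#'   (default 0.1).
#' @param seed Optional integer seed.
#' @return A list with `raw_score` and `p`.
#' @export
motif_enrichment <- function(mat, target_seqs, bg_seqs, bg = NULL,
                             n_draws = 1000, length_tol = 0.1, seed = NULL) {
  if (length(bg_seqs) < length(target_seqs)) {
    abort("background set smaller than target set")
  }
  if (is.null(bg)) bg <- base_frequencies(bg_seqs)
  alr_t <- alr_set(mat, target_seqs, bg)
  alr_t <- alr_t[!is.na(alr_t)]
  if (length(alr_t) == 0) abort("no scorable target sequences")
  alr_b <- alr_set(mat, bg_seqs, bg)
  keep <- !is.na(alr_b)
  alr_b <- alr_b[keep]
  bg_lengths <- nchar(bg_seqs)[keep]
  obs <- mean(alr_t)
  target_total <- sum(nchar(target_seqs))
  run <- function() {
    hits <- 0L
    n <- length(alr_t)
    for (d in seq_len(n_draws)) {
      idx <- draw_matched_subset(bg_lengths, n, target_total, length_tol)
      if (mean(alr_b[idx]) >= obs) hits <- hits + 1L
    }
    hits
  }
  hits <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(raw_score = log(obs), p = (1 + hits) / (n_draws + 1))
}

#' Score every motif in every cluster at every time point
#'
#' For each motif and cluster, computes the Clover-style raw score and the
#' background-resampling enrichment p-value of the cluster's APR sequences at
#' each time point, and flags the (motif, cluster) series as retained when
#' the minimum p over time points is at most `p_cut`.
#'
#' @param motifs Motif tibble (`motif_id`, `mat`).
#' @param apr_seqs A tibble with columns `cluster`, `time`, `seq` (one row
#'   per APR region sequence).
#' @param bg_seqs Background sequences (expressed-gene promoters).
#' @param n_draws Background draws per cell (default 1000).
#' @param p_cut Retention p-value cutoff (default 0.01).
#' @param length_tol Relative total-length tolerance for draws (default 0.1).
#' @param seed Optional integer seed.
#' @return A tibble `motif_id`, `cluster`, `time`, `raw_score`, `p`,
#'   `retained`. Cells with no scorable sequence get `NA` scores and never
#'   drive retention.
#' @export
score_motif_series <- function(motifs, apr_seqs, bg_seqs, n_draws = 1000,
                               p_cut = 0.01, length_tol = 0.1, seed = NULL) {
  bg <- base_frequencies(bg_seqs)
  cells <- distinct(apr_seqs, .data$cluster, .data$time)
  run <- function() {
    res <- vector("list", nrow(motifs))
    for (i in seq_len(nrow(motifs))) {
      mat <- motifs$mat[[i]]
      alr_b <- alr_set(mat, bg_seqs, bg)
      keep <- !is.na(alr_b)
      alr_bk <- alr_b[keep]
      bg_lengths <- nchar(bg_seqs)[keep]
      rows <- purrr::pmap(cells, function(cluster, time) {
        seqs <- apr_seqs$seq[apr_seqs$cluster == cluster &
                               apr_seqs$time == time]
        alr_t <- alr_set(mat, seqs, bg)
        alr_t <- alr_t[!is.na(alr_t)]
        if (length(alr_t) == 0 || length(alr_t) > length(alr_bk)) {
          return(tibble(motif_id = motifs$motif_id[i], cluster = cluster,
                        time = time, raw_score = NA_real_, p = NA_real_))
        }
        obs <- mean(alr_t)
        total <- sum(nchar(seqs))
        hits <- 0L
        for (d in seq_len(n_draws)) {
          idx <- draw_matched_subset(bg_lengths, length(alr_t), total,
                                     length_tol)
          if (mean(alr_bk[idx]) >= obs) hits <- hits + 1L
        }
        tibble(motif_id = motifs$motif_id[i], cluster = cluster, time = time,
               raw_score = log(obs), p = (1 + hits) / (n_draws + 1))
      })
      res[[i]] <- bind_rows(rows)
    }
    bind_rows(res)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out |>
    group_by(.data$motif_id, .data$cluster) |>
    mutate(retained = any(.data$p <= p_cut, na.rm = TRUE)) |>
    ungroup()
}

#' Rank retained motifs within each cluster
#'
#' @param series Output of [score_motif_series()] (or a compatible tibble).
#' @param method Ranking statistic: `"score_range"` (max - min raw score over
#'   time, the default), `"max_score"`, `"score_at_peak"` (raw score at the
#'   time point closest to the cluster's peak median expression) or
#'   `"lag_correlation"` (|R| at the optimal lag; needs `lag_results`).
#' @param medians Cluster median profiles (`cluster`, `time`, `median`),
#'   required for `"score_at_peak"`.
#' @param lag_results A lag-correlation tibble (`motif_id`, `cluster`,
#'   `r_opt`), required for `"lag_correlation"`.
#' @return A tibble `motif_id`, `cluster`, `statistic`, `rank` (rank 1 =
#'   top), ranked within cluster; ties broken lexicographically by motif id.
#' @export
rank_motifs <- function(series, method = c("score_range", "max_score",
                                           "score_at_peak",
                                           "lag_correlation"),
                        medians = NULL, lag_results = NULL) {
  method <- match.arg(method)
  retained <- filter(series, .data$retained, !is.na(.data$raw_score))
  stat <- switch(
    method,
    score_range = retained |>
      group_by(.data$motif_id, .data$cluster) |>
      summarise(statistic = max(.data$raw_score) - min(.data$raw_score),
                .groups = "drop"),
    max_score = retained |>
      group_by(.data$motif_id, .data$cluster) |>
      summarise(statistic = max(.data$raw_score), .groups = "drop"),
    score_at_peak = {
      if (is.null(medians)) abort("`medians` is required for score_at_peak")
      peaks <- medians |>
        group_by(.data$cluster) |>
        summarise(peak_time = .data$time[which.max(abs(.data$median))],
                  .groups = "drop")
      retained |>
        inner_join(peaks, by = "cluster") |>
        group_by(.data$motif_id, .data$cluster) |>
        summarise(statistic =
                    .data$raw_score[which.min(abs(.data$time -
                                                    .data$peak_time))],
                  .groups = "drop")
    },
    lag_correlation = {
      if (is.null(lag_results)) {
        abort("`lag_results` is required for lag_correlation")
      }
      retained |>
        distinct(.data$motif_id, .data$cluster) |>
        inner_join(lag_results, by = c("motif_id", "cluster")) |>
        transmute(.data$motif_id, .data$cluster,
                  statistic = abs(.data$r_opt))
    }
  )
  stat |>
    group_by(.data$cluster) |>
    arrange(desc(.data$statistic), .data$motif_id, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
}
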