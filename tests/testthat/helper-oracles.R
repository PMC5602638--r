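# Independent reference implementations used as oracles. These are written
# as literal, loop-based transcriptions of the definitions and share no code
# with the package internals.

# per-bp coverage of a read set over [0, max_end), point-sampled at grid
# starts
oracle_coverage_at <- function(reads, positions) {
  vapply(positions, function(p) {
    sum(reads$start <= p & p < reads$end)
  }, numeric(1))
}

# naive O(n*k) Gaussian smoothing with local kernel-mass renormalization
oracle_smooth <- function(x, sigma, step, halfwidth_sd = 4) {
  half <- ceiling(halfwidth_sd * sigma / step)
  k <- dnorm(seq(-half, half) * step, sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    js <- max(1, i - half):min(n, i + half)
    w <- k[js - i + half + 1]
    out[i] <- sum(w * x[js]) / sum(w)
  }
  out
}

# exhaustive per-point flanking maxima (bp window [near, far] to each side)
oracle_flanks <- function(pos, value, near, far) {
  n <- length(pos)
  left <- rep(-Inf, n); right <- rep(-Inf, n)
  for (i in seq_len(n)) {
    lw <- value[pos >= pos[i] - far & pos <= pos[i] - near]
    rw <- value[pos >= pos[i] + near & pos <= pos[i] + far]
    if (length(lw) > 0) left[i] <- max(lw)
    if (length(rw) > 0) right[i] <- max(rw)
  }
  list(left = left, right = right)
}

# literal per-point valley rule applied to a single-chromosome track,
# followed by merging of consecutive valley points
oracle_call_valleys <- function(pos, value, near, far, dip_fraction, step) {
  fl <- oracle_flanks(pos, value, near, far)
  vmin <- pmin(fl$left, fl$right)
  is_valley <- is.finite(vmin) & value < dip_fraction * vmin
  calls <- data.frame(start = numeric(), end = numeric(), score = numeric())
  i <- 1
  n <- length(pos)
  while (i <= n) {
    if (is_valley[i]) {
      j <- i
      while (j < n && is_valley[j + 1]) j <- j + 1
      calls <- rbind(calls, data.frame(start = pos[i], end = pos[j] + step,
                                       score = max(vmin[i:j])))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  calls
}

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# exhaustive placement enumeration of the log-average-likelihood score
oracle_raw_score <- function(mat, seqs, bg) {
  w <- ncol(mat)
  alrs <- vapply(seqs, function(s) {
    chars <- strsplit(toupper(s), "")[[1]]
    L <- length(chars)
    if (L < w) return(NA_real_)
    np <- L - w + 1
    tot <- 0
    for (i in seq_len(np)) {
      pf <- 1; pr <- 1
      for (j in seq_len(w)) {
        b <- chars[i + j - 1]
        pf <- pf * if (b %in% rownames(mat)) mat[b, j] / bg[b] else 1
        # reverse-complement placement: complement base, reversed column
        bc <- COMP[[chars[i + w - j]]]
        pr <- pr * if (bc %in% rownames(mat)) mat[bc, j] / bg[bc] else 1
      }
      tot <- tot + pf + pr
    }
    tot / (2 * np)
  }, numeric(1), USE.NAMES = FALSE)
  log(mean(alrs[!is.na(alrs)]))
}

# hand step-up Benjamini-Hochberg
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in rev(seq_len(m))) {
    val <- min(1, p[ord[k]] * m / k)
    prev <- min(prev, val)
    q[ord[k]] <- prev
  }
  q
}

# textbook Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random smooth-ish positive track for oracle-equivalence checks
random_track <- function(n_bins, step = 10, seed = NULL, chrom = "chr1") {
  gen <- function() {
    x <- cumsum(rnorm(n_bins))
    x <- x - min(x) + runif(1, 0, 5)
    tibble::tibble(chrom = chrom, pos = (seq_len(n_bins) - 1) * step,
                   value = x)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# named PWM matrix helper (columns recycled)
make_pwm <- function(...) {
  m <- cbind(...)
  rownames(m) <- c("A", "C", "G", "T")
  m
}
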