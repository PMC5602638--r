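# Coverage tracks and histone-acetylation valley detection.
#
# A coverage track is a tibble with columns chrom, pos (bp coordinate of the
# sample point, 0-based), value (signal), on a fixed-step grid (default 10 bp).
# All genomic intervals in the package are 0-based half-open (BED dialect).

#' Deduplicate and 3'-extend aligned reads
#'
#' Collapses exact duplicate reads (identical chrom/start/end/strand) to a
#' single record and extends each read in its 3' direction, emulating the
#' standard ChIP-seq fragment-length correction applied before coverage
#' computation.
#'
#' @param reads A data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `strand` (`"+"` or `"-"`).
#' @param extension Number of base pairs to extend each read in its 3'
#'   direction (default 122). Minus-strand starts are floored at 0.
#' @return A tibble with the same columns, deduplicated and extended.
#' @export
#' @examples
#' reads <- tibble::tibble(chrom = "chr1", start = 100, end = 136, strand = "+")
#' preprocess_reads(reads)
preprocess_reads <- function(reads, extension = 122) {
  check_reads(reads)
  if (!is.numeric(extension) || length(extension) != 1 || is.na(extension) ||
      extension < 0) {
    abort("`extension` must be a single non-negative number.")
  }
  reads |>
    as_tibble() |>
    distinct(.data$chrom, .data$start, .data$end, .data$strand,
             .keep_all = TRUE) |>
    mutate(
      end   = if_else(.data$strand == "+", .data$end + extension, .data$end),
      start = if_else(.data$strand == "-",
                      pmax(0, .data$start - extension), .data$start)
    )
}

check_reads <- function(reads) {
  need <- c("chrom", "start", "end", "strand")
  missing <- setdiff(need, names(reads))
  if (length(missing) > 0) {
    abort(paste0("`reads` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(reads$start >= reads$end)) {
    abort("all reads must satisfy start < end")
  }
  if (!all(reads$strand %in% c("+", "-"))) {
    abort("read strand must be '+' or '-'")
  }
  invisible(reads)
}

#' Build a fixed-step coverage track from read intervals
#'
#' Samples per-base-pair read coverage on a regular grid. The value at each
#' sample point is the number of reads whose interval contains the point's
#' coordinate (point-sampling convention, matching stepped bedGraph output).
#'
#' @param reads A data frame of read intervals (see [preprocess_reads()]).
#' @param step Grid step in bp (default 10).
#' @return A tibble with columns `chrom`, `pos`, `value`; one row per grid
#'   point per chromosome, spanning each chromosome's covered range.
#' @export
build_coverage <- function(reads, step = 10) {
  check_reads(reads)
  if (step <= 0) abort("`step` must be positive.")
  if (nrow(reads) == 0) {
    warn("empty read set: returning empty coverage")
    return(tibble(chrom = character(), pos = numeric(), value = numeric()))
  }
  reads |>
    as_tibble() |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      j1 <- ceiling(df$start / step)       # first grid index covered
      j2 <- ceiling(df$end / step) - 1     # last grid index covered
      keep <- j2 >= j1
      j1 <- j1[keep]; j2 <- j2[keep]
      if (length(j1) == 0) {
        return(tibble(pos = numeric(), value = numeric()))
      }
      off <- min(j1)
      n <- max(j2) - off + 1
      delta <- numeric(n + 1)
      add <- tabulate(j1 - off + 1, nbins = n + 1)
      rem <- tabulate(j2 - off + 2, nbins = n + 1)
      value <- cumsum(add - rem)[seq_len(n)]
      tibble(pos = (off + seq_len(n) - 1) * step, value = value)
    }) |>
    ungroup()
}

gaussian_kernel <- function(sigma, step, halfwidth_sd = 4) {
  half <- ceiling(halfwidth_sd * sigma / step)
  k <- dnorm(seq(-half, half) * step, sd = sigma)
  k / sum(k)
}

#' Smooth a coverage track with a Gaussian kernel
#'
#' Discrete convolution with a normalized Gaussian kernel (standard deviation
#' `sigma` bp, truncated at 4 sigma and renormalized). Edges use
#' local-mass renormalization (division by the kernel mass falling on the
#' track), so a constant track is reproduced exactly everywhere.
#'
#' @param track A coverage tibble (`chrom`, `pos`, `value`) on a uniform grid.
#' @param sigma Kernel standard deviation in bp (default 40).
#' @param step Grid step in bp (default 10; must match the track grid).
#' @return A tibble on the same grid with smoothed `value`.
#' @export
smooth_coverage <- function(track, sigma = 40, step = 10) {
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma <= 0) {
    abort("`sigma` must be a single positive number.")
  }
  kern <- gaussian_kernel(sigma, step)
  track |>
    as_tibble() |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      df$value <- smooth_vector(df$value, kern)
      df
    }) |>
    ungroup()
}

smooth_vector <- function(x, kern) {
  n <- length(x)
  half <- (length(kern) - 1L) / 2L
  if (n == 1) return(x)
  num <- convolve(x, rev(kern), type = "open")
  den <- convolve(rep(1, n), rev(kern), type = "open")
  out <- (num / den)[(half + 1L):(half + n)]
  pmax(out, 0)
}

#' Flanking-window maxima at every sample point
#'
#' For each sample point, the maximum smoothed signal in the windows
#' `near`-`far` bp to its left and to its right, computed with a
#' monotonic-queue sliding-window algorithm. Windows are truncated at track
#' boundaries; a side whose window holds no sample point yields `-Inf` and
#' the point is not callable as a valley.
#'
#' @param track A smoothed coverage tibble.
#' @param near,far Window bounds in bp (defaults 50 and 500).
#' @param step Grid step in bp (default 10).
#' @return The track with added columns `left_max` and `right_max`.
#' @export
flanking_maxima <- function(track, near = 50, far = 500, step = 10) {
  if (!(near > 0 && far > near)) abort("need 0 < near < far")
  k1 <- as.integer(ceiling(near / step))
  k2 <- as.integer(floor(far / step))
  track |>
    as_tibble() |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      df$left_max <- window_max_left(df$value, k1, k2)
      df$right_max <- rev(window_max_left(rev(df$value), k1, k2))
      df
    }) |>
    ungroup()
}

#' Call histone-acetylation valleys on a smoothed coverage track
#'
#' A sample point is a valley point when its smoothed signal is strictly less
#' than `dip_fraction` times the minimum of its two flanking-window maxima
#' (windows `near`-`far` bp to either side). The point's valley score is that
#' minimum flanking maximum; elsewhere the valley-score signal is zero. Runs
#' of consecutive valley sample points are merged into one call covering
#' `[first_point, last_point + step)`, scored by the maximum point score in
#' the run.
#'
#' @param track A smoothed coverage tibble (`chrom`, `pos`, `value`).
#' @param near,far Flanking-window bounds in bp (defaults 50, 500).
#' @param dip_fraction Dip threshold as a fraction of the minimum flanking
#'   maximum (default 0.70); the comparison is strict.
#' @param step Grid step in bp (default 10).
#' @return A tibble of valley calls: `chrom`, `start`, `end`, `score`.
#' @export
call_valleys <- function(track, near = 50, far = 500, dip_fraction = 0.70,
                         step = 10) {
  if (!(dip_fraction > 0 && dip_fraction < 1)) {
    abort("`dip_fraction` must lie in (0, 1)")
  }
  fm <- flanking_maxima(track, near = near, far = far, step = step)
  fm |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      vmin <- pmin(df$left_max, df$right_max)
      ok <- is.finite(vmin)
      valley <- ok & (df$value < dip_fraction * vmin)
      if (!any(valley)) {
        return(tibble(start = numeric(), end = numeric(), score = numeric()))
      }
      idx <- which(valley)
      run <- cumsum(c(1, diff(idx) != 1))
      tibble(
        start = as.numeric(tapply(df$pos[idx], run, min)),
        end   = as.numeric(tapply(df$pos[idx], run, max)) + step,
        score = as.numeric(tapply(vmin[idx], run, max))
      )
    }) |>
    ungroup()
}

#' Per-point valley-score signal
#'
#' The unmerged valley-score track: the minimum flanking maximum at valley
#' points, zero elsewhere. Useful for bedGraph export and inspection.
#'
#' @inheritParams call_valleys
#' @return The track with an added `valley_score` column.
#' @export
valley_score_signal <- function(track, near = 50, far = 500,
                                dip_fraction = 0.70, step = 10) {
  fm <- flanking_maxima(track, near = near, far = far, step = step)
  vmin <- pmin(fm$left_max, fm$right_max)
  valley <- is.finite(vmin) & (fm$value < dip_fraction * vmin)
  fm$valley_score <- ifelse(valley, vmin, 0)
  fm$left_max <- NULL
  fm$right_max <- NULL
  fm
}
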