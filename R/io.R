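# Plain-text genomic file formats used between pipeline stages. All
# intervals are 0-based half-open (BED dialect).

#' Read a BED file of read intervals
#'
#' @param path Path to a BED3+/BED6 file.
#' @return A tibble `chrom`, `start`, `end`, `strand` (strand defaults to
#'   `"+"` when absent).
#' @export
read_bed_reads <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  out <- tibble(chrom = as.character(df[[1]]),
                start = as.numeric(df[[2]]),
                end = as.numeric(df[[3]]),
                strand = if (ncol(df) >= 6) as.character(df[[6]]) else "+")
  check_reads(out)
  out
}

#' Write intervals as BED6
#'
#' @param x A tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  df <- tibble(
    chrom = x$chrom, start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0,
    strand = if ("strand" %in% names(x)) x$strand else "."
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage file into a fixed-step track
#'
#' Each bedGraph interval is expanded onto the sampling grid (value assigned
#' to every grid point whose coordinate falls in the interval).
#'
#' @param path Path to a bedGraph file.
#' @param step Grid step in bp (default 10).
#' @return A coverage tibble `chrom`, `pos`, `value`.
#' @export
read_bedgraph <- function(path, step = 10) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                        show_col_types = FALSE, progress = FALSE,
                        comment = "#")
  df |>
    group_by(.data$chrom) |>
    group_modify(function(d, key) {
      j1 <- ceiling(d$start / step)
      j2 <- ceiling(d$end / step) - 1
      keep <- j2 >= j1
      d <- d[keep, ]; j1 <- j1[keep]; j2 <- j2[keep]
      n_each <- j2 - j1 + 1
      tibble(pos = step * unlist(purrr::map2(j1, j2, seq)),
             value = rep(d$value, n_each))
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$pos)
}

#' Write a fixed-step track as bedGraph
#'
#' Consecutive grid points with equal value are merged into one interval.
#'
#' @param track A coverage tibble (`chrom`, `pos`, `value`).
#' @param path Output path.
#' @param step Grid step in bp (default 10).
#' @export
write_bedgraph <- function(track, path, step = 10) {
  rows <- track |>
    group_by(.data$chrom) |>
    group_modify(function(d, key) {
      d <- arrange(d, .data$pos)
      brk <- cumsum(c(1, diff(d$pos) != step | diff(d$value) != 0))
      tibble(
        start = as.numeric(tapply(d$pos, brk, min)),
        end = as.numeric(tapply(d$pos, brk, max)) + step,
        value = as.numeric(tapply(d$value, brk, `[`, 1))
      )
    }) |>
    ungroup()
  readr::write_tsv(
    mutate(rows,
           start = format(.data$start, scientific = FALSE, trim = TRUE),
           end = format(.data$end, scientific = FALSE, trim = TRUE)),
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models from BED6
#'
#' The TSS is the interval start for plus-strand genes and the interval end
#' for minus-strand genes; the BED name field becomes `gene_id`.
#'
#' @param path Path to a BED6 file.
#' @return A gene-model tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @export
read_gene_models <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(df) < 6) abort("gene models require BED6 (name and strand fields)")
  out <- tibble(
    gene_id = as.character(df[[4]]),
    chrom = as.character(df[[1]]),
    strand = as.character(df[[6]]),
    tss = if_else(.data$strand == "+", as.numeric(df[[2]]),
                  as.numeric(df[[3]]))
  ) |> select("gene_id", "chrom", "tss", "strand")
  check_genes(out)
  out
}
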