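# Gene models, promoter windows, active-promoter-region (APR) assignment and
# sequence extraction. Gene models are tibbles with columns gene_id, chrom,
# tss, strand (and optionally `expressed`).

check_genes <- function(genes) {
  need <- c("gene_id", "chrom", "tss", "strand")
  missing <- setdiff(need, names(genes))
  if (length(missing) > 0) {
    abort(paste0("`genes` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id)) abort("gene_id must be unique")
  if (any(genes$tss < 0)) abort("tss must be >= 0")
  invisible(genes)
}

#' Strand-aware promoter windows around transcription start sites
#'
#' For a plus-strand gene the window is `[tss - upstream, tss + downstream)`;
#' minus-strand windows are mirrored. Starts are clamped at 0.
#'
#' @param genes A gene-model tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @param upstream,downstream Window extent in bp relative to the TSS
#'   (defaults 1500 and 500, the promoter-scanning window).
#' @return The gene tibble with added `start` and `end` columns (0-based
#'   half-open).
#' @export
promoter_windows <- function(genes, upstream = 1500, downstream = 500) {
  check_genes(genes)
  if (upstream + downstream <= 0) abort("upstream + downstream must be > 0")
  genes |>
    as_tibble() |>
    mutate(
      start = pmax(0, if_else(.data$strand == "+",
                              .data$tss - upstream, .data$tss - downstream)),
      end   = if_else(.data$strand == "+",
                      .data$tss + downstream, .data$tss + upstream)
    )
}

#' Assign valleys to genes as active promoter regions (APRs)
#'
#' A valley becomes an APR of every gene whose `[tss - radius, tss + radius)`
#' window it overlaps by at least one base pair (a valley near two TSSs
#' serves both genes). With `containment = TRUE` the valley must lie entirely
#' inside the window.
#'
#' @param valleys A tibble of valley calls (`chrom`, `start`, `end`, `score`,
#'   plus any extra columns such as `time`, which are carried through).
#' @param genes A gene-model tibble.
#' @param radius Half-width of the TSS window in bp (default 5000).
#' @param containment Require full containment instead of any overlap
#'   (default `FALSE`).
#' @return A tibble with one row per (gene, valley) assignment: `gene_id`
#'   plus all valley columns.
#' @export
assign_aprs <- function(valleys, genes, radius = 5000, containment = FALSE) {
  check_genes(genes)
  valleys <- as_tibble(valleys)
  if (nrow(valleys) == 0 || nrow(genes) == 0) {
    return(bind_cols(tibble(gene_id = character()), valleys[0, ]))
  }
  vgr <- GenomicRanges::GRanges(
    valleys$chrom,
    IRanges::IRanges(start = valleys$start + 1, end = valleys$end)
  )
  win_start <- pmax(0, genes$tss - radius)
  ggr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = win_start + 1, end = genes$tss + radius)
  )
  # chromosomes absent from the gene set simply yield no assignment
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    vgr, ggr, type = if (containment) "within" else "any"
  ))
  out <- valleys[S4Vectors::queryHits(hits), , drop = FALSE]
  out <- bind_cols(
    tibble(gene_id = genes$gene_id[S4Vectors::subjectHits(hits)]),
    out
  )
  arrange(out, .data$gene_id, .data$chrom, .data$start)
}

#' Extract region sequences from a genome
#'
#' Regions are extracted independently (never concatenated), so a motif match
#' can never span two regions, and are returned uppercased.
#'
#' @param regions A tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open); extra columns are carried through.
#' @param genome A [Biostrings::DNAStringSet] or the path to a FASTA file.
#' @return The region tibble with an added character column `seq`.
#' @export
extract_sequences <- function(regions, genome) {
  if (is.character(genome) && length(genome) == 1) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  regions <- as_tibble(regions)
  if (nrow(regions) == 0) return(mutate(regions, seq = character()))
  bad_chrom <- setdiff(unique(regions$chrom), names(genome))
  if (length(bad_chrom) > 0) {
    abort(paste0("chromosome(s) not in genome: ",
                 paste(bad_chrom, collapse = ", ")))
  }
  lens <- setNames(Biostrings::width(genome), names(genome))
  out_of_bounds <- regions$start < 0 | regions$end > lens[regions$chrom]
  if (any(out_of_bounds)) {
    i <- which(out_of_bounds)[1]
    abort(sprintf("region %s:%d-%d outside chromosome bounds",
                  regions$chrom[i], regions$start[i], regions$end[i]))
  }
  seqs <- Biostrings::subseq(
    genome[regions$chrom],
    start = regions$start + 1,
    end = regions$end
  )
  mutate(regions, seq = unname(toupper(as.character(seqs))))
}
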