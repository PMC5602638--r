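# Fully in-silico datasets with known ground truth: a genome with planted
# promoter valleys, time-varying motif occupancy inside the valleys,
# temporal expression whose cluster medians follow motif occupancy shifted
# by a planted lag, and TF ChIP reads concentrated on target promoters.
#
# The generator emulates the statistical structure the pipeline assumes:
# histone-acetylation plateaus over promoters with ~100 bp valleys at
# regulatory sites, motif occupancy that tracks each cluster's activity,
# expression fold changes that lag motif occupancy by 0-2 h, and ChIP read
# enrichment over bound promoters. It does not emulate read-level sequencing
# artifacts (errors, GC bias, mappability).

#' Simulation configuration
#'
#' Defaults define the reference synthetic study: a 2 x 2 Mbp genome with
#' 200 genes (disjoint +/-5 kbp TSS windows), four temporal clusters (two
#' up-, two down-regulated, 15 member genes each) with planted regulator
#' motifs, per-cluster lags spanning 0.5-2 h, signal time points 0/1/2/4 h,
#' expression time points 0/2/4/12 h with 3 replicates, 10% signal noise,
#' and ChIP read sets with 3-fold promoter enrichment.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_genes Total genes (split evenly across chromosomes).
#' @param n_unexpressed Genes simulated below the expression filter.
#' @param members_per_cluster DE genes per cluster.
#' @param n_motifs Total motifs (targets first, then decoys).
#' @param motif_width Motif width in bp.
#' @param dominant_prob Probability of the consensus base at each motif
#'   position.
#' @param signal_times HAc/motif time grid, hours.
#' @param expr_times Expression time grid, hours (0 h required).
#' @param n_reps Expression replicates per time point.
#' @param base_freq Genome base frequencies (A/C/G/T).
#' @param step Coverage grid step, bp.
#' @param plateau_height,baseline HAc plateau and inter-gene signal levels.
#' @param plateau_halfwidth Plateau half-width around each TSS, bp.
#' @param dip_depth,dip_sigma Valley depth and Gaussian half-width, bp.
#' @param signal_noise_sd SD of additive Gaussian signal noise (default 10%
#'   of the plateau).
#' @param max_occupancy Motif sites per member promoter (occupancy levels
#'   run 0..`max_occupancy`).
#' @param expr_noise_sd SD of expression noise (log2 units).
#' @param expr_baseline Baseline log2 intensity of expressed genes.
#' @param clusters A tibble defining the planted clusters: `cluster`,
#'   `direction`, `lag` (h), `role` (`"activator"`/`"repressor"`) and
#'   `profile` (list of median log2 fold changes on `expr_times`).
#' @param chip_times TF ChIP time points, hours (subset of `signal_times`).
#' @param reads_per_tf Uniform background reads per TF per time point.
#' @param read_length ChIP read length, bp.
#' @param enrich_factor Fold read enrichment over bound promoters.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2, chrom_length = 2e6, n_genes = 200,
                       n_unexpressed = 20, members_per_cluster = 15,
                       n_motifs = 20, motif_width = 10, dominant_prob = 0.85,
                       signal_times = c(0, 1, 2, 4),
                       expr_times = c(0, 2, 4, 12), n_reps = 3,
                       base_freq = c(0.25, 0.25, 0.25, 0.25), step = 10,
                       plateau_height = 100, baseline = 2,
                       plateau_halfwidth = 4800, dip_depth = 85,
                       dip_sigma = 60, signal_noise_sd = 10,
                       max_occupancy = 3, expr_noise_sd = 0.3,
                       expr_baseline = 8,
                       clusters = default_sim_clusters(),
                       chip_times = c(0, 2, 4), reads_per_tf = 20000,
                       read_length = 36, enrich_factor = 3) {
  cfg <- as.list(environment())
  if (dip_depth >= plateau_height) abort("dip must not undercut zero signal")
  if (plateau_height - dip_depth >= 0.7 * plateau_height) {
    abort("planted dips must fall below 70% of the plateau")
  }
  spacing <- chrom_length / ceiling(n_genes / n_chrom)
  if (spacing < 2 * 5000 + 2 * plateau_halfwidth / 2) {
    abort("genome too small for this many genes with disjoint TSS windows")
  }
  structure(cfg, class = "sim_config")
}

#' Planted cluster definitions used by the default simulation
#'
#' Two up- and two down-regulated clusters with distinguishable temporal
#' shapes (early-peak versus late-rise), lags covering the allowed 0-2 h
#' range, and both activator and repressor regulator roles.
#'
#' @return A tibble `cluster`, `direction`, `lag`, `role`, `profile`.
#' @export
default_sim_clusters <- function() {
  tibble(
    cluster = c("UC1", "UC2", "DC1", "DC2"),
    direction = c("up", "up", "down", "down"),
    lag = c(1.0, 2.0, 0.5, 1.5),
    role = c("activator", "repressor", "activator", "repressor"),
    profile = list(c(0, 4, 3, 1), c(0, 1, 3.5, 4),
                   c(0, -4, -3, -1), c(0, -1, -3.5, -4))
  )
}

random_pwm <- function(width, dominant_prob, consensus = NULL) {
  if (is.null(consensus)) {
    consensus <- sample(DNA_BASES, width, replace = TRUE)
  }
  mat <- matrix((1 - dominant_prob) / 3, nrow = 4, ncol = width,
                dimnames = list(DNA_BASES, NULL))
  for (j in seq_len(width)) mat[consensus[j], j] <- dominant_prob
  list(mat = mat, consensus = paste(consensus, collapse = ""))
}

# occupancy level (0..K) of a cluster's regulator at each signal time:
# the planted-lag-shifted median profile, min-max normalized, scaled to K,
# and inverted for repressors
occupancy_levels <- function(profile, expr_times, signal_times, lag, role,
                             k_max) {
  a <- interp_profile(expr_times, profile, signal_times + lag)
  if (max(a) == min(a)) abort("degenerate planted profile")
  a_norm <- (a - min(a)) / (max(a) - min(a))
  lev <- round(k_max * a_norm)
  if (role == "repressor") lev <- k_max - lev
  as.integer(lev)
}

#' Generate the complete synthetic dataset
#'
#' Builds the genome, gene models, planted motif instances, HAc signal
#' tracks, expression matrix and TF ChIP reads, together with a ground-truth
#' manifest, deterministically from `seed`.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer master seed.
#' @return A list with `genome` ([Biostrings::DNAStringSet]), `genes`,
#'   `tracks` (tibble `chrom`, `pos`, `value`, `time`), `expr`, `samples`,
#'   `motifs`, `tf_motifs`, `tf_reads`, and `truth` (a list holding cluster
#'   definitions, memberships, planted site coordinates and occupancy
#'   levels).
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = 1) {
  withr::with_seed(seed, simulate_dataset_impl(cfg))
}

simulate_dataset_impl <- function(cfg) {
  geno <- simulate_genome_impl(cfg)
  truth <- plant_truth(cfg, geno$genes)
  genome <- plant_motifs(cfg, geno$genome, truth)
  tracks <- simulate_hac_impl(cfg, geno$genes, truth)
  exprs <- simulate_expression_impl(cfg, geno$genes, truth)
  tf_reads <- simulate_tf_reads_impl(cfg, geno$genes, truth)
  list(
    genome = genome, genes = geno$genes, tracks = tracks,
    expr = exprs$expr, samples = exprs$samples,
    motifs = truth$motifs, tf_motifs = truth$tf_motifs,
    tf_reads = tf_reads, truth = truth
  )
}

#' Simulate a random genome with regularly spaced genes
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A list with `genome` (DNAStringSet) and `genes` (gene-model
#'   tibble); TSSs are spaced so that +/-5 kbp windows are disjoint.
#' @export
simulate_genome <- function(cfg = sim_config(), seed = 1) {
  withr::with_seed(seed, simulate_genome_impl(cfg))
}

simulate_genome_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    paste(sample(DNA_BASES, cfg$chrom_length, replace = TRUE,
                 prob = cfg$base_freq), collapse = "")
  }, character(1)))
  names(genome) <- chroms
  n_per <- ceiling(cfg$n_genes / cfg$n_chrom)
  margin <- 10000
  spacing <- (cfg$chrom_length - 2 * margin) / n_per
  genes <- purrr::map_dfr(seq_along(chroms), function(ci) {
    n_here <- min(n_per, cfg$n_genes - (ci - 1) * n_per)
    if (n_here <= 0) return(NULL)
    tibble(
      gene_id = sprintf("g%03d", (ci - 1) * n_per + seq_len(n_here)),
      chrom = chroms[ci],
      tss = round(margin + (seq_len(n_here) - 0.5) * spacing),
      strand = rep(c("+", "-"), length.out = n_here)
    )
  })
  list(genome = genome, genes = genes)
}

plant_truth <- function(cfg, genes) {
  clusters <- cfg$clusters
  n_target <- nrow(clusters)
  if (cfg$n_motifs < n_target) abort("need at least one motif per cluster")
  pwms <- lapply(seq_len(cfg$n_motifs), function(i) {
    random_pwm(cfg$motif_width, cfg$dominant_prob)
  })
  motif_ids <- c(sprintf("V$TARGET_%s", clusters$cluster),
                 sprintf("V$DECOY_%02d", seq_len(cfg$n_motifs - n_target)))
  motifs <- tibble(
    motif_id = motif_ids,
    width = cfg$motif_width,
    mat = lapply(pwms, `[[`, "mat"),
    consensus = vapply(pwms, `[[`, character(1), "consensus")
  )
  clusters$motif_id <- motif_ids[seq_len(n_target)]
  clusters$tf <- sprintf("TF_%s", clusters$cluster)
  # assign genes: unexpressed, members, expressed filler
  ids <- sample(genes$gene_id)
  n_mem <- n_target * cfg$members_per_cluster
  if (cfg$n_unexpressed + n_mem > length(ids)) {
    abort("not enough genes for the requested clusters")
  }
  unexpressed <- ids[seq_len(cfg$n_unexpressed)]
  member_ids <- ids[cfg$n_unexpressed + seq_len(n_mem)]
  members <- tibble(
    gene_id = member_ids,
    cluster = rep(clusters$cluster, each = cfg$members_per_cluster)
  )
  levels <- purrr::pmap_dfr(clusters, function(cluster, direction, lag, role,
                                               profile, motif_id, tf) {
    tibble(cluster = cluster, time = cfg$signal_times,
           level = occupancy_levels(profile, cfg$expr_times, cfg$signal_times,
                                    lag, role, cfg$max_occupancy))
  })
  # valley sites: `max_occupancy` motif-bearing sites upstream of each member
  # TSS plus one always-open empty site near the TSS (strand-aware offsets)
  site_offsets <- 2400 + 800 * (seq_len(cfg$max_occupancy) - 1)
  gene_info <- genes[match(members$gene_id, genes$gene_id), ]
  sgn <- if_else(gene_info$strand == "+", 1, -1)
  sites <- purrr::map_dfr(seq_len(cfg$max_occupancy), function(s) {
    tibble(gene_id = members$gene_id, cluster = members$cluster,
           site = s, chrom = gene_info$chrom,
           pos = gene_info$tss - sgn * site_offsets[s])
  })
  empty_sites <- tibble(
    gene_id = genes$gene_id, cluster = NA_character_, site = 0L,
    chrom = genes$chrom,
    pos = genes$tss - if_else(genes$strand == "+", 1, -1) * 200
  )
  list(
    clusters = clusters, motifs = motifs,
    tf_motifs = select(clusters, "tf", "motif_id"),
    members = members, unexpressed = unexpressed,
    sites = sites, empty_sites = empty_sites, levels = levels
  )
}

plant_motifs <- function(cfg, genome, truth) {
  sites <- truth$sites |>
    inner_join(select(truth$clusters, "cluster", "motif_id"), by = "cluster") |>
    inner_join(select(truth$motifs, "motif_id", "consensus"), by = "motif_id")
  half <- floor(cfg$motif_width / 2)
  for (ch in unique(sites$chrom)) {
    s <- sites[sites$chrom == ch, ]
    at <- IRanges::IRanges(start = s$pos - half + 1,
                           width = cfg$motif_width)
    genome[[ch]] <- Biostrings::replaceAt(
      genome[[ch]], at, Biostrings::DNAStringSet(s$consensus))
  }
  genome
}

open_sites <- function(truth, time) {
  lev <- filter(truth$levels, .data$time == !!time)
  motif_open <- truth$sites |>
    inner_join(select(lev, "cluster", "level"), by = "cluster") |>
    filter(.data$site <= .data$level)
  bind_rows(
    select(motif_open, "gene_id", "chrom", "pos"),
    select(truth$empty_sites, "gene_id", "chrom", "pos")
  )
}

#' Simulate histone-acetylation signal tracks
#'
#' Each gene promoter carries a signal plateau around its TSS; Gaussian dips
#' are planted at the regulatory sites open at each time point (a cluster's
#' motif sites open according to its occupancy level, plus one always-open
#' site per gene). Additive Gaussian noise, clipped at zero.
#'
#' @param cfg A [sim_config()].
#' @param truth Ground truth from [simulate_dataset()] (or `plant_truth`).
#' @param genes Gene-model tibble.
#' @param seed Integer seed.
#' @param noise_sd Signal noise SD (defaults to `cfg$signal_noise_sd`).
#' @return A tibble `chrom`, `pos`, `value`, `time`.
#' @export
simulate_hac <- function(cfg, genes, truth, seed = 1,
                         noise_sd = cfg$signal_noise_sd) {
  withr::with_seed(seed, simulate_hac_impl(cfg, genes, truth, noise_sd))
}

simulate_hac_impl <- function(cfg, genes, truth,
                              noise_sd = cfg$signal_noise_sd) {
  n_bins <- floor(cfg$chrom_length / cfg$step)
  grid <- (seq_len(n_bins) - 1) * cfg$step
  purrr::map_dfr(cfg$signal_times, function(t) {
    open <- open_sites(truth, t)
    purrr::map_dfr(unique(genes$chrom), function(ch) {
      v <- rep(cfg$baseline, n_bins)
      for (tss in genes$tss[genes$chrom == ch]) {
        i1 <- max(1, floor((tss - cfg$plateau_halfwidth) / cfg$step) + 1)
        i2 <- min(n_bins, floor((tss + cfg$plateau_halfwidth) / cfg$step) + 1)
        v[i1:i2] <- cfg$plateau_height
      }
      reach <- 5 * cfg$dip_sigma
      for (p in open$pos[open$chrom == ch]) {
        i1 <- max(1, floor((p - reach) / cfg$step) + 1)
        i2 <- min(n_bins, floor((p + reach) / cfg$step) + 1)
        x <- grid[i1:i2]
        v[i1:i2] <- v[i1:i2] -
          cfg$dip_depth * exp(-(x - p)^2 / (2 * cfg$dip_sigma^2))
      }
      if (noise_sd > 0) v <- v + rnorm(n_bins, 0, noise_sd)
      tibble(chrom = ch, pos = grid, value = pmax(v, 0), time = t)
    })
  })
}

#' Simulate the temporal expression matrix
#'
#' Member genes follow their cluster's median log2 fold-change profile (the
#' planted regulator occupancy shifted by the cluster lag) with a per-gene
#' scale factor and Gaussian noise; filler genes are flat and expressed;
#' a configurable number of genes stay below the expression filter.
#'
#' @inheritParams simulate_hac
#' @return A list with `expr` (tibble `gene_id` + sample columns) and
#'   `samples` (tibble `sample`, `time`, `rep`).
#' @export
simulate_expression <- function(cfg, genes, truth, seed = 1) {
  withr::with_seed(seed, simulate_expression_impl(cfg, genes, truth))
}

simulate_expression_impl <- function(cfg, genes, truth) {
  samples <- tidyr::expand_grid(time = cfg$expr_times,
                                rep = seq_len(cfg$n_reps)) |>
    mutate(sample = sprintf("t%g_r%d", .data$time, .data$rep)) |>
    select("sample", "time", "rep")
  n <- nrow(genes)
  profiles <- matrix(0, nrow = n, ncol = length(cfg$expr_times))
  base <- rep(cfg$expr_baseline, n)
  mem_idx <- match(truth$members$gene_id, genes$gene_id)
  for (i in seq_len(nrow(truth$clusters))) {
    cl <- truth$clusters$cluster[i]
    rows <- mem_idx[truth$members$cluster == cl]
    scale <- runif(length(rows), 0.9, 1.1)
    profiles[rows, ] <- outer(scale, truth$clusters$profile[[i]])
  }
  filler <- setdiff(seq_len(n), c(mem_idx,
                                  match(truth$unexpressed, genes$gene_id)))
  base[filler] <- runif(length(filler), 6.5, 12)
  base[match(truth$unexpressed, genes$gene_id)] <-
    runif(length(truth$unexpressed), 3, 5.3)
  vals <- vapply(seq_len(nrow(samples)), function(j) {
    ti <- which(cfg$expr_times == samples$time[j])
    base + profiles[, ti] + rnorm(n, 0, cfg$expr_noise_sd)
  }, numeric(n))
  colnames(vals) <- samples$sample
  expr <- bind_cols(tibble(gene_id = genes$gene_id), as_tibble(vals))
  list(expr = expr, samples = samples)
}

#' Simulate TF ChIP-seq read sets
#'
#' Each planted regulator TF gets, per ChIP time point, reads sampled
#' uniformly over the genome plus Poisson-distributed extra reads over its
#' target-cluster promoter windows, scaled by the cluster's occupancy at
#' that time and the configured enrichment factor.
#'
#' @inheritParams simulate_hac
#' @return A tibble `tf`, `time`, `chrom`, `start`, `end`, `strand`.
#' @export
simulate_tf_reads <- function(cfg, genes, truth, seed = 1) {
  withr::with_seed(seed, simulate_tf_reads_impl(cfg, genes, truth))
}

simulate_tf_reads_impl <- function(cfg, genes, truth) {
  chroms <- unique(genes$chrom)
  genome_len <- cfg$n_chrom * cfg$chrom_length
  win <- promoter_windows(genes, upstream = 2000, downstream = 500)
  purrr::pmap_dfr(truth$clusters, function(cluster, direction, lag, role,
                                           profile, motif_id, tf) {
    lev <- filter(truth$levels, .data$cluster == !!cluster)
    members <- truth$members$gene_id[truth$members$cluster == cluster]
    mwin <- filter(win, .data$gene_id %in% members)
    purrr::map_dfr(cfg$chip_times, function(t) {
      n_unif <- rpois(1, cfg$reads_per_tf)
      chrom <- sample(chroms, n_unif, replace = TRUE)
      start <- floor(runif(n_unif, 0, cfg$chrom_length - cfg$read_length))
      occ <- lev$level[lev$time == t] / cfg$max_occupancy
      lambda <- (cfg$enrich_factor - 1) * cfg$reads_per_tf *
        (2500 / genome_len) * occ
      extra <- purrr::map_dfr(seq_len(nrow(mwin)), function(i) {
        k <- rpois(1, lambda)
        if (k == 0) return(NULL)
        tibble(chrom = mwin$chrom[i],
               start = floor(runif(k, mwin$start[i],
                                   mwin$end[i] - cfg$read_length)))
      })
      all <- bind_rows(tibble(chrom = chrom, start = start), extra)
      tibble(tf = tf, time = t, chrom = all$chrom, start = all$start,
             end = all$start + cfg$read_length,
             strand = sample(c("+", "-"), nrow(all), replace = TRUE))
    })
  })
}

#' Synthetic motif score series with a planted lag
#'
#' Generates a motif score series on the signal time grid equal to the
#' lag-shifted interpolated expression profile plus Gaussian noise: the
#' construction used for lag-recovery calibration.
#'
#' @param profile Median expression values on `expr_times`.
#' @param lag Planted lag in hours.
#' @param expr_times,signal_times Time grids (defaults 0/2/4/12 and 0/1/2/4).
#' @param noise_sd Noise SD in score units (default 0); 10% noise
#'   corresponds to `0.1 * diff(range(profile))`.
#' @param sign `+1` for an activator-like series, `-1` for a repressor.
#' @return A tibble `time`, `score`.
#' @export
simulate_lag_series <- function(profile, lag, expr_times = c(0, 2, 4, 12),
                                signal_times = c(0, 1, 2, 4), noise_sd = 0,
                                sign = 1) {
  s <- sign * interp_profile(expr_times, profile, signal_times + lag)
  if (noise_sd > 0) s <- s + rnorm(length(s), 0, noise_sd)
  tibble(time = signal_times, score = s)
}

#' Write a synthetic dataset to disk in pipeline formats
#'
#' Emits FASTA (genome), BED6 (gene models, TF reads), bedGraph (HAc signal
#' per time point), TSV (expression matrix, sample sheet), a TRANSFAC motif
#' file and a machine-readable ground-truth manifest (JSON).
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @param step Coverage grid step used for bedGraph output.
#' @return The directory, invisibly.
#' @export
write_dataset <- function(sim, dir, step = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  genes_bed <- sim$genes |>
    mutate(start = if_else(.data$strand == "+", .data$tss, .data$tss - 1),
           end = .data$start + 1, name = .data$gene_id)
  write_bed(genes_bed, file.path(dir, "genes.bed"))
  for (t in unique(sim$tracks$time)) {
    write_bedgraph(filter(sim$tracks, .data$time == t),
                   file.path(dir, sprintf("hac_t%g.bedgraph", t)), step)
  }
  readr::write_tsv(sim$expr, file.path(dir, "expression.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"),
                   progress = FALSE)
  write_motifs_transfac(sim$motifs, file.path(dir, "motifs.transfac"))
  for (tf in unique(sim$tf_reads$tf)) {
    for (t in unique(sim$tf_reads$time)) {
      sub <- filter(sim$tf_reads, .data$tf == !!tf, .data$time == t)
      write_bed(sub, file.path(dir, sprintf("reads_%s_t%g.bed", tf, t)))
    }
  }
  manifest <- list(
    clusters = as.data.frame(select(sim$truth$clusters, -"profile")),
    profiles = setNames(sim$truth$clusters$profile,
                        sim$truth$clusters$cluster),
    members = as.data.frame(sim$truth$members),
    sites = as.data.frame(sim$truth$sites),
    levels = as.data.frame(sim$truth$levels),
    unexpressed = sim$truth$unexpressed
  )
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory back into pipeline inputs
#'
#' Loads the files emitted by [write_dataset()] (or equivalently shaped user
#' data: FASTA genome, BED6 gene models, per-time-point bedGraph coverage,
#' TSV expression and samples, TRANSFAC motifs, optional per-TF BED reads)
#' into the list accepted by [run_valley_tf()].
#'
#' @param dir Dataset directory.
#' @param step Coverage grid step in bp (default 10).
#' @return A list with `genome`, `genes`, `tracks`, `expr`, `samples`,
#'   `motifs`, and `tf_reads`/`tf_motifs` when read files are present.
#' @export
read_dataset <- function(dir, step = 10) {
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  genes <- read_gene_models(file.path(dir, "genes.bed"))
  bg_files <- list.files(dir, pattern = "^hac_t.*\\.bedgraph$",
                         full.names = TRUE)
  if (length(bg_files) == 0) abort("no hac_t*.bedgraph tracks found")
  tracks <- purrr::map_dfr(bg_files, function(f) {
    t <- as.numeric(sub("^hac_t(.*)\\.bedgraph$", "\\1", basename(f)))
    mutate(read_bedgraph(f, step = step), time = t)
  })
  expr <- readr::read_tsv(file.path(dir, "expression.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  samples <- readr::read_tsv(file.path(dir, "samples.tsv"),
                             show_col_types = FALSE, progress = FALSE)
  motifs <- read_motifs(file.path(dir, "motifs.transfac"), "transfac")
  out <- list(genome = genome, genes = genes, tracks = tracks, expr = expr,
              samples = samples, motifs = motifs)
  read_files <- list.files(dir, pattern = "^reads_.*\\.bed$",
                           full.names = TRUE)
  if (length(read_files) > 0) {
    out$tf_reads <- purrr::map_dfr(read_files, function(f) {
      parts <- sub("^reads_(.*)_t([0-9.]+)\\.bed$", "\\1\t\\2", basename(f))
      parts <- strsplit(parts, "\t")[[1]]
      mutate(read_bed_reads(f), tf = parts[1], time = as.numeric(parts[2]))
    })
    truth_path <- file.path(dir, "truth.json")
    if (file.exists(truth_path)) {
      truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
      out$tf_motifs <- as_tibble(truth$clusters[, c("tf", "motif_id")])
    }
  }
  out
}
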