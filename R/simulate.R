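# Synthetic-data generator with planted ground truth.
#
# Coverage model: per-base counts are negative-binomial with mean
#   background_mean * m(p) * (1 - protection inside planted sites),
# where m(p) is a smooth low-frequency sinusoidal-mixture positional
# multiplier shared by replicates (real mitochondrial coverage is smoothly
# non-uniform; a flat Poisson null would make footprint calling
# unrealistically easy). Replicates share m(p) and the planted sites but draw
# counts independently, with an extra per-replicate multiplicative scale.

#' Simulation configuration
#'
#' Defaults are the study conditions the generator emulates: a mouse-scale
#' mitochondrial genome (16,299 bp), deep coverage (mean 50x per base),
#' overdispersed counts (negative-binomial size 10), footprints 10-60 bp wide
#' planted as coverage depressions, duplicate structure (two replicates,
#' 5 percent multiplicative replicate noise) and a NUMT contamination rate
#' of 0.002 (0.2 percent of reads).
#'
#' @param genome_length Genome size in bases (mouse mtDNA scale by default;
#'   use 16569 for the human scale).
#' @param background_mean Expected coverage per base away from footprints.
#' @param dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param planted_sites Data frame with columns \code{start}, \code{width}
#'   (10-60 bases) and \code{protection} (fractional coverage reduction in
#'   [0, 1]); NULL plants nothing.
#' @param n_replicates Replicates per condition (default 2, the duplicate
#'   design the concordance filter expects).
#' @param replicate_noise_sd SD of the per-replicate log-normal scale factor.
#' @param stage_script Binary matrix (planted site x stage): which stages
#'   each site is planted in. Column names are stage labels.
#' @param numt_rate Fraction of simulated reads of NUMT origin.
#' @param bias_kmer Optional list \code{(kmer, enrichment)}: cut sites land
#'   on occurrences of \code{kmer} with the given fold preference.
#' @param multiplier_amplitude Amplitudes of the two sinusoidal components of
#'   the positional multiplier.
#' @param seed Integer seed; every stochastic step derives from it.
#' @return A list of class \code{SimulationConfig}.
#' @export
simulation_config <- function(genome_length = 16299L, background_mean = 50,
                              dispersion = 10, planted_sites = NULL,
                              n_replicates = 2L, replicate_noise_sd = 0.05,
                              stage_script = NULL, numt_rate = 0.002,
                              bias_kmer = NULL,
                              multiplier_amplitude = c(0.3, 0.15),
                              seed = 1L) {
  genome_length <- as.integer(genome_length)
  stopifnot(genome_length >= 100L, background_mean > 0, dispersion > 0,
            n_replicates >= 1L, replicate_noise_sd >= 0,
            numt_rate >= 0, numt_rate <= 1)
  if (!is.null(planted_sites)) {
    stopifnot(all(c("start", "width", "protection") %in% names(planted_sites)))
    if (any(planted_sites$width < 1L))
      stop("planted site widths must be positive")
    if (any(planted_sites$protection < 0 | planted_sites$protection > 1))
      stop("protection must be in [0, 1]")
    if (any(planted_sites$start < 0L |
            planted_sites$start >= genome_length))
      stop("planted site start outside genome")
  }
  if (!is.null(stage_script)) {
    stage_script <- as.matrix(stage_script)
    if (is.null(planted_sites) || nrow(stage_script) != nrow(planted_sites))
      stop("stage_script rows must match planted_sites rows")
    if (!all(stage_script %in% c(0, 1)))
      stop("stage_script must be binary")
    if (is.null(colnames(stage_script)))
      colnames(stage_script) <- paste0("stage", seq_len(ncol(stage_script)))
  }
  if (!is.null(bias_kmer))
    stopifnot(is.list(bias_kmer), !is.null(bias_kmer$kmer),
              !is.null(bias_kmer$enrichment), bias_kmer$enrichment > 0)
  structure(list(genome_length = genome_length,
                 background_mean = background_mean, dispersion = dispersion,
                 planted_sites = planted_sites, n_replicates = n_replicates,
                 replicate_noise_sd = replicate_noise_sd,
                 stage_script = stage_script, numt_rate = numt_rate,
                 bias_kmer = bias_kmer,
                 multiplier_amplitude = multiplier_amplitude,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' The seven-stage mouse and three-stage human developmental stage labels
#' @param series \code{"mouse"} (early 2-cell through E7.2) or \code{"human"}
#'   (2-cell, 8-cell, ICM).
#' @return Character vector of ordered stage labels.
#' @export
developmental_stages <- function(series = c("mouse", "human")) {
  series <- match.arg(series)
  if (series == "mouse") c("early2C", "2C", "4C", "8C", "ICM", "E6", "E7.2")
  else c("2C", "8C", "ICM")
}

#' Simulate a random circular genome sequence
#' @param length Genome length in bases.
#' @param seed Integer seed.
#' @param name Sequence name.
#' @param gc GC content of the random sequence.
#' @return A [circular_genome()] with sequence.
#' @export
simulate_genome <- function(length = 16299L, seed = 1L, name = "mt",
                            gc = 0.4) {
  withr_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    s <- paste(sample(names(p), length, replace = TRUE, prob = p),
               collapse = "")
    circular_genome(name, length, s)
  })
}

# run expr under a seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# smooth positional multiplier shared across replicates/stages of one config
positional_multiplier <- function(config) {
  L <- config$genome_length
  withr_seed(config$seed + 1000L, {
    ph <- stats::runif(2, 0, 2 * pi)
    p <- 0:(L - 1L)
    a <- config$multiplier_amplitude
    m <- 1 + a[1] * sin(2 * pi * p / L + ph[1]) +
      a[2] * sin(4 * pi * p / L + ph[2])
    pmax(m, 0.05)
  })
}

# per-base expected coverage given planted sites (subset selects rows)
expected_mean <- function(config, mult, site_rows = NULL) {
  L <- config$genome_length
  mu <- config$background_mean * mult
  ps <- config$planted_sites
  if (!is.null(ps)) {
    rows <- if (is.null(site_rows)) seq_len(nrow(ps)) else site_rows
    for (i in rows) {
      b <- ((ps$start[i] + 0:(ps$width[i] - 1L)) %% L) + 1L
      mu[b] <- mu[b] * (1 - ps$protection[i])
    }
  }
  mu
}

#' Simulate replicate coverage tracks with planted footprints
#'
#' @param config A [simulation_config()].
#' @param genome Optional [circular_genome()] to attach (defaults to a
#'   sequence-free genome of the configured length).
#' @param stage_id Stage label for the returned tracks.
#' @param site_rows Optional subset of planted-site rows to plant (used by
#'   [simulate_stage_series()] to follow the stage script).
#' @param seed_offset Added to the config seed for the count draws, so
#'   different stages/replicate groups of one configuration are independent.
#' @return List: \code{replicates} (list of [coverage_track()]s),
#'   \code{truth} (planted sites as a data frame with \code{start},
#'   \code{end} half-open, \code{protection}), \code{multiplier}.
#' @export
simulate_track <- function(config, genome = NULL, stage_id = "stage",
                           site_rows = NULL, seed_offset = 0L) {
  stopifnot(inherits(config, "SimulationConfig"))
  L <- config$genome_length
  if (is.null(genome)) genome <- circular_genome("mt", L)
  stopifnot(genome$length == L)
  mult <- positional_multiplier(config)
  mu <- expected_mean(config, mult, site_rows)
  reps <- withr_seed(config$seed + 2000L + seed_offset, {
    lapply(seq_len(config$n_replicates), function(r) {
      scale <- exp(stats::rnorm(1, 0, config$replicate_noise_sd))
      counts <- stats::rnbinom(L, size = config$dispersion, mu = mu * scale)
      coverage_track(genome, counts, sample_id = "sim",
                     stage_id = stage_id, replicate_id = paste0("rep", r))
    })
  })
  ps <- config$planted_sites
  truth <- if (is.null(ps)) {
    data.frame(start = integer(), end = integer(), protection = numeric())
  } else {
    rows <- if (is.null(site_rows)) seq_len(nrow(ps)) else site_rows
    data.frame(start = ps$start[rows],
               end = (ps$start[rows] + ps$width[rows]) %% L,
               protection = ps$protection[rows])
  }
  if (nrow(truth)) truth$end[truth$end == 0L] <- L
  list(replicates = reps, truth = truth, multiplier = mult)
}

#' Simulate an ordered developmental stage series
#'
#' Each stage gets \code{n_replicates} tracks planting exactly the sites the
#' stage script switches on for it; the scripted occupancy is returned as the
#' ground truth matrix for end-to-end comparison.
#'
#' @param config A [simulation_config()] with a \code{stage_script}.
#' @param genome Optional [circular_genome()].
#' @return List: \code{stages} (named list; per stage the
#'   \code{simulate_track()} result), \code{truth_occupancy} (binary site x
#'   stage matrix), \code{truth_sites} (planted site coordinates).
#' @export
simulate_stage_series <- function(config, genome = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.null(config$stage_script)) stop("config carries no stage_script")
  script <- config$stage_script
  stages <- colnames(script)
  out <- vector("list", length(stages)); names(out) <- stages
  for (t in seq_along(stages)) {
    rows <- which(script[, t] == 1)
    out[[t]] <- simulate_track(config, genome, stage_id = stages[t],
                               site_rows = rows,
                               seed_offset = 10L * t)
  }
  ps <- config$planted_sites
  L <- config$genome_length
  truth_sites <- data.frame(start = ps$start,
                            end = ifelse((ps$start + ps$width) %% L == 0L, L,
                                         (ps$start + ps$width) %% L))
  list(stages = out, truth_occupancy = script, truth_sites = truth_sites)
}

#' Simulate aligned reads with NUMT alleles and optional cut-site bias
#'
#' Reads are sampled along the circle with start probability proportional to
#' the positional multiplier (and, when \code{bias_kmer} is set, boosted by
#' the configured fold enrichment at cut positions whose centered k-mer
#' matches). A \code{numt_rate} fraction of reads is of NUMT origin and
#' carries the catalog's NUMT allele at every catalog position it covers;
#' all other reads carry the reference (mitochondrial) base.
#'
#' @param config A [simulation_config()].
#' @param genome A [circular_genome()] with sequence.
#' @param catalog Optional [numt_catalog()]; without it no alleles are
#'   substituted.
#' @param n_reads Number of reads.
#' @param read_length Read length in bases (must not exceed the genome).
#' @param seed_offset Added to the config seed.
#' @return List: \code{reads} (data frame \code{start} 0-based, \code{width},
#'   \code{strand}, \code{seq}, \code{is_numt}), \code{cut_positions}
#'   (0-based 5' cut sites, one per read).
#' @export
simulate_reads <- function(config, genome, catalog = NULL, n_reads = 10000L,
                           read_length = 50L, seed_offset = 0L) {
  stopifnot(inherits(config, "SimulationConfig"), is_circular_genome(genome))
  if (is.null(genome$sequence)) stop("genome carries no sequence")
  L <- genome$length
  read_length <- as.integer(read_length)
  if (read_length > L) stop("read_length exceeds genome length")
  w <- if (L == config$genome_length) positional_multiplier(config)
       else rep(1, L)
  if (!is.null(config$bias_kmer)) {
    k <- nchar(config$bias_kmer$kmer)
    doubled <- paste0(genome$sequence, substr(genome$sequence, 1L, k))
    starts <- ((0:(L - 1L) - k %/% 2L) %% L) + 1L
    km <- substring(doubled, starts, starts + k - 1L)
    w <- w * ifelse(km == toupper(config$bias_kmer$kmer),
                    config$bias_kmer$enrichment, 1)
  }
  withr_seed(config$seed + 3000L + seed_offset, {
    start <- sample.int(L, n_reads, replace = TRUE, prob = w) - 1L
    is_numt <- stats::runif(n_reads) < config$numt_rate
    doubled_seq <- paste0(genome$sequence,
                          substr(genome$sequence, 1L, read_length))
    seqs <- substring(doubled_seq, start + 1L, start + read_length)
    if (!is.null(catalog) && any(is_numt) && nrow(catalog)) {
      for (i in seq_len(nrow(catalog))) {
        pos <- catalog$position[i]
        off <- ((pos - start) %% L + L) %% L
        hit <- which(is_numt & off < read_length)
        if (length(hit))
          substr(seqs[hit], off[hit] + 1L, off[hit] + 1L) <-
            catalog$numt_allele[i]
      }
    }
    reads <- data.frame(start = start, width = read_length, strand = "+",
                        seq = seqs, is_numt = is_numt,
                        stringsAsFactors = FALSE)
    list(reads = reads, cut_positions = start)
  })
}

#' Write simulated reads as a minimal coordinate-sorted SAM file
#'
#' Emits an @HD/@SQ header and one unpaired, forward-strand alignment line
#' per read (MAPQ 60, full-length match CIGAR), sorted by position, so the
#' file is consumable by [coverage_from_alignments()] and by samtools. Reads
#' running past the reference end are represented by their in-bounds prefix
#' (SAM cannot express a wrapped linear alignment).
#'
#' @param reads Read table from [simulate_reads()].
#' @param genome The [circular_genome()] the reads came from.
#' @param path Output SAM path.
#' @return The path, invisibly.
#' @export
write_read_sam <- function(reads, genome, path) {
  stopifnot(is_circular_genome(genome))
  L <- genome$length
  o <- order(reads$start)
  start <- reads$start[o]; width <- reads$width[o]; seqs <- reads$seq[o]
  clip <- pmin(width, L - start)                 # truncate at reference end
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", genome$name, "\tLN:", L),
    sprintf("read%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
            seq_along(start), genome$name, start + 1L, clip,
            substr(seqs, 1L, clip)))
  writeLines(lines, path)
  invisible(path)
}

#' Example planted-site designs for the developmental series
#'
#' Ready-made ground-truth designs exercising all trajectory classes: a
#' seven-stage mouse-style series (core, emergent-persistent, alternating and
#' transient rows) and a three-stage human-style series (core,
#' emergent-persistent and alternating; with three stages a single presence
#' block ending before the last stage is rare, mirroring the shorter series).
#' Sites are 30 bp wide at 0.97 protection, spaced well apart, and each
#' stage carries several planted sites, the density regime the
#' quantile-based caller is calibrated for.
#'
#' @param series \code{"mouse"} (7 stages, 10 sites) or \code{"human"}
#'   (3 stages, 8 sites).
#' @return List with \code{planted_sites} (data frame for
#'   [simulation_config()]) and \code{stage_script} (binary site x stage
#'   matrix with stage labels from [developmental_stages()]).
#' @export
example_stage_script <- function(series = c("mouse", "human")) {
  series <- match.arg(series)
  if (series == "mouse") {
    script <- rbind(
      c(1, 1, 1, 1, 1, 1, 1),   # core
      c(0, 1, 1, 1, 1, 1, 1),   # emergent_persistent
      c(0, 0, 0, 1, 1, 1, 1),   # emergent_persistent
      c(0, 0, 0, 0, 0, 1, 1),   # emergent_persistent
      c(1, 0, 1, 1, 0, 1, 1),   # alternating
      c(1, 1, 0, 1, 1, 0, 1),   # alternating
      c(0, 1, 1, 0, 1, 1, 1),   # alternating
      c(1, 1, 1, 1, 1, 0, 0),   # transient
      c(0, 1, 1, 1, 1, 1, 0),   # transient
      c(1, 1, 1, 0, 0, 0, 0))   # transient
    colnames(script) <- developmental_stages("mouse")
    starts <- c(200L, 1800L, 3400L, 5000L, 6600L, 8200L, 9800L, 11400L,
                13000L, 14600L)
  } else {
    script <- rbind(
      c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), c(1, 1, 1),   # core
      c(0, 1, 1), c(0, 0, 1),                            # emergent_persistent
      c(1, 0, 1), c(1, 0, 1))                            # alternating
    colnames(script) <- developmental_stages("human")
    starts <- c(300L, 2300L, 4300L, 6300L, 8300L, 10300L, 12300L, 14300L)
  }
  list(planted_sites = data.frame(start = starts, width = 30L,
                                  protection = 0.97),
       stage_script = script)
}
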