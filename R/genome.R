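#' Circular genome reference
#'
#' A minimal description of a circular genome: a name, a length in bases and
#' optionally the nucleotide sequence. All coordinates in the package are
#' 0-based half-open and modular: position \code{p} and \code{p + length} are
#' the same base.
#'
#' @param name Single character scalar naming the sequence (the reference name
#'   alignments must carry).
#' @param length Genome length in bases (positive integer).
#' @param sequence Optional nucleotide string of exactly \code{length} bases,
#'   alphabet A/C/G/T/N.
#' @return An object of class \code{CircularGenome} (a list with fields
#'   \code{name}, \code{length}, \code{sequence}).
#' @examples
#' g <- circular_genome("mt", 16299)
#' @export
circular_genome <- function(name, length, sequence = NULL) {
  stopifnot(is.character(name), base::length(name) == 1L, nzchar(name))
  length <- as.integer(length)
  if (is.na(length) || length < 1L)
    stop("genome length must be a positive integer")
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != length)
      stop("sequence length (", nchar(sequence), ") does not equal genome length (",
           length, ")")
    if (grepl("[^ACGTN]", sequence))
      stop("sequence contains characters outside A/C/G/T/N")
  }
  structure(list(name = name, length = length, sequence = sequence),
            class = "CircularGenome")
}

#' @export
print.CircularGenome <- function(x, ...) {
  cat("CircularGenome '", x$name, "': ", x$length, " bp",
      if (is.null(x$sequence)) " (no sequence)" else " (with sequence)",
      "\n", sep = "")
  invisible(x)
}

is_circular_genome <- function(x) inherits(x, "CircularGenome")

#' Check that two objects refer to the same genome
#' @noRd
check_same_genome <- function(a, b) {
  ga <- attr(a, "genome"); gb <- attr(b, "genome")
  if (is_circular_genome(a)) ga <- a
  if (is_circular_genome(b)) gb <- b
  if (is.null(ga) || is.null(gb)) stop("object carries no genome attribute")
  if (ga$name != gb$name || ga$length != gb$length)
    stop("genome mismatch: '", ga$name, "' (", ga$length, " bp) vs '",
         gb$name, "' (", gb$length, " bp)")
  invisible(ga)
}

#' Per-base coverage on a circular genome
#'
#' @param genome A [circular_genome()].
#' @param counts Numeric vector of non-negative per-base counts, one entry per
#'   genome base.
#' @param sample_id,stage_id,replicate_id Text labels carried through the
#'   pipeline (provenance of every downstream site call).
#' @return An object of class \code{CoverageTrack}.
#' @examples
#' g <- circular_genome("mt", 100)
#' tr <- coverage_track(g, rep(5, 100), sample_id = "s1")
#' @export
coverage_track <- function(genome, counts, sample_id = "sample",
                           stage_id = "stage", replicate_id = "rep1") {
  stopifnot(is_circular_genome(genome))
  counts <- as.numeric(counts)
  if (length(counts) != genome$length)
    stop("counts length (", length(counts), ") does not equal genome length (",
         genome$length, ")")
  if (anyNA(counts) || any(counts < 0))
    stop("coverage counts must be non-negative and NA-free")
  structure(list(genome = genome, counts = counts,
                 sample_id = as.character(sample_id),
                 stage_id = as.character(stage_id),
                 replicate_id = as.character(replicate_id)),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack on '", x$genome$name, "' (", x$genome$length, " bp): ",
      "sample=", x$sample_id, " stage=", x$stage_id, " rep=", x$replicate_id,
      "; mean depth ", signif(mean(x$counts), 4), "\n", sep = "")
  invisible(x)
}

#' Rotate a coverage track around the circle
#'
#' Returns the track whose base 0 is the original base \code{k}: counts are
#' shifted left by \code{k} modulo the genome length. Every position-dependent
#' result of the pipeline is equivariant under this rotation.
#'
#' @param track A [coverage_track()].
#' @param k Rotation offset in bases (any integer; taken modulo genome length).
#' @return A rotated \code{CoverageTrack}.
#' @export
rotate_track <- function(track, k) {
  stopifnot(inherits(track, "CoverageTrack"))
  L <- track$genome$length
  k <- ((as.integer(k) %% L) + L) %% L
  if (k == 0L) return(track)
  idx <- c((k + 1L):L, seq_len(k))
  track$counts <- track$counts[idx]
  track
}

#' Rotate a genome sequence (for equivariance checks)
#' @noRd
rotate_genome <- function(genome, k) {
  L <- genome$length
  k <- ((as.integer(k) %% L) + L) %% L
  if (k == 0L || is.null(genome$sequence)) return(genome)
  s <- genome$sequence
  genome$sequence <- paste0(substr(s, k + 1L, L), substr(s, 1L, k))
  genome
}

#' Feature annotation table
#'
#' Named, typed intervals on the circle (regulatory elements, tRNA/rRNA genes,
#' protein-coding genes, the D-loop, G-quadruplex motifs). A feature whose
#' \code{end} is less than or equal to its \code{start} wraps around the origin.
#'
#' @param genome A [circular_genome()].
#' @param feature_id Unique feature identifiers.
#' @param class Feature class; one of \code{regulatory}, \code{tRNA},
#'   \code{rRNA}, \code{protein_coding}, \code{d_loop}, \code{gqp},
#'   \code{other}.
#' @param start,end 0-based half-open coordinates on the circle.
#' @param strand \code{"+"}, \code{"-"} or \code{"."}.
#' @return A \code{data.frame} of class \code{FeatureAnnotation} with a
#'   \code{genome} attribute.
#' @export
feature_annotation <- function(genome, feature_id, class, start, end,
                               strand = ".") {
  stopifnot(is_circular_genome(genome))
  n <- length(feature_id)
  class <- rep_len(as.character(class), n)
  strand <- rep_len(as.character(strand), n)
  start <- as.integer(start); end <- as.integer(end)
  ok_class <- c("regulatory", "tRNA", "rRNA", "protein_coding", "d_loop",
                "gqp", "other")
  if (!all(class %in% ok_class))
    stop("unknown feature class: ", paste(setdiff(class, ok_class), collapse = ", "))
  if (anyDuplicated(feature_id)) stop("feature_ids must be unique")
  if (n && (any(start < 0L) || any(start >= genome$length)))
    stop("feature start out of range [0, genome length)")
  if (n && (any(end < 0L) || any(end > genome$length)))
    stop("feature end out of range")
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be '+', '-' or '.'")
  df <- data.frame(feature_id = as.character(feature_id), class = class,
                   start = start, end = end, strand = strand,
                   stringsAsFactors = FALSE)
  attr(df, "genome") <- genome
  class(df) <- c("FeatureAnnotation", "data.frame")
  df
}

#' Subset a feature annotation by class
#' @param annotation A [feature_annotation()].
#' @param classes Character vector of classes to keep.
#' @return The filtered \code{FeatureAnnotation}.
#' @export
features_of_class <- function(annotation, classes) {
  stopifnot(inherits(annotation, "FeatureAnnotation"))
  out <- annotation[annotation$class %in% classes, , drop = FALSE]
  attr(out, "genome") <- attr(annotation, "genome")
  class(out) <- c("FeatureAnnotation", "data.frame")
  out
}
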