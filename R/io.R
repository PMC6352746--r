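# Format IO: FASTA reference, coordinate-sorted SAM/BAM alignments, bedGraph
# coverage, BED/GFF feature annotation. Readers return the package's circular
# containers; writers round-trip losslessly for dense tracks and non-wrapping
# features.

#' Load a circular genome from a single-record FASTA file
#'
#' @param path Path to a FASTA file containing exactly one record (a
#'   multi-record file is rejected: the reference of this pipeline is a single
#'   mitochondrial genome).
#' @return A [circular_genome()] with sequence.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file contains no record: ", path)
  if (length(seqs) > 1L)
    stop("FASTA file contains ", length(seqs),
         " records; a single mitochondrial reference is required")
  if (Biostrings::width(seqs)[1] == 0L) stop("FASTA record is empty")
  name <- sub("\\s.*$", "", names(seqs)[1])
  circular_genome(name, Biostrings::width(seqs)[1],
                  as.character(seqs[[1]]))
}

#' Write a circular genome to FASTA
#' @param genome A [circular_genome()] with sequence.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genome <- function(genome, path) {
  stopifnot(is_circular_genome(genome))
  if (is.null(genome$sequence)) stop("genome carries no sequence")
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Per-base coverage from coordinate-sorted alignments
#'
#' Builds a circular coverage track from a SAM or BAM file. In
#' \code{full_read} mode every base covered by an alignment is incremented; in
#' \code{cut_sites} mode only the 5' insertion point of each read is counted
#' (alignment start on the plus strand, alignment end minus one on the minus
#' strand), optionally with the +4/-5 transposase offset. Alignments running
#' past the reference end wrap around the origin.
#'
#' @param path SAM or BAM file, coordinate sorted.
#' @param genome A [circular_genome()]; its name must match the alignment
#'   reference.
#' @param mode \code{"cut_sites"} (default) or \code{"full_read"}.
#' @param tn5_shift Apply the +4 (plus strand) / -5 (minus strand) transposase
#'   offset to cut sites. Default \code{FALSE}.
#' @param dedup Remove duplicate alignments (same start, width, strand).
#'   Default \code{FALSE}: mitochondrial coverage is legitimately deep and
#'   deduplication discards true signal.
#' @param sample_id,stage_id,replicate_id Labels for the returned track.
#' @return A [coverage_track()].
#' @export
coverage_from_alignments <- function(path, genome,
                                     mode = c("cut_sites", "full_read"),
                                     tn5_shift = FALSE, dedup = FALSE,
                                     sample_id = "sample", stage_id = "stage",
                                     replicate_id = "rep1") {
  mode <- match.arg(mode)
  stopifnot(is_circular_genome(genome))
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "cigar", "strand"),
                               flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  a <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(a$pos)
  rname <- as.character(a$rname)[keep]
  pos <- a$pos[keep]; cig <- a$cigar[keep]
  strand <- as.character(a$strand)[keep]
  if (length(pos) && any(rname != genome$name))
    stop("alignment reference '", unique(rname)[1],
         "' does not match genome '", genome$name, "'")
  if (is.unsorted(pos)) stop("alignments are not coordinate sorted")
  L <- genome$length
  w <- if (length(cig)) GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
       else integer(0)
  start0 <- pos - 1L                      # SAM is 1-based
  if (dedup) {
    k <- !duplicated(data.frame(start0, w, strand))
    start0 <- start0[k]; w <- w[k]; strand <- strand[k]
  }
  counts <- numeric(L)
  if (length(start0)) {
    if (mode == "full_read") {
      # difference-array accumulation with modular wrap
      s <- start0 %% L
      e <- s + w
      wrap <- e > L
      adds <- c(s, rep(0L, sum(wrap)))
      subs <- c(pmin(e, L), e[wrap] - L)
      # a subtraction at position L falls off the half-open end
      dsub <- tabulate(subs + 1L, nbins = L + 1L)[seq_len(L)]
      counts <- cumsum(tabulate(adds + 1L, nbins = L) - dsub)
    } else {
      cut <- ifelse(strand == "-", start0 + w - 1L, start0)
      if (tn5_shift) cut <- cut + ifelse(strand == "-", -5L, 4L)
      cut <- ((cut %% L) + L) %% L
      counts <- tabulate(cut + 1L, nbins = L)
    }
  }
  coverage_track(genome, counts, sample_id, stage_id, replicate_id)
}

#' Load a dense coverage track from bedGraph
#'
#' Intervals are 0-based half-open; bases not covered by any record get 0.
#'
#' @param path bedGraph file.
#' @param genome A [circular_genome()].
#' @param sample_id,stage_id,replicate_id Labels for the returned track.
#' @return A [coverage_track()].
#' @export
load_coverage <- function(path, genome, sample_id = "sample",
                          stage_id = "stage", replicate_id = "rep1") {
  stopifnot(is_circular_genome(genome))
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  counts <- numeric(genome$length)
  if (file.size(path) > 0) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr)) {
      s <- GenomicRanges::start(gr) - 1L       # to 0-based
      e <- GenomicRanges::end(gr)              # half-open end
      v <- S4Vectors::mcols(gr)$score
      if (any(s < 0L) || any(e > genome$length))
        stop("bedGraph interval out of genome bounds")
      if (any(v < 0)) stop("bedGraph contains negative coverage")
      for (i in seq_along(s)) counts[(s[i] + 1L):e[i]] <- v[i]
    }
  }
  coverage_track(genome, counts, sample_id, stage_id, replicate_id)
}

#' Write a coverage track as bedGraph
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_coverage <- function(track, path) {
  stopifnot(inherits(track, "CoverageTrack"))
  r <- rle(track$counts)
  e <- cumsum(r$lengths)
  s <- c(0L, e[-length(e)])
  keep <- r$values != 0
  df <- data.frame(chrom = track$genome$name, start = s[keep],
                   end = e[keep], value = r$values[keep])
  # bedGraph is 0-based half-open as written
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load features from BED or GFF
#'
#' BED coordinates are taken as 0-based half-open, GFF as 1-based closed (both
#' converted to the internal 0-based half-open convention). A wrap-around
#' feature split into two BED records sharing one name — one ending at the
#' genome end, one starting at base 0 — is reassembled into a single wrapped
#' feature.
#'
#' @param path BED or GFF/GFF3 file (format chosen by extension).
#' @param genome A [circular_genome()].
#' @param class_map Named character vector mapping the file's feature names
#'   (BED name column) or types (GFF type column) to the annotation classes of
#'   [feature_annotation()]; unmapped features become \code{"other"}.
#' @return A [feature_annotation()].
#' @export
load_features <- function(path, genome, class_map = NULL) {
  stopifnot(is_circular_genome(genome))
  if (!file.exists(path)) stop("feature file not found: ", path)
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE)
  gr <- rtracklayer::import(path, format = if (is_gff) "gff" else "bed")
  if (!length(gr))
    return(feature_annotation(genome, character(), character(),
                              integer(), integer(), character()))
  s <- GenomicRanges::start(gr) - 1L           # both formats land 1-based here
  e <- GenomicRanges::end(gr)                  # closed end -> half-open end
  if (any(s < 0L) || any(e > genome$length))
    stop("feature coordinate out of genome range")
  mc <- S4Vectors::mcols(gr)
  nm <- if (!is.null(mc$name)) as.character(mc$name)
        else if (!is.null(mc$Name)) as.character(mc$Name)
        else if (!is.null(mc$ID)) as.character(mc$ID)
        else paste0("feature_", seq_along(gr))
  nm[is.na(nm)] <- paste0("feature_", which(is.na(nm)))
  type_key <- if (is_gff && !is.null(mc$type)) as.character(mc$type) else nm
  cls <- rep("other", length(gr))
  if (!is.null(class_map)) {
    hit <- type_key %in% names(class_map)
    cls[hit] <- unname(class_map[type_key[hit]])
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(feature_id = nm, class = cls, start = s, end = e,
                   strand = strand, stringsAsFactors = FALSE)
  # reassemble origin-split pairs (same name; one hits the end, one base 0)
  dup <- unique(df$feature_id[duplicated(df$feature_id)])
  for (id in dup) {
    rows <- which(df$feature_id == id)
    if (length(rows) == 2L) {
      a <- rows[df$end[rows] == genome$length]
      b <- rows[df$start[rows] == 0L]
      if (length(a) == 1L && length(b) == 1L && a != b) {
        df$end[a] <- df$end[b]                 # wrapped: end < start
        df <- df[-b, , drop = FALSE]
        next
      }
    }
    stop("duplicate feature_id '", id, "' is not an origin-split pair")
  }
  feature_annotation(genome, df$feature_id, df$class, df$start, df$end,
                     df$strand)
}

#' Write a feature annotation as BED6
#'
#' Wrapped features are split into two blocks sharing the feature name, the
#' encoding [load_features()] reassembles.
#'
#' @param annotation A [feature_annotation()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_features <- function(annotation, path) {
  stopifnot(inherits(annotation, "FeatureAnnotation"))
  g <- attr(annotation, "genome")
  rows <- list()
  for (i in seq_len(nrow(annotation))) {
    s <- annotation$start[i]; e <- annotation$end[i]
    if (e > s) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$name, start = s, end = e, name = annotation$feature_id[i],
        score = 0, strand = annotation$strand[i])
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$name, start = s, end = g$length,
        name = annotation$feature_id[i], score = 0,
        strand = annotation$strand[i])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$name, start = 0L, end = e,
        name = annotation$feature_id[i], score = 0,
        strand = annotation$strand[i])
    }
  }
  df <- do.call(rbind, rows)
  df$strand[df$strand == "."] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a site set as BED6 plus a score TSV
#'
#' The BED score column is \code{1000 * (1 - score / threshold)} clipped to
#' [0, 1000] (deeper footprints score higher); the companion TSV keeps exact
#' footprint-occupancy scores.
#'
#' @param sites A \code{SiteSet} (see [scan_footprints()]).
#' @param path Output BED path; the TSV is written next to it with extension
#'   \code{.tsv}.
#' @param threshold Calling threshold used for the BED score transform;
#'   defaults to the set's stored threshold attribute.
#' @return The BED path, invisibly.
#' @export
write_sites_bed <- function(sites, path, threshold = attr(sites, "threshold")) {
  stopifnot(inherits(sites, "SiteSet"))
  g <- attr(sites, "genome")
  if (is.null(threshold) || !is.finite(threshold)) threshold <- 1
  bedscore <- round(pmin(1000, pmax(0, 1000 * (1 - sites$score / threshold))))
  df <- data.frame(chrom = if (nrow(sites)) g$name else character(),
                   start = sites$start, end = sites$end,
                   name = if (nrow(sites))
                     sprintf("site_%04d", seq_len(nrow(sites))) else character(),
                   score = bedscore, strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tsv <- sub("\\.bed$", ".tsv", path)
  if (tsv == path) tsv <- paste0(path, ".tsv")
  utils::write.table(
    data.frame(start = sites$start, end = sites$end, score = sites$score,
               stage_id = sites$stage_id, sample_id = sites$sample_id),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
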