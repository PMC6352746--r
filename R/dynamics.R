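# Occupancy dynamics across an ordered developmental series.

#' Build the site-by-stage occupancy matrix
#'
#' Reference sites are the transitive merge of all per-stage sites; presence
#' of reference site s at stage t is 1 iff some stage-t site overlaps s by at
#' least one base (modular).
#'
#' @param per_stage_sites Named list of \code{SiteSet}s in developmental
#'   order (names are the stage labels; unnamed lists get \code{stage1..n}).
#' @return An \code{OccupancyMatrix}: list with \code{sites} (merged
#'   reference \code{SiteSet}), \code{stages} (ordered labels) and
#'   \code{presence} (binary site x stage matrix).
#' @export
build_occupancy <- function(per_stage_sites) {
  stopifnot(is.list(per_stage_sites), length(per_stage_sites) >= 2L)
  stages <- names(per_stage_sites)
  if (is.null(stages) || any(!nzchar(stages)))
    stages <- paste0("stage", seq_along(per_stage_sites))
  ref <- merge_sites(per_stage_sites)
  g <- attr(ref, "genome")
  pres <- matrix(0L, nrow(ref), length(stages),
                 dimnames = list(NULL, stages))
  for (t in seq_along(per_stage_sites)) {
    s <- per_stage_sites[[t]]
    if (!nrow(s) || !nrow(ref)) next
    m <- interval_overlap_matrix(ref, s, g$length)
    pres[, t] <- as.integer(rowSums(m) > 0L)
  }
  structure(list(sites = ref, stages = stages, presence = pres),
            class = "OccupancyMatrix")
}

#' @export
print.OccupancyMatrix <- function(x, ...) {
  cat("OccupancyMatrix: ", nrow(x$presence), " reference sites x ",
      length(x$stages), " stages (", paste(x$stages, collapse = " < "),
      ")\n", sep = "")
  invisible(x)
}

#' Classify a developmental occupancy trajectory
#'
#' Partitions every nonzero binary presence vector into exactly one of four
#' classes: \code{core} (present at every stage), \code{emergent_persistent}
#' (absent early, then present through the final stage), \code{alternating}
#' (present, lost, present again at any point), and \code{transient} (a
#' single block of presence that ends before the final stage). A site present
#' only at the last stage is emergent-persistent (persistence suffix of
#' length one).
#'
#' @param presence_vector Binary vector (0/1), one entry per ordered stage,
#'   length >= 2, not all zero.
#' @return One of \code{"core"}, \code{"emergent_persistent"},
#'   \code{"alternating"}, \code{"transient"}.
#' @export
classify_dynamics <- function(presence_vector) {
  v <- as.integer(presence_vector)
  n <- length(v)
  if (n < 2L) stop("at least two stages are required")
  if (!all(v %in% c(0L, 1L))) stop("presence vector must be binary")
  ones <- which(v == 1L)
  if (!length(ones)) stop("zero presence vector: site observed at no stage")
  first <- ones[1]; last <- ones[length(ones)]
  if (any(v[first:last] == 0L)) return("alternating")
  if (last == n) {
    if (first == 1L) return("core")
    return("emergent_persistent")
  }
  "transient"
}

#' Classify every row of an occupancy matrix
#' @param occupancy An \code{OccupancyMatrix} from [build_occupancy()].
#' @return Character vector of classes, one per reference site.
#' @export
classify_occupancy <- function(occupancy) {
  stopifnot(inherits(occupancy, "OccupancyMatrix"))
  apply(occupancy$presence, 1L, classify_dynamics)
}

#' Per-stage site gain and loss
#'
#' Counts, for each stage, the reference sites that switch on (absent at the
#' previous stage, present now) and off. At the first stage every present
#' site counts as gained and nothing as lost.
#'
#' @param occupancy An \code{OccupancyMatrix}.
#' @return Data frame with columns \code{stage}, \code{gained}, \code{lost}.
#' @export
gain_loss <- function(occupancy) {
  stopifnot(inherits(occupancy, "OccupancyMatrix"))
  p <- occupancy$presence
  nt <- ncol(p)
  gained <- integer(nt); lost <- integer(nt)
  gained[1] <- sum(p[, 1] == 1L)
  for (t in 2:nt) {
    gained[t] <- sum(p[, t - 1] == 0L & p[, t] == 1L)
    lost[t] <- sum(p[, t - 1] == 1L & p[, t] == 0L)
  }
  data.frame(stage = occupancy$stages, gained = gained, lost = lost)
}

#' Distribution of sites over annotation classes
#'
#' A site counts toward a class iff it overlaps at least one feature of that
#' class (a site spanning a boundary counts in both classes). The occupied
#' base fraction of a class is the number of class bases covered by any site
#' divided by the class's total bases.
#'
#' @param sites A \code{SiteSet}.
#' @param annotation A [feature_annotation()].
#' @param classes Classes to report; defaults to those present in the
#'   annotation.
#' @return Data frame with \code{class}, \code{n_sites},
#'   \code{occupied_fraction}.
#' @export
region_distribution <- function(sites, annotation, classes = NULL) {
  stopifnot(inherits(sites, "SiteSet"), inherits(annotation, "FeatureAnnotation"))
  if (!nrow(annotation)) stop("empty annotation")
  g <- check_same_genome(sites, annotation)
  L <- g$length
  if (is.null(classes)) classes <- unique(annotation$class)
  site_cov <- interval_bitmap(sites, L)
  out <- lapply(classes, function(cl) {
    feats <- annotation[annotation$class == cl, , drop = FALSE]
    if (!nrow(feats))
      return(data.frame(class = cl, n_sites = 0L, occupied_fraction = NA_real_))
    m <- if (nrow(sites)) interval_overlap_matrix(sites, feats, L)
         else matrix(FALSE, 0, nrow(feats))
    fc <- interval_bitmap(feats, L)
    data.frame(class = cl, n_sites = sum(rowSums(m) > 0L),
               occupied_fraction = sum(fc & site_cov) / sum(fc))
  })
  do.call(rbind, out)
}

#' Overlap of adult footprint sites with the embryonic series
#'
#' For each adult site reports whether it overlaps any embryonic reference
#' site and, if so, the earliest developmental stage at which an overlapping
#' embryonic site was present. The summary gives the overlap count/fraction
#' and the distribution of earliest stages.
#'
#' @param adult_sites A \code{SiteSet} (typically the output of
#'   [prevalence_filter()] over adult samples).
#' @param occupancy The embryonic \code{OccupancyMatrix}.
#' @return List with \code{table} (per adult site: coordinates,
#'   \code{overlaps_embryo}, \code{earliest_stage}) and \code{summary}
#'   (\code{n_adult}, \code{n_overlapping}, \code{fraction_overlapping},
#'   \code{earliest_stage_counts}).
#' @export
embryo_adult_overlap <- function(adult_sites, occupancy) {
  stopifnot(inherits(adult_sites, "SiteSet"),
            inherits(occupancy, "OccupancyMatrix"))
  g <- check_same_genome(adult_sites, occupancy$sites)
  L <- g$length
  n <- nrow(adult_sites)
  ov <- logical(n); earliest <- rep(NA_character_, n)
  if (n && nrow(occupancy$sites)) {
    m <- interval_overlap_matrix(adult_sites, occupancy$sites, L)
    first_stage <- apply(occupancy$presence, 1L, function(r) which(r == 1L)[1])
    for (i in seq_len(n)) {
      hits <- which(m[i, ])
      if (length(hits)) {
        ov[i] <- TRUE
        earliest[i] <- occupancy$stages[min(first_stage[hits])]
      }
    }
  }
  tab <- data.frame(start = adult_sites$start, end = adult_sites$end,
                    overlaps_embryo = ov, earliest_stage = earliest)
  counts <- table(factor(earliest[ov], levels = occupancy$stages))
  list(table = tab,
       summary = list(n_adult = n, n_overlapping = sum(ov),
                      fraction_overlapping = if (n) sum(ov) / n else NA_real_,
                      earliest_stage_counts = counts))
}

#' Write an occupancy matrix as TSV
#' @param occupancy An \code{OccupancyMatrix}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_occupancy <- function(occupancy, path) {
  stopifnot(inherits(occupancy, "OccupancyMatrix"))
  df <- data.frame(start = occupancy$sites$start, end = occupancy$sites$end,
                   occupancy$presence, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
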