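# Footprint occupancy scoring and site calling.
#
# The footprint occupancy score (FOS) at a position compares coverage in a
# central window with coverage in the two flanking windows of equal width:
#
#   FOS = (C + pc) / max(Lf, eps) + (C + pc) / max(Rf, eps)
#
# where C, Lf, Rf are the mean per-base coverage of the center, left and
# right windows, pc a pseudocount and eps a small guard against empty flanks.
# Low scores indicate protection (a footprint). Windows slide over every
# genome position at a range of widths; the per-position statistic is the
# minimum score over all scanned configurations.

#' Scoring parameters for footprint calling
#'
#' Window geometry uses equal center and flank widths, so a center width of
#' \code{c} scans a total window of \code{3c} bases. The default center widths
#' 6..41 give total windows of 18..123 bases, inside the 18-124 base envelope
#' the method is defined for.
#'
#' @param center_lengths Integer vector of center-window widths to scan.
#' @param min_total_window,max_total_window Bounds (bases) every scanned total
#'   window (3 x center width) must respect.
#' @param min_flank_mean Minimum mean flank coverage for a configuration to be
#'   scorable at a position; positions scorable under no configuration break
#'   candidate runs and never seed a site. Guards against calls in coverage
#'   deserts.
#' @param call_quantile Quantile of the null best-score distribution used as
#'   the calling threshold (positions strictly below it are candidate bases).
#' @param pseudocount Added to the center mean before the ratio.
#' @param eps Lower guard on flank means in the denominator.
#' @return A list of class \code{ScoringParams}.
#' @export
scoring_params <- function(center_lengths = 6:41,
                           min_total_window = 18L, max_total_window = 124L,
                           min_flank_mean = 5, call_quantile = 0.01,
                           pseudocount = 1, eps = 0.25) {
  center_lengths <- sort(unique(as.integer(center_lengths)))
  if (!length(center_lengths) || any(center_lengths < 1L))
    stop("center_lengths must be positive integers")
  tot <- 3L * center_lengths
  if (any(tot < min_total_window) || any(tot > max_total_window))
    stop("total windows (3 x center) must lie in [", min_total_window, ", ",
         max_total_window, "]")
  if (call_quantile <= 0 || call_quantile >= 1)
    stop("call_quantile must be in (0, 1)")
  if (pseudocount < 0 || min_flank_mean < 0) stop("negative parameter")
  structure(list(center_lengths = center_lengths,
                 min_total_window = as.integer(min_total_window),
                 max_total_window = as.integer(max_total_window),
                 min_flank_mean = min_flank_mean,
                 call_quantile = call_quantile,
                 pseudocount = pseudocount, eps = eps),
            class = "ScoringParams")
}

#' Footprint occupancy score at one position
#'
#' The center window of \code{center_len} bases is placed so that it contains
#' \code{position} (center start = position - floor(center_len / 2), modular);
#' flanks of \code{flank_len} bases sit immediately left and right of it.
#'
#' @param track A [coverage_track()].
#' @param position 0-based genome position.
#' @param center_len,flank_len Window widths in bases (>= 1).
#' @param pseudocount Added to the center mean.
#' @param eps Lower guard on flank means.
#' @return The (non-negative, finite) footprint occupancy score.
#' @examples
#' g <- circular_genome("mt", 200)
#' tr <- coverage_track(g, rep(9, 200))
#' fos_score(tr, 100, 10, 10)  # uniform coverage 9: (9+1)/9 * 2 = 2.222
#' @export
fos_score <- function(track, position, center_len, flank_len,
                      pseudocount = 1, eps = 0.25) {
  stopifnot(inherits(track, "CoverageTrack"))
  center_len <- as.integer(center_len); flank_len <- as.integer(flank_len)
  if (center_len < 1L || flank_len < 1L)
    stop("center_len and flank_len must be >= 1")
  L <- track$genome$length
  if (center_len + 2L * flank_len > L)
    stop("total window exceeds genome length")
  cs <- ((position - center_len %/% 2L) %% L + L) %% L
  idx <- function(s, w) ((s + 0:(w - 1L)) %% L) + 1L
  cm <- mean(track$counts[idx(cs, center_len)])
  lm <- mean(track$counts[idx(cs - flank_len, flank_len)])
  rm_ <- mean(track$counts[idx(cs + center_len, flank_len)])
  (cm + pseudocount) / max(lm, eps) + (cm + pseudocount) / max(rm_, eps)
}

# Vectorised per-position best score over all configurations.
# Returns list(best = numeric(L), scorable = logical(L)).
best_fos_scores <- function(track, params) {
  L <- track$genome$length
  counts <- track$counts
  S <- c(0, cumsum(c(counts, counts)))       # prefix sums over doubled track
  pos <- 0:(L - 1L)
  best <- rep(Inf, L)
  scorable <- logical(L)
  roll <- function(starts, w) {              # mean over w bases from starts
    st <- ((starts %% L) + L) %% L
    (S[st + w + 1L] - S[st + 1L]) / w
  }
  for (cl in params$center_lengths) {
    if (3L * cl > L) next
    cs <- pos - cl %/% 2L
    cm <- roll(cs, cl)
    lm <- roll(cs - cl, cl)
    rm_ <- roll(cs + cl, cl)
    ok <- pmin(lm, rm_) >= params$min_flank_mean
    sc <- (cm + params$pseudocount) / pmax(lm, params$eps) +
          (cm + params$pseudocount) / pmax(rm_, params$eps)
    sc[!ok] <- Inf
    scorable <- scorable | ok
    best <- pmin(best, sc)
  }
  list(best = best, scorable = scorable)
}

new_site_set <- function(genome, start = integer(), end = integer(),
                         score = numeric(), stage_id = character(),
                         sample_id = character(), threshold = NA_real_) {
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   score = as.numeric(score),
                   stage_id = as.character(stage_id),
                   sample_id = as.character(sample_id),
                   stringsAsFactors = FALSE)
  attr(df, "genome") <- genome
  attr(df, "threshold") <- threshold
  class(df) <- c("SiteSet", "data.frame")
  df
}

#' Construct a site set from coordinates
#'
#' @param genome A [circular_genome()].
#' @param start,end 0-based half-open circular coordinates (end < start
#'   wraps the origin).
#' @param score Footprint occupancy scores (defaults to \code{NA}).
#' @param stage_id,sample_id Provenance labels (recycled).
#' @return A \code{SiteSet} data frame sorted by start.
#' @export
site_set <- function(genome, start, end, score = NA_real_,
                     stage_id = "stage", sample_id = "sample") {
  stopifnot(is_circular_genome(genome))
  n <- length(start)
  iv_check(as.integer(start), as.integer(end), genome$length)
  df <- new_site_set(genome, start, end, rep_len(as.numeric(score), n),
                     rep_len(stage_id, n), rep_len(sample_id, n))
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "genome") <- genome
  class(df) <- c("SiteSet", "data.frame")
  df
}

#' Call footprint sites on a coverage track
#'
#' Scores every position with the minimum footprint occupancy score over all
#' scanned window configurations, derives an empirical calling threshold, and
#' reports maximal circular runs of positions scoring strictly below it.
#'
#' The threshold is the \code{call_quantile} of the null best-score
#' distribution built from random circular rotations of the track. Because
#' the best-score field is exactly rotation-equivariant, every rotation
#' contributes the identical multiset of scores, so the pooled null quantile
#' equals the quantile of the observed track's own per-position best scores;
#' it is computed directly from that single scan. A consequence of the strict
#' comparison is that a constant-score (e.g. uniform-coverage) track calls no
#' sites. Unscorable positions (all flank means below \code{min_flank_mean})
#' break runs and never seed a site.
#'
#' @param track A [coverage_track()].
#' @param params A [scoring_params()].
#' @return A \code{SiteSet}: columns \code{start}, \code{end} (0-based
#'   half-open, wrap-around possible), \code{score} (run minimum),
#'   \code{stage_id}, \code{sample_id}; attributes \code{genome} and
#'   \code{threshold}.
#' @export
scan_footprints <- function(track, params = scoring_params()) {
  stopifnot(inherits(track, "CoverageTrack"))
  L <- track$genome$length
  if (all(track$counts == 0)) {
    warning("all-zero coverage track: no positions are scorable")
    return(new_site_set(track$genome))
  }
  bf <- best_fos_scores(track, params)
  finite <- is.finite(bf$best)
  if (!any(finite)) {
    warning("no scorable positions (coverage below min_flank_mean everywhere)")
    return(new_site_set(track$genome))
  }
  threshold <- stats::quantile(bf$best[finite], probs = params$call_quantile,
                               names = FALSE, type = 7)
  called <- finite & bf$best < threshold
  if (!any(called)) return(new_site_set(track$genome, threshold = threshold))
  # maximal circular runs of called positions
  r <- rle(called)
  ends <- cumsum(r$lengths)                 # 1-based inclusive run ends
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  runs <- data.frame(start = starts[r$values] - 1L,   # 0-based
                     end = ends[r$values])            # half-open
  if (nrow(runs) > 1L && called[1L] && called[L]) {
    # join the run touching the origin
    first <- 1L; last <- nrow(runs)
    runs$start[first] <- runs$start[last]
    runs <- runs[-last, , drop = FALSE]
  }
  score <- vapply(seq_len(nrow(runs)), function(i) {
    len <- interval_length(runs$start[i], runs$end[i], L)
    b <- ((runs$start[i] + 0:(len - 1L)) %% L) + 1L
    min(bf$best[b])
  }, numeric(1))
  out <- new_site_set(track$genome, runs$start, runs$end, score,
                      rep(track$stage_id, nrow(runs)),
                      rep(track$sample_id, nrow(runs)), threshold = threshold)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genome") <- track$genome
  attr(out, "threshold") <- threshold
  class(out) <- c("SiteSet", "data.frame")
  out
}

#' Replicate-concordant footprint sites
#'
#' Keeps only sites supported by both replicates: a site is retained iff it
#' shares at least one base (modular) with a site of the other replicate.
#' Retained coordinates are, by default, the union of each overlapping pair
#' (merged transitively afterwards so the result is non-overlapping);
#' \code{mode = "intersection"} keeps only the shared bases.
#'
#' @param rep_a,rep_b \code{SiteSet}s from the two replicates of one stage.
#' @param mode \code{"union"} (default) or \code{"intersection"}.
#' @return A \code{SiteSet}; symmetric in its two arguments.
#' @export
concordant_sites <- function(rep_a, rep_b, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  g <- check_same_genome(rep_a, rep_b)
  L <- g$length
  if (!nrow(rep_a) || !nrow(rep_b)) return(new_site_set(g))
  m <- interval_overlap_matrix(rep_a, rep_b, L)
  pairs <- which(m, arr.ind = TRUE)
  if (!nrow(pairs)) return(new_site_set(g))
  pieces <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    sc <- suppressWarnings(min(rep_a$score[i], rep_b$score[j], na.rm = TRUE))
    if (!is.finite(sc)) sc <- NA_real_
    if (mode == "union") {
      # union of an overlapping pair is a single circular interval: merge
      mu <- merge_circular(data.frame(start = c(rep_a$start[i], rep_b$start[j]),
                                      end = c(rep_a$end[i], rep_b$end[j])), L)
      pieces[[k]] <- data.frame(start = mu$intervals$start,
                                end = mu$intervals$end, score = sc)
    } else {
      sa <- iv_segments(rep_a$start[i], rep_a$end[i], L)
      sb <- iv_segments(rep_b$start[j], rep_b$end[j], L)
      xs <- xe <- integer(0)
      for (u in seq_len(nrow(sa))) for (v in seq_len(nrow(sb))) {
        s <- max(sa$seg_start[u], sb$seg_start[v])
        e <- min(sa$seg_end[u], sb$seg_end[v])
        if (s < e) { xs <- c(xs, s); xe <- c(xe, e) }
      }
      pieces[[k]] <- data.frame(start = xs, end = xe, score = sc)
    }
  }
  dd <- do.call(rbind, pieces)
  mm <- merge_circular(dd[, c("start", "end")], L)
  score <- vapply(seq_len(nrow(mm$intervals)),
                  function(gi) min(dd$score[mm$group == gi]), numeric(1))
  out <- new_site_set(g, mm$intervals$start, mm$intervals$end, score,
                      rep(rep_a$stage_id[1] %||% "stage", nrow(mm$intervals)),
                      rep(rep_a$sample_id[1] %||% "sample", nrow(mm$intervals)))
  attr(out, "threshold") <- attr(rep_a, "threshold")
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1])) b else a

#' Merge site sets by transitive single-base overlap
#'
#' Sites (within or across the supplied sets) that share at least one base are
#' merged transitively into one site; half-open adjacency does not merge. The
#' result is pairwise non-overlapping and sorted by start. Provenance
#' (contributing stages and samples) is aggregated; each merged site's score
#' is the minimum over its members.
#'
#' @param sets A \code{SiteSet} or list of \code{SiteSet}s on one genome.
#' @return A merged \code{SiteSet} with comma-joined \code{stage_id} /
#'   \code{sample_id} provenance.
#' @export
merge_sites <- function(sets) {
  if (inherits(sets, "SiteSet")) sets <- list(sets)
  stopifnot(length(sets) >= 1L)
  g <- attr(sets[[1]], "genome")
  for (s in sets) check_same_genome(sets[[1]], s)
  all <- do.call(rbind, lapply(sets, function(s) as.data.frame(s)))
  if (is.null(all) || !nrow(all)) return(new_site_set(g))
  m <- merge_circular(all[, c("start", "end")], g$length)
  agg <- function(x) paste(unique(x), collapse = ",")
  score <- vapply(seq_len(nrow(m$intervals)),
                  function(i) suppressWarnings(min(all$score[m$group == i],
                                                   na.rm = TRUE)),
                  numeric(1))
  score[!is.finite(score)] <- NA_real_
  stg <- vapply(seq_len(nrow(m$intervals)),
                function(i) agg(all$stage_id[m$group == i]), character(1))
  smp <- vapply(seq_len(nrow(m$intervals)),
                function(i) agg(all$sample_id[m$group == i]), character(1))
  new_site_set(g, m$intervals$start, m$intervals$end, score, stg, smp)
}

#' Filter merged sites by cross-sample prevalence
#'
#' Merges the per-sample site sets into reference sites, then keeps each
#' reference site iff the fraction of samples contributing at least one
#' overlapping site reaches \code{min_fraction} (\code{>=} by default;
#' strictly \code{>} with \code{strict = TRUE}, for "common to more than x%
#' of samples" usage).
#'
#' @param sets List of \code{SiteSet}s, one per sample.
#' @param min_fraction Required fraction of samples in (0, 1].
#' @param strict Require strictly greater than \code{min_fraction}.
#' @return A \code{SiteSet} of retained reference sites, with a
#'   \code{prevalence} column (fraction of supporting samples).
#' @export
prevalence_filter <- function(sets, min_fraction, strict = FALSE) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must be in (0, 1]")
  ref <- merge_sites(sets)
  if (!nrow(ref)) return(ref)
  g <- attr(ref, "genome")
  nsup <- integer(nrow(ref))
  for (s in sets) {
    if (!nrow(s)) next
    m <- interval_overlap_matrix(ref, s, g$length)
    nsup <- nsup + (rowSums(m) > 0L)
  }
  frac <- nsup / length(sets)
  keep <- if (strict) frac > min_fraction else frac >= min_fraction
  out <- ref[keep, , drop = FALSE]
  out$prevalence <- frac[keep]
  rownames(out) <- NULL
  attr(out, "genome") <- g
  class(out) <- c("SiteSet", "data.frame")
  out
}
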