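# Circular interval algebra.
#
# Intervals are 0-based half-open on a circle of length L. A record with
# end > start is ordinary; end < start wraps the origin (covers start..L-1
# and 0..end-1); start == 0, end == L is the full circle. end == start is
# invalid (no empty intervals). Overlap means >= 1 shared base: half-open
# adjacency ([10,30) next to [30,50)) is NOT overlap, including at the origin.

iv_check <- function(start, end, L) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) return(invisible(TRUE))
  if (any(start < 0L) || any(start >= L)) stop("interval start out of [0, L)")
  if (any(end < 0L) || any(end > L)) stop("interval end out of [0, L]")
  if (any(end == start)) stop("empty interval (end == start)")
  invisible(TRUE)
}

#' Length of circular intervals
#' @param start,end 0-based half-open circular coordinates (end < start wraps).
#' @param L Genome length.
#' @return Integer vector of interval lengths in bases.
#' @export
interval_length <- function(start, end, L) {
  ifelse(end > start, end - start, end - start + L)
}

# Decompose each circular interval into 1 or 2 linear half-open segments.
# Returns data.frame(seg_start, seg_end, id) with id = input row index.
iv_segments <- function(start, end, L) {
  n <- length(start)
  if (n == 0L)
    return(data.frame(seg_start = integer(), seg_end = integer(), id = integer()))
  wrap <- end < start
  s1 <- start
  e1 <- ifelse(wrap, L, end)
  out <- data.frame(seg_start = s1, seg_end = e1, id = seq_len(n))
  if (any(wrap & end > 0L)) {
    w <- which(wrap & end > 0L)
    out <- rbind(out, data.frame(seg_start = 0L, seg_end = end[w], id = w))
  }
  out
}

#' Pairwise overlap test between two sets of circular intervals
#'
#' @param a_start,a_end,b_start,b_end Coordinate vectors (recycled pairwise is
#'   NOT done; use [interval_overlap_matrix()] for all-vs-all).
#' @param L Genome length.
#' @return Logical vector: does interval i of A share at least one base with
#'   interval i of B?
#' @export
intervals_overlap <- function(a_start, a_end, b_start, b_end, L) {
  n <- max(length(a_start), length(b_start))
  a_start <- rep_len(a_start, n); a_end <- rep_len(a_end, n)
  b_start <- rep_len(b_start, n); b_end <- rep_len(b_end, n)
  out <- logical(n)
  for (i in seq_len(n)) {
    sa <- iv_segments(a_start[i], a_end[i], L)
    sb <- iv_segments(b_start[i], b_end[i], L)
    hit <- FALSE
    for (j in seq_len(nrow(sa))) {
      if (any(pmax(sa$seg_start[j], sb$seg_start) <
              pmin(sa$seg_end[j], sb$seg_end))) { hit <- TRUE; break }
    }
    out[i] <- hit
  }
  out
}

#' All-vs-all overlap matrix between two circular interval sets
#' @param a,b Data frames with \code{start}, \code{end} columns.
#' @param L Genome length.
#' @return Logical matrix \code{nrow(a)} x \code{nrow(b)}.
#' @export
interval_overlap_matrix <- function(a, b, L) {
  m <- matrix(FALSE, nrow(a), nrow(b))
  if (!nrow(a) || !nrow(b)) return(m)
  sa <- iv_segments(a$start, a$end, L)
  sb <- iv_segments(b$start, b$end, L)
  for (i in seq_len(nrow(sa))) {
    hit <- pmax(sa$seg_start[i], sb$seg_start) < pmin(sa$seg_end[i], sb$seg_end)
    if (any(hit)) {
      rows <- sa$id[i]; cols <- unique(sb$id[hit])
      m[rows, cols] <- TRUE
    }
  }
  m
}

#' Circular gap between two intervals
#'
#' Number of bases strictly between two non-overlapping circular intervals,
#' along the shorter side. Overlapping intervals have gap 0.
#'
#' @param a_start,a_end,b_start,b_end Coordinates (vectorised elementwise).
#' @param L Genome length.
#' @return Integer vector of gaps in bases (0 when the intervals overlap).
#' @export
circular_gap <- function(a_start, a_end, b_start, b_end, L) {
  n <- max(length(a_start), length(b_start))
  a_start <- rep_len(a_start, n); a_end <- rep_len(a_end, n)
  b_start <- rep_len(b_start, n); b_end <- rep_len(b_end, n)
  ov <- intervals_overlap(a_start, a_end, b_start, b_end, L)
  # distance from A's end to B's start going clockwise, and the reverse
  d1 <- ((b_start - a_end) %% L + L) %% L
  d2 <- ((a_start - b_end) %% L + L) %% L
  ifelse(ov, 0L, pmin(d1, d2))
}

#' Membership bitmap of a circular interval set
#' @param df Data frame with \code{start}, \code{end}.
#' @param L Genome length.
#' @return Logical vector of length L: is each base covered?
#' @export
interval_bitmap <- function(df, L) {
  cov <- logical(L)
  if (!nrow(df)) return(cov)
  seg <- iv_segments(df$start, df$end, L)
  for (i in seq_len(nrow(seg)))
    cov[(seg$seg_start[i] + 1L):seg$seg_end[i]] <- TRUE
  cov
}

# Linear strict-overlap merge of half-open intervals already known not to wrap
# in the current frame. Adjacency (next start == current end) does not merge.
# Returns merged intervals plus, for each input, the merged-group index.
merge_linear_strict <- function(start, end) {
  o <- order(start, end)
  s <- start[o]; e <- end[o]
  grp_sorted <- integer(length(s))
  ms <- me <- integer(0)
  cur_s <- s[1]; cur_e <- e[1]; g <- 1L; grp_sorted[1] <- 1L
  for (i in seq_along(s)[-1]) {
    if (s[i] < cur_e) {            # strict overlap only
      cur_e <- max(cur_e, e[i])
    } else {
      ms <- c(ms, cur_s); me <- c(me, cur_e)
      cur_s <- s[i]; cur_e <- e[i]; g <- g + 1L
    }
    grp_sorted[i] <- g
  }
  ms <- c(ms, cur_s); me <- c(me, cur_e)
  grp <- integer(length(s)); grp[o] <- grp_sorted
  list(start = ms, end = me, group = grp)
}

#' Merge circular intervals by transitive >= 1-base overlap
#'
#' Computes the transitive closure of strict overlap (shared base) among a set
#' of circular intervals. Half-open adjacency does not merge; wrap-around
#' intervals are first-class. If the inputs' overlap closure covers the whole
#' circle the result is the single full-circle interval [0, L).
#'
#' @param df Data frame with \code{start}, \code{end} columns (0-based
#'   half-open, end < start wraps).
#' @param L Genome length.
#' @return List with \code{intervals} (data.frame \code{start}, \code{end},
#'   sorted by start) and \code{group} (integer vector assigning each input row
#'   to its merged interval).
#' @export
merge_circular <- function(df, L) {
  n <- nrow(df)
  if (n == 0L)
    return(list(intervals = data.frame(start = integer(), end = integer()),
                group = integer()))
  iv_check(df$start, df$end, L)
  full <- df$start == 0L & df$end == L
  if (any(interval_length(df$start, df$end, L) == L) || any(full))
    return(list(intervals = data.frame(start = 0L, end = L),
                group = rep(1L, n)))
  cov <- interval_bitmap(df, L)
  if (!all(cov)) {
    g <- which(!cov)[1] - 1L                 # an uncovered base (0-based)
    shift <- (g + 1L) %% L                   # origin just after the gap base
  } else {
    # fully covered: cut at a start that is not strictly interior to any
    # other interval; if none exists the closure is the full circle
    shift <- NA_integer_
    for (i in seq_len(n)) {
      s <- df$start[i]
      interior <- FALSE
      for (j in seq_len(n)) {
        if (j == i) next
        # is s strictly inside interval j (covered but not its start)?
        lj <- interval_length(df$start[j], df$end[j], L)
        off <- ((s - df$start[j]) %% L + L) %% L
        if (off > 0L && off < lj) { interior <- TRUE; break }
      }
      if (!interior) { shift <- s; break }
    }
    if (is.na(shift))
      return(list(intervals = data.frame(start = 0L, end = L),
                  group = rep(1L, n)))
  }
  # rotate so no interval wraps: new coordinate = (x - shift) mod L
  ns <- ((df$start - shift) %% L + L) %% L
  len <- interval_length(df$start, df$end, L)
  ne <- ns + len                             # guaranteed <= L in this frame
  if (any(ne > L)) stop("internal error: interval wraps after rotation")
  m <- merge_linear_strict(ns, ne)
  out_s <- (m$start + shift) %% L
  out_e_raw <- m$end + shift
  out_e <- ifelse(out_e_raw <= L, out_e_raw, out_e_raw - L)
  # a merged interval of length L covers every base: canonical full circle
  full_len <- (m$end - m$start) == L
  out_s[full_len] <- 0L; out_e[full_len] <- L
  res <- data.frame(start = as.integer(out_s), end = as.integer(out_e))
  o <- order(res$start)
  remap <- integer(nrow(res)); remap[o] <- seq_len(nrow(res))
  res <- res[o, , drop = FALSE]; rownames(res) <- NULL
  list(intervals = res, group = remap[m$group])
}

#' Dilate circular intervals and measure covered fraction
#'
#' Expands every interval by \code{radius} bases on each side (modular) and
#' returns the fraction of genome bases covered by the union. Used as the
#' default expected fraction for the co-localization chi-square null.
#'
#' @param df Data frame with \code{start}, \code{end}.
#' @param L Genome length.
#' @param radius Dilation radius in bases.
#' @return Fraction of the circle covered by the dilated union, in [0, 1].
#' @export
dilated_fraction <- function(df, L, radius) {
  if (!nrow(df)) return(0)
  len <- interval_length(df$start, df$end, L)
  newlen <- pmin(len + 2L * radius, L)
  s <- ((df$start - radius) %% L + L) %% L
  e <- (s + newlen) %% L
  e[newlen == L] <- L
  s[newlen == L] <- 0L
  e[e == 0L & newlen < L] <- L
  mean(interval_bitmap(data.frame(start = s, end = e), L))
}
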