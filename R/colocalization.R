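# Co-localization of footprint sites with annotated features, G-quadruplex
# motif scanning, and enrichment statistics.

#' Proximity parameters for co-localization
#' @param max_gap Exclusive gap bound in bases: a feature with no shared base
#'   but a circular gap strictly below \code{max_gap} counts as proximal.
#'   Default 40.
#' @return A list of class \code{ProximityParams}.
#' @export
proximity_params <- function(max_gap = 40L) {
  max_gap <- as.integer(max_gap)
  if (is.na(max_gap) || max_gap < 0L) stop("max_gap must be >= 0")
  structure(list(max_gap = max_gap), class = "ProximityParams")
}

#' G-quadruplex motif parameters
#'
#' The default motif is the minimal quadparser-style pattern: four runs of at
#' least three guanines separated by loops of one to seven bases,
#' \code{G3+ (N1-7 G3+) x3}, scanned on both strands.
#'
#' @param min_run Minimum G-run length (>= 2).
#' @param loop_min,loop_max Loop length bounds in bases.
#' @param n_runs Number of G runs (>= 2).
#' @return A list of class \code{GQPMotifParams}.
#' @export
gqp_params <- function(min_run = 3L, loop_min = 1L, loop_max = 7L,
                       n_runs = 4L) {
  stopifnot(min_run >= 2L, loop_min <= loop_max, loop_min >= 0L, n_runs >= 2L)
  structure(list(min_run = as.integer(min_run), loop_min = as.integer(loop_min),
                 loop_max = as.integer(loop_max), n_runs = as.integer(n_runs)),
            class = "GQPMotifParams")
}

# Leftmost non-overlapping matches of the quadruplex pattern on one strand of
# a circular sequence: scan the doubled sequence, keep matches starting in the
# first copy, wrap coordinates.
gqp_scan_strand <- function(seq, L, params) {
  pat <- sprintf("G{%d,}(?:[ACGTN]{%d,%d}G{%d,}){%d}",
                 params$min_run, params$loop_min, params$loop_max,
                 params$min_run, params$n_runs - 1L)
  doubled <- paste0(seq, seq)
  m <- gregexpr(pat, doubled, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(), end = integer()))
  st <- as.integer(m); len <- attr(m, "match.length")
  keep <- st <= L & len < L
  st <- st[keep] - 1L; len <- len[keep]          # to 0-based
  e <- st + len
  data.frame(start = st %% L, end = ifelse(e >= L & e %% L > 0L, e %% L,
                                           ifelse(e > L, e - L, e)))
}

#' Scan a circular genome for G-quadruplex-prone sequences
#'
#' Finds maximal leftmost non-overlapping matches of the guanine-run motif on
#' the given sequence and, independently, on its reverse complement (C-run
#' quadruplexes on the forward strand), modular across the origin.
#'
#' @param genome A [circular_genome()] with sequence.
#' @param params A [gqp_params()].
#' @return A [feature_annotation()] of class \code{gqp}, feature ids
#'   \code{gqp_0001...}, strand \code{+} for G-run matches on the forward
#'   strand and \code{-} for matches on the reverse complement.
#' @export
scan_gqp <- function(genome, params = gqp_params()) {
  stopifnot(is_circular_genome(genome))
  if (is.null(genome$sequence)) stop("genome carries no sequence")
  L <- genome$length
  fwd <- gqp_scan_strand(genome$sequence, L, params)
  rcseq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genome$sequence)))
  rev <- gqp_scan_strand(rcseq, L, params)
  # map reverse-complement coordinates back to the forward frame:
  # rc interval [s, s+len) corresponds to forward [L-s-len, L-s)
  if (nrow(rev)) {
    len <- interval_length(rev$start, rev$end, L)
    fs <- ((L - rev$start - len) %% L + L) %% L
    fe <- (fs + len) %% L
    fe[fe == 0L] <- L
    rev <- data.frame(start = fs, end = fe)
  }
  n <- nrow(fwd) + nrow(rev)
  if (!n)
    return(feature_annotation(genome, character(), character(), integer(),
                              integer(), character()))
  df <- rbind(cbind(fwd, strand = rep("+", nrow(fwd))),
              cbind(rev, strand = rep("-", nrow(rev))))
  df <- df[order(df$start, df$strand), , drop = FALSE]
  feature_annotation(genome, sprintf("gqp_%04d", seq_len(n)),
                     "gqp", df$start, df$end, df$strand)
}

#' Co-localization status of features relative to footprint sites
#'
#' Each feature is \code{overlap} (shares >= 1 base with some site),
#' \code{proximal} (no shared base but circular gap strictly below
#' \code{max_gap}), or \code{none}.
#'
#' @param sites A \code{SiteSet}.
#' @param features A [feature_annotation()].
#' @param params A [proximity_params()].
#' @return List with \code{status} (data frame: \code{feature_id},
#'   \code{class}, \code{status}, \code{gap}) and \code{counts} (named
#'   vector over the three statuses).
#' @export
colocalize <- function(sites, features, params = proximity_params()) {
  stopifnot(inherits(sites, "SiteSet"), inherits(features, "FeatureAnnotation"))
  g <- check_same_genome(sites, features)
  L <- g$length
  nf <- nrow(features)
  status <- rep("none", nf); gap <- rep(NA_integer_, nf)
  if (nf && nrow(sites)) {
    m <- interval_overlap_matrix(features, sites, L)
    for (i in seq_len(nf)) {
      if (any(m[i, ])) { status[i] <- "overlap"; gap[i] <- 0L }
      else {
        d1 <- ((sites$start - features$end[i]) %% L + L) %% L
        d2 <- ((features$start[i] - sites$end) %% L + L) %% L
        gap[i] <- min(pmin(d1, d2))
        if (gap[i] < params$max_gap) status[i] <- "proximal"
      }
    }
  }
  counts <- c(overlap = sum(status == "overlap"),
              proximal = sum(status == "proximal"),
              none = sum(status == "none"))
  list(status = data.frame(feature_id = features$feature_id,
                           class = features$class, status = status,
                           gap = gap, stringsAsFactors = FALSE),
       counts = counts)
}

#' Chi-square test of co-localization enrichment
#'
#' One-degree-of-freedom goodness-of-fit test of the observed
#' (co-localized, not co-localized) split of \code{n_features} features
#' against the binomial expectation under \code{expected_fraction}.
#'
#' @param n_features Number of features tested.
#' @param n_colocalized Number co-localized (overlap or proximal).
#' @param expected_fraction Null probability that a random feature
#'   co-localizes; typically [expected_colocalization_fraction()] (the
#'   fraction of genome bases within the proximity distance of any site).
#' @return List of class \code{EnrichmentResult}: \code{n_features},
#'   \code{n_colocalized}, \code{expected_colocalized}, \code{chi_square},
#'   \code{df}, \code{p_value}.
#' @examples
#' # 25 of 81 features co-localized against a null fraction of 0.20
#' chi_square_enrichment(81, 25, 0.20)
#' @export
chi_square_enrichment <- function(n_features, n_colocalized,
                                  expected_fraction) {
  if (n_features < 1L || n_colocalized < 0L || n_colocalized > n_features)
    stop("need 0 <= n_colocalized <= n_features, n_features >= 1")
  if (expected_fraction <= 0 || expected_fraction >= 1)
    stop("expected_fraction must be strictly inside (0, 1)")
  e1 <- n_features * expected_fraction
  e0 <- n_features * (1 - expected_fraction)
  if (min(e1, e0) < 1)
    stop("expected count below 1; the chi-square approximation is invalid")
  if (min(e1, e0) < 5)
    warning("expected count below 5; chi-square approximation is rough")
  chi <- (n_colocalized - e1)^2 / e1 + ((n_features - n_colocalized) - e0)^2 / e0
  structure(list(n_features = as.integer(n_features),
                 n_colocalized = as.integer(n_colocalized),
                 expected_colocalized = e1, chi_square = chi, df = 1L,
                 p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE)),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat("Co-localization enrichment: ", x$n_colocalized, "/", x$n_features,
      " observed vs ", signif(x$expected_colocalized, 4),
      " expected; chi-square = ", signif(x$chi_square, 4), " (df ", x$df,
      "), p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Null co-localization fraction from dilated site coverage
#'
#' Fraction of genome bases that co-localize with some site: bases inside a
#' site plus bases at circular gap strictly below \code{max_gap} (so the
#' dilation radius is exactly \code{max_gap}). This is the probability that
#' a random single-base feature would co-localize.
#'
#' @param sites A \code{SiteSet}.
#' @param params A [proximity_params()].
#' @return A fraction in [0, 1].
#' @export
expected_colocalization_fraction <- function(sites,
                                             params = proximity_params()) {
  stopifnot(inherits(sites, "SiteSet"))
  g <- attr(sites, "genome")
  dilated_fraction(as.data.frame(sites)[, c("start", "end")], g$length,
                   params$max_gap)
}

#' Rotation permutation test of co-localization
#'
#' Builds a null by rotating the whole feature set by uniform random offsets
#' around the circle (sites stay fixed, preserving the coverage structure the
#' site calls depend on) and recomputing the number of co-localized features.
#'
#' @param sites A \code{SiteSet}.
#' @param features A [feature_annotation()].
#' @param params A [proximity_params()].
#' @param n_perm Number of rotations (>= 100).
#' @param seed Integer seed for the rotation offsets.
#' @return List: \code{observed} (co-localized count), \code{permutation_p}
#'   (\code{(1 + #[perm >= obs]) / (n_perm + 1)}), \code{n_permutations},
#'   \code{null_counts}.
#' @export
rotation_permutation_test <- function(sites, features,
                                      params = proximity_params(),
                                      n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(sites, "SiteSet"), inherits(features, "FeatureAnnotation"))
  if (n_perm < 100L) stop("n_perm must be >= 100")
  g <- check_same_genome(sites, features)
  L <- g$length
  # a feature co-localizes (overlap, or gap < max_gap) iff it intersects the
  # sites dilated by max_gap bases; counting against the dilated bitmap is
  # exact and fast enough to rotate thousands of times
  dil <- local({
    df <- as.data.frame(sites)[, c("start", "end")]
    len <- interval_length(df$start, df$end, L)
    newlen <- pmin(len + 2L * params$max_gap, L)
    s <- ((df$start - params$max_gap) %% L + L) %% L
    e <- (s + newlen) %% L
    e[newlen == L] <- L; s[newlen == L] <- 0L
    e[e == 0L & newlen < L] <- L
    interval_bitmap(data.frame(start = s, end = e), L)
  })
  fb <- unlist(lapply(seq_len(nrow(features)), function(i) {
    s <- features$start[i]
    s + 0:(interval_length(s, features$end[i], L) - 1L)
  }))
  fi <- rep(seq_len(nrow(features)),
            interval_length(features$start, features$end, L))
  count_at <- function(k) {
    hit <- dil[((fb + k) %% L) + 1L]
    length(unique(fi[hit]))
  }
  obs <- count_at(0L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ks <- sample.int(L, n_perm, replace = TRUE) - 1L
  null_counts <- vapply(ks, count_at, numeric(1))
  list(observed = obs,
       permutation_p = (1 + sum(null_counts >= obs)) / (n_perm + 1),
       n_permutations = as.integer(n_perm), null_counts = null_counts)
}
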