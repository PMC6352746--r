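# Independent brute-force oracles. Everything here recomputes results from
# first principles (explicit loops, per-base set arithmetic), deliberately
# sharing no code with the package internals.

# bases covered by a circular half-open interval (0-based)
bases_of <- function(start, end, L) {
  if (end > start) return(start:(end - 1L))
  c(start:(L - 1L), if (end > 0L) 0:(end - 1L))
}

# footprint occupancy score by explicit loops over window members
bf_fos <- function(counts, position, center_len, flank_len,
                   pc = 1, eps = 0.25) {
  L <- length(counts)
  cs <- ((position - center_len %/% 2L) %% L + L) %% L
  acc <- function(s, w) {
    tot <- 0
    for (i in 0:(w - 1L)) tot <- tot + counts[(((s + i) %% L) + L) %% L + 1L]
    tot / w
  }
  cm <- acc(cs, center_len)
  lm <- acc(cs - flank_len, flank_len)
  rm_ <- acc(cs + center_len, flank_len)
  (cm + pc) / max(lm, eps) + (cm + pc) / max(rm_, eps)
}

# per-position best score and scorability by loops over all configurations
bf_best_scores <- function(counts, params) {
  L <- length(counts)
  best <- rep(Inf, L); scorable <- logical(L)
  for (p in 0:(L - 1L)) {
    for (cl in params$center_lengths) {
      if (3L * cl > L) next
      cs <- ((p - cl %/% 2L) %% L + L) %% L
      acc <- function(s, w) {
        tot <- 0
        for (i in 0:(w - 1L)) tot <- tot + counts[(((s + i) %% L) + L) %% L + 1L]
        tot / w
      }
      lm <- acc(cs - cl, cl); rm_ <- acc(cs + cl, cl)
      if (min(lm, rm_) < params$min_flank_mean) next
      cm <- acc(cs, cl)
      sc <- (cm + params$pseudocount) / max(lm, params$eps) +
        (cm + params$pseudocount) / max(rm_, params$eps)
      scorable[p + 1L] <- TRUE
      if (sc < best[p + 1L]) best[p + 1L] <- sc
    }
  }
  list(best = best, scorable = scorable)
}

# naive footprint caller: quantile threshold + circular run walk
bf_scan <- function(counts, params, bf = bf_best_scores(counts, params)) {
  L <- length(counts)
  fin <- is.finite(bf$best)
  if (!any(fin)) return(data.frame(start = integer(), end = integer()))
  thr <- stats::quantile(bf$best[fin], probs = params$call_quantile,
                         names = FALSE)
  called <- fin & bf$best < thr
  if (!any(called)) return(data.frame(start = integer(), end = integer()))
  if (all(called)) return(data.frame(start = 0L, end = L))
  u <- which(!called)[1] - 1L                 # an uncalled anchor, 0-based
  runs <- list(); cur <- NULL
  for (step in 1:L) {
    p <- (u + step) %% L
    if (called[p + 1L]) {
      if (is.null(cur)) cur <- c(p, p) else cur[2] <- p
    } else if (!is.null(cur)) {
      runs[[length(runs) + 1L]] <- cur; cur <- NULL
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
  df <- do.call(rbind, lapply(runs, function(r)
    data.frame(start = r[1], end = (r[2] + 1L) %% L)))
  df$end[df$end == 0L] <- L
  df[order(df$start), , drop = FALSE]
}

# contiguous circular base set -> (start, end) arc
arc_from_bases <- function(B, L) {
  B <- sort(unique(B))
  if (length(B) == L) return(c(0L, L))
  notin <- setdiff(0:(L - 1L), B)
  g <- notin[1]
  ord <- ((B - g - 1L) %% L + L) %% L         # order after the gap base
  first <- B[which.min(ord)]
  last <- B[which.max(ord)]
  e <- (last + 1L) %% L
  c(first, if (e == 0L) L else e)
}

# quadratic transitive-closure merge via per-base sets and union-find
bf_merge <- function(df, L) {
  n <- nrow(df)
  if (n == 0L) return(data.frame(start = integer(), end = integer()))
  B <- lapply(seq_len(n), function(i) bases_of(df$start[i], df$end[i], L))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && length(intersect(B[[i]], B[[j]]))) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- lapply(unique(roots), function(r) {
    arc <- arc_from_bases(unlist(B[roots == r]), L)
    data.frame(start = arc[1], end = arc[2])
  })
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

bf_overlap <- function(s1, e1, s2, e2, L)
  length(intersect(bases_of(s1, e1, L), bases_of(s2, e2, L))) > 0L

# all-pairs replicate concordance with union coordinates
bf_concordant <- function(a, b, L) {
  pieces <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    Bi <- bases_of(a$start[i], a$end[i], L)
    Bj <- bases_of(b$start[j], b$end[j], L)
    if (length(intersect(Bi, Bj))) {
      arc <- arc_from_bases(union(Bi, Bj), L)
      pieces[[length(pieces) + 1L]] <- data.frame(start = arc[1], end = arc[2])
    }
  }
  if (!length(pieces)) return(data.frame(start = integer(), end = integer()))
  bf_merge(do.call(rbind, pieces), L)
}

bf_prevalence <- function(sets, L, min_fraction, strict = FALSE) {
  all <- do.call(rbind, lapply(sets, function(s) s[, c("start", "end")]))
  ref <- bf_merge(all, L)
  if (!nrow(ref)) return(ref)
  frac <- vapply(seq_len(nrow(ref)), function(i) {
    supp <- vapply(sets, function(s) {
      any(vapply(seq_len(nrow(s)), function(j)
        bf_overlap(ref$start[i], ref$end[i], s$start[j], s$end[j], L),
        logical(1)))
    }, logical(1))
    mean(supp)
  }, numeric(1))
  keep <- if (strict) frac > min_fraction else frac >= min_fraction
  ref[keep, , drop = FALSE]
}

# rule-by-rule trajectory classifier oracle
bf_classify <- function(v) {
  n <- length(v)
  stopifnot(sum(v) > 0L)
  is_core <- all(v == 1L)
  is_emergent <- !is_core && v[n] == 1L &&
    { k <- which(v == 1L)[1]; k > 1L && all(v[k:n] == 1L) }
  is_alternating <- any(vapply(seq_len(n - 2L), function(i) {
    v[i] == 1L && any(vapply((i + 1L):(n - 1L), function(j)
      v[j] == 0L && any(v[(j + 1L):n] == 1L), logical(1)))
  }, logical(1)))
  ones <- which(v == 1L)
  is_transient <- all(diff(ones) == 1L) && ones[length(ones)] < n &&
    !is_alternating
  hits <- c(core = is_core, emergent_persistent = is_emergent,
            alternating = is_alternating, transient = is_transient)
  stopifnot(sum(hits) == 1L)
  names(hits)[hits]
}

# per-base colocalization status oracle
bf_coloc_status <- function(fs, fe, sites, L, max_gap) {
  FB <- bases_of(fs, fe, L)
  best_d <- Inf
  for (j in seq_len(nrow(sites))) {
    SB <- bases_of(sites$start[j], sites$end[j], L)
    if (length(intersect(FB, SB))) return("overlap")
    for (u in FB) for (w in SB) {
      d <- min(((w - u) %% L + L) %% L, ((u - w) %% L + L) %% L)
      best_d <- min(best_d, d - 1L)
    }
  }
  if (best_d < max_gap) "proximal" else "none"
}

# regex oracle for the quadruplex motif on one strand (stringi engine)
bf_gqp_strand <- function(seq, L, params) {
  pat <- sprintf("G{%d,}(?:[ACGTN]{%d,%d}G{%d,}){%d}",
                 params$min_run, params$loop_min, params$loop_max,
                 params$min_run, params$n_runs - 1L)
  doubled <- paste0(seq, seq)
  m <- stringi::stri_locate_all_regex(doubled, pat)[[1]]
  if (is.na(m[1, 1])) return(data.frame(start = integer(), end = integer()))
  keep <- m[, 1] <= L
  st <- m[keep, 1] - 1L
  en <- m[keep, 2]                            # inclusive -> half-open
  e <- ifelse(en > L, en - L, en)
  data.frame(start = st %% L, end = e)
}

# deterministic synthetic catalog whose mt allele is the reference base
make_catalog <- function(genome, positions) {
  ref <- vapply(positions + 1L, function(i)
    substr(genome$sequence, i, i), character(1))
  alt <- vapply(ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                character(1))
  numt_catalog(genome, positions, ref, alt)
}

# random circular interval set for algebra fuzzing
random_intervals <- function(n, L, allow_wrap = TRUE) {
  s <- sample.int(L, n, replace = TRUE) - 1L
  w <- sample.int(max(2L, L %/% 4L), n, replace = TRUE)
  w <- pmin(w, L - 1L)
  e <- (s + w) %% L
  e[e == 0L] <- L
  if (!allow_wrap) { e <- pmin(s + w, L) }
  data.frame(start = s, end = e)
}
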