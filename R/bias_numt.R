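# Transposase k-mer digestion-bias screen and NUMT read-contamination screen.

#' Screen cut sites for k-mer sequence bias
#'
#' Compares, for every k-mer, the number of cut events whose centered k-mer
#' (the k bases from \code{cut - floor(k/2)} to \code{cut + ceil(k/2) - 1},
#' modular) equals it against the binomial expectation under the genome-wide
#' circular k-mer frequency. Per-k-mer two-sided binomial tests are
#' Benjamini-Hochberg corrected across all 4^k k-mers; the screen reports
#' bias iff some k-mer has adjusted p below \code{alpha} AND an
#' observed/expected enrichment outside [0.5, 2].
#'
#' @param cut_positions Integer vector (multiset) of 0-based cut positions.
#' @param genome A [circular_genome()] with sequence (A/C/G/T only).
#' @param k K-mer size; default 6.
#' @param alpha Significance level on the adjusted p-values.
#' @return A list of class \code{KmerBiasReport}: \code{k}, \code{n_cuts},
#'   \code{table} (data frame \code{kmer}, \code{observed}, \code{expected},
#'   \code{enrichment}, \code{p_value}, \code{p_adj}, sorted by
#'   \code{p_adj}), \code{biased} (logical), \code{flagged_kmers}.
#' @export
kmer_bias_screen <- function(cut_positions, genome, k = 6L, alpha = 0.05) {
  stopifnot(is_circular_genome(genome))
  if (is.null(genome$sequence)) stop("genome carries no sequence")
  k <- as.integer(k)
  L <- genome$length
  if (k < 1L || k > L) stop("k must be in [1, genome length]")
  if (grepl("N", genome$sequence, fixed = TRUE))
    stop("k-mer screen requires an N-free sequence")
  n <- length(cut_positions)
  if (n == 0L) stop("no cut events supplied")
  cut <- ((as.integer(cut_positions) %% L) + L) %% L
  doubled <- paste0(genome$sequence, substr(genome$sequence, 1L, k))
  # genome-wide circular k-mer counts: all L windows of the wrapped sequence
  ref <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(substr(doubled, 1L, L + k - 1L)), width = k)
  ref_freq <- ref / sum(ref)
  starts <- ((cut - k %/% 2L) %% L) + 1L          # 1-based into doubled
  kmers <- substring(doubled, starts, starts + k - 1L)
  obs_tab <- table(factor(kmers, levels = names(ref)))
  observed <- as.integer(obs_tab)
  expected <- n * as.numeric(ref_freq)
  enrichment <- ifelse(expected > 0, observed / expected, NA_real_)
  pval <- vapply(seq_along(observed), function(i) {
    if (ref_freq[i] == 0) return(if (observed[i] > 0) 0 else 1)
    stats::binom.test(observed[i], n, p = ref_freq[i])$p.value
  }, numeric(1))
  p_adj <- stats::p.adjust(pval, method = "BH")
  flagged <- p_adj < alpha & !is.na(enrichment) &
    (enrichment < 0.5 | enrichment > 2)
  tab <- data.frame(kmer = names(ref), observed = observed,
                    expected = expected, enrichment = enrichment,
                    p_value = pval, p_adj = p_adj,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$p_adj, -abs(log(pmax(tab$enrichment, 1e-12)))), ]
  rownames(tab) <- NULL
  structure(list(k = k, n_cuts = n, table = tab, biased = any(flagged),
                 flagged_kmers = names(ref)[flagged]),
            class = "KmerBiasReport")
}

#' @export
print.KmerBiasReport <- function(x, ...) {
  cat("K-mer bias screen (k = ", x$k, ", ", x$n_cuts, " cuts): ",
      if (x$biased) paste0("BIAS detected (", length(x$flagged_kmers),
                           " k-mer(s): ",
                           paste(utils::head(x$flagged_kmers, 5), collapse = ", "),
                           ")")
      else "no digestion bias detected", "\n", sep = "")
  invisible(x)
}

#' NUMT diagnostic variant catalog
#'
#' @param genome A [circular_genome()].
#' @param position 0-based positions of diagnostic variants.
#' @param mt_allele,numt_allele Single-nucleotide alleles distinguishing true
#'   mitochondrial reads from reads of nuclear-mitochondrial (NUMT) origin;
#'   must differ at every position.
#' @param source_id Text label(s) for the catalog source.
#' @return A data frame of class \code{NUMTCatalog}.
#' @export
numt_catalog <- function(genome, position, mt_allele, numt_allele,
                         source_id = "catalog") {
  stopifnot(is_circular_genome(genome))
  position <- as.integer(position)
  mt_allele <- toupper(as.character(mt_allele))
  numt_allele <- toupper(as.character(numt_allele))
  if (any(position < 0L) || any(position >= genome$length))
    stop("catalog position outside genome")
  if (any(mt_allele == numt_allele))
    stop("mt_allele must differ from numt_allele at every position")
  if (!all(c(mt_allele, numt_allele) %in% c("A", "C", "G", "T")))
    stop("alleles must be single nucleotides A/C/G/T")
  df <- data.frame(position = position, mt_allele = mt_allele,
                   numt_allele = numt_allele,
                   source_id = rep_len(as.character(source_id),
                                       length(position)),
                   stringsAsFactors = FALSE)
  attr(df, "genome") <- genome
  class(df) <- c("NUMTCatalog", "data.frame")
  df
}

#' Read a NUMT catalog from TSV
#' @param path TSV with columns \code{position} (0-based),
#'   \code{mt_allele}, \code{numt_allele}, optional \code{source_id}.
#' @param genome A [circular_genome()].
#' @return A [numt_catalog()].
#' @export
load_numt_catalog <- function(path, genome) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  numt_catalog(genome, df$position, df$mt_allele, df$numt_allele,
               if (!is.null(df$source_id)) df$source_id else "catalog")
}

#' Write a NUMT catalog as TSV
#' @param catalog A [numt_catalog()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_numt_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "NUMTCatalog"))
  utils::write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-position NUMT read fractions
#'
#' At each catalog position, the fraction of informative reads (those whose
#' base call equals either the mitochondrial or the NUMT allele) that carry
#' the NUMT allele. Positions with zero informative reads are undefined
#' (\code{NA}), not zero.
#'
#' @param reads Data frame of aligned reads with columns \code{start}
#'   (0-based), \code{width} and \code{seq} (read sequence in reference
#'   orientation), e.g. from [simulate_reads()].
#' @param catalog A [numt_catalog()].
#' @return Data frame of class \code{NUMTReport}: \code{position},
#'   \code{n_mt}, \code{n_numt}, \code{n_informative}, \code{numt_fraction}
#'   (NA where undefined), with the genome as attribute.
#' @export
numt_read_fraction <- function(reads, catalog) {
  stopifnot(inherits(catalog, "NUMTCatalog"),
            all(c("start", "width", "seq") %in% names(reads)))
  g <- attr(catalog, "genome")
  L <- g$length
  out <- lapply(seq_len(nrow(catalog)), function(i) {
    pos <- catalog$position[i]
    off <- ((pos - reads$start) %% L + L) %% L
    cov <- off < reads$width
    if (!any(cov))
      return(data.frame(position = pos, n_mt = 0L, n_numt = 0L,
                        n_informative = 0L, numt_fraction = NA_real_))
    base <- substr(reads$seq[cov], off[cov] + 1L, off[cov] + 1L)
    n_mt <- sum(base == catalog$mt_allele[i])
    n_numt <- sum(base == catalog$numt_allele[i])
    n_inf <- n_mt + n_numt
    data.frame(position = pos, n_mt = n_mt, n_numt = n_numt,
               n_informative = n_inf,
               numt_fraction = if (n_inf) n_numt / n_inf else NA_real_)
  })
  df <- do.call(rbind, out)
  attr(df, "genome") <- g
  class(df) <- c("NUMTReport", "data.frame")
  df
}

#' Compare NUMT fractions inside vs outside footprint sites
#'
#' Partitions catalog positions by membership in any footprint site and
#' compares the defined per-position NUMT fractions between the two groups
#' with a two-sided Mann-Whitney (Wilcoxon rank-sum) test. Group means and
#' SDs are unweighted over positions. If either group has no defined
#' fraction the comparison is undefined (p \code{NA}) but means are still
#' reported.
#'
#' @param report A \code{NUMTReport} from [numt_read_fraction()].
#' @param sites A \code{SiteSet}.
#' @return List of class \code{NUMTComparison}: \code{in_sites} /
#'   \code{out_sites} (each \code{n}, \code{mean}, \code{sd}),
#'   \code{statistic}, \code{p_value}, \code{method}.
#' @export
compare_numt_groups <- function(report, sites) {
  stopifnot(inherits(report, "NUMTReport"), inherits(sites, "SiteSet"))
  g <- check_same_genome(report, sites)
  L <- g$length
  in_site <- rep(FALSE, nrow(report))
  if (nrow(sites)) {
    cov <- interval_bitmap(as.data.frame(sites)[, c("start", "end")], L)
    in_site <- cov[report$position + 1L]
  }
  fin <- report$numt_fraction[in_site & !is.na(report$numt_fraction)]
  fout <- report$numt_fraction[!in_site & !is.na(report$numt_fraction)]
  gsum <- function(x) list(n = length(x),
                           mean = if (length(x)) mean(x) else NA_real_,
                           sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  stat <- p <- NA_real_
  if (length(fin) && length(fout)) {
    wt <- suppressWarnings(stats::wilcox.test(fin, fout,
                                              alternative = "two.sided"))
    stat <- unname(wt$statistic); p <- wt$p.value
    if (is.nan(p)) p <- 1   # zero-variance ties: no evidence of a difference
  }
  structure(list(in_sites = gsum(fin), out_sites = gsum(fout),
                 statistic = stat, p_value = p,
                 method = "two-sided Mann-Whitney rank-sum"),
            class = "NUMTComparison")
}

#' @export
print.NUMTComparison <- function(x, ...) {
  cat("NUMT read fractions: sites mean ",
      signif(x$in_sites$mean, 3), " (n=", x$in_sites$n, "), non-sites mean ",
      signif(x$out_sites$mean, 3), " (n=", x$out_sites$n, "); ",
      x$method, " p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}
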