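test_that("canonical quadruplex is found once; run-free sequence gives none", {
  seq <- paste0(strrep("A", 200), "GGGAGGGTGGGTGGG", strrep("A", 285))
  g <- circular_genome("mt", 500, seq)
  hits <- scan_gqp(g)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 200L)
  expect_equal(hits$end, 215L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$class, "gqp")

  none <- circular_genome("mt", 300, strrep("AT", 150))
  expect_equal(nrow(scan_gqp(none)), 0L)
})

test_that("quadruplex scan equals a regex oracle on the doubled sequence", {
  skip_if_not_installed("stringi")
  params <- gqp_params()
  set.seed(17)
  for (rep in 1:8) {
    g <- simulate_genome(4000, seed = 100 + rep, gc = 0.55)
    mine <- scan_gqp(g, params)
    fwd <- mine[mine$strand == "+", ]
    oracle <- bf_gqp_strand(g$sequence, g$length, params)
    expect_equal(fwd$start, oracle$start)
    expect_equal(fwd$end, oracle$end)
    # minus strand: oracle run on the reverse complement, mapped back
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(g$sequence)))
    orc <- bf_gqp_strand(rc, g$length, params)
    if (nrow(orc)) {
      len <- interval_length(orc$start, orc$end, g$length)
      fs <- sort((g$length - orc$start - len) %% g$length)
      expect_equal(sort(mine$start[mine$strand == "-"]), fs)
    } else {
      expect_equal(sum(mine$strand == "-"), 0L)
    }
  }
})

test_that("reverse-complementing the genome swaps motif strands", {
  g <- simulate_genome(3000, seed = 55, gc = 0.6)
  rc <- circular_genome("mt", 3000, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(g$sequence))))
  a <- scan_gqp(g)
  b <- scan_gqp(rc)
  key <- function(x, strand) {
    x <- x[x$strand == strand, ]
    sort(paste(x$start, x$end))
  }
  flip <- function(x) {
    len <- interval_length(x$start, x$end, 3000L)
    fs <- (3000L - x$start - len) %% 3000L
    fe <- (fs + len) %% 3000L
    fe[fe == 0L] <- 3000L
    sort(paste(fs, fe))
  }
  expect_equal(key(b, "-"), flip(a[a$strand == "+", ]))
  expect_equal(key(b, "+"), flip(a[a$strand == "-", ]))
})

test_that("colocalization status distinguishes overlap, proximal and none", {
  g <- circular_genome("mt", 1000)
  sites <- site_set(g, c(110, 140), c(130, 160))
  feats <- feature_annotation(g, c("f1", "f2", "f3"), "regulatory",
                              c(100, 195, 300), c(120, 215, 320))
  cl <- colocalize(sites, feats)
  expect_equal(cl$status$status, c("overlap", "proximal", "none"))
  expect_equal(cl$status$gap, c(0L, 35L, 140L))
  expect_equal(unname(cl$counts), c(1L, 1L, 1L))

  # brute-force per-base distances on random circular inputs
  set.seed(19)
  for (rep in 1:20) {
    Ls <- 150L
    gs <- circular_genome("mt", Ls)
    si <- random_intervals(3, Ls)
    fi <- random_intervals(4, Ls)
    ss <- site_set(gs, si$start, si$end)
    ff <- feature_annotation(gs, paste0("f", 1:4), "other",
                             fi$start, fi$end)
    mine <- colocalize(ss, ff, proximity_params(15))$status$status
    oracle <- vapply(1:4, function(i)
      bf_coloc_status(fi$start[i], fi$end[i], as.data.frame(ss), Ls, 15L),
      character(1))
    expect_equal(mine, oracle)
  }
})

test_that("chi-square enrichment reproduces textbook arithmetic", {
  r <- chi_square_enrichment(81, 25, 0.20)
  expect_equal(r$chi_square, (25 - 16.2)^2 / 16.2 + (56 - 64.8)^2 / 64.8,
               tolerance = 1e-12)
  expect_equal(r$chi_square, 5.975308642, tolerance = 1e-8)
  ref <- suppressWarnings(stats::chisq.test(c(25, 56), p = c(0.2, 0.8)))
  expect_equal(r$p_value, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(r$p_value, 0.0145, tolerance = 1e-3)
  expect_equal(r$df, 1L)

  exact <- chi_square_enrichment(100, 20, 0.2)
  expect_equal(exact$chi_square, 0)
  expect_equal(exact$p_value, 1)
  expect_error(chi_square_enrichment(10, 11, 0.2), "n_colocalized")
  expect_error(chi_square_enrichment(100, 5, 0), "inside")
  expect_warning(chi_square_enrichment(12, 3, 0.2), "below 5")
})

test_that("expected fraction equals dilated-site base coverage", {
  g <- circular_genome("mt", 1000)
  sites <- site_set(g, 100, 120)
  # overlap (100..119) or gap < 40 (60..99 left, 120..159 right): 100 bases
  expect_equal(expected_colocalization_fraction(sites, proximity_params(40)),
               100 / 1000)
  # a single-base feature at gap 39 is proximal, at gap 40 it is not
  f39 <- feature_annotation(g, "f", "other", 159, 160)
  f40 <- feature_annotation(g, "f", "other", 160, 161)
  expect_equal(colocalize(sites, f39, proximity_params(40))$status$status,
               "proximal")
  expect_equal(colocalize(sites, f40, proximity_params(40))$status$status,
               "none")
})

test_that("rotation permutation test is deterministic and detects identity", {
  g <- circular_genome("mt", 10000)
  starts <- c(150, 900, 2100, 3700, 4600, 6500, 7900, 9300)
  sites <- site_set(g, starts, starts + 35)
  feats <- feature_annotation(g, paste0("f", seq_along(starts)), "regulatory",
                              sites$start, sites$end)
  r1 <- rotation_permutation_test(sites, feats, n_perm = 200, seed = 4)
  r2 <- rotation_permutation_test(sites, feats, n_perm = 200, seed = 4)
  expect_identical(r1$permutation_p, r2$permutation_p)
  expect_equal(r1$observed, 8)
  # identical features: observed is maximal, p near the attainable floor
  expect_lte(r1$permutation_p, 1 / 201 + 0.02)

  # the test's internal colocalized count agrees with colocalize()
  set.seed(21)
  for (rep in 1:15) {
    Ls <- 500L
    gs <- circular_genome("mt", Ls)
    si <- random_intervals(4, Ls)
    fi <- random_intervals(6, Ls)
    ss <- site_set(gs, si$start, si$end)
    ff <- feature_annotation(gs, paste0("f", 1:6), "other",
                             fi$start, fi$end)
    pt <- rotation_permutation_test(ss, ff, proximity_params(25),
                                    n_perm = 100, seed = 1)
    cc <- colocalize(ss, ff, proximity_params(25))$counts
    expect_equal(pt$observed, unname(sum(cc[c("overlap", "proximal")])))
  }
})
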