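test_that("footprint occupancy score matches direct substitution", {
  g <- circular_genome("mt", 300)
  flat <- coverage_track(g, rep(9, 300))
  # uniform coverage 9, pseudocount 1: (9+1)/9 + (9+1)/9 = 20/9
  for (p in c(0, 150, 299))
    expect_equal(fos_score(flat, p, 10, 10), 20 / 9)

  # center 0, flanks 9: 1/9 + 1/9 = 2/9
  counts <- rep(9, 300); counts[101:110] <- 0
  tr <- coverage_track(g, counts)
  expect_equal(fos_score(tr, 105, 10, 10), 2 / 9)

  expect_error(fos_score(tr, 10, 0, 5), ">= 1")
  expect_error(fos_score(tr, 10, 200, 80), "exceeds genome length")
})

test_that("scored windows wrap the origin like any other position", {
  g <- circular_genome("mt", 200)
  set.seed(7)
  counts <- rpois(200, 30)
  tr <- coverage_track(g, counts)
  for (p in c(0, 1, 5, 195, 199))
    for (cl in c(6, 11, 20))
      expect_equal(fos_score(tr, p, cl, cl), bf_fos(counts, p, cl, cl),
                   tolerance = 1e-12)
})

test_that("uniform and all-zero tracks call no sites", {
  g <- circular_genome("mt", 500)
  expect_equal(nrow(scan_footprints(coverage_track(g, rep(20, 500)))), 0L)
  expect_warning(s0 <- scan_footprints(coverage_track(g, rep(0, 500))),
                 "all-zero")
  expect_equal(nrow(s0), 0L)
})

test_that("a planted protection is called as one site containing its center", {
  cfg <- simulation_config(genome_length = 2000, background_mean = 50,
                           n_replicates = 1,
                           planted_sites = data.frame(start = 800, width = 20,
                                                      protection = 0.9),
                           seed = 3)
  tr <- simulate_track(cfg)$replicates[[1]]
  s <- scan_footprints(tr)
  center <- 810L
  containing <- interval_bitmap(as.data.frame(s)[, c("start", "end")],
                                2000L)[center + 1L]
  expect_true(containing)
  # non-overlapping sites: at most (hence exactly) one contains the center
  hits <- mapply(function(st, en) center %in% bases_of(st, en, 2000L),
                 s$start, s$end)
  expect_equal(sum(hits), 1L)
  expect_lt(s$score[which(hits)], attr(s, "threshold"))
})

test_that("replicate concordance keeps shared sites with union coordinates", {
  g <- circular_genome("mt", 1000)
  a <- site_set(g, 10, 30, score = 0.5)
  b <- site_set(g, 25, 50, score = 0.7)
  cc <- concordant_sites(a, b)
  expect_equal(cc$start, 10L)
  expect_equal(cc$end, 50L)
  expect_equal(cc$score, 0.5)

  # half-open adjacency shares no base
  b2 <- site_set(g, 30, 50)
  expect_equal(nrow(concordant_sites(a, b2)), 0L)

  # intersection mode keeps the shared bases only
  ci <- concordant_sites(a, b, mode = "intersection")
  expect_equal(ci$start, 25L)
  expect_equal(ci$end, 30L)

  # symmetry
  set.seed(13)
  for (rep in 1:25) {
    x <- random_intervals(4, 200L); y <- random_intervals(4, 200L)
    sx <- site_set(circular_genome("mt", 200), x$start, x$end)
    sy <- site_set(circular_genome("mt", 200), y$start, y$end)
    f <- concordant_sites(sx, sy); r <- concordant_sites(sy, sx)
    expect_equal(f[, c("start", "end")], r[, c("start", "end")])
  }
})

test_that("site merging is idempotent and respects single-base overlap", {
  g <- circular_genome("mt", 16299)
  s <- site_set(g, c(1, 5, 30), c(10, 20, 40))
  m <- merge_sites(s)
  expect_equal(m$start, c(1L, 30L))
  expect_equal(m$end, c(20L, 40L))
  m2 <- merge_sites(m)
  expect_equal(m2[, c("start", "end")], m[, c("start", "end")])

  w <- site_set(g, c(16290, 16280), c(5, 16295))
  mw <- merge_sites(w)
  expect_equal(mw$start, 16280L)
  expect_equal(mw$end, 5L)

  # provenance aggregates contributing stages
  a <- site_set(g, 100, 130, stage_id = "2C")
  b <- site_set(g, 120, 150, stage_id = "8C")
  expect_equal(merge_sites(list(a, b))$stage_id, "2C,8C")
})

test_that("prevalence filtering thresholds the supporting-sample fraction", {
  g <- circular_genome("mt", 5000)
  mk <- function(...) site_set(g, ...)
  shared <- lapply(1:5, function(i) mk(100 + i, 140 + i))  # all overlap
  expect_equal(nrow(prevalence_filter(shared, 0.9)), 1L)

  four <- c(lapply(1:4, function(i) mk(100 + i, 140 + i)),
            list(mk(3000, 3040)))
  pf <- prevalence_filter(four, 0.9)
  expect_equal(nrow(pf), 0L)   # 4/5 = 0.8 support falls short of 0.9
  pf2 <- prevalence_filter(four, 0.1)
  expect_equal(nrow(pf2), 2L)

  # strict flag: fraction must strictly exceed
  pf3 <- prevalence_filter(shared, 1, strict = FALSE)
  expect_equal(nrow(pf3), 1L)
  pf4 <- prevalence_filter(shared, 1, strict = TRUE)
  expect_equal(nrow(pf4), 0L)
  expect_equal(pf3$prevalence, 1)
})
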