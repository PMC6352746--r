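test_that("trajectory classes match their verbal definitions", {
  expect_equal(classify_dynamics(c(1, 1, 1, 1, 1, 1, 1)), "core")
  expect_equal(classify_dynamics(c(0, 0, 1, 1, 1)), "emergent_persistent")
  expect_equal(classify_dynamics(c(0, 1, 0, 1, 1)), "alternating")
  expect_equal(classify_dynamics(c(0, 1, 1, 0, 0)), "transient")
  # boundary cases the definitions never enumerate
  expect_equal(classify_dynamics(c(0, 0, 0, 1)), "emergent_persistent")
  expect_equal(classify_dynamics(c(1, 0, 0, 0)), "transient")
  expect_equal(classify_dynamics(c(1, 0, 0, 1)), "alternating")
  expect_error(classify_dynamics(c(0, 0, 0)), "zero presence")
  expect_error(classify_dynamics(1), "two stages")
})

test_that("occupancy matrix rows come from modular overlap with merged sites", {
  g <- circular_genome("mt", 1000)
  occ <- build_occupancy(list(s1 = site_set(g, 0, 10),
                              s2 = site_set(g, 5, 20)))
  expect_equal(nrow(occ$presence), 1L)
  expect_equal(occ$sites$start, 0L)
  expect_equal(occ$sites$end, 20L)
  expect_equal(unname(occ$presence[1, ]), c(1L, 1L))

  occ2 <- build_occupancy(list(s1 = site_set(g, 0, 10),
                               s2 = site_set(g, 100, 120)))
  expect_equal(nrow(occ2$presence), 2L)
  expect_equal(unname(occ2$presence), rbind(c(1L, 0L), c(0L, 1L)))

  # row/column sums equal brute-force overlap counting on random stage sets
  set.seed(23)
  for (rep in 1:10) {
    sets <- lapply(1:4, function(t) {
      iv <- random_intervals(3, 300L)
      site_set(circular_genome("mt", 300), iv$start, iv$end)
    })
    o <- build_occupancy(sets)
    ref <- bf_merge(do.call(rbind, lapply(sets,
                                          function(s) s[, c("start", "end")])),
                    300L)
    expect_equal(o$sites$start, ref$start)
    expect_equal(o$sites$end, ref$end)
    for (i in seq_len(nrow(ref))) for (t in 1:4) {
      s <- sets[[t]]
      hit <- any(vapply(seq_len(nrow(s)), function(j)
        bf_overlap(ref$start[i], ref$end[i], s$start[j], s$end[j], 300L),
        logical(1)))
      expect_equal(unname(o$presence[i, t] == 1L), hit)
    }
    expect_true(all(rowSums(o$presence) >= 1L))
  }
})

test_that("gain/loss bookkeeping telescopes across the series", {
  g <- circular_genome("mt", 1000)
  occ <- build_occupancy(list(a = site_set(g, c(0, 500), c(10, 520)),
                              b = site_set(g, c(0, 100), c(10, 130))))
  gl <- gain_loss(occ)
  expect_equal(gl$gained, c(2L, 1L))
  expect_equal(gl$lost, c(0L, 1L))

  set.seed(41)
  for (rep in 1:20) {
    p <- matrix(rbinom(35, 1, 0.5), 5, 7)
    p[rowSums(p) == 0, sample(7, 1)] <- 1L
    occ <- list(sites = NULL, stages = paste0("t", 1:7), presence = p)
    class(occ) <- "OccupancyMatrix"
    gl <- gain_loss(occ)
    expect_equal(gl$gained[-1], sapply(2:7, function(t)
      sum(p[, t - 1] == 0 & p[, t] == 1)))
    # conservation: net gains equal the first-to-last column difference
    expect_equal(sum(gl$gained) - sum(gl$lost),
                 sum(p[, 7]) - 0L)
  }
})

test_that("region distribution counts boundary-spanning sites in both classes", {
  g <- circular_genome("mt", 1000)
  ann <- feature_annotation(g,
                            c("dloop", "trna1", "nd1"),
                            c("d_loop", "tRNA", "protein_coding"),
                            c(900, 100, 200), c(1000, 170, 500),
                            c(".", "+", "+"))
  s <- site_set(g, 920, 960)
  rd <- region_distribution(s, ann)
  expect_equal(rd$n_sites[rd$class == "d_loop"], 1L)
  expect_equal(rd$n_sites[rd$class == "tRNA"], 0L)
  expect_equal(rd$occupied_fraction[rd$class == "d_loop"], 40 / 100)

  spanning <- site_set(g, 160, 210)   # crosses the tRNA/protein boundary gap
  rd2 <- region_distribution(spanning, ann)
  expect_equal(rd2$n_sites[rd2$class == "tRNA"], 1L)
  expect_equal(rd2$n_sites[rd2$class == "protein_coding"], 1L)
  expect_error(region_distribution(s, ann[0, ]), "empty annotation")
})

test_that("adult-site overlap reports the earliest embryonic stage", {
  g <- circular_genome("mt", 1000)
  occ <- build_occupancy(list(t1 = site_set(g, 700, 720),
                              t2 = site_set(g, 700, 730),
                              t3 = site_set(g, c(5, 700), c(30, 730))))
  adult <- site_set(g, c(0, 400), c(10, 420))
  eo <- embryo_adult_overlap(adult, occ)
  expect_equal(eo$table$overlaps_embryo, c(TRUE, FALSE))
  expect_equal(eo$table$earliest_stage[1], "t3")
  expect_equal(eo$summary$n_overlapping, 1L)
  expect_equal(eo$summary$fraction_overlapping, 0.5)

  none <- embryo_adult_overlap(site_set(g, 400, 420), occ)
  expect_equal(none$summary$n_overlapping, 0L)
})
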