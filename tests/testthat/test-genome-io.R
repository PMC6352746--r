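test_that("FASTA loading enforces the single-record contract and round-trips", {
  g <- simulate_genome(500, seed = 11, name = "mt")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genome(g, fa)
  g2 <- load_genome(fa)
  expect_equal(g2$length, 500L)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$name, "mt")

  two <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), two)
  expect_error(load_genome(two), "2 records")
  expect_error(load_genome(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("coverage from alignments counts full reads and cut sites correctly", {
  g <- circular_genome("mt", 100)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               "@SQ\tSN:mt\tLN:100",
               # one read [10,30), 0-based
               paste0("r1\t0\tmt\t11\t60\t20M\t*\t0\t0\t",
                      strrep("A", 20), "\t*")), sam)
  full <- coverage_from_alignments(sam, g, mode = "full_read")
  expect_equal(sum(full$counts), 20)
  expect_equal(full$counts[11:30], rep(1, 20))
  expect_equal(sum(full$counts[-(11:30)]), 0)

  cut <- coverage_from_alignments(sam, g, mode = "cut_sites")
  expect_equal(which(cut$counts == 1), 11)   # base 10, 0-based
  expect_equal(sum(cut$counts), 1)

  # minus-strand read: 5' cut at the alignment end
  sam2 <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:mt\tLN:100",
               paste0("r1\t16\tmt\t11\t60\t20M\t*\t0\t0\t",
                      strrep("A", 20), "\t*")), sam2)
  cutm <- coverage_from_alignments(sam2, g, mode = "cut_sites")
  expect_equal(which(cutm$counts == 1), 30)  # base 29
  cutm5 <- coverage_from_alignments(sam2, g, mode = "cut_sites",
                                    tn5_shift = TRUE)
  expect_equal(which(cutm5$counts == 1), 25) # 29 - 5 = 24, 0-based
})

test_that("alignment reader rejects reference mismatch and unsorted input", {
  g <- circular_genome("chrM", 100)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:mt\tLN:100",
               paste0("r1\t0\tmt\t11\t60\t5M\t*\t0\t0\tAAAAA\t*")), sam)
  expect_error(coverage_from_alignments(sam, g), "does not match")

  g2 <- circular_genome("mt", 100)
  sam2 <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:mt\tLN:100",
               "r1\t0\tmt\t50\t60\t5M\t*\t0\t0\tAAAAA\t*",
               "r2\t0\tmt\t11\t60\t5M\t*\t0\t0\tAAAAA\t*"), sam2)
  expect_error(coverage_from_alignments(sam2, g2), "not coordinate sorted")
})

test_that("coverage mass is conserved against the generator's bookkeeping", {
  cfg <- simulation_config(genome_length = 400, background_mean = 20,
                           seed = 5)
  g <- simulate_genome(400, seed = 5)
  sim <- simulate_reads(cfg, g, n_reads = 1000, read_length = 40)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_read_sam(sim$reads, g, sam)
  tr <- coverage_from_alignments(sam, g, mode = "full_read")
  # SAM clips reads at the linear reference end
  expect_equal(sum(tr$counts),
               sum(pmin(sim$reads$width, 400 - sim$reads$start)))
  cut <- coverage_from_alignments(sam, g, mode = "cut_sites")
  expect_equal(sum(cut$counts), 1000)
  expect_equal(which(cut$counts > 0) - 1L, sort(unique(sim$cut_positions)))
})

test_that("bedGraph coverage round-trips and handles sparse/empty input", {
  g <- circular_genome("mt", 50)
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("mt\t0\t5\t3", bg)
  tr <- load_coverage(bg, g)
  expect_equal(tr$counts[1:5], rep(3, 5))
  expect_equal(sum(tr$counts), 15)

  empty <- withr::local_tempfile(fileext = ".bedGraph")
  file.create(empty)
  expect_equal(sum(load_coverage(empty, g)$counts), 0)

  set.seed(2)
  tr2 <- coverage_track(g, rpois(50, 4))
  out <- withr::local_tempfile(fileext = ".bedGraph")
  write_coverage(tr2, out)
  expect_equal(load_coverage(out, g)$counts, tr2$counts)

  bad <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("mt\t40\t60\t3", bad)
  expect_error(load_coverage(bad, g), "bounds")
})

test_that("feature loading converts BED and GFF conventions identically", {
  g <- circular_genome("mt", 100)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("mt\t0\t10\ttRNA-Phe\t0\t+", bed)
  fb <- load_features(bed, g, class_map = c(`tRNA-Phe` = "tRNA"))
  expect_equal(fb$start, 0L)
  expect_equal(fb$end, 10L)
  expect_equal(fb$class, "tRNA")

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "mt\tsrc\ttRNA\t1\t10\t.\t+\t.\tID=tRNA-Phe"), gff)
  fg <- load_features(gff, g, class_map = c(tRNA = "tRNA"))
  expect_equal(fg$start, fb$start)
  expect_equal(fg$end, fb$end)
})

test_that("origin-split BED blocks reassemble into one wrapped feature", {
  g <- circular_genome("mt", 100)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("mt\t90\t100\tdloop\t0\t+",
               "mt\t0\t15\tdloop\t0\t+"), bed)
  f <- load_features(bed, g, class_map = c(dloop = "d_loop"))
  expect_equal(nrow(f), 1L)
  expect_equal(f$start, 90L)
  expect_equal(f$end, 15L)
  # matches manual modular construction: bases 90..99, 0..14
  expect_setequal(bases_of(f$start, f$end, 100), c(90:99, 0:14))

  # write/load round trip through the two-block encoding
  out <- withr::local_tempfile(fileext = ".bed")
  write_features(f, out)
  f2 <- load_features(out, g, class_map = c(dloop = "d_loop"))
  expect_equal(f2$start, f$start)
  expect_equal(f2$end, f$end)
})
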