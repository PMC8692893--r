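test_that("a fixed seed reproduces every generator byte-identically", {
  cfg <- simConfig(seed = 17,
                   germline = list(n_clusters = 2L, missing = list(),
                                   prejoined = integer(0)),
                   repertoire = list(
                     pair_table = c("IGNARV1|IGNARJ1" = 0.9,
                                    "IGNARV2|IGNARJ2" = 0.1),
                     n_clones = 100L))
  g1 <- makeSyntheticGenome(cfg)
  g2 <- makeSyntheticGenome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(as.data.frame(g1$features), as.data.frame(g2$features))
  s1 <- simulateRepertoire(cfg, 200)
  s2 <- simulateRepertoire(cfg, 200)
  expect_identical(as.character(s1$reads), as.character(s2$reads))
  expect_identical(mcols(s1$reads)$quality, mcols(s2$reads)$quality)
  expect_identical(s1$truth, s2$truth)
  l1 <- simulateVnarLibrary(cfg, 200)
  l2 <- simulateVnarLibrary(cfg, 200)
  expect_identical(as.character(l1$sequences), as.character(l2$sequences))
  expect_identical(l1$truth, l2$truth)
  # a different seed changes the output
  s3 <- simulateRepertoire(simConfig(seed = 18, germline = cfg@germline,
                                     repertoire = cfg@repertoire), 200)
  expect_false(identical(as.character(s1$reads), as.character(s3$reads)))
})

test_that("a one-cluster configuration plants exactly the complete composition", {
  cfg <- simConfig(seed = 21,
                   germline = list(n_clusters = 1L, missing = list(),
                                   prejoined = integer(0)))
  gen <- makeSyntheticGenome(cfg)
  mc <- mcols(gen$features)
  segs <- mc[mc$type == "gene_segment", ]
  expect_equal(nrow(segs), 12)   # 1V + 3D + 1J + 5C + Sec + Tm
  expect_equal(sort(as.vector(table(segs$kind))),
               sort(c(V = 1L, D = 3L, J = 1L, C = 5L, Sec = 1L, Tm = 1L)),
               ignore_attr = TRUE)
  # every planted feature is on the contig and none overlap
  ir <- ranges(gen$features)
  ov <- findOverlaps(ir, ir)
  expect_equal(length(ov), length(ir))   # self-hits only
})

test_that("planted RSS mismatch counts interact with the scanner budgets as configured", {
  base <- list(n_clusters = 1L, missing = list(), prejoined = integer(0))
  at2 <- makeSyntheticGenome(simConfig(
    seed = 22, germline = c(base, list(rss_heptamer_mm = 2L))))
  hits2 <- findRSS(at2$genome)
  planted <- at2$features[mcols(at2$features)$type ==
                            "recombination_feature"]
  found <- countOverlaps(planted, hits2, type = "equal")
  expect_true(all(found >= 1))
  at3 <- makeSyntheticGenome(simConfig(
    seed = 22, germline = c(base, list(rss_heptamer_mm = 3L))))
  hits3 <- findRSS(at3$genome)
  planted3 <- at3$features[mcols(at3$features)$type ==
                             "recombination_feature"]
  expect_true(all(countOverlaps(planted3, hits3, type = "equal") == 0))
})

test_that("truth GFF and FASTA are written next to the genome", {
  dir <- tempfile("sim")
  cfg <- simConfig(seed = 23, germline = list(n_clusters = 1L,
                                              missing = list(),
                                              prejoined = integer(0)))
  makeSyntheticGenome(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "genome.fasta")))
  gff <- readLines(file.path(dir, "truth.gff3"))
  expect_equal(gff[1], "##gff-version 3")
  expect_equal(sum(grepl("gene_segment", gff)), 12)
})

test_that("repertoire truth has one row per read and respects the configured model", {
  cfg <- simConfig(seed = 24,
                   germline = list(n_clusters = 2L, missing = list(),
                                   prejoined = integer(0)),
                   repertoire = list(
                     pair_table = c("IGNARV1|IGNARJ1" = 0.75,
                                    "IGNARV2|IGNARJ2" = 0.25),
                     n_clones = 800L, clone_exponent = 0.6,
                     shm_rate = 0, error_rate = 0))
  sim <- simulateRepertoire(cfg, 6000)
  expect_equal(nrow(sim$truth), 6000)
  expect_identical(sim$truth$read_id, names(sim$reads))
  # pair shares within 3 sigma of the two-stage design
  share <- mean(sim$truth$v_call == "IGNARV1")
  sd <- pairShareSD(0.75, 800, 0.6, 6000)
  expect_lt(abs(share - 0.75), 3 * sd)
  # forced in-frame junctions and zero-noise counts
  expect_true(all(sim$truth$in_frame))
  expect_true(all(sim$truth$n_shm == 0))
  expect_true(all(sim$truth$n_err == 0))
  # constant Q30 qualities
  q <- unique(unlist(strsplit(as.character(mcols(sim$reads)$quality), "")))
  expect_equal(q, "?")
})

test_that("clone sizes follow the configured power law (top-100 mass oracle)", {
  cfg <- simConfig(seed = 25,
                   germline = list(n_clusters = 1L, missing = list(),
                                   prejoined = integer(0)),
                   repertoire = list(
                     pair_table = c("IGNARV1|IGNARJ1" = 1),
                     n_clones = 2000L, clone_exponent = 1.0))
  sim <- simulateRepertoire(cfg, 30000)
  counts <- table(sim$truth$clone_id)
  top100 <- sum(sort(as.integer(counts), decreasing = TRUE)[1:100]) /
    sum(counts)
  w <- (1:2000)^-1
  expected <- sum(sort(w, decreasing = TRUE)[1:100]) / sum(w)
  expect_equal(top100, expected, tolerance = 0.03)
})

test_that("somatic hypermutation and sequencing error rates match configuration", {
  cfg <- simConfig(seed = 26,
                   germline = list(n_clusters = 1L, missing = list(),
                                   prejoined = integer(0)),
                   repertoire = list(pair_table = c("IGNARV1|IGNARJ1" = 1),
                                     n_clones = 400L, shm_rate = 0.02,
                                     error_rate = 0.005))
  sim <- simulateRepertoire(cfg, 4000)
  len <- mean(nchar(as.character(sim$reads)))
  shm_rate <- mean(sim$truth$n_shm[!duplicated(sim$truth$clone_id)]) / len
  err_rate <- mean(sim$truth$n_err) / len
  expect_equal(shm_rate, 0.02, tolerance = 0.15)
  expect_equal(err_rate, 0.005, tolerance = 0.15)
})

test_that("a pair table naming unknown segments is rejected", {
  cfg <- simConfig(seed = 27,
                   germline = list(n_clusters = 1L, missing = list(),
                                   prejoined = integer(0)),
                   repertoire = list(pair_table = c("IGNARV9|IGNARJ9" = 1)))
  expect_error(simulateRepertoire(cfg, 10), "absent")
})

test_that("invalid configurations fail validation up front", {
  expect_error(simConfig(repertoire = list(
    pair_table = c("IGNARV1|IGNARJ1" = 0.5))), "sum to 1")
  expect_error(simConfig(repertoire = list(shm_rate = 1.2)), "shm_rate")
  expect_error(simConfig(library = list(unique_fraction = 0)),
               "unique_fraction")
  expect_error(simConfig(library = list(
    type_mixture = c(I = 0.5, II = 0.1))), "type_mixture")
})

test_that("the library generator realises the configured unique fraction exactly", {
  cfg <- simConfig(seed = 28, library = list(unique_fraction = 0.8))
  lib <- simulateVnarLibrary(cfg, 1000)
  expect_equal(unname(uniqueRatio(lib$sequences)["distinct_fraction"]), 0.8)
  expect_equal(sum(is.na(lib$truth$duplicate_of)), 800)
})

test_that("time-course simulation expands the programmed clones", {
  cfg <- simConfig(seed = 29,
                   germline = list(n_clusters = 1L, missing = list(),
                                   prejoined = integer(0)),
                   repertoire = list(pair_table = c("IGNARV1|IGNARJ1" = 1),
                                     n_clones = 1000L,
                                     clone_exponent = 1.0))
  tc <- simulateTimeCourse(cfg, 15000, nTimepoints = 2,
                           expandRanks = 191:200, expandFactor = 8)
  expanded <- attr(tc, "expanded_clones")
  f1 <- table(tc[[1]]$truth$clone_id)[expanded] / 15000
  f2 <- table(tc[[2]]$truth$clone_id)[expanded] / 15000
  f1[is.na(f1)] <- 0
  expect_true(all(f2 > f1))
  # both time points share the same clone sequences
  expect_identical(tc[[1]]$clones$sequence, tc[[2]]$clones$sequence)
})
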