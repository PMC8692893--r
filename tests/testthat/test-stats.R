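test_that("Shannon index closed forms and direct-summation values hold", {
  expect_equal(unname(shannonIndex(c(only = 12))["shannon"]), 0)
  expect_equal(unname(shannonIndex(c(a = 50, b = 50))["shannon"]), log(2),
               tolerance = 1e-12)
  h <- shannonIndex(c(a = 5, b = 3, c = 2))
  expected <- -(0.5 * log(0.5) + 0.3 * log(0.3) + 0.2 * log(0.2))
  expect_equal(unname(h["shannon"]), expected, tolerance = 1e-12)
  expect_equal(unname(h["evenness"]), expected / log(3), tolerance = 1e-12)
  expect_error(shannonIndex(numeric(0)), "empty")
})

test_that("Shannon index is bounded by ln(k) with equality at uniformity and drops under skew", {
  set.seed(441)
  for (rep in 1:10) {
    k <- sample(2:40, 1)
    counts <- sample(1:50, k, replace = TRUE)
    h <- unname(shannonIndex(counts)["shannon"])
    expect_gte(h, 0)
    expect_lte(h, log(k) + 1e-12)
    uniform <- rep(7, k)
    expect_equal(unname(shannonIndex(uniform)["shannon"]), log(k),
                 tolerance = 1e-12)
    skewed <- counts
    skewed[which.max(counts)] <- skewed[which.max(counts)] + sum(counts)
    expect_lt(unname(shannonIndex(skewed)["shannon"]), h + 1e-12)
  }
})

test_that("Wu-Kabat variability matches hand computation on a fixture alignment", {
  aln <- rbind(c("C", "A", "A", "A"),
               c("C", "A", "G", "A"),
               c("C", "G", "T", "A"),
               c("C", "G", "Y", "-"))
  v <- positionalVariability(aln, regions = c("FR1", "CDR1", "CDR3", "FR4"))
  expect_equal(v$variability[1], 1)                # invariant column
  expect_equal(v$variability[2], 2 / 0.5)          # {A:2, G:2}
  expect_equal(v$variability[3], 4 / 0.25)         # four distinct residues
  expect_equal(v$variability[4], 1)                # gap excluded
  expect_equal(v$coverage, c(4L, 4L, 4L, 3L))
  expect_equal(v$region, c("FR1", "CDR1", "CDR3", "FR4"))
})

test_that("a column with one observed residue scores exactly 1 and empty columns are missing", {
  aln <- rbind(c("A", "-"), c("A", "-"))
  v <- positionalVariability(aln)
  expect_equal(v$variability[1], 1)
  expect_true(is.na(v$variability[2]))
})

test_that("the simulated library's variability peaks inside CDR3", {
  cfg <- simConfig(seed = 91)
  lib <- simulateVnarLibrary(cfg, 300)
  aligned <- alignToReference(lib$sequences)
  v <- positionalVariability(aligned)
  expect_equal(v$region[which.max(v$variability)], "CDR3")
})

test_that("V-J pairing frequencies sum to one and concentrate correctly", {
  df <- data.frame(
    sequence_id = paste0("r", 1:6), sequence = strrep("A", 6),
    v_call = c(rep("IGNARV1", 5), "IGNARV2"),
    j_call = c(rep("IGNARJ1", 5), "IGNARJ2"),
    cdr3_aa = c("AAA", "AAA", "CCC", "DDD", "EEE", "FFF"),
    productive = TRUE, pass_qc = TRUE)
  vj <- vjPairMatrix(df)
  expect_equal(sum(vj$matrix), 1, tolerance = 1e-12)
  expect_equal(vj$matrix["IGNARV1", "IGNARJ1"], 5 / 6)
  expect_equal(unname(vj$v_usage["IGNARV1"]), 5 / 6)
  one <- vjPairMatrix(df[1:5, ])
  expect_equal(unname(one$matrix[1, 1]), 1)
  # clonotype weighting collapses the repeated clonotype
  vjc <- vjPairMatrix(df, weightBy = "clonotype")
  expect_equal(vjc$matrix["IGNARV1", "IGNARJ1"], 4 / 5)
})

test_that("top-n cumulative frequency follows direct arithmetic and saturates", {
  expect_equal(topNCumulative(rep(1, 100), n = 100), 1)
  expect_equal(topNCumulative(c(a = 50, b = 30, c = 20), n = 1), 0.5)
  expect_message(v <- topNCumulative(c(a = 1, b = 1), n = 10), "exceeds")
  expect_equal(v, 1)
  # increasing skew raises the top-n mass (oracle on generated counts)
  set.seed(442)
  masses <- vapply(c(0.5, 1, 1.5), function(alpha) {
    w <- (1:2000)^(-alpha)
    counts <- as.vector(rmultinom(1, 50000, w / sum(w)))
    topNCumulative(counts, n = 100)
  }, numeric(1))
  expect_true(all(diff(masses) > 0))
})

test_that("uniqueness reports both the distinct and singleton definitions", {
  u <- uniqueRatio(c("A", "B", "C", "D"))
  expect_equal(unname(u["distinct_fraction"]), 1)
  seqs <- c(rep("AAA", 3), rep("CCC", 3), "G", "T", "AC", "AG")
  u2 <- uniqueRatio(seqs)
  expect_equal(unname(u2["distinct_fraction"]), 6 / 10)
  expect_equal(unname(u2["singleton_fraction"]), 4 / 10)
})

test_that("clonotype overlap follows the min-denominator definition with Jaccard optional", {
  a <- c(x = 3, y = 2, z = 1)
  b <- c(x = 1, y = 5, w = 2, v = 1)
  expect_equal(clonotypeOverlap(a, a), 1)
  expect_equal(clonotypeOverlap(a, c(q = 1, r = 1)), 0)
  expect_equal(clonotypeOverlap(a, b), 2 / 3)
  expect_equal(clonotypeOverlap(a, b, method = "jaccard"), 2 / 5)
  sub <- c(x = 9, y = 1)
  expect_equal(clonotypeOverlap(sub, b), 2 / 2)   # subset: 1 under min
  expect_equal(clonotypeOverlap(a, b), clonotypeOverlap(b, a))
  expect_error(clonotypeOverlap(a, numeric(0)), "empty")
})

test_that("clonotype tracking conserves mass and reports absent-then-present trajectories", {
  t1 <- c(big = 90, mid = 9, small = 1)
  t2 <- c(big = 50, mid = 10, newcomer = 40)
  m <- clonotypeTracking(list(t1 = t1, t2 = t2), topN = 2)
  expect_equal(colSums(m), c(t1 = 1, t2 = 1), tolerance = 1e-12)
  expect_equal(m["newcomer", "t1"], 0)
  expect_equal(m["newcomer", "t2"], 0.4)
  expect_true(all(c("big", "mid", "newcomer", "other") %in% rownames(m)))
})

test_that("sample-level statistics agree with the simulator truth table", {
  cfg <- simConfig(seed = 92,
                   germline = list(n_clusters = 2L, missing = list(),
                                   prejoined = integer(0)),
                   repertoire = list(
                     pair_table = c("IGNARV1|IGNARJ1" = 0.8,
                                    "IGNARV2|IGNARJ2" = 0.2),
                     n_clones = 500L, clone_exponent = 0.6))
  db <- makeGermlineReferences(cfg)
  sim <- simulateRepertoire(cfg, 1500, germline = db)
  smp <- annotateReads(sim$reads, db)
  tr <- sim$truth[sim$truth$productive, ]
  truth_counts <- table(paste(tr$v_call, tr$j_call, tr$cdr3_aa, sep = "|"))
  h_pipe <- unname(shannonIndex(smp)["shannon"])
  h_truth <- unname(shannonIndex(as.numeric(truth_counts))["shannon"])
  expect_equal(h_pipe, h_truth, tolerance = 0.05)
  expect_equal(topNCumulative(smp, 50),
               topNCumulative(as.numeric(truth_counts), 50),
               tolerance = 0.02)
  # CDR3 amino-acid lengths stay on the conventional 0-40 profile axis
  df <- as.data.frame(rearrangements(smp))
  lens <- nchar(df$cdr3_aa[df$pass_qc & df$frame == "in"])
  expect_true(all(lens >= 0 & lens <= 40))
})
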