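test_that("read filtering applies each rule once and conserves reads", {
  reads <- DNAStringSet(c(
    good = strrep("ACGT", 100),
    short = strrep("ACGT", 20),
    enn = paste0(strrep("N", 40), strrep("ACGT", 90)),
    lowq = strrep("ACGT", 100)))
  mcols(reads)$quality <- c(strrep("I", 400), strrep("I", 80),
                            strrep("I", 400), strrep("#", 400))
  out <- filterReads(reads)
  expect_equal(out$report$total, 4L)
  expect_equal(out$report$removed_length, 1L)
  expect_equal(out$report$removed_n, 1L)
  expect_equal(out$report$removed_quality, 1L)
  expect_equal(out$report$kept, 1L)
  expect_equal(names(out$reads), "good")
  expect_equal(out$report$kept + out$report$removed_length +
                 out$report$removed_n + out$report$removed_quality,
               out$report$total)
})

test_that("filtering FASTA input without qualities skips the quality rule with a warning", {
  reads <- DNAStringSet(c(a = strrep("ACGT", 100)))
  expect_warning(out <- filterReads(reads), "qualit")
  expect_equal(out$report$kept, 1L)
})

test_that("an empty read set filters to an empty result with a zeroed report", {
  out <- filterReads(DNAStringSet())
  expect_length(out$reads, 0)
  expect_equal(out$report$total, 0L)
  expect_equal(out$report$kept, 0L)
})

test_that("an exact germline V+junction+J read annotates perfectly", {
  db <- tinyGermline()
  read <- buildRead(db, junction = "GGTACAGCTTT")   # full IGNARD1 + TT
  smp <- annotateReads(asReads(read), db)
  df <- as.data.frame(rearrangements(smp))
  expect_true(df$pass_qc)
  expect_equal(df$v_call, "IGNARV1")
  expect_equal(df$j_call, "IGNARJ1")
  expect_equal(df$v_identity, 1.0)
  expect_equal(df$j_identity, 1.0)
  expect_equal(df$d_call, "IGNARD1")
})

test_that("a junction of pure non-templated bases gives no D call", {
  db <- tinyGermline()
  read <- buildRead(db, junction = "TTTTTTTT")
  df <- as.data.frame(rearrangements(annotateReads(asReads(read), db)))
  expect_equal(df$d_call, "none")
})

test_that("random sequence is flagged unassigned with a reason", {
  set.seed(431)
  db <- tinyGermline()
  df <- as.data.frame(rearrangements(
    annotateReads(asReads(randomSeq(400)), db)))
  expect_false(df$pass_qc)
  expect_match(df$qc_reason, "no V assignment")
})

test_that("base-by-base extension disambiguates alleles differing only at the 3' end", {
  db <- tinyGermline()
  vA <- as.character(db$sequences[["IGNARV1"]])
  vB <- mutateAt(vA, nchar(vA) - c(0L, 1L, 2L))
  tab <- rbind(db$table[db$table$segment != "IGNARV1", ],
               data.frame(segment = c("IGNARV1", "IGNARV1b"), kind = "V",
                          cluster = 1L,
                          anchor = db$table$anchor[db$table$segment ==
                                                     "IGNARV1"]))
  seqs <- c(db$sequences[setdiff(names(db$sequences), "IGNARV1")],
            DNAStringSet(c(IGNARV1 = vA, IGNARV1b = vB)))
  db2 <- list(sequences = seqs, table = tab)
  readA <- paste0(vA, "TTTT",
                  as.character(db$sequences[["IGNARJ1"]]))
  readB <- paste0(vB, "TTTT",
                  as.character(db$sequences[["IGNARJ1"]]))
  dfA <- as.data.frame(rearrangements(annotateReads(asReads(readA), db2)))
  dfB <- as.data.frame(rearrangements(annotateReads(asReads(readB), db2)))
  expect_equal(dfA$v_call, "IGNARV1")
  expect_equal(dfB$v_call, "IGNARV1b")
})

test_that("annotation is invariant to reverse-complemented input reads", {
  db <- tinyGermline()
  read <- buildRead(db, junction = "CATCGGCATAA", jTrim = 2L)
  rc <- as.character(reverseComplement(DNAString(read)))
  d1 <- as.data.frame(rearrangements(annotateReads(asReads(read), db)))
  d2 <- as.data.frame(rearrangements(annotateReads(asReads(rc), db)))
  expect_equal(d2$strand, "-")
  for (col in c("v_call", "d_call", "j_call", "cdr3", "cdr3_aa", "frame",
                "productive"))
    expect_equal(d2[[col]], d1[[col]], label = col)
})

test_that("every read lands in exactly one row and QC reasons partition failures", {
  set.seed(432)
  db <- tinyGermline()
  reads <- asReads(c(buildRead(db, junction = "ACGTAA"), randomSeq(400),
                     buildRead(db, junction = "G")))
  smp <- annotateReads(reads, db)
  df <- as.data.frame(rearrangements(smp))
  expect_equal(nrow(df), 3)
  expect_setequal(df$sequence_id, names(reads))
  expect_true(all(df$pass_qc == (df$qc_reason == "")))
})

test_that("zero-noise simulator output is recovered exactly for in-frame reads", {
  cfg <- simConfig(seed = 77,
                   germline = list(n_clusters = 2L, missing = list(),
                                   prejoined = integer(0)),
                   repertoire = list(
                     pair_table = c("IGNARV1|IGNARJ1" = 0.7,
                                    "IGNARV2|IGNARJ2" = 0.3),
                     n_clones = 300L, shm_rate = 0, error_rate = 0,
                     d_trim_max = 1L))
  db <- makeGermlineReferences(cfg)
  sim <- simulateRepertoire(cfg, 400, germline = db)
  df <- as.data.frame(rearrangements(annotateReads(sim$reads, db)))
  tr <- sim$truth
  inf <- tr$in_frame
  expect_true(all(df$pass_qc))
  expect_equal(df$v_call[inf], tr$v_call[inf])
  expect_equal(df$j_call[inf], tr$j_call[inf])
  expect_equal(df$cdr3[inf], tr$cdr3_nt[inf])
  expect_equal(df$cdr3_aa[inf], tr$cdr3_aa[inf])
  expect_equal(df$frame[inf] == "in", tr$in_frame[inf])
  expect_equal(df$productive[inf], tr$productive[inf])
  # D calls agree wherever enough germline D survives trimming; junction
  # boundary extension can reattribute a base or two in the remainder
  expect_gte(mean(df$d_call[inf] == tr$d_expected[inf]), 0.9)
})

test_that("V/J accuracy degrades monotonically with rising SHM, within sampling error", {
  acc <- vapply(c(0, 0.02, 0.08), function(shm) {
    cfg <- simConfig(seed = 78,
                     germline = list(n_clusters = 2L, missing = list(),
                                     prejoined = integer(0)),
                     repertoire = list(
                       pair_table = c("IGNARV1|IGNARJ1" = 0.7,
                                      "IGNARV2|IGNARJ2" = 0.3),
                       n_clones = 200L, shm_rate = shm, error_rate = 0))
    db <- makeGermlineReferences(cfg)
    sim <- simulateRepertoire(cfg, 250, germline = db)
    df <- as.data.frame(rearrangements(annotateReads(sim$reads, db)))
    mean(df$v_call == sim$truth$v_call & df$j_call == sim$truth$j_call)
  }, numeric(1))
  expect_equal(acc[1], 1)
  expect_true(acc[3] <= acc[1] + 0.01 && acc[2] <= acc[1] + 0.01)
})

test_that("extractCDR3 agrees with full annotation on a constructed read", {
  db <- tinyGermline()
  read <- buildRead(db, junction = "GGTACAGCTAA")
  df <- as.data.frame(rearrangements(annotateReads(asReads(read), db)))
  single <- extractCDR3(read, df$v_call, df$j_call, db)
  expect_equal(single$cdr3_nt, df$cdr3)
  expect_equal(single$frame, df$frame)
  expect_equal(single$productive, df$productive)
})

test_that("the rearrangement table round-trips through TSV including failed reads", {
  set.seed(433)
  db <- tinyGermline()
  reads <- asReads(c(buildRead(db, junction = "ACGTAA"), randomSeq(400)))
  smp <- annotateReads(reads, db, sampleID = "s1")
  f <- tempfile(fileext = ".tsv")
  tab <- buildRearrangementTable(smp, f)
  expect_equal(nrow(read.delim(f)), 2)
  back <- readRearrangementTable(f, sampleID = "s1")
  expect_equal(as.data.frame(rearrangements(back)),
               as.data.frame(rearrangements(smp)))
  expect_equal(sampleID(back), "s1")
  # the unassigned read keeps its row with empty calls
  df <- as.data.frame(rearrangements(back))
  expect_equal(df$v_call[2], "")
  expect_false(df$pass_qc[2])
})
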