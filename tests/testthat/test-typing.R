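# assemble a vNAR amino-acid string from the reference template with a
# chosen cysteine/tryptophan placement
templateSeq <- function(fr1_cys = TRUE, fr3b_cys = TRUE, cdr1_cys = 0,
                        cdr1_trp = FALSE, fr2_cys = FALSE, fr4_cys = FALSE,
                        cdr3 = "ARSGAYGSSYDV", hv2_cys = 0) {
  ref <- vnarReference()
  ch <- strsplit(ref$aa, "")[[1L]]
  lab <- ref$regions
  if (!fr1_cys) ch[ref$anchors[["fr1_cys"]]] <- "S"
  if (!fr3b_cys) ch[ref$anchors[["fr3b_cys"]]] <- "S"
  cdr1 <- which(lab == "CDR1")
  if (cdr1_cys > 0) ch[cdr1[seq_len(cdr1_cys)]] <- "C"
  if (cdr1_trp) ch[cdr1[length(cdr1)]] <- "W"
  if (fr2_cys) ch[setdiff(which(lab == "FR2"),
                          ref$anchors[["fr2_trp"]])[1L]] <- "C"
  if (fr4_cys) ch[setdiff(which(lab == "FR4"),
                          ref$anchors[["fr4_trp"]])[1L]] <- "C"
  if (hv2_cys > 0) ch[which(lab == "HV2")[seq_len(hv2_cys)]] <- "C"
  paste(c(ch[lab %in% c("FR1", "CDR1", "FR2", "HV2", "FR3a", "FR3b")],
          strsplit(cdr3, "")[[1L]], ch[lab == "FR4"]), collapse = "")
}

test_that("the reference sequence maps onto its own region annotation", {
  ref <- vnarReference()
  rm_ <- assignRegions(ref$aa)
  expect_true(rm_$alignable[1])
  expect_identical(rm_$labels[[1]], ref$regions)
})

test_that("a CDR3 insertion lengthens CDR3 without moving framework labels", {
  ref <- vnarReference()
  ins <- templateSeq(cdr3 = "ARSGAGGGGGAYGSSYDV")   # +6 aa inside CDR3
  rm_ <- assignRegions(ins)
  lab <- rm_$labels[[1]]
  base <- table(factor(ref$regions, levels = unique(ref$regions)))
  got <- table(factor(lab, levels = unique(ref$regions)))
  expect_equal(got[["CDR3"]], base[["CDR3"]] + 6)
  for (r in c("FR1", "CDR1", "FR2", "HV2", "FR3a", "FR3b", "FR4"))
    expect_equal(got[[r]], base[[r]], label = r)
})

test_that("the rule table reproduces the named vNAR types", {
  classify1 <- function(seq) {
    rm_ <- assignRegions(seq)
    classifyType(seq, rm_$labels[[1]])
  }
  expect_equal(classify1(templateSeq())$type, "IV")  # canonical pair only
  t2 <- classify1(templateSeq(cdr1_cys = 1, cdr3 = "ARSGCYGSSYDV"))
  expect_equal(t2$type, "II")
  expect_equal(t2$cysteine_count, 4L)                # classical 4-Cys type II
  expect_true(t2$canonical_pair)
  t3 <- classify1(templateSeq(cdr1_cys = 1, cdr1_trp = TRUE,
                              cdr3 = "ARSGCYGSSYDV"))
  expect_equal(t3$type, "III")
  t1 <- classify1(templateSeq(fr2_cys = TRUE, fr4_cys = TRUE,
                              cdr3 = "ARCGAYGCSYDV"))
  expect_equal(t1$type, "I")
  expect_equal(classify1(templateSeq(fr2_cys = TRUE))$type, "new")
  expect_equal(classify1(templateSeq(fr1_cys = FALSE, cdr1_cys = 1,
                                     cdr3 = "ARSGCYGSSYDV"))$type, "new")
  expect_equal(classify1(templateSeq(cdr1_cys = 2,
                                     cdr3 = "ARSGCYGSSYDV"))$type, "new")
  expect_equal(classify1(templateSeq(hv2_cys = 1))$type, "new")
  nc <- classify1(templateSeq(fr2_cys = TRUE))
  expect_match(nc$noncanonical_regions, "FR2")
})

test_that("the rule table partitions every cysteine placement pattern", {
  # enumerate counts over the six rule-relevant regions and the CDR1 Trp
  grid <- expand.grid(fr1 = 0:1, cdr1 = 0:2, fr2 = 0:1, fr3b = 0:1,
                      cdr3 = 0:3, fr4 = 0:1, hv2 = 0:1, trp = c(FALSE, TRUE))
  rules <- defaultTypeRules()
  lab <- c(rep("FR1", 2), rep("CDR1", 3), rep("FR2", 2), rep("HV2", 2),
           rep("FR3a", 2), rep("FR3b", 2), rep("CDR3", 4), rep("FR4", 2))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ch <- rep("A", length(lab))
    place <- function(region, k) {
      idx <- which(lab == region)
      if (k > 0) ch[idx[seq_len(k)]] <<- "C"
    }
    place("FR1", g$fr1); place("CDR1", g$cdr1); place("FR2", g$fr2)
    place("FR3b", g$fr3b); place("CDR3", g$cdr3); place("FR4", g$fr4)
    place("HV2", g$hv2)
    if (g$trp) ch[which(lab == "CDR1")[3]] <- "W"
    call <- classifyType(paste(ch, collapse = ""), lab, rules)
    expect_true(call$type %in% c("I", "II", "III", "IV", "new"))
    expect_length(call$type, 1)
  }
})

test_that("classification ignores substitutions that are not Cys or Trp", {
  seq2 <- templateSeq(cdr1_cys = 1, cdr3 = "ARSGCYGSSYDV")
  rm_ <- assignRegions(seq2)
  base <- classifyType(seq2, rm_$labels[[1]])$type
  set.seed(451)
  ch <- strsplit(seq2, "")[[1L]]
  free <- which(!ch %in% c("C", "W"))
  for (rep in 1:5) {
    mod <- ch
    swap <- sample(free, 6)
    mod[swap] <- sample(c("A", "D", "E", "G", "H", "K", "N", "Q", "S",
                          "T"), 6, replace = TRUE)
    m <- paste(mod, collapse = "")
    rm2 <- assignRegions(m)
    expect_equal(classifyType(m, rm2$labels[[1]])$type, base)
  }
})

test_that("type profiles sum to 100 and the cysteine histogram equals a direct tally", {
  seqs <- c(rep(templateSeq(cdr1_cys = 1, cdr3 = "ARSGCYGSSYDV"), 6),
            rep(templateSeq(), 3),
            templateSeq(fr2_cys = TRUE))
  prof <- typeProfile(seqs)
  expect_equal(sum(prof$types$percent), 100, tolerance = 1e-9)
  expect_equal(prof$types$percent[prof$types$type == "II"], 60)
  expect_equal(prof$types$percent[prof$types$type == "IV"], 30)
  expect_equal(prof$types$percent[prof$types$type == "new"], 10)
  direct <- table(vapply(strsplit(seqs, ""), function(x) sum(x == "C"),
                         integer(1)))
  expect_equal(prof$cysteines$count, as.integer(direct))
  expect_equal(prof$cysteines$cysteines, as.integer(names(direct)))
  expect_equal(prof$unique_fraction, 3 / 10)
})

test_that("the YAML rule file loads to the built-in rule table", {
  path <- system.file("extdata", "vnar_type_rules.yaml", package = "vnarseq")
  expect_equal(loadTypeRules(path), defaultTypeRules())
})

test_that("unalignable sequences are excluded from typing with a reason", {
  set.seed(452)
  junk <- paste(sample(c("G", "P"), 90, TRUE), collapse = "")
  calls <- classifyVnar(c(templateSeq(), junk))
  expect_false(calls$alignable[2])
  expect_true(is.na(calls$type[2]))
  expect_equal(calls$type[1], "IV")
})

test_that("classification recovers the simulated library's planted types", {
  cfg <- simConfig(seed = 93)
  lib <- simulateVnarLibrary(cfg, 600)
  calls <- classifyVnar(lib$sequences)
  expect_gte(mean(calls$type == lib$truth$type, na.rm = TRUE), 0.99)
  one <- simulateVnarLibrary(
    simConfig(seed = 94, library = list(
      type_mixture = c(I = 0, II = 1, III = 0, IV = 0, new = 0))), 150)
  expect_true(all(one$truth$type == "II"))
  calls1 <- classifyVnar(one$sequences)
  expect_true(all(calls1$type == "II"))
})
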