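# amplification primers flanking the vNAR amplicon (optional in simulation)
PRIMER_VNAR_V <- "AGACCGCTTGGCCTCCGACTTGGGTTGAACAAACACCGACA"
PRIMER_VNAR_J <- "ACATGGCTACGATCCGACTTAATCCATTTGCCCTCTGTTCT"

# hand-designed, mutually distant 9-mer germline D segments (no stop codon
# in any frame) shared across clusters
DEFAULT_D_SEQS <- c(IGNARD1 = "GGTACAGCT", IGNARD2 = "CATCGGCAT",
                    IGNARD3 = "ACCGTTCCA")

germlineDefaults <- function() {
  list(
    n_clusters = 7L,
    # segment kinds absent from the incomplete clusters
    missing = list("3" = "V", "4" = "J", "7" = c("V", "D", "J")),
    # clusters whose third D is germline-fused (planted without RSS)
    prejoined = c(2L, 5L, 6L),
    c_length = 280L, sec_length = 120L, tm_length = 110L,
    intersegment_gap = 300L, intercluster_gap = 60000L, flank_pad = 2000L,
    gc = 0.42,
    rss_heptamer_mm = 0L, rss_nonamer_mm = 0L,
    spacer_v = 23L, spacer_d5 = 12L, spacer_d3 = 12L, spacer_j = 22L,
    planted_substitutions = 0L)
}

repertoireDefaults <- function() {
  list(
    # within-cluster pairing of the four expressed clusters; the dominant
    # IGNARV1-IGNARJ1 pair carries 96% of the repertoire
    pair_table = c("IGNARV1|IGNARJ1" = 0.96, "IGNARV2|IGNARJ2" = 0.02,
                   "IGNARV5|IGNARJ5" = 0.015, "IGNARV6|IGNARJ6" = 0.005),
    n_clones = 10000L, clone_exponent = 0.6,
    d_usage = 1.0,
    v_trim_mean = 1, v_trim_max = 5L,
    d_trim_mean = 1, d_trim_max = 2L,
    j_trim_mean = 1, j_trim_max = 6L,
    n_insert_mean = 2,
    force_in_frame = TRUE,
    shm_rate = 0.01, error_rate = 0.001,
    read_length = 400L, add_primers = FALSE)
}

libraryDefaults <- function() {
  list(
    # type mixture of an immunised bamboo-shark phage library; the 0.3%
    # not covered by the II/new/IV shares is split between rare I and III
    type_mixture = c(I = 0.002, II = 0.790, III = 0.001, IV = 0.019,
                     new = 0.188),
    # conditional four-cysteine share within types II/III realising the
    # 74.5% four-cysteine marginal
    cys4_given_typeII = 0.745 / 0.791,
    unique_fraction = 0.838,
    cdr3_length_min = 3L, cdr3_length_offset = 5L, cdr3_length_lambda = 9,
    cdr3_length_max = 32L,
    framework_diversity = 0.05, cdr1_diversity = 0.6, hv2_diversity = 0.5)
}

#' Build a simulation configuration
#'
#' Returns a \code{\linkS4class{SimConfig}} whose defaults describe the
#' study conditions the package emulates throughout: a seven-cluster IgNAR
#' germline (four complete, three incomplete, pre-joined D segments in
#' clusters 2/5/6), a blood repertoire dominated by the IGNARV1-IGNARJ1
#' pair at 96%, power-law clone sizes, 1% somatic hypermutation and 0.1%
#' per-base sequencing error on single-end 400 bp reads, and a phage
#' library with 79.0% type II / 18.8% new / 1.9% type IV vNARs, a 74.5%
#' four-cysteine marginal and 83.8% sequence uniqueness. Any entry can be
#' overridden through the three named lists.
#'
#' @param seed master seed; all generators derive their streams from it,
#'   so a fixed seed gives byte-identical output.
#' @param germline,repertoire,library named lists overriding individual
#'   defaults.
#' @return a validated \code{SimConfig}.
#' @export
#' @examples
#' cfg <- simConfig(seed = 7, repertoire = list(shm_rate = 0))
#' cfg
simConfig <- function(seed = 1L, germline = list(), repertoire = list(),
                      library = list()) {
  g <- utils::modifyList(germlineDefaults(), germline)
  r <- utils::modifyList(repertoireDefaults(), repertoire)
  l <- utils::modifyList(libraryDefaults(), library)
  methods::new("SimConfig", seed = as.integer(seed), germline = g,
               repertoire = r, library = l)
}

# reverse the genetic code into codon choices per amino acid (stops excluded)
aaCodons <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
      tab[["*"]] <<- NULL
    }
    tab
  }
})

# random codon encoding of an amino-acid string
encodeAA <- function(aa) {
  codons <- aaCodons()
  base::paste(vapply(strsplit(aa, "")[[1L]],
                     function(a) sample(codons[[a]], 1L), character(1)),
              collapse = "")
}

# the planted-truth guarantee: D 9-mers must occur nowhere except where
# planted, since 9 bp carries too little information to be uniquely
# mappable otherwise. Generated non-D sequences are redrawn until free of
# near-matches (<= 1 mismatch, either strand), and assembled background is
# scrubbed by single-base flips outside protected (planted) positions.
dScreenPatterns <- function() {
  c(unname(DEFAULT_D_SEQS), vapply(unname(DEFAULT_D_SEQS), revComp,
                                   character(1)))
}

containsDMatch <- function(seq, pats = dScreenPatterns()) {
  s <- Biostrings::DNAString(seq)
  for (p in pats)
    if (length(Biostrings::matchPattern(p, s, max.mismatch = 1L)))
      return(TRUE)
  FALSE
}

drawDFree <- function(gen, pats = dScreenPatterns(), tries = 50L) {
  for (t in seq_len(tries)) {
    s <- gen()
    if (!containsDMatch(s, pats)) return(s)
  }
  stop("could not draw a sequence free of D-segment near-matches")
}

FLIP_BASE <- c(A = "C", C = "G", G = "T", T = "A", N = "A")

scrubContig <- function(contig, protected) {
  pats <- dScreenPatterns()
  ch <- strsplit(contig, "")[[1L]]
  prot <- logical(length(ch))
  for (iv in protected) prot[iv[1L]:iv[2L]] <- TRUE
  for (pass in 1:6) {
    dirty <- FALSE
    s <- Biostrings::DNAString(paste(ch, collapse = ""))
    for (p in pats) {
      m <- Biostrings::matchPattern(p, s, max.mismatch = 1L)
      pch <- strsplit(p, "")[[1L]]
      for (k in seq_along(m)) {
        pos <- BiocGenerics::start(m)[k]:BiocGenerics::end(m)[k]
        free <- pos[!prot[pos]]
        if (!length(free)) next
        # flip a currently matching base so the window drops to >= 2
        # mismatches and stays dead
        matching <- free[ch[free] == pch[free - pos[1L] + 1L]]
        tgt <- if (length(matching))
          matching[ceiling(length(matching) / 2)]
        else free[ceiling(length(free) / 2)]
        ch[tgt] <- FLIP_BASE[[ch[tgt]]]
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }
  paste(ch, collapse = "")
}

#' Generate the germline segment reference set of a configuration
#'
#' Builds the nucleotide germline database that both the genome generator
#' plants and the repertoire simulator recombines: per-cluster V segments
#' (random codon encodings of the vNAR reference frame through the FR3b
#' cysteine anchor, plus six germline CDR3 nucleotides), per-cluster J
#' segments (CDR3 tail, FR4 with its tryptophan anchor, downstream tail),
#' the shared D 9-mers, and shared C/Sec/Tm sequences. Anchor columns give
#' the CDR3 anchor codon starts used by annotation.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @return list with \code{sequences} (named DNAStringSet) and
#'   \code{table} (data.frame: segment, kind, cluster, anchor).
#' @export
makeGermlineReferences <- function(config) {
  stopifnot(methods::is(config, "SimConfig"))
  g <- config@germline
  ref <- vnarReference()
  withSeed(childSeed(config@seed, "germline_refs"), {
    v_core_aa <- substr(ref$aa, 1L, ref$anchors[["fr3b_cys"]])
    fr4_aa <- substr(ref$aa, ref$anchors[["fr4_trp"]],
                     ref$anchors[["fr4_trp"]] + 9L)
    seqs <- character(0); kind <- character(0); cluster <- integer(0)
    anchor <- integer(0); nm <- character(0)
    for (ci in seq_len(g$n_clusters)) {
      miss <- g$missing[[as.character(ci)]] %||% character(0)
      if (!"V" %in% miss) {
        vnt <- drawDFree(function()
          paste0(encodeAA(v_core_aa), encodeAA("AR")))
        nm <- c(nm, paste0("IGNARV", ci)); seqs <- c(seqs, vnt)
        kind <- c(kind, "V"); cluster <- c(cluster, ci)
        anchor <- c(anchor, (ref$anchors[["fr3b_cys"]] - 1L) * 3L + 1L)
      }
      if (!"J" %in% miss) {
        jnt <- drawDFree(function()
          paste0(encodeAA("GSY"), encodeAA(fr4_aa), encodeAA("GSSS")))
        nm <- c(nm, paste0("IGNARJ", ci)); seqs <- c(seqs, jnt)
        kind <- c(kind, "J"); cluster <- c(cluster, ci)
        anchor <- c(anchor, 10L)
      }
    }
    nm <- c(nm, names(DEFAULT_D_SEQS))
    seqs <- c(seqs, unname(DEFAULT_D_SEQS))
    kind <- c(kind, rep("D", length(DEFAULT_D_SEQS)))
    cluster <- c(cluster, rep(NA_integer_, length(DEFAULT_D_SEQS)))
    anchor <- c(anchor, rep(NA_integer_, length(DEFAULT_D_SEQS)))
    for (k in 1:5) {
      nm <- c(nm, paste0("IGNARC", k))
      seqs <- c(seqs, drawDFree(function() randomDNA(g$c_length, g$gc)))
      kind <- c(kind, "C"); cluster <- c(cluster, NA_integer_)
      anchor <- c(anchor, NA_integer_)
    }
    nm <- c(nm, "IGNARSEC", "IGNARTM")
    seqs <- c(seqs, drawDFree(function() randomDNA(g$sec_length, g$gc)),
              drawDFree(function() randomDNA(g$tm_length, g$gc)))
    kind <- c(kind, "Sec", "Tm")
    cluster <- c(cluster, NA_integer_, NA_integer_)
    anchor <- c(anchor, NA_integer_, NA_integer_)
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- nm
    S4Vectors::mcols(dna) <- S4Vectors::DataFrame(kind = kind,
                                                  anchor = anchor)
    list(sequences = dna,
         table = data.frame(segment = nm, kind = kind, cluster = cluster,
                            anchor = anchor, stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic germline genome with planted clusters and RSS
#'
#' Plants the configured IgNAR clusters into a random background contig:
#' each V is followed by a downstream RSS, each J preceded by an upstream
#' RSS, each D flanked by two RSS (except pre-joined D segments, planted
#' without RSS), with heptamer/nonamer mismatch counts exactly as
#' configured. The truth annotation lists every planted feature.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param db optional reference set from
#'   \code{\link{makeGermlineReferences}} (regenerated from the config
#'   when omitted).
#' @param dir optional output directory; writes \code{genome.fasta} and
#'   \code{truth.gff3}.
#' @return list with \code{genome} (DNAStringSet of one contig),
#'   \code{features} (truth GRanges with kind/cluster/segment/rss
#'   metadata) and \code{db}.
#' @export
makeSyntheticGenome <- function(config, db = NULL, dir = NULL) {
  stopifnot(methods::is(config, "SimConfig"))
  g <- config@germline
  stopifnot(g$intersegment_gap > 0L, g$intercluster_gap > 0L)
  if (is.null(db)) db <- makeGermlineReferences(config)
  seqmap <- setNames(as.character(db$sequences), names(db$sequences))

  withSeed(childSeed(config@seed, "genome"), {
    parts <- character(0)
    pos <- 0L
    feat <- list()
    protected <- list()   # positions the background scrub must not touch
    addPart <- function(s) {
      parts[[length(parts) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    addFeature <- function(s, type, kind = NA, cluster = NA, segment = NA,
                           strand = "+", spacer = NA) {
      start <- pos + 1L
      addPart(s)
      if (type == "gene_segment") {
        protected[[length(protected) + 1L]] <<- c(start, pos)
      } else {
        # heptamer and nonamer ends of the RSS block; the spacer may flip
        protected[[length(protected) + 1L]] <<- c(start, start + 8L)
        protected[[length(protected) + 1L]] <<- c(pos - 8L, pos)
      }
      feat[[length(feat) + 1L]] <<- data.frame(
        start = start, end = pos, type = type, kind = kind,
        cluster = cluster, segment = segment, strand = strand,
        spacer = spacer, stringsAsFactors = FALSE)
    }
    rssBlock <- function(spacer) {
      hept <- mutatePositions("CACAGTG", g$rss_heptamer_mm)
      nona <- mutatePositions("ACAAAAACC", g$rss_nonamer_mm)
      paste0(hept, randomDNA(spacer, 0.5), nona)
    }
    plant <- function(name) {
      s <- seqmap[[name]]
      if (g$planted_substitutions > 0L)
        s <- mutatePositions(s, g$planted_substitutions)
      s
    }
    addPart(randomDNA(g$flank_pad, g$gc))
    for (ci in seq_len(g$n_clusters)) {
      cname <- paste0("IgNAR", ci)
      miss <- g$missing[[as.character(ci)]] %||% character(0)
      gap <- function() addPart(randomDNA(g$intersegment_gap, g$gc))
      if (!"V" %in% miss) {
        addFeature(plant(paste0("IGNARV", ci)), "gene_segment", "V",
                   cname, paste0("IGNARV", ci))
        addFeature(rssBlock(g$spacer_v), "recombination_feature",
                   strand = "+", spacer = g$spacer_v, cluster = cname)
        gap()
      }
      if (!"D" %in% miss) {
        for (k in 1:3) {
          dname <- names(DEFAULT_D_SEQS)[k]
          pj <- k == 3L && ci %in% g$prejoined
          if (!pj)
            addFeature(revComp(rssBlock(g$spacer_d5)),
                       "recombination_feature", strand = "-",
                       spacer = g$spacer_d5, cluster = cname)
          addFeature(plant(dname), "gene_segment", "D", cname, dname)
          if (!pj)
            addFeature(rssBlock(g$spacer_d3), "recombination_feature",
                       strand = "+", spacer = g$spacer_d3, cluster = cname)
          gap()
        }
      }
      if (!"J" %in% miss) {
        addFeature(revComp(rssBlock(g$spacer_j)), "recombination_feature",
                   strand = "-", spacer = g$spacer_j, cluster = cname)
        addFeature(plant(paste0("IGNARJ", ci)), "gene_segment", "J",
                   cname, paste0("IGNARJ", ci))
        gap()
      }
      if (!"C" %in% miss) {
        for (k in 1:5) {
          addFeature(plant(paste0("IGNARC", k)), "gene_segment", "C",
                     cname, paste0("IGNARC", k))
          gap()
        }
      }
      if (!"Sec" %in% miss) {
        addFeature(plant("IGNARSEC"), "gene_segment", "Sec", cname,
                   "IGNARSEC")
        gap()
      }
      if (!"Tm" %in% miss)
        addFeature(plant("IGNARTM"), "gene_segment", "Tm", cname,
                   "IGNARTM")
      if (ci < g$n_clusters)
        addPart(randomDNA(g$intercluster_gap, g$gc))
    }
    addPart(randomDNA(g$flank_pad, g$gc))

    contig <- scrubContig(paste(parts, collapse = ""), protected)
    fd <- do.call(rbind, feat)
    gr <- GenomicRanges::GRanges("Chr44_syn",
                                 IRanges::IRanges(fd$start, fd$end),
                                 strand = fd$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      type = fd$type, kind = fd$kind, cluster = fd$cluster,
      segment = fd$segment, spacer = fd$spacer)
    genome <- Biostrings::DNAStringSet(c(Chr44_syn = contig))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      Biostrings::writeXStringSet(genome, file.path(dir, "genome.fasta"))
      writeTruthGFF(gr, file.path(dir, "truth.gff3"))
    }
    list(genome = genome, features = gr, db = db)
  })
}

writeTruthGFF <- function(gr, file) {
  mc <- S4Vectors::mcols(gr)
  lines <- c("##gff-version 3",
    sprintf("%s\tvnarseq_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
            as.character(GenomicRanges::seqnames(gr)),
            ifelse(mc$type == "gene_segment",
                   paste0(mc$kind, "_gene_segment"), mc$type),
            GenomicRanges::start(gr), GenomicRanges::end(gr),
            as.character(GenomicRanges::strand(gr)),
            ifelse(mc$type == "gene_segment",
                   sprintf("ID=%s_%s;cluster=%s", mc$cluster, mc$segment,
                           mc$cluster),
                   sprintf("spacer=%d;cluster=%s", mc$spacer, mc$cluster))))
  writeLines(lines, file)
  invisible(file)
}

rGeomCapped <- function(n, mean, cap) {
  base::pmin(rgeom(n, prob = 1 / (1 + mean)), cap)
}

#' Simulate a V(D)J repertoire read set with ground truth
#'
#' Clones are drawn under a discrete power law over clone ranks
#' (\eqn{p_r \propto r^{-\alpha}}); each clone receives one recombination
#' event (V-J by the configured pair table, uniform D choice, geometric
#' trimming, Poisson N insertions) and a clone-level somatic hypermutation
#' pattern. Reads sample clones with replacement and then acquire per-base
#' sequencing error; qualities are constant Q30. With
#' \code{force_in_frame} (the default, emulating mRNA-derived amplicons)
#' the second N insertion is lengthened by 0-2 nt so the junction preserves
#' the V reading frame.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param nReads number of reads to emit.
#' @param germline optional germline database (defaults to
#'   \code{\link{makeGermlineReferences}(config)}).
#' @param sampleID identifier recorded with the output.
#' @param cloneWeights optional numeric vector overriding the power-law
#'   clone weights (recycled/normalised internally).
#' @param streamSeed optional label mixed into the read-sampling seed so
#'   repeated draws (e.g. time points) share clones but not reads.
#' @return list with \code{reads} (DNAStringSet with
#'   \code{mcols()$quality}), \code{truth} (one row per read: true
#'   V/D/J, CDR3 nt/aa, frame, productivity, SHM and error counts) and
#'   \code{clones} (per-clone truth).
#' @export
simulateRepertoire <- function(config, nReads, germline = NULL,
                               sampleID = "sim1", cloneWeights = NULL,
                               streamSeed = "reads") {
  stopifnot(methods::is(config, "SimConfig"), nReads >= 1L)
  r <- config@repertoire
  db <- if (is.null(germline)) makeGermlineReferences(config) else
    resolveGermline(germline)
  clones <- withSeed(childSeed(config@seed, "clones"),
                     buildClones(config, db))
  nc <- nrow(clones)
  w <- if (is.null(cloneWeights))
    (seq_len(nc))^(-r$clone_exponent) else rep_len(cloneWeights, nc)
  w <- w / sum(w)

  withSeed(childSeed(config@seed, streamSeed), {
    idx <- sample.int(nc, nReads, replace = TRUE, prob = w)
    seqs <- clones$sequence[idx]
    nerr <- integer(nReads)
    if (r$error_rate > 0) {
      for (i in seq_len(nReads)) {
        m <- mutateAtRate(seqs[i], r$error_rate)
        seqs[i] <- m$seq; nerr[i] <- m$n
      }
    }
    if (r$add_primers)
      seqs <- paste0(PRIMER_VNAR_V, seqs, revComp(PRIMER_VNAR_J))
    long <- nchar(seqs) > r$read_length
    seqs[long] <- substr(seqs[long], 1L, r$read_length)
    ids <- sprintf("read%06d", seq_len(nReads))
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- ids
    S4Vectors::mcols(reads)$quality <- strrep("?", nchar(seqs))  # Q30
    truth <- data.frame(
      read_id = ids, clone_id = clones$clone_id[idx],
      v_call = clones$v_call[idx], d_call = clones$d_call[idx],
      d_expected = clones$d_expected[idx], j_call = clones$j_call[idx],
      cdr3_nt = clones$cdr3_nt[idx], cdr3_aa = clones$cdr3_aa[idx],
      in_frame = clones$in_frame[idx], productive = clones$productive[idx],
      n_shm = clones$n_shm[idx], n_err = nerr,
      stringsAsFactors = FALSE)
    list(reads = reads, truth = truth, clones = clones,
         sampleID = sampleID)
  })
}

# one recombination event + SHM pattern per clone
buildClones <- function(config, db) {
  r <- config@repertoire
  tab <- db$table
  seqmap <- setNames(as.character(db$sequences), names(db$sequences))
  pairs <- strsplit(names(r$pair_table), "|", fixed = TRUE)
  vn <- vapply(pairs, `[`, character(1), 1L)
  jn <- vapply(pairs, `[`, character(1), 2L)
  if (!all(c(vn, jn) %in% tab$segment))
    stop("pair_table references segments absent from the germline: ",
         paste(setdiff(c(vn, jn), tab$segment), collapse = ", "))
  dnames <- tab$segment[tab$kind == "D"]
  nc <- r$n_clones
  pair_idx <- sample.int(length(vn), nc, replace = TRUE,
                         prob = r$pair_table)
  o_d <- character(nc); o_dexp <- character(nc); o_dret <- integer(nc)
  o_seq <- character(nc); o_cdr3 <- character(nc); o_cdr3aa <- character(nc)
  o_inf <- logical(nc); o_prod <- logical(nc); o_shm <- integer(nc)
  # per-clone draws, vectorised
  va_all <- tab$anchor[base::match(vn[pair_idx], tab$segment)]
  ja_all <- tab$anchor[base::match(jn[pair_idx], tab$segment)]
  v_trim_all <- rGeomCapped(nc, r$v_trim_mean, r$v_trim_max)
  j_trim_all <- rGeomCapped(nc, r$j_trim_mean, r$j_trim_max)
  use_d_all <- length(dnames) > 0L & runif(nc) < r$d_usage
  d_pick <- if (length(dnames)) sample(dnames, nc, replace = TRUE)
    else rep("none", nc)
  t5_all <- rGeomCapped(nc, r$d_trim_mean, r$d_trim_max)
  t3_all <- rGeomCapped(nc, r$d_trim_mean, r$d_trim_max)
  n1_all <- rpois(nc, r$n_insert_mean)
  n2_all <- rpois(nc, r$n_insert_mean)
  for (i in seq_len(nc)) {
    vseq <- seqmap[[vn[pair_idx[i]]]]
    jseq <- seqmap[[jn[pair_idx[i]]]]
    va <- va_all[i]; ja <- ja_all[i]
    v_trim <- v_trim_all[i]; j_trim <- j_trim_all[i]
    v_keep <- nchar(vseq) - v_trim
    d_name <- "none"; d_sub <- ""
    if (use_d_all[i]) {
      d_name <- d_pick[i]
      dfull <- seqmap[[d_name]]
      d_sub <- substr(dfull, 1L + t5_all[i], nchar(dfull) - t3_all[i])
    }
    n1 <- n1_all[i]; n2 <- n2_all[i]
    if (r$force_in_frame) {
      delta <- (v_keep + n1 + nchar(d_sub) + n2 + (ja - j_trim) - va) %% 3L
      n2 <- n2 + (3L - delta) %% 3L
    }
    ins1 <- if (n1 > 0L)
      base::paste(sample(BASES, n1, TRUE), collapse = "") else ""
    ins2 <- if (n2 > 0L)
      base::paste(sample(BASES, n2, TRUE), collapse = "") else ""
    amp <- base::paste0(substr(vseq, 1L, v_keep), ins1, d_sub, ins2,
                        substr(jseq, 1L + j_trim, nchar(jseq)))
    shm <- mutateAtRate(amp, r$shm_rate)
    amp <- shm$seq
    j_anchor_amp <- v_keep + n1 + nchar(d_sub) + n2 + (ja - j_trim)
    cdr3 <- substr(amp, va + 3L, j_anchor_amp - 1L)
    inframe <- (j_anchor_amp - va) %% 3L == 0L
    cdr3_aa <- if (inframe) translateDNA(cdr3) else ""
    jxn_aa <- if (inframe)
      translateDNA(substr(amp, va, j_anchor_amp + 2L)) else ""
    o_d[i] <- d_name
    o_dexp[i] <- if (nchar(d_sub) >= 6L) d_name else "none"
    o_dret[i] <- nchar(d_sub)
    o_seq[i] <- amp; o_cdr3[i] <- cdr3; o_cdr3aa[i] <- cdr3_aa
    o_inf[i] <- inframe
    o_prod[i] <- inframe && !grepl("\\*", jxn_aa)
    o_shm[i] <- shm$n
  }
  data.frame(
    clone_id = sprintf("clone%05d", seq_len(nc)),
    v_call = vn[pair_idx], d_call = o_d, d_expected = o_dexp,
    j_call = jn[pair_idx], d_retained = o_dret, sequence = o_seq,
    cdr3_nt = o_cdr3, cdr3_aa = o_cdr3aa, in_frame = o_inf,
    productive = o_prod, n_shm = o_shm, stringsAsFactors = FALSE)
}

#' Simulate a repertoire time course with programmed clonal expansion
#'
#' All time points share one clone set; the clones at the given ranks have
#' their sampling weight multiplied by \code{expandFactor} at each
#' successive time point, emulating antigen-driven expansion of initially
#' low-frequency clones under repeated immunisation.
#'
#' @inheritParams simulateRepertoire
#' @param nTimepoints number of time points.
#' @param expandRanks clone ranks (1 = largest) programmed to expand.
#' @param expandFactor per-time-point weight multiplier.
#' @return list of per-time-point results as in
#'   \code{\link{simulateRepertoire}}, plus attribute
#'   \code{"expanded_clones"} naming the programmed clones.
#' @export
simulateTimeCourse <- function(config, nReads, nTimepoints = 2L,
                               expandRanks = 191:200, expandFactor = 8,
                               germline = NULL) {
  stopifnot(nTimepoints >= 2L)
  r <- config@repertoire
  base <- (seq_len(r$n_clones))^(-r$clone_exponent)
  out <- vector("list", nTimepoints)
  for (t in seq_len(nTimepoints)) {
    w <- base
    w[expandRanks] <- w[expandRanks] * expandFactor^(t - 1L)
    out[[t]] <- simulateRepertoire(
      config, nReads, germline = germline,
      sampleID = paste0("tp", t), cloneWeights = w,
      streamSeed = paste0("reads_tp", t))
  }
  names(out) <- paste0("tp", seq_len(nTimepoints))
  attr(out, "expanded_clones") <- sprintf("clone%05d", expandRanks)
  out
}

#' Simulate a vNAR amino-acid library with a configured type mixture
#'
#' Builds full-length vNAR sequences on the region-annotated reference
#' frame: framework positions carry the reference residue with a small
#' substitution rate, CDR1/HV2/CDR3 are randomised (CDR3 length
#' Poisson-shifted), and cysteines/tryptophans are then placed to realise
#' each sequence's drawn type and cysteine count. Random residues never
#' include cysteine or tryptophan, so the planted pattern is the complete
#' pattern. Sequence duplication realises the configured unique fraction
#' exactly: \code{round(unique_fraction * nSeqs)} distinct sequences plus
#' resampled duplicates, shuffled.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param nSeqs number of sequences to emit.
#' @return list with \code{sequences} (AAStringSet) and \code{truth}
#'   (seq_id, type, cysteine count, duplicate source).
#' @export
simulateVnarLibrary <- function(config, nSeqs) {
  stopifnot(methods::is(config, "SimConfig"), nSeqs >= 1L)
  l <- config@library
  ref <- vnarReference()
  rlab <- ref$regions
  tmpl <- strsplit(ref$aa, "")[[1L]]
  AA18 <- setdiff(c("A", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                    "P", "Q", "R", "S", "T", "V", "Y"), character(0))
  anchors <- ref$anchors
  fr_idx <- which(rlab %in% c("FR1", "FR2", "FR3a", "FR3b", "FR4"))
  fr_idx <- setdiff(fr_idx, anchors)
  cdr1_idx <- which(rlab == "CDR1")
  hv2_idx <- which(rlab == "HV2")
  fr2_free <- setdiff(which(rlab == "FR2"), anchors)
  fr4_free <- setdiff(which(rlab == "FR4"), anchors)

  withSeed(childSeed(config@seed, "library"), {
    nUnique <- max(1L, round(l$unique_fraction * nSeqs))
    nUnique <- min(nUnique, nSeqs)
    types <- sample(names(l$type_mixture), nUnique, replace = TRUE,
                    prob = l$type_mixture)
    buildOne <- function(type) {
      body <- tmpl
      sub <- runif(length(fr_idx)) < l$framework_diversity
      body[fr_idx[sub]] <- sample(AA18, sum(sub), replace = TRUE)
      cs <- runif(length(cdr1_idx)) < l$cdr1_diversity
      body[cdr1_idx[cs]] <- sample(AA18, sum(cs), replace = TRUE)
      hs <- runif(length(hv2_idx)) < l$hv2_diversity
      body[hv2_idx[hs]] <- sample(AA18, sum(hs), replace = TRUE)
      clen <- min(l$cdr3_length_max,
                  max(l$cdr3_length_min,
                      l$cdr3_length_offset + rpois(1L, l$cdr3_length_lambda)))
      cdr3 <- sample(AA18, clen, replace = TRUE)
      placeCdr3Cys <- function(k) {
        pos <- sample(length(cdr3), min(k, length(cdr3)))
        cdr3[pos] <<- "C"
      }
      if (type == "I") {
        body[sample(fr2_free, 1L)] <- "C"
        body[sample(fr4_free, 1L)] <- "C"
        placeCdr3Cys(2L)
      } else if (type %in% c("II", "III")) {
        cp <- sample(cdr1_idx, if (type == "III") 2L else 1L)
        body[cp[1L]] <- "C"
        if (type == "III") body[cp[2L]] <- "W"
        k <- if (runif(1L) < l$cys4_given_typeII) 1L else 2L
        placeCdr3Cys(k)
      } else if (type == "new") {
        variant <- sample(3L, 1L)
        if (variant == 1L) {
          body[sample(fr2_free, 1L)] <- "C"
        } else if (variant == 2L) {
          cp <- sample(cdr1_idx, 2L)
          body[cp] <- "C"
          placeCdr3Cys(1L)
        } else {
          body[anchors[["fr1_cys"]]] <- sample(AA18, 1L)
          body[sample(cdr1_idx, 1L)] <- "C"
          placeCdr3Cys(1L)
        }
      }
      paste(c(body[seq_len(max(which(rlab == "FR3b")))], cdr3,
              body[which(rlab == "FR4")]), collapse = "")
    }
    seqs <- vapply(types, buildOne, character(1), USE.NAMES = FALSE)
    # enforce distinctness of the unique pool (collisions are rare)
    for (pass in 1:5) {
      dup <- which(duplicated(seqs))
      if (!length(dup)) break
      seqs[dup] <- vapply(types[dup], buildOne, character(1),
                          USE.NAMES = FALSE)
    }
    nDup <- nSeqs - nUnique
    src <- if (nDup > 0L) sample.int(nUnique, nDup, replace = TRUE)
      else integer(0)
    all_seq <- c(seqs, seqs[src])
    all_type <- c(types, types[src])
    all_src <- c(rep(NA_integer_, nUnique), src)
    ord <- sample.int(length(all_seq))
    ids <- sprintf("lib%06d", seq_along(all_seq))
    aa <- Biostrings::AAStringSet(all_seq[ord])
    names(aa) <- ids
    truth <- data.frame(
      seq_id = ids, type = all_type[ord],
      cysteine_count = vapply(strsplit(all_seq[ord], ""), function(x)
        sum(x == "C"), integer(1)),
      duplicate_of = ifelse(is.na(all_src[ord]), NA_character_,
                            sprintf("u%06d", all_src[ord])),
      stringsAsFactors = FALSE)
    list(sequences = aa, truth = truth)
  })
}
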