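suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
})

HEPT <- "CACAGTG"
NONA <- "ACAAAAACC"

# brute-force RSS oracle: evaluate every window on both strands by direct
# Hamming distance, independently of the package scanner
oracleRSS <- function(genome, heptamer = HEPT, nonamer = NONA,
                      spacers = c(12L, 22L, 23L), hb = 2L, nb = 3L) {
  if (is.null(names(genome)))
    names(genome) <- paste0("contig", seq_along(genome))
  hamming <- function(chars, motif) {
    # mismatch counts of `motif` at every start position of chars
    k <- length(motif)
    L <- length(chars)
    if (L < k) return(integer(0))
    mm <- integer(L - k + 1L)
    ok <- chars %in% c("A", "C", "G", "T", "N")
    for (p in seq_len(k)) {
      seg <- chars[p:(L - k + p)]
      mm <- mm + as.integer(seg != motif[p] | seg == "N")
      mm[!ok[p:(L - k + p)]] <- NA_integer_   # invalid character
    }
    mm
  }
  hm_motif <- strsplit(heptamer, "")[[1L]]
  nm_motif <- strsplit(nonamer, "")[[1L]]
  rows <- list()
  for (ci in seq_along(genome)) {
    L <- nchar(as.character(genome[[ci]]))
    for (strand in c("+", "-")) {
      s <- if (strand == "+") as.character(genome[[ci]]) else
        as.character(reverseComplement(genome[[ci]]))
      chars <- strsplit(s, "")[[1L]]
      hmm <- hamming(chars, hm_motif)
      nmm <- hamming(chars, nm_motif)
      for (sp in spacers) {
        w <- 16L + sp
        imax <- L - w + 1L
        if (imax < 1L) next
        i <- seq_len(imax)
        h <- hmm[i]
        n <- nmm[i + 7L + sp]
        hit <- !is.na(h) & !is.na(n) & h <= hb & n <= nb
        if (!any(hit)) next
        i <- i[hit]
        start <- if (strand == "+") i else L - (i + w - 1L) + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          contig = names(genome)[ci], start = start, strand = strand,
          spacer = sp, hmm = h[hit], nmm = n[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(contig = character(0), start = integer(0),
                      strand = character(0), spacer = integer(0),
                      hmm = integer(0), nmm = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start, out$strand, out$spacer), ]
  rownames(out) <- NULL
  out
}

rssHitsAsDF <- function(gr) {
  if (length(gr) == 0L)
    return(data.frame(contig = character(0), start = integer(0),
                      strand = character(0), spacer = integer(0),
                      hmm = integer(0), nmm = integer(0)))
  out <- data.frame(
    contig = as.character(seqnames(gr)), start = start(gr),
    strand = as.character(strand(gr)),
    spacer = mcols(gr)$spacer_length,
    hmm = mcols(gr)$heptamer_mismatches,
    nmm = mcols(gr)$nonamer_mismatches,
    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start, out$strand, out$spacer), ]
  rownames(out) <- NULL
  out
}

# mutate k positions of a DNA string deterministically given a seed
mutateAt <- function(seq, pos) {
  flip <- c(A = "C", C = "G", G = "T", T = "A")
  ch <- strsplit(seq, "")[[1L]]
  for (p in pos) ch[p] <- flip[[ch[p]]]
  paste(ch, collapse = "")
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# cached single-cluster germline database used across annotation tests
tinyGermline <- local({
  db <- NULL
  function() {
    if (is.null(db)) {
      cfg <- simConfig(seed = 101L,
                       germline = list(n_clusters = 1L, missing = list(),
                                       prejoined = integer(0)))
      db <<- makeGermlineReferences(cfg)
    }
    db
  }
})

# read built from germline parts: full V + junction + J (optionally trimmed)
buildRead <- function(db, v = "IGNARV1", j = "IGNARJ1", junction = "",
                      jTrim = 0L) {
  vs <- as.character(db$sequences[[v]])
  js <- as.character(db$sequences[[j]])
  paste0(vs, junction, substr(js, 1L + jTrim, nchar(js)))
}

asReads <- function(seqs, ids = NULL) {
  x <- DNAStringSet(seqs)
  names(x) <- ids %||% paste0("r", seq_along(seqs))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standard deviation of the read-level dominant-pair share estimator under
# the simulator's two-stage design (clone draw + read multinomial)
pairShareSD <- function(p, nClones, alpha, nReads) {
  w <- (seq_len(nClones))^(-alpha)
  w <- w / sum(w)
  sqrt(p * (1 - p) * (sum(w^2) + 1 / nReads))
}
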