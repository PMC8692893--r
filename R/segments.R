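#' Locate germline gene segments by similarity search
#'
#' Seed-and-extend similarity search of labelled reference segment sequences
#' (V/D/J/C/Sec/Tm) against both strands of a genome, scored with affine-gap
#' Smith-Waterman local alignment (defaults: match 2, mismatch -3, gap open
#' -5, gap extend -2). Exact seed words anchor candidate windows; each window
#' is then aligned in full. References too short for seeding (below
#' \code{2 * seedLength}) are matched directly with at most one mismatch;
#' references shorter than \code{minRefLength} are skipped with a warning.
#'
#' Overlapping hits of the same kind are collapsed to the highest-identity
#' one (ties: leftmost start, then plus strand). When a set of RSS hits is
#' supplied, each segment is annotated with the nearest compatible RSS
#' within \code{flank} bp: downstream for V, upstream for J, both for D.
#'
#' @param genome DNAStringSet (or FASTA path) to search.
#' @param references named \link[Biostrings]{DNAStringSet} of reference
#'   segments. The segment kind is taken from \code{mcols(references)$kind}
#'   when present, otherwise parsed from the leading letters of each name
#'   (\code{V}, \code{D}, \code{J}, \code{C}, \code{Sec}, \code{Tm}).
#'   An integer \code{mcols(references)$anchor} (CDR3 anchor codon start,
#'   1-based within the reference) is propagated to hits that cover it.
#' @param minIdentity minimum alignment identity (matches / alignment
#'   columns) for a hit to be retained.
#' @param rss optional GRanges from \code{\link{findRSS}} used to annotate
#'   flanking RSS evidence.
#' @param flank window in bp within which a flanking RSS is associated.
#' @param seedLength exact seed word length for the search.
#' @param minRefLength references shorter than this are skipped.
#' @return GRanges of segments with metadata columns \code{kind},
#'   \code{reference}, \code{identity}, \code{seq}, \code{anchor},
#'   \code{rss_up}, \code{rss_down} (spacer lengths or NA).
#' @export
scanSegments <- function(genome, references, minIdentity = 0.7,
                         rss = NULL, flank = 40L, seedLength = 12L,
                         minRefLength = 8L) {
  genome <- asDNAStringSet(genome)
  stopifnot(minIdentity > 0, minIdentity <= 1)
  if (is.null(names(genome)))
    names(genome) <- paste0("contig", seq_along(genome))
  kinds <- referenceKinds(references)
  anchors <- S4Vectors::mcols(references)$anchor
  if (is.null(anchors)) anchors <- rep(NA_integer_, length(references))

  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -3, baseOnly = FALSE)
  hits <- list()
  for (ri in seq_along(references)) {
    ref <- references[[ri]]
    w <- length(ref)
    if (w < minRefLength) {
      warning("reference ", names(references)[ri],
              " shorter than ", minRefLength, " nt: skipped")
      next
    }
    for (ci in seq_along(genome)) {
      L <- Biostrings::width(genome)[ci]
      for (str in c("+", "-")) {
        subject <- if (str == "+") genome[[ci]] else
          Biostrings::reverseComplement(genome[[ci]])
        found <- if (w < 2L * seedLength)
          shortRefHits(ref, subject, minIdentity)
        else
          seedExtendHits(ref, subject, submat, minIdentity, seedLength)
        if (is.null(found) || !nrow(found)) next
        # map scanned-strand coordinates back to forward coordinates
        if (str == "-") {
          s <- L - found$end + 1L
          e <- L - found$start + 1L
          found$start <- s; found$end <- e
        }
        found$contig <- names(genome)[ci]
        found$strand <- str
        found$kind <- kinds[ri]
        found$reference <- names(references)[ri]
        found$anchor <- ifelse(
          !is.na(anchors[ri]) & found$ref_start <= anchors[ri] &
            found$ref_end >= anchors[ri] + 2L,
          anchors[ri] - found$ref_start + 1L, NA_integer_)
        hits[[length(hits) + 1L]] <- found
      }
    }
  }
  if (!length(hits)) return(emptySegments())
  df <- do.call(rbind, hits)
  df <- collapseSameKind(df)
  gr <- GenomicRanges::GRanges(
    df$contig, IRanges::IRanges(df$start, df$end), strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    kind = df$kind, reference = df$reference, identity = df$identity,
    seq = df$seq, anchor = df$anchor)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))]
  annotateFlankingRSS(gr, rss, flank)
}

referenceKinds <- function(references) {
  k <- S4Vectors::mcols(references)$kind
  if (!is.null(k)) return(normalizeKind(k))
  nm <- sub("^IGNAR", "", names(references))   # locus-prefixed names
  m <- regmatches(nm, regexpr("^(SEC|TM|Sec|Tm|V|D|J|C)", nm,
                              ignore.case = TRUE))
  if (length(m) != length(references))
    stop("cannot parse segment kind from reference names; ",
         "provide mcols(references)$kind")
  normalizeKind(m)
}

normalizeKind <- function(k) {
  k <- toupper(k)
  k[k == "SEC"] <- "Sec"
  k[k == "TM"] <- "Tm"
  stopifnot(all(k %in% c("V", "D", "J", "C", "Sec", "Tm")))
  k
}

# direct (near-)exact matching for short references such as 9-bp D segments
shortRefHits <- function(ref, subject, minIdentity) {
  w <- length(ref)
  mm_allowed <- 1L
  m <- Biostrings::matchPattern(ref, subject, max.mismatch = mm_allowed)
  if (!length(m)) return(NULL)
  mm <- Biostrings::neditStartingAt(ref, subject, starting.at = BiocGenerics::start(m))
  identity <- 1 - mm / w
  keep <- identity >= minIdentity
  if (!any(keep)) return(NULL)
  data.frame(start = BiocGenerics::start(m)[keep],
             end = BiocGenerics::end(m)[keep],
             identity = identity[keep],
             seq = as.character(m)[keep],
             ref_start = 1L, ref_end = w,
             stringsAsFactors = FALSE)
}

# seed-and-extend: exact seed words locate candidate windows, each window is
# refined with a local affine-gap alignment of the full reference
seedExtendHits <- function(ref, subject, submat, minIdentity, seedLength) {
  w <- length(ref)
  L <- length(subject)
  starts <- seq(1L, w - seedLength + 1L, by = max(4L, seedLength %/% 2L))
  implied <- integer(0)
  for (o in starts) {
    seed <- Biostrings::subseq(ref, o, o + seedLength - 1L)
    m <- Biostrings::matchPattern(seed, subject)
    if (length(m))
      implied <- c(implied, BiocGenerics::start(m) - o + 1L)
  }
  if (!length(implied)) return(NULL)
  slack <- 20L + as.integer(0.1 * w)
  win <- IRanges::reduce(IRanges::IRanges(
    start = pmax(1L, implied - slack),
    end = pmin(L, implied + w - 1L + slack)))
  out <- list()
  for (k in seq_along(win)) {
    ws <- BiocGenerics::start(win)[k]
    sub <- Biostrings::subseq(subject, ws, BiocGenerics::end(win)[k])
    pa <- Biostrings::pairwiseAlignment(
      ref, sub, type = "local", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)
    alen <- Biostrings::nchar(pa)
    if (alen == 0L) next
    identity <- Biostrings::nmatch(pa) / alen
    cover <- (Biostrings::width(Biostrings::pattern(pa))) / w
    if (identity < minIdentity || cover < 0.5) next
    sr <- Biostrings::subject(pa)
    gs <- ws + BiocGenerics::start(sr@range) - 1L
    ge <- ws + BiocGenerics::end(sr@range) - 1L
    pr <- Biostrings::pattern(pa)@range
    out[[length(out) + 1L]] <- data.frame(
      start = gs, end = ge, identity = identity,
      seq = as.character(Biostrings::subseq(subject, gs, ge)),
      ref_start = BiocGenerics::start(pr), ref_end = BiocGenerics::end(pr),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# overlapping hits of the same kind collapse to the best one
collapseSameKind <- function(df) {
  df <- df[order(df$kind, -df$identity, df$start,
                 ifelse(df$strand == "+", 0L, 1L)), ]
  keep <- rep(TRUE, nrow(df))
  for (kind in unique(df$kind)) {
    idx <- which(df$kind == kind)
    taken <- list()
    for (i in idx) {
      ok <- TRUE
      for (t in taken) {
        if (df$contig[i] == df$contig[t] &&
            df$start[i] <= df$end[t] && df$end[i] >= df$start[t]) {
          ok <- FALSE; break
        }
      }
      if (ok) taken[[length(taken) + 1L]] <- i else keep[i] <- FALSE
    }
  }
  df[keep, , drop = FALSE]
}

annotateFlankingRSS <- function(gr, rss, flank) {
  n <- length(gr)
  up <- rep(NA_integer_, n)
  down <- rep(NA_integer_, n)
  if (!is.null(rss) && length(rss) && n) {
    rdf <- data.frame(
      contig = as.character(GenomicRanges::seqnames(rss)),
      start = GenomicRanges::start(rss), end = GenomicRanges::end(rss),
      strand = as.character(GenomicRanges::strand(rss)),
      spacer = S4Vectors::mcols(rss)$spacer_length)
    for (i in seq_len(n)) {
      kind <- S4Vectors::mcols(gr)$kind[i]
      if (!kind %in% c("V", "D", "J")) next
      ctg <- as.character(GenomicRanges::seqnames(gr))[i]
      s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
      pos <- as.character(GenomicRanges::strand(gr))[i] != "-"
      # in segment orientation: downstream RSS reads heptamer-first on the
      # segment strand; upstream RSS appears on the opposite strand
      dn <- rdf[rdf$contig == ctg &
                  (if (pos) rdf$strand == "+" & rdf$start > e &
                     rdf$start <= e + flank
                   else rdf$strand == "-" & rdf$end < s &
                     rdf$end >= s - flank), , drop = FALSE]
      upx <- rdf[rdf$contig == ctg &
                   (if (pos) rdf$strand == "-" & rdf$end < s &
                      rdf$end >= s - flank
                    else rdf$strand == "+" & rdf$start > e &
                      rdf$start <= e + flank), , drop = FALSE]
      if (kind %in% c("V", "D") && nrow(dn)) {
        ord <- if (pos) order(dn$start) else order(-dn$end)
        down[i] <- dn$spacer[ord[1L]]
      }
      if (kind %in% c("J", "D") && nrow(upx)) {
        ord <- if (pos) order(-upx$end) else order(upx$start)
        up[i] <- upx$spacer[ord[1L]]
      }
    }
  }
  S4Vectors::mcols(gr)$rss_up <- up
  S4Vectors::mcols(gr)$rss_down <- down
  gr
}

emptySegments <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    kind = character(0), reference = character(0), identity = numeric(0),
    seq = character(0), anchor = integer(0), rss_up = integer(0),
    rss_down = integer(0))
  gr
}
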