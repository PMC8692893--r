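#' Default RSS motif set
#'
#' The canonical recombination-signal-sequence motif: heptamer
#' \code{CACAGTG} and nonamer \code{ACAAAAACC}. Shark IgNAR loci carry
#' motif variants; additional rows (one heptamer/nonamer pair each) can be
#' appended to extend the scan.
#'
#' @return data.frame with columns \code{heptamer} (7 nt) and
#'   \code{nonamer} (9 nt).
#' @export
#' @examples
#' defaultRSSMotifs()
defaultRSSMotifs <- function() {
  data.frame(heptamer = "CACAGTG", nonamer = "ACAAAAACC",
             stringsAsFactors = FALSE)
}

#' Scan a genome for recombination signal sequences
#'
#' Finds every window, on both strands, where a heptamer within
#' \code{heptamerBudget} mismatches is separated by an allowed spacer length
#' from a nonamer within \code{nonamerBudget} mismatches. \code{N} bases (and
#' any non-ACGTN character, which invalidates the window) count as
#' mismatches, never as wildcards. The scan is exactly equivalent to an
#' exhaustive Hamming-distance evaluation of all windows.
#'
#' A hit spans the full heptamer--spacer--nonamer window
#' (width \code{7 + spacer + 9}). Minus-strand hits correspond to RSS in the
#' opposite orientation (e.g. the upstream RSS of a plus-strand J segment).
#'
#' @param genome \link[Biostrings]{DNAStringSet} (or single DNAString /
#'   character) of contigs, or path to a FASTA file.
#' @param motifs data.frame of heptamer/nonamer pairs, see
#'   \code{\link{defaultRSSMotifs}}.
#' @param spacers allowed spacer lengths in bp; shark IgNAR clusters use
#'   12, 22 and 23 bp spacers.
#' @param heptamerBudget,nonamerBudget maximum number of mismatches allowed
#'   against the heptamer (default 2) and the nonamer (default 3).
#' @return \link[GenomicRanges]{GRanges}, sorted by (contig, start), with
#'   metadata columns \code{spacer_length}, \code{heptamer_mismatches},
#'   \code{nonamer_mismatches} and \code{motif}. Duplicate
#'   (contig, start, strand, spacer) windows matched by several motifs keep
#'   the lowest-mismatch motif.
#' @export
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = paste0(
#'   "AAAA", "CACAGTG", strrep("T", 12), "ACAAAAACC", "AAAA")))
#' findRSS(g)
findRSS <- function(genome, motifs = defaultRSSMotifs(),
                    spacers = c(12L, 22L, 23L),
                    heptamerBudget = 2L, nonamerBudget = 3L) {
  genome <- asDNAStringSet(genome)
  stopifnot(heptamerBudget >= 0L, nonamerBudget >= 0L, length(spacers) >= 1L)
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L) {
    warning("empty genome: no RSS scan performed")
    return(emptyRSSHits())
  }
  if (is.null(names(genome)))
    names(genome) <- paste0("contig", seq_along(genome))
  spacers <- sort(unique(as.integer(spacers)))

  res <- list()
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    fwd <- as.character(genome[[ci]])
    L <- nchar(fwd)
    rev <- revComp(fwd)
    for (mi in seq_len(nrow(motifs))) {
      hept <- toupper(motifs$heptamer[mi])
      nona <- toupper(motifs$nonamer[mi])
      stopifnot(nchar(hept) == 7L, nchar(nona) == 9L)
      for (strand in c("+", "-")) {
        subject <- if (strand == "+") fwd else rev
        hits <- .cpp_rss_scan(subject, hept, nona, spacers,
                              heptamerBudget, nonamerBudget)
        if (!nrow(hits)) next
        w <- 16L + hits$spacer
        start <- if (strand == "+") hits$start else L - (hits$start + w - 1L) + 1L
        res[[length(res) + 1L]] <- data.frame(
          contig = contig, start = start, width = w, strand = strand,
          spacer_length = hits$spacer,
          heptamer_mismatches = hits$heptamer_mm,
          nonamer_mismatches = hits$nonamer_mm,
          motif = mi, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(emptyRSSHits())
  df <- do.call(rbind, res)
  # deduplicate (contig, start, strand, spacer): keep lowest total mismatch
  key <- paste(df$contig, df$start, df$strand, df$spacer_length)
  df <- df[order(key, df$heptamer_mismatches + df$nonamer_mismatches,
                 df$motif), ]
  df <- df[!duplicated(paste(df$contig, df$start, df$strand,
                             df$spacer_length)), ]
  df <- df[order(df$contig, df$start, df$strand, df$spacer_length), ]
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start, width = df$width),
    strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    spacer_length = df$spacer_length,
    heptamer_mismatches = df$heptamer_mismatches,
    nonamer_mismatches = df$nonamer_mismatches,
    motif = df$motif)
  gr
}

emptyRSSHits <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    spacer_length = integer(0), heptamer_mismatches = integer(0),
    nonamer_mismatches = integer(0), motif = integer(0))
  gr
}

# coerce character / DNAString / file path to a DNAStringSet
asDNAStringSet <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (methods::is(x, "DNAString"))
    return(Biostrings::DNAStringSet(list(x)))
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  if (is.character(x)) return(Biostrings::DNAStringSet(x))
  stop("cannot interpret input as DNA sequences")
}
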