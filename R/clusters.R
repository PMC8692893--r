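COMPLETE_COMPOSITION <- c(V = 1L, D = 3L, J = 1L, C = 5L, Sec = 1L, Tm = 1L)
KIND_ORDER <- c("V", "D", "J", "C", "Sec", "Tm")

#' Assemble located segments into IgNAR clusters
#'
#' Groups coordinate-sorted segments on the same contig and strand into
#' clusters whenever successive gaps are at most \code{maxGap} bp (shark
#' IgNAR clusters are spatially distant within their chromosome region, so
#' a generous per-cluster gap still separates clusters cleanly). Clusters
#' are named \code{IgNAR1, IgNAR2, ...} in genomic order and classified as
#' \emph{complete} when they contain exactly one V, three D, one J, five C,
#' one Sec and one Tm segment, non-overlapping and in genomic order.
#'
#' A D segment without any flanking RSS evidence is flagged as pre-joined
#' (germline-fused), provided RSS annotation was available in the input.
#'
#' Because a 9-bp D segment carries too little sequence information to be
#' uniquely mappable on its own, a D hit without RSS evidence is retained
#' only within \code{dContext} bp of a non-D segment on the same contig and
#' strand (the cluster context in which pre-joined D segments occur); RSS
#' annotation must have been performed for this filtration to apply.
#'
#' @param segments GRanges from \code{\link{scanSegments}}.
#' @param maxGap maximum gap in bp between successive segments of one
#'   cluster (default 50 kb).
#' @param dContext context window for RSS-less D hits (default 2 kb).
#' @return an \code{\linkS4class{IgNARClusterSet}}.
#' @export
assembleClusters <- function(segments, maxGap = 50000L, dContext = 2000L) {
  if (length(segments) == 0L) {
    return(methods::new("IgNARClusterSet",
      segments = emptyClusterSegments(),
      clusters = S4Vectors::DataFrame(name = character(0),
                                      completeness = character(0)),
      sequences = Biostrings::DNAStringSet()))
  }
  mc <- S4Vectors::mcols(segments)
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(segments)),
    start = GenomicRanges::start(segments),
    end = GenomicRanges::end(segments),
    strand = as.character(GenomicRanges::strand(segments)),
    kind = mc$kind, identity = mc$identity,
    seq = if (!is.null(mc$seq)) mc$seq else NA_character_,
    anchor = if (!is.null(mc$anchor)) mc$anchor else NA_integer_,
    rss_up = if (!is.null(mc$rss_up)) mc$rss_up else NA_integer_,
    rss_down = if (!is.null(mc$rss_down)) mc$rss_down else NA_integer_,
    has_rss_info = !is.null(mc$rss_up),
    stringsAsFactors = FALSE)
  df <- df[order(df$contig, df$start), ]
  # unsupported short-D filtration (see above)
  if (any(df$has_rss_info)) {
    isD <- df$kind == "D"
    unsupported <- isD & is.na(df$rss_up) & is.na(df$rss_down)
    if (any(unsupported)) {
      keep <- !unsupported
      for (i in which(unsupported)) {
        near <- !isD & df$contig == df$contig[i] &
          df$strand == df$strand[i] &
          pmax(df$start, df$start[i]) - pmin(df$end, df$end[i]) <= dContext
        if (any(near)) keep[i] <- TRUE
      }
      df <- df[keep, , drop = FALSE]
      if (!nrow(df)) return(assembleClusters(emptyClusterSegments()))
    }
  }
  # gap-grouping within each contig x strand, clusters named in genomic order
  skey <- paste(df$contig, df$strand)
  grp <- integer(nrow(df))
  g <- 0L
  for (sk in unique(skey)) {
    idx <- which(skey == sk)
    g <- g + 1L
    grp_end <- df$end[idx[1L]]
    grp[idx[1L]] <- g
    for (i in idx[-1L]) {
      if (df$start[i] - grp_end - 1L > maxGap) {
        g <- g + 1L
        grp_end <- df$end[i]
      } else {
        grp_end <- max(grp_end, df$end[i])
      }
      grp[i] <- g
    }
  }
  # rows are sorted by (contig, start), so first-occurrence order of the
  # group ids is genomic order
  cluster_rank <- match(grp, unique(grp))

  clusters <- list(); seg_rows <- list()
  for (idx in sort(unique(cluster_rank))) {
    sub <- df[cluster_rank == idx, , drop = FALSE]
    cname <- paste0("IgNAR", idx)
    sub <- nameClusterSegments(sub, idx)
    sub$cluster <- cname
    sub$prejoined <- ifelse(sub$kind == "D",
      ifelse(sub$has_rss_info, is.na(sub$rss_up) & is.na(sub$rss_down), NA),
      FALSE)
    clusters[[idx]] <- data.frame(
      name = cname, contig = sub$contig[1L],
      start = min(sub$start), end = max(sub$end),
      strand = sub$strand[1L], n_segments = nrow(sub),
      completeness = classifyCompleteness(sub),
      stringsAsFactors = FALSE)
    seg_rows[[idx]] <- sub
  }
  allseg <- do.call(rbind, seg_rows)
  ctab <- do.call(rbind, clusters)

  gr <- GenomicRanges::GRanges(
    allseg$contig, IRanges::IRanges(allseg$start, allseg$end),
    strand = allseg$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    kind = allseg$kind, identity = allseg$identity,
    cluster = allseg$cluster, segment = allseg$segment,
    prejoined = allseg$prejoined, rss_up = allseg$rss_up,
    rss_down = allseg$rss_down, anchor = allseg$anchor, seq = allseg$seq)
  seqs <- if (all(!is.na(allseg$seq))) {
    s <- Biostrings::DNAStringSet(allseg$seq)
    names(s) <- allseg$segment
    s
  } else Biostrings::DNAStringSet()
  methods::new("IgNARClusterSet", segments = gr,
               clusters = S4Vectors::DataFrame(ctab),
               sequences = seqs)
}

# per-cluster segment names following the locus convention: IGNARV1,
# IGNARJ1, IGNARD1-2, IGNARC1-5, IGNARSEC1, IGNARTM1
nameClusterSegments <- function(sub, clusterIdx) {
  nm <- character(nrow(sub))
  for (kind in unique(sub$kind)) {
    idx <- which(sub$kind == kind)
    base <- paste0("IGNAR", toupper(kind), clusterIdx)
    nm[idx] <- if (length(idx) == 1L && kind %in% c("V", "J", "Sec", "Tm"))
      base else paste0(base, "-", seq_along(idx))
  }
  sub$segment <- nm
  sub
}

classifyCompleteness <- function(sub) {
  counts <- table(factor(sub$kind, levels = KIND_ORDER))
  if (!all(as.integer(counts) == COMPLETE_COMPOSITION[KIND_ORDER]))
    return("incomplete")
  # genomic order of kinds, read along the segment strand
  ord <- order(sub$start)
  if (sub$strand[1L] == "-") ord <- rev(ord)
  ranks <- match(sub$kind[ord], KIND_ORDER)
  if (is.unsorted(ranks)) return("incomplete")
  # no overlapping segments
  s <- sort(sub$start); e <- sub$end[order(sub$start)]
  if (any(s[-1L] <= e[-length(e)])) return("incomplete")
  "complete"
}

emptyClusterSegments <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    kind = character(0), identity = numeric(0), cluster = character(0),
    segment = character(0), prejoined = logical(0), rss_up = integer(0),
    rss_down = integer(0), anchor = integer(0), seq = character(0))
  gr
}

#' Export a germline reference database
#'
#' Writes one FASTA record per segment (named as in the locus convention,
#' e.g. \code{IGNARV1}, \code{IGNARJ1}) plus a segment table TSV carrying
#' coordinates, strand, identity, RSS evidence, CDR3 anchor positions and
#' cluster completeness. The pair of files round-trips losslessly through
#' \code{\link{importGermline}} / \code{\link{readGermlineDb}}.
#'
#' @param x an \code{\linkS4class{IgNARClusterSet}} with sequences.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written file paths.
#' @export
exportGermline <- function(x, dir) {
  stopifnot(methods::is(x, "IgNARClusterSet"))
  if (nrow(x@clusters) == 0L) stop("no clusters to export")
  if (length(x@sequences) == 0L) stop("cluster set carries no sequences")
  if (anyDuplicated(names(x@sequences)))
    stop("duplicate segment names: ",
         paste(unique(names(x@sequences)[duplicated(names(x@sequences))]),
               collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "germline.fasta")
  tsv <- file.path(dir, "segments.tsv")
  Biostrings::writeXStringSet(x@sequences, fa)
  mc <- S4Vectors::mcols(x@segments)
  ctab <- as.data.frame(x@clusters)
  df <- data.frame(
    segment = mc$segment, cluster = mc$cluster, kind = mc$kind,
    contig = as.character(GenomicRanges::seqnames(x@segments)),
    start = GenomicRanges::start(x@segments),
    end = GenomicRanges::end(x@segments),
    strand = as.character(GenomicRanges::strand(x@segments)),
    identity = mc$identity, prejoined = mc$prejoined,
    rss_up = mc$rss_up, rss_down = mc$rss_down, anchor = mc$anchor,
    completeness = ctab$completeness[match(mc$cluster, ctab$name)],
    stringsAsFactors = FALSE)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fa, table = tsv))
}

#' Read a germline database directory
#'
#' @param dir directory written by \code{\link{exportGermline}}.
#' @return \code{readGermlineDb}: a list with elements \code{sequences}
#'   (named DNAStringSet) and \code{table} (data.frame, one row per
#'   segment).
#' @export
readGermlineDb <- function(dir) {
  fa <- file.path(dir, "germline.fasta")
  tsv <- file.path(dir, "segments.tsv")
  if (!file.exists(fa) || !file.exists(tsv))
    stop("not a germline database directory: ", dir)
  seqs <- Biostrings::readDNAStringSet(fa)
  tab <- read.delim(tsv, stringsAsFactors = FALSE)
  tab$prejoined <- as.logical(tab$prejoined)
  for (col in c("rss_up", "rss_down", "anchor"))
    tab[[col]] <- as.integer(tab[[col]])
  tab$identity <- as.numeric(tab$identity)
  seqs <- seqs[tab$segment]
  list(sequences = seqs, table = tab)
}

#' @describeIn readGermlineDb reconstruct the full
#'   \code{\linkS4class{IgNARClusterSet}} object.
#' @export
importGermline <- function(dir) {
  db <- readGermlineDb(dir)
  tab <- db$table
  gr <- GenomicRanges::GRanges(
    tab$contig, IRanges::IRanges(tab$start, tab$end), strand = tab$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    kind = tab$kind, identity = tab$identity, cluster = tab$cluster,
    segment = tab$segment, prejoined = tab$prejoined,
    rss_up = tab$rss_up, rss_down = tab$rss_down, anchor = tab$anchor,
    seq = as.character(db$sequences))
  agg <- do.call(rbind, lapply(split(tab, tab$cluster), function(s) {
    data.frame(name = s$cluster[1L], contig = s$contig[1L],
               start = min(s$start), end = max(s$end),
               strand = s$strand[1L], n_segments = nrow(s),
               completeness = s$completeness[1L], stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$contig, agg$start), ]
  rownames(agg) <- NULL
  methods::new("IgNARClusterSet", segments = gr,
               clusters = S4Vectors::DataFrame(agg), sequences = db$sequences)
}

#' Export segments and RSS hits as GFF3
#'
#' Gene segments are written with their kind as feature type and RSS hits
#' as \code{recombination_feature} records, 1-based coordinates as GFF3
#' requires.
#'
#' @param x an \code{\linkS4class{IgNARClusterSet}}.
#' @param file output GFF3 path.
#' @param rss optional GRanges of RSS hits from \code{\link{findRSS}}.
#' @return invisibly, \code{file}.
#' @export
exportSegmentsGFF <- function(x, file, rss = NULL) {
  mc <- S4Vectors::mcols(x@segments)
  lines <- c("##gff-version 3",
    sprintf("%s\tvnarseq\t%s\t%d\t%d\t.\t%s\t.\tID=%s;cluster=%s;identity=%.4f",
            as.character(GenomicRanges::seqnames(x@segments)),
            paste0(mc$kind, "_gene_segment"),
            GenomicRanges::start(x@segments),
            GenomicRanges::end(x@segments),
            as.character(GenomicRanges::strand(x@segments)),
            mc$segment, mc$cluster, mc$identity))
  if (!is.null(rss) && length(rss)) {
    rmc <- S4Vectors::mcols(rss)
    lines <- c(lines,
      sprintf("%s\tvnarseq\trecombination_feature\t%d\t%d\t.\t%s\t.\tspacer=%d;heptamer_mm=%d;nonamer_mm=%d",
              as.character(GenomicRanges::seqnames(rss)),
              GenomicRanges::start(rss), GenomicRanges::end(rss),
              as.character(GenomicRanges::strand(rss)),
              rmc$spacer_length, rmc$heptamer_mismatches,
              rmc$nonamer_mismatches))
  }
  writeLines(lines, file)
  invisible(file)
}
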