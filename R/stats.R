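# accept a RepertoireSample, a clonotype table (data.frame with count),
# or a bare numeric count vector
asCounts <- function(x, productiveOnly = TRUE) {
  if (methods::is(x, "RepertoireSample"))
    x <- clonotypeCounts(x, productiveOnly = productiveOnly)
  if (is.data.frame(x)) {
    stopifnot("count" %in% colnames(x))
    counts <- x$count
    names(counts) <- if ("clonotype" %in% colnames(x)) x$clonotype
      else as.character(seq_along(counts))
    return(counts)
  }
  if (is.numeric(x)) {
    if (is.null(names(x))) names(x) <- as.character(seq_along(x))
    return(x)
  }
  stop("cannot interpret input as clonotype counts")
}

#' Shannon-Wiener diversity of a clonotype table
#'
#' \eqn{H = -\sum_i p_i \ln p_i} in nats over unique clonotypes, the
#' standard diversity measure for CDR3 amino-acid repertoires. \code{H} is 0
#' for a single clonotype and \eqn{\ln k} for \eqn{k} uniform clonotypes.
#'
#' @param x a \code{\linkS4class{RepertoireSample}}, a clonotype table from
#'   \code{\link{clonotypeCounts}}, or a numeric count vector.
#' @param productiveOnly when \code{x} is a sample, count only productive
#'   rearrangements (the default used throughout the package).
#' @return named numeric: \code{shannon} (nats) and \code{evenness}
#'   (Pielou's \eqn{H / \ln k}; \code{NA} for a single clonotype).
#' @export
#' @examples
#' shannonIndex(c(a = 5, b = 3, c = 2))
shannonIndex <- function(x, productiveOnly = TRUE) {
  counts <- asCounts(x, productiveOnly)
  if (!length(counts) || sum(counts) <= 0) stop("empty sample")
  p <- counts / sum(counts)
  p <- p[p > 0]
  h <- -sum(p * log(p))
  k <- length(p)
  c(shannon = h, evenness = if (k > 1L) h / log(k) else NA_real_)
}

#' Wu-Kabat positional variability of aligned amino-acid sequences
#'
#' Per alignment column, variability = (number of distinct residues
#' observed) / (frequency of the most common residue). An invariant column
#' scores exactly 1; gaps are excluded from residue counts; columns with no
#' coverage are reported as \code{NA}.
#'
#' @param alignment a character matrix (rows = sequences, columns = aligned
#'   positions), an \link[Biostrings]{AAStringSet} of equal-width aligned
#'   sequences, or the list returned by \code{\link{alignToReference}}.
#' @param regions optional character vector of region labels per column
#'   (FR1, CDR1, FR2, HV2, FR3a, FR3b, CDR3, FR4).
#' @return data.frame with columns \code{position}, \code{region},
#'   \code{coverage}, \code{variability}.
#' @export
positionalVariability <- function(alignment, regions = NULL) {
  if (is.list(alignment) && !is.null(alignment$matrix)) {
    if (is.null(regions)) regions <- alignment$regions
    alignment <- alignment$matrix
  }
  if (methods::is(alignment, "AAStringSet")) {
    stopifnot(length(unique(Biostrings::width(alignment))) == 1L)
    alignment <- do.call(rbind, strsplit(as.character(alignment), ""))
  }
  stopifnot(is.matrix(alignment))
  nc <- ncol(alignment)
  if (is.null(regions)) regions <- rep(NA_character_, nc)
  stopifnot(length(regions) == nc)
  score <- numeric(nc); cov <- integer(nc)
  for (j in seq_len(nc)) {
    res <- alignment[, j]
    res <- res[!res %in% c("-", ".", "", NA)]
    cov[j] <- length(res)
    if (!length(res)) { score[j] <- NA_real_; next }
    tab <- table(res)
    score[j] <- length(tab) / (max(tab) / length(res))
  }
  data.frame(position = seq_len(nc), region = regions,
             coverage = cov, variability = score,
             stringsAsFactors = FALSE)
}

#' Align amino-acid sequences to the region-labelled reference frame
#'
#' Global pairwise alignment (BLOSUM62, affine gaps) of each sequence to a
#' region-annotated reference; residues are projected onto reference
#' columns (insertions relative to the reference are dropped, deletions
#' appear as gaps), producing the fixed-width alignment matrix used by
#' \code{\link{positionalVariability}}.
#'
#' @param sequences AAStringSet or character vector of vNAR amino-acid
#'   sequences.
#' @param reference a reference description as returned by
#'   \code{\link{vnarReference}}.
#' @return list with \code{matrix} (characters, rows = sequences) and
#'   \code{regions} (label per column).
#' @export
alignToReference <- function(sequences, reference = vnarReference()) {
  if (is.character(sequences))
    sequences <- Biostrings::AAStringSet(sequences)
  refaa <- reference$aa
  w <- nchar(refaa)
  mat <- matrix("-", nrow = length(sequences), ncol = w)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  pa <- Biostrings::pairwiseAlignment(
    sequences, Biostrings::AAString(refaa), type = "global",
    substitutionMatrix = B62, gapOpening = 10, gapExtension = 0.5)
  pat <- as.character(Biostrings::pattern(pa))
  sub <- as.character(Biostrings::subject(pa))
  for (i in seq_along(sequences)) {
    pc <- strsplit(pat[i], "")[[1]]
    sc <- strsplit(sub[i], "")[[1]]
    ref_pos <- cumsum(sc != "-")
    keep <- sc != "-"
    mat[i, ref_pos[keep]] <- pc[keep]
  }
  list(matrix = mat, regions = reference$regions)
}

#' V-J pairing frequency matrix
#'
#' @param x a \code{\linkS4class{RepertoireSample}} or rearrangement
#'   data.frame; only pass-QC rows are counted.
#' @param weightBy \code{"read"} (default) counts every rearrangement,
#'   \code{"clonotype"} counts each clonotype once.
#' @param productiveOnly restrict to productive rearrangements.
#' @return list with \code{matrix} (V x J frequencies summing to 1),
#'   \code{v_usage} and \code{j_usage} marginals.
#' @export
vjPairMatrix <- function(x, weightBy = c("read", "clonotype"),
                         productiveOnly = FALSE) {
  weightBy <- match.arg(weightBy)
  df <- if (methods::is(x, "RepertoireSample"))
    as.data.frame(rearrangements(x)) else as.data.frame(x)
  df <- df[df$pass_qc, , drop = FALSE]
  if (productiveOnly) df <- df[df$productive, , drop = FALSE]
  if (!nrow(df)) stop("empty sample")
  if (weightBy == "clonotype")
    df <- df[!duplicated(paste(df$v_call, df$j_call, df$cdr3_aa)), ,
             drop = FALSE]
  tab <- table(df$v_call, df$j_call)
  m <- tab / sum(tab)
  list(matrix = unclass(m),
       v_usage = rowSums(m), j_usage = colSums(m))
}

#' Cumulative frequency of the top-n clonotypes
#'
#' The fraction of reads carried by the \code{n} most frequent clonotypes
#' (ties broken by clonotype key); rising top-100 mass over an immunisation
#' course indicates clonal expansion.
#'
#' @inheritParams shannonIndex
#' @param n number of top clonotypes (default 100).
#' @return single numeric in (0, 1]; returns 1 with a message when \code{n}
#'   exceeds the number of clonotypes.
#' @export
topNCumulative <- function(x, n = 100L, productiveOnly = TRUE) {
  counts <- asCounts(x, productiveOnly)
  stopifnot(n >= 1L)
  if (n >= length(counts)) {
    if (n > length(counts))
      message("n exceeds the number of clonotypes; returning 1")
    return(1)
  }
  ord <- order(-counts, names(counts))
  sum(counts[ord[seq_len(n)]]) / sum(counts)
}

#' Sequence uniqueness of a sample
#'
#' Reports both uniqueness definitions for full-length nucleotide
#' sequences: the fraction of distinct sequences among all reads (the
#' primary definition) and the fraction of reads whose sequence occurs
#' exactly once.
#'
#' @param x a \code{\linkS4class{RepertoireSample}}, a character vector of
#'   sequences, or an XStringSet.
#' @return named numeric: \code{distinct_fraction} and
#'   \code{singleton_fraction}.
#' @export
uniqueRatio <- function(x) {
  seqs <- if (methods::is(x, "RepertoireSample")) {
    df <- as.data.frame(rearrangements(x))
    df$sequence[df$pass_qc]
  } else if (methods::is(x, "XStringSet")) as.character(x)
  else as.character(x)
  if (!length(seqs)) stop("empty sample")
  tab <- table(seqs)
  c(distinct_fraction = length(tab) / length(seqs),
    singleton_fraction = sum(tab == 1L) / length(seqs))
}

#' Clonotype overlap between two samples
#'
#' Default definition: shared clonotype keys divided by the smaller
#' repertoire's clonotype count (symmetric; equals 1 when one sample's
#' clonotypes are a subset of the other's). Jaccard available as an option.
#'
#' @param a,b samples or clonotype tables (see \code{\link{shannonIndex}}).
#' @param method \code{"min"} (default) or \code{"jaccard"}.
#' @param productiveOnly restrict to productive rearrangements.
#' @return overlap rate in [0, 1].
#' @export
clonotypeOverlap <- function(a, b, method = c("min", "jaccard"),
                             productiveOnly = TRUE) {
  method <- match.arg(method)
  ca <- asCounts(a, productiveOnly); cb <- asCounts(b, productiveOnly)
  if (!length(ca) || !length(cb)) stop("empty sample")
  shared <- length(intersect(names(ca), names(cb)))
  if (method == "min") shared / min(length(ca), length(cb))
  else shared / length(union(names(ca), names(cb)))
}

#' Clonotype frequency trajectories across time points
#'
#' For the union of each time point's top-\code{topN} clonotypes, the
#' frequency at every time point; the remaining repertoire mass is reported
#' as \code{"other"}, so columns sum to 1.
#'
#' @param samples list (ordered by time) of samples or clonotype tables.
#' @param topN number of top clonotypes taken from each time point.
#' @param productiveOnly restrict to productive rearrangements.
#' @return matrix (tracked clonotypes + \code{"other"}) x time points.
#' @export
clonotypeTracking <- function(samples, topN = 100L, productiveOnly = TRUE) {
  stopifnot(length(samples) >= 2L)
  counts <- lapply(samples, asCounts, productiveOnly = productiveOnly)
  tracked <- unique(unlist(lapply(counts, function(ct) {
    ord <- order(-ct, names(ct))
    names(ct)[ord[seq_len(min(topN, length(ct)))]]
  })))
  tp_names <- names(samples) %||% paste0("t", seq_along(samples))
  m <- matrix(0, nrow = length(tracked) + 1L, ncol = length(samples),
              dimnames = list(c(tracked, "other"), tp_names))
  for (j in seq_along(counts)) {
    f <- counts[[j]] / sum(counts[[j]])
    hit <- intersect(names(f), tracked)
    m[hit, j] <- f[hit]
    m["other", j] <- 1 - sum(m[hit, j])
  }
  m
}
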