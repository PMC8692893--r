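#' IgNARClusterSet: mined germline clusters
#'
#' Container for the result of germline mining: the located gene segments
#' (a \link[GenomicRanges]{GRanges} with metadata columns \code{kind},
#' \code{identity}, \code{cluster}, \code{segment}, \code{prejoined},
#' \code{rss_up}, \code{rss_down}, \code{anchor}, \code{seq}), a per-cluster
#' summary table, and the segment sequences as a named
#' \link[Biostrings]{DNAStringSet}.
#'
#' A cluster is \emph{complete} when it contains exactly one V, three D, one
#' J, five C segments, one secretory (Sec) and one transmembrane (Tm) tail in
#' genomic order; anything else is \emph{incomplete}.
#'
#' @slot segments GRanges of located segments.
#' @slot clusters DataFrame with one row per cluster (name, seqnames, start,
#'   end, strand, n_segments, completeness).
#' @slot sequences named DNAStringSet of segment sequences.
#'
#' @aliases IgNARClusterSet-class
#' @exportClass IgNARClusterSet
setClass("IgNARClusterSet",
  representation(
    segments  = "GRanges",
    clusters  = "DFrame",
    sequences = "DNAStringSet"
  )
)

setValidity("IgNARClusterSet", function(object) {
  msg <- NULL
  need <- c("kind", "identity", "cluster", "segment")
  miss <- setdiff(need, colnames(S4Vectors::mcols(object@segments)))
  if (length(miss))
    msg <- c(msg, paste("segments lack metadata columns:",
                        paste(miss, collapse = ", ")))
  if (!all(c("name", "completeness") %in% colnames(object@clusters)))
    msg <- c(msg, "cluster table needs 'name' and 'completeness' columns")
  if (length(object@sequences) &&
      !setequal(names(object@sequences),
                S4Vectors::mcols(object@segments)$segment))
    msg <- c(msg, "sequence names must match segment names")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn IgNARClusterSet segments as a GRanges
#' @param x,object an \code{IgNARClusterSet}
#' @export
clusterSegments <- function(x) x@segments

#' @describeIn IgNARClusterSet per-cluster summary table
#' @export
clusterTable <- function(x) x@clusters

#' @describeIn IgNARClusterSet named DNAStringSet of segment sequences
#' @export
germlineSequences <- function(x) x@sequences

setMethod("show", "IgNARClusterSet", function(object) {
  tab <- object@clusters
  cat("IgNARClusterSet with", nrow(tab), "cluster(s),",
      length(object@segments), "segment(s)\n")
  if (nrow(tab)) {
    comp <- sum(tab$completeness == "complete")
    cat("  complete:", comp, " incomplete:", nrow(tab) - comp, "\n")
    cat("  clusters:", paste(tab$name, collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' RepertoireSample: annotated rearrangements of one sample
#'
#' One immune-repertoire sample (individual x time point) holding an
#' AIRR-style rearrangement table: one row per read with V/D/J calls, CDR3
#' nucleotide and amino-acid sequence, frame/productivity and QC status.
#' Only rows with \code{pass_qc == TRUE} enter repertoire statistics.
#'
#' @slot sampleID scalar character identifier.
#' @slot rearrangements DataFrame, one row per input read.
#'
#' @aliases RepertoireSample-class
#' @exportClass RepertoireSample
setClass("RepertoireSample",
  representation(
    sampleID       = "character",
    rearrangements = "DFrame"
  )
)

setValidity("RepertoireSample", function(object) {
  msg <- NULL
  if (length(object@sampleID) != 1L)
    msg <- c(msg, "sampleID must be a single string")
  need <- c("sequence_id", "v_call", "j_call", "cdr3_aa", "productive",
            "pass_qc")
  miss <- setdiff(need, colnames(object@rearrangements))
  if (length(miss))
    msg <- c(msg, paste("rearrangement table lacks columns:",
                        paste(miss, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' @describeIn RepertoireSample sample identifier
#' @param x,object a \code{RepertoireSample}
#' @export
sampleID <- function(x) x@sampleID

#' @describeIn RepertoireSample the rearrangement table (all reads)
#' @export
rearrangements <- function(x) x@rearrangements

setMethod("show", "RepertoireSample", function(object) {
  df <- object@rearrangements
  cat("RepertoireSample", sQuote(object@sampleID), "with", nrow(df),
      "read(s)\n")
  if (nrow(df)) {
    cat("  pass QC:", sum(df$pass_qc), " productive:",
        sum(df$productive & df$pass_qc), "\n")
  }
  invisible(NULL)
})

#' @describeIn RepertoireSample clonotype count table. Clonotypes are keyed
#'   by \code{(v_call, j_call, cdr3_aa)}; by default only productive
#'   pass-QC rearrangements are counted.
#' @param productiveOnly logical; restrict to productive rearrangements.
#' @export
clonotypeCounts <- function(x, productiveOnly = TRUE) {
  df <- if (methods::is(x, "RepertoireSample"))
    as.data.frame(x@rearrangements) else as.data.frame(x)
  df <- df[df$pass_qc, , drop = FALSE]
  if (productiveOnly) df <- df[df$productive, , drop = FALSE]
  if (!nrow(df)) stop("empty sample")
  key <- paste(df$v_call, df$j_call, df$cdr3_aa, sep = "|")
  counts <- sort(table(key), decreasing = TRUE)
  # stable tie-break on the key itself
  counts <- counts[order(-as.integer(counts), names(counts))]
  data.frame(clonotype = names(counts),
             count = as.integer(counts),
             freq = as.integer(counts) / sum(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' SimConfig: full generative specification for the simulators
#'
#' Holds every parameter of the synthetic-data generators: the germline
#' layout (cluster composition, segment lengths, RSS spacers and planted
#' mismatch counts), the repertoire model (V-J pair probabilities, D usage
#' and trimming, N insertions, somatic hypermutation, clone-size law,
#' sequencing error, read length), and the vNAR library model (type mixture,
#' cysteine counts, unique fraction). Construct with \code{\link{simConfig}}.
#'
#' @slot seed integer master seed; fixed seed implies byte-identical output.
#' @slot germline named list of germline-layout parameters.
#' @slot repertoire named list of repertoire-model parameters.
#' @slot library named list of library-model parameters.
#'
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    seed       = "integer",
    germline   = "list",
    repertoire = "list",
    library    = "list"
  )
)

setValidity("SimConfig", function(object) {
  msg <- NULL
  rp <- object@repertoire
  if (!is.null(rp$pair_table)) {
    if (abs(sum(rp$pair_table) - 1) > 1e-9)
      msg <- c(msg, "pair_table probabilities must sum to 1")
    if (any(rp$pair_table < 0))
      msg <- c(msg, "pair_table probabilities must be non-negative")
  }
  for (f in c("shm_rate", "error_rate"))
    if (!is.null(rp[[f]]) && (rp[[f]] < 0 || rp[[f]] >= 1))
      msg <- c(msg, paste(f, "must lie in [0, 1)"))
  lb <- object@library
  if (!is.null(lb$type_mixture) && abs(sum(lb$type_mixture) - 1) > 1e-9)
    msg <- c(msg, "type_mixture must sum to 1")
  if (!is.null(lb$unique_fraction) &&
      (lb$unique_fraction <= 0 || lb$unique_fraction > 1))
    msg <- c(msg, "unique_fraction must lie in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig (seed ", object@seed, ")\n", sep = "")
  cat("  germline  :", object@germline$n_clusters, "cluster(s)\n")
  pt <- object@repertoire$pair_table
  cat("  repertoire: dominant pair ",
      names(pt)[which.max(pt)], " (", round(max(pt) * 100, 1), "%), SHM ",
      object@repertoire$shm_rate, ", error ",
      object@repertoire$error_rate, "\n", sep = "")
  tm <- object@library$type_mixture
  cat("  library   : ", paste(sprintf("%s=%.1f%%", names(tm), 100 * tm),
                              collapse = " "), "\n", sep = "")
  invisible(NULL)
})
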