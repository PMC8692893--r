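#' Quality-filter repertoire reads
#'
#' Removes reads shorter than \code{minLength}, reads whose fraction of N
#' bases exceeds \code{maxNFraction}, and (when per-base qualities are
#' available) reads whose mean Phred quality falls below
#' \code{minMeanQuality}. Rules are applied in that order and each read is
#' charged to the first rule it fails, so kept + removed = input.
#'
#' @param reads DNAStringSet, optionally with \code{mcols(reads)$quality}
#'   (character or BStringSet of Phred+33 strings) as produced by
#'   \code{\link{readSequences}} on FASTQ input.
#' @param minLength,maxNFraction,minMeanQuality thresholds; defaults 200 nt,
#'   0.02, Q20.
#' @return list with \code{reads} (the kept DNAStringSet) and \code{report}
#'   (counts per removal rule).
#' @export
filterReads <- function(reads, minLength = 200L, maxNFraction = 0.02,
                        minMeanQuality = 20) {
  n <- length(reads)
  if (n == 0L) {
    return(list(reads = reads,
                report = list(total = 0L, removed_length = 0L,
                              removed_n = 0L, removed_quality = 0L,
                              kept = 0L)))
  }
  len <- Biostrings::width(reads)
  nfrac <- Biostrings::letterFrequency(reads, "N")[, 1L] / pmax(len, 1L)
  fail_len <- len < minLength
  fail_n <- !fail_len & nfrac > maxNFraction
  qual <- S4Vectors::mcols(reads)$quality
  if (is.null(qual)) {
    warning("no per-base qualities: quality rule skipped")
    fail_q <- rep(FALSE, n)
  } else {
    meanq <- vapply(as.character(qual), function(q)
      mean(utf8ToInt(q)) - 33, numeric(1), USE.NAMES = FALSE)
    fail_q <- !fail_len & !fail_n & meanq < minMeanQuality
  }
  keep <- !(fail_len | fail_n | fail_q)
  list(reads = reads[keep],
       report = list(total = n,
                     removed_length = sum(fail_len),
                     removed_n = sum(fail_n),
                     removed_quality = sum(fail_q),
                     kept = sum(keep)))
}

#' Annotate repertoire reads against a germline database
#'
#' Two-stage V(D)J assignment. The primary stage scores every read against
#' every germline V and J sequence with affine-gap Smith-Waterman local
#' alignment (match 2, mismatch -3, gap open -5, extend -2) and keeps the
#' top-\code{topK} candidates per side. The secondary stage recomputes, for
#' each close candidate, an end-free global alignment over the read region
#' it covers and then extends the junction-side boundary base-by-base while
#' the read matches the germline, yielding the maximal germline-attributable
#' span; the final call maximises identity, then alignment length, then
#' database order. D segments are called inside the junction by
#' near-exact matching (at most \code{dMaxMismatch} mismatches over at least
#' \code{dMinLength} bp). The CDR3 is cut between the FR3b cysteine codon of
#' the V call and the FR4 tryptophan-motif codon of the J call (anchor
#' positions stored in the germline table), translated in the V frame.
#'
#' Reads are orientation-canonicalised by a k-mer vote against the V
#' references before alignment, so annotation is invariant to
#' reverse-complemented input.
#'
#' @param reads DNAStringSet of (quality-filtered) reads.
#' @param germline a germline database: either the list returned by
#'   \code{\link{readGermlineDb}} / \code{\link{makeGermlineReferences}} or
#'   a directory written by \code{\link{exportGermline}}.
#' @param sampleID identifier for the resulting sample.
#' @param topK number of primary candidates kept per side.
#' @param minScore minimum primary local-alignment score for an assignment.
#' @param scoreMargin refine only candidates whose primary score is within
#'   this margin of the best candidate (the others cannot overtake on
#'   identity at these scoring parameters).
#' @param dMinLength,dMaxMismatch D-call rule: minimum matched length and
#'   maximum mismatches.
#' @return a \code{\linkS4class{RepertoireSample}}; every input read appears
#'   in exactly one row, failed reads carry \code{pass_qc = FALSE} and a
#'   \code{qc_reason}.
#' @export
annotateReads <- function(reads, germline, sampleID = "sample1",
                          topK = 3L, minScore = 40, scoreMargin = 16,
                          dMinLength = 6L, dMaxMismatch = 1L) {
  db <- resolveGermline(germline)
  tab <- db$table
  vsel <- tab$kind == "V"; jsel <- tab$kind == "J"; dsel <- tab$kind == "D"
  if (!any(vsel) || !any(jsel))
    stop("germline database must contain at least one V and one J segment")
  vnames <- tab$segment[vsel]; jnames <- tab$segment[jsel]
  vseq <- as.character(db$sequences[vnames])
  jseq <- as.character(db$sequences[jnames])
  dnames <- tab$segment[dsel]
  dseq <- as.character(db$sequences[dnames])
  vanchor <- tab$anchor[vsel]
  janchor <- tab$anchor[jsel]

  n <- length(reads)
  ids <- names(reads) %||% paste0("read", seq_len(n))
  if (n == 0L) {
    return(methods::new("RepertoireSample", sampleID = sampleID,
                        rearrangements = emptyRearrangements()))
  }

  strand <- readStrandVote(reads, vseq)
  canon <- reads
  if (any(strand == "-"))
    canon[strand == "-"] <-
      Biostrings::reverseComplement(reads[strand == "-"])
  seqs <- as.character(canon)

  vs <- .cpp_sw_scores(seqs, vseq, 2, -3, 5, 2)
  js <- .cpp_sw_scores(seqs, jseq, 2, -3, 5, 2)

  vref <- refineSide(seqs, vseq, vs, vanchor, TRUE, topK, minScore,
                     scoreMargin)
  jref <- refineSide(seqs, jseq, js, janchor, FALSE, topK, minScore,
                     scoreMargin)

  v_call <- ifelse(is.na(vref$idx), "", vnames[vref$idx])
  j_call <- ifelse(is.na(jref$idx), "", jnames[jref$idx])

  qc_reason <- rep("", n)
  qc_reason[is.na(vref$idx)] <- "no V assignment"
  qc_reason[qc_reason == "" & is.na(jref$idx)] <- "no J assignment"
  ok <- qc_reason == ""

  # CDR3 anchors; crossed anchors mean the V and J calls genuinely overlap
  va <- vref$anchor_read; ja <- jref$anchor_read
  missing_anchor <- ok & (is.na(va) | is.na(ja))
  qc_reason[missing_anchor] <- "anchor not covered"
  crossed <- ok & !missing_anchor & (va + 3L) > ja
  qc_reason[crossed] <- "overlapping calls"
  anchored <- ok & !missing_anchor & !crossed

  # junction between the refined boundaries; a small boundary overlap is a
  # junction-attribution tie (both segments can extend into the same
  # chance-matching bases) and truncates to an empty junction
  junction_nt <- rep("", n)
  j_eff <- base::pmax(jref$read_start, vref$read_end + 1L)
  has_junc <- anchored & (j_eff - vref$read_end - 1L) > 0L
  junction_nt[has_junc] <- substr(seqs[has_junc],
                                  vref$read_end[has_junc] + 1L,
                                  j_eff[has_junc] - 1L)
  d_call <- rep("", n)
  d_call[anchored] <- "none"
  if (length(dseq) && any(has_junc)) {
    dres <- .cpp_call_d(junction_nt[has_junc], dseq,
                        dMinLength, dMaxMismatch)
    hit <- !is.na(dres$d_index)
    d_call[which(has_junc)[hit]] <- dnames[dres$d_index[hit]]
  }
  cdr3_nt <- rep("", n); cdr3_aa <- rep("", n)
  junction <- rep("", n); junction_aa <- rep("", n)
  frame <- rep("out", n); productive <- rep(FALSE, n)
  if (any(anchored)) {
    ai <- which(anchored)
    cdr3_nt[ai] <- substr(seqs[ai], va[ai] + 3L, ja[ai] - 1L)
    junction[ai] <- substr(seqs[ai], va[ai], ja[ai] + 2L)
    inframe <- ai[(ja[ai] - va[ai]) %% 3L == 0L]
    frame[inframe] <- "in"
    cdr3_aa[inframe] <- vapply(cdr3_nt[inframe], translateDNA,
                               character(1), USE.NAMES = FALSE)
    junction_aa[inframe] <- vapply(junction[inframe], translateDNA,
                                   character(1), USE.NAMES = FALSE)
    productive[inframe] <- !grepl("\\*", junction_aa[inframe]) &
      !grepl("\\*", cdr3_aa[inframe])
  }
  pass <- anchored

  df <- S4Vectors::DataFrame(
    sequence_id = ids,
    sequence = seqs,
    strand = strand,
    v_call = v_call, d_call = d_call, j_call = j_call,
    v_identity = vref$identity, j_identity = jref$identity,
    v_score = vref$score, j_score = jref$score,
    junction = junction, junction_aa = junction_aa,
    cdr3 = cdr3_nt, cdr3_aa = cdr3_aa,
    frame = frame, productive = productive,
    pass_qc = pass, qc_reason = qc_reason)
  methods::new("RepertoireSample", sampleID = sampleID, rearrangements = df)
}

resolveGermline <- function(germline) {
  if (is.character(germline) && length(germline) == 1L)
    return(readGermlineDb(germline))
  if (methods::is(germline, "IgNARClusterSet")) {
    mc <- S4Vectors::mcols(germline@segments)
    return(list(sequences = germline@sequences,
                table = data.frame(segment = mc$segment, kind = mc$kind,
                                   anchor = mc$anchor,
                                   stringsAsFactors = FALSE)))
  }
  stopifnot(is.list(germline), !is.null(germline$sequences),
            !is.null(germline$table))
  germline
}

# orientation vote: shared 12-mers with the V references, forward vs
# reverse-complement; ties default to forward
readStrandVote <- function(reads, vseq, k = 12L) {
  words <- unique(unlist(lapply(vseq, function(s) {
    st <- seq(1L, max(1L, nchar(s) - k + 1L), by = 24L)
    substring(s, st, st + k - 1L)
  })))
  words <- words[nchar(words) == k]
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(words))
  fwd <- colSums(Biostrings::vcountPDict(pd, reads))
  rc <- colSums(Biostrings::vcountPDict(
    pd, Biostrings::reverseComplement(reads)))
  ifelse(rc > fwd, "-", "+")
}

# secondary stage for one side (V or J): end-free global alignment of each
# close candidate, base-by-base matched extension toward the junction, best
# call by (identity, alignment length, database order)
refineSide <- function(seqs, refs, scores, anchors, extendRight, topK,
                       minScore, scoreMargin) {
  n <- length(seqs); m <- length(refs)
  best <- apply(scores, 1L, max)
  idx <- rep(NA_integer_, n)
  out <- list(idx = idx, identity = rep(NA_real_, n),
              score = best, read_start = rep(NA_integer_, n),
              read_end = rep(NA_integer_, n),
              anchor_read = rep(NA_integer_, n))
  eligible <- which(best >= minScore)
  if (!length(eligible)) return(out)

  pr <- vector("list", length(eligible))
  pf <- vector("list", length(eligible))
  for (t in seq_along(eligible)) {
    i <- eligible[t]
    ord <- order(-scores[i, ], seq_len(m))[seq_len(min(topK, m))]
    ord <- ord[scores[i, ord] >= scores[i, ord[1L]] - scoreMargin]
    pr[[t]] <- rep(i, length(ord))
    pf[[t]] <- ord
  }
  pair_read <- unlist(pr); pair_ref <- unlist(pf)
  aln <- .cpp_overlap_align(seqs[pair_read], refs, pair_ref,
                            ifelse(is.na(anchors[pair_ref]), -1L,
                                   anchors[pair_ref]),
                            extendRight, 2, -3, 5, 2)
  identity <- aln$matches / pmax(aln$aln_len, 1L)
  # pick the best candidate per read
  o <- order(pair_read, -identity, -aln$aln_len, pair_ref)
  first <- !duplicated(pair_read[o])
  sel <- o[first]
  ri <- pair_read[sel]
  out$idx[ri] <- pair_ref[sel]
  out$identity[ri] <- identity[sel]
  out$read_start[ri] <- aln$read_start[sel]
  out$read_end[ri] <- aln$read_end[sel]
  out$anchor_read[ri] <- ifelse(aln$anchor_read[sel] < 0L, NA_integer_,
                                aln$anchor_read[sel])
  out
}

emptyRearrangements <- function() {
  S4Vectors::DataFrame(
    sequence_id = character(0), sequence = character(0),
    strand = character(0), v_call = character(0), d_call = character(0),
    j_call = character(0), v_identity = numeric(0),
    j_identity = numeric(0), v_score = numeric(0), j_score = numeric(0),
    junction = character(0), junction_aa = character(0),
    cdr3 = character(0), cdr3_aa = character(0), frame = character(0),
    productive = logical(0), pass_qc = logical(0), qc_reason = character(0))
}

#' Extract the CDR3 of a single read given fixed V and J calls
#'
#' Runs the secondary (end-free global alignment + base-by-base extension)
#' stage for one read against a chosen V and J germline segment and cuts
#' the CDR3 between the stored anchors.
#'
#' @param read a DNAString or character read sequence.
#' @param vCall,jCall germline segment names present in \code{germline}.
#' @inheritParams annotateReads
#' @return list with \code{cdr3_nt}, \code{cdr3_aa}, \code{frame}
#'   (\code{"in"}/\code{"out"}) and \code{productive}.
#' @export
extractCDR3 <- function(read, vCall, jCall, germline) {
  db <- resolveGermline(germline)
  seq <- as.character(read)
  tab <- db$table
  vrow <- match(vCall, tab$segment); jrow <- match(jCall, tab$segment)
  if (is.na(vrow) || is.na(jrow)) stop("unknown V or J call")
  va <- .cpp_overlap_align(seq, as.character(db$sequences[vCall]), 1L,
                           tab$anchor[vrow] %||% -1L, TRUE, 2, -3, 5, 2)
  ja <- .cpp_overlap_align(seq, as.character(db$sequences[jCall]), 1L,
                           tab$anchor[jrow] %||% -1L, FALSE, 2, -3, 5, 2)
  vpos <- va$anchor_read[1L]; jpos <- ja$anchor_read[1L]
  if (is.na(vpos) || vpos < 0L || is.na(jpos) || jpos < 0L ||
      vpos + 3L > jpos)
    return(list(cdr3_nt = NA_character_, cdr3_aa = NA_character_,
                frame = "out", productive = FALSE))
  cdr3 <- substr(seq, vpos + 3L, jpos - 1L)
  inframe <- (jpos - vpos) %% 3L == 0L
  aa <- if (inframe) translateDNA(cdr3) else NA_character_
  junction_aa <- if (inframe) translateDNA(substr(seq, vpos, jpos + 2L))
    else NA_character_
  list(cdr3_nt = cdr3, cdr3_aa = aa,
       frame = if (inframe) "in" else "out",
       productive = isTRUE(inframe && !grepl("\\*", junction_aa)))
}

#' Write / read an AIRR-style rearrangement table
#'
#' One row per read with the standard columns (\code{sequence_id},
#' \code{v_call}, \code{d_call}, \code{j_call}, \code{junction},
#' \code{junction_aa}, \code{cdr3}, \code{cdr3_aa}, \code{productive}) plus
#' the package's QC columns; the table round-trips losslessly through
#' \code{readRearrangementTable}.
#'
#' @param sample a \code{\linkS4class{RepertoireSample}}.
#' @param file optional TSV path to write.
#' @return \code{buildRearrangementTable}: the table as a data.frame
#'   (invisibly when \code{file} is given).
#' @export
buildRearrangementTable <- function(sample, file = NULL) {
  df <- as.data.frame(rearrangements(sample))
  if (!is.null(file)) {
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' @describeIn buildRearrangementTable read a written table back into a
#'   \code{RepertoireSample}.
#' @param sampleID sample identifier for the reconstructed object.
#' @export
readRearrangementTable <- function(file, sampleID = "sample1") {
  df <- read.delim(file, stringsAsFactors = FALSE, na.strings = NULL)
  for (col in c("junction", "junction_aa", "cdr3", "cdr3_aa", "v_call",
                "d_call", "j_call", "qc_reason"))
    if (col %in% colnames(df)) df[[col]][is.na(df[[col]])] <- ""
  for (col in c("v_identity", "j_identity", "v_score", "j_score"))
    if (col %in% colnames(df))
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  df$productive <- as.logical(df$productive)
  df$pass_qc <- as.logical(df$pass_qc)
  methods::new("RepertoireSample", sampleID = sampleID,
               rearrangements = S4Vectors::DataFrame(df))
}
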