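REGION_LEVELS <- c("FR1", "CDR1", "FR2", "HV2", "FR3a", "FR3b", "CDR3", "FR4")

#' The region-annotated vNAR reference frame
#'
#' A synthetic full-length vNAR amino-acid reference with its region
#' annotation (FR1, CDR1, FR2, HV2, FR3a, FR3b, CDR3, FR4), the canonical
#' cysteine anchors (FR1 and FR3b, which form the conserved intradomain
#' disulfide of all vNAR types), the conserved FR2 tryptophan and the FR4
#' tryptophan motif. Both files live under \code{inst/extdata} and can be
#' replaced to re-key the package to another numbering.
#'
#' @param fasta,regions optional paths overriding the shipped reference
#'   FASTA and region table.
#' @return list with \code{aa} (reference string), \code{regions} (label
#'   per residue), \code{table} (region boundary data.frame) and
#'   \code{anchors} (named positions: \code{fr1_cys}, \code{fr3b_cys},
#'   \code{fr2_trp}, \code{fr4_trp}).
#' @export
vnarReference <- function(fasta = NULL, regions = NULL) {
  fasta <- fasta %||% system.file("extdata", "vnar_reference.fasta",
                                  package = "vnarseq", mustWork = TRUE)
  regions <- regions %||% system.file("extdata", "vnar_regions.tsv",
                                      package = "vnarseq", mustWork = TRUE)
  aa <- as.character(Biostrings::readAAStringSet(fasta)[[1L]])
  tab <- read.delim(regions, stringsAsFactors = FALSE)
  stopifnot(all(tab$region %in% REGION_LEVELS),
            max(tab$end) == nchar(aa))
  lab <- character(nchar(aa))
  for (i in seq_len(nrow(tab)))
    lab[tab$start[i]:tab$end[i]] <- tab$region[i]
  ch <- strsplit(aa, "")[[1L]]
  anchors <- c(
    fr1_cys = which(ch == "C" & lab == "FR1")[1L],
    fr3b_cys = tail(which(ch == "C" & lab == "FR3b"), 1L),
    fr2_trp = which(ch == "W" & lab == "FR2")[1L],
    fr4_trp = which(ch == "W" & lab == "FR4")[1L])
  list(aa = aa, regions = lab, table = tab, anchors = anchors)
}

#' Assign region labels to vNAR amino-acid sequences
#'
#' Globally aligns each sequence to the region-annotated reference
#' (BLOSUM62, affine gaps) and propagates the region labels: residues
#' aligned to a reference position take its label; insertions relative to
#' the reference take the label of the neighbouring variable region when
#' they sit at a framework/CDR boundary, otherwise the label of the
#' preceding reference position. Sequences whose identity over
#' framework-labelled columns falls below \code{minFrameworkIdentity} are
#' flagged unalignable and excluded from typing.
#'
#' @param sequences AAStringSet or character vector (>= 60 aa each).
#' @param reference see \code{\link{vnarReference}}.
#' @param minFrameworkIdentity minimum framework identity (default 0.5).
#' @return list with \code{labels} (per-sequence character vectors of
#'   region labels, one per residue), \code{framework_identity} and
#'   \code{alignable}.
#' @export
assignRegions <- function(sequences, reference = vnarReference(),
                          minFrameworkIdentity = 0.5) {
  if (is.character(sequences))
    sequences <- Biostrings::AAStringSet(sequences)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  # chunked to bound the footprint of the alignment objects
  chunks <- split(seq_along(sequences),
                  ceiling(seq_along(sequences) / 5000L))
  pat <- character(length(sequences))
  sub <- character(length(sequences))
  for (idx in chunks) {
    pa <- Biostrings::pairwiseAlignment(
      sequences[idx], Biostrings::AAString(reference$aa), type = "global",
      substitutionMatrix = B62, gapOpening = 10, gapExtension = 0.5)
    pat[idx] <- as.character(Biostrings::pattern(pa))
    sub[idx] <- as.character(Biostrings::subject(pa))
  }
  rlab <- reference$regions
  is_variable <- rlab %in% c("CDR1", "HV2", "CDR3")
  n <- length(sequences)
  labels <- vector("list", n)
  fid <- numeric(n)
  nref <- length(rlab)
  for (i in seq_len(n)) {
    pc <- strsplit(pat[i], "")[[1L]]
    sc <- strsplit(sub[i], "")[[1L]]
    ref_pos <- cumsum(sc != "-")             # 0 before the first ref column
    aligned <- sc != "-"
    lab <- character(length(pc))
    lab[aligned] <- rlab[ref_pos[aligned]]
    ins <- which(!aligned)
    if (length(ins)) {
      r <- ref_pos[ins]
      nxt <- ifelse(r < nref, rlab[pmin(r + 1L, nref)], NA_character_)
      prv <- ifelse(r >= 1L, rlab[pmax(r, 1L)], NA_character_)
      use_nxt <- !is.na(nxt) & nxt %in% c("CDR1", "HV2", "CDR3")
      lab[ins] <- ifelse(use_nxt, nxt, ifelse(!is.na(prv), prv, nxt))
    }
    keep <- pc != "-"
    labels[[i]] <- lab[keep]
    fr_cols <- aligned & !is_variable[pmax(ref_pos, 1L)] & ref_pos >= 1L
    fid[i] <- if (any(fr_cols))
      sum(pc[fr_cols] == sc[fr_cols]) / sum(fr_cols) else 0
  }
  list(labels = labels, framework_identity = fid,
       alignable = fid >= minFrameworkIdentity)
}

#' Default vNAR type rule table
#'
#' The cysteine-pattern taxonomy: all named types require the canonical
#' FR1 + FR3b cysteine pair and no stray cysteines (HV2/FR3a, or extra
#' copies in FR1/FR3b). Type I adds FR2 and FR4 cysteines with an even
#' number (>= 2) in CDR3 and none in CDR1; type II has exactly one CDR1
#' cysteine and at least one in CDR3; type III is the type II pattern plus
#' a conserved CDR1 tryptophan; type IV has the canonical pair only.
#' Everything else - including sequences lacking the canonical pair - is
#' \code{"new"}. An editable YAML rendering ships as
#' \code{system.file("extdata", "vnar_type_rules.yaml", package = "vnarseq")}
#' and loads through \code{loadTypeRules}.
#'
#' @return named list of per-type constraint lists, in evaluation order.
#' @export
defaultTypeRules <- function() {
  list(
    I = list(cdr1_cys = 0L, cdr3_cys_min = 2L, cdr3_cys_even = TRUE,
             fr2_cys = TRUE, fr4_cys = TRUE),
    III = list(cdr1_cys = 1L, cdr3_cys_min = 1L, cdr3_cys_even = FALSE,
               fr2_cys = FALSE, fr4_cys = FALSE, cdr1_trp = TRUE),
    II = list(cdr1_cys = 1L, cdr3_cys_min = 1L, cdr3_cys_even = FALSE,
              fr2_cys = FALSE, fr4_cys = FALSE, cdr1_trp = FALSE),
    IV = list(cdr1_cys = 0L, cdr3_cys_min = 0L, cdr3_cys_even = FALSE,
              fr2_cys = FALSE, fr4_cys = FALSE, cdr3_cys_max = 0L))
}

#' @describeIn defaultTypeRules load a rule table from YAML.
#' @param path YAML file with a top-level \code{types} mapping.
#' @export
loadTypeRules <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$types))
  lapply(y$types, function(r) {
    for (f in c("cdr1_cys", "cdr3_cys_min", "cdr3_cys_max"))
      if (!is.null(r[[f]])) r[[f]] <- as.integer(r[[f]])
    r
  })
}

#' Classify one region-mapped vNAR sequence into a cysteine-pattern type
#'
#' @param sequence amino-acid string.
#' @param labels region label per residue (from
#'   \code{\link{assignRegions}}).
#' @param rules rule table, see \code{\link{defaultTypeRules}}.
#' @return one-row data.frame: \code{type} (I/II/III/IV/new),
#'   \code{cysteine_count}, \code{canonical_pair},
#'   \code{noncanonical_regions} (comma-separated).
#' @export
classifyType <- function(sequence, labels, rules = defaultTypeRules()) {
  ch <- strsplit(as.character(sequence), "")[[1L]]
  stopifnot(length(ch) == length(labels))
  cys <- vapply(REGION_LEVELS, function(r)
    sum(ch == "C" & labels == r), integer(1))
  trp_cdr1 <- any(ch == "W" & labels == "CDR1")
  canonical <- cys[["FR1"]] >= 1L && cys[["FR3b"]] >= 1L
  stray <- cys[["HV2"]] > 0L || cys[["FR3a"]] > 0L ||
    cys[["FR1"]] > 1L || cys[["FR3b"]] > 1L
  type <- "new"
  if (canonical && !stray) {
    for (tn in names(rules)) {
      r <- rules[[tn]]
      ok <- cys[["CDR1"]] == (r$cdr1_cys %||% 0L) &&
        cys[["CDR3"]] >= (r$cdr3_cys_min %||% 0L) &&
        (is.null(r$cdr3_cys_max) || cys[["CDR3"]] <= r$cdr3_cys_max) &&
        (!isTRUE(r$cdr3_cys_even) || cys[["CDR3"]] %% 2L == 0L) &&
        ((cys[["FR2"]] >= 1L) == isTRUE(r$fr2_cys)) &&
        ((cys[["FR4"]] >= 1L) == isTRUE(r$fr4_cys)) &&
        (is.null(r$cdr1_trp) || trp_cdr1 == isTRUE(r$cdr1_trp))
      if (ok) { type <- tn; break }
    }
  }
  noncan <- setdiff(names(cys)[cys > 0L], c("FR1", "FR3b"))
  if (cys[["FR1"]] > 1L) noncan <- c("FR1", noncan)
  if (cys[["FR3b"]] > 1L) noncan <- c(noncan, "FR3b")
  data.frame(type = type, cysteine_count = sum(ch == "C"),
             canonical_pair = canonical,
             noncanonical_regions = paste(noncan, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Classify a set of vNAR sequences
#'
#' Region assignment (\code{\link{assignRegions}}) followed by
#' \code{\link{classifyType}} on every alignable sequence.
#'
#' @inheritParams assignRegions
#' @param rules rule table, see \code{\link{defaultTypeRules}}.
#' @return data.frame with one row per sequence: \code{seq_id},
#'   \code{type} (NA for unalignable input), \code{cysteine_count},
#'   \code{canonical_pair}, \code{noncanonical_regions}, \code{alignable}.
#' @export
classifyVnar <- function(sequences, reference = vnarReference(),
                         rules = defaultTypeRules(),
                         minFrameworkIdentity = 0.5) {
  if (is.character(sequences))
    sequences <- Biostrings::AAStringSet(sequences)
  ids <- names(sequences) %||% paste0("seq", seq_along(sequences))
  rm_ <- assignRegions(sequences, reference, minFrameworkIdentity)
  n <- length(sequences)
  seqchar <- as.character(sequences)
  type <- rep(NA_character_, n)
  cysn <- rep(NA_integer_, n)
  canon <- rep(NA, n)
  noncan <- rep(NA_character_, n)
  for (i in which(rm_$alignable)) {
    row <- classifyType(seqchar[i], rm_$labels[[i]], rules)
    type[i] <- row$type
    cysn[i] <- row$cysteine_count
    canon[i] <- row$canonical_pair
    noncan[i] <- row$noncanonical_regions
  }
  data.frame(seq_id = ids, type = type, cysteine_count = cysn,
             canonical_pair = canon, noncanonical_regions = noncan,
             alignable = rm_$alignable, stringsAsFactors = FALSE)
}

#' Type and cysteine-count profile of a vNAR library
#'
#' @param sequences AAStringSet or character vector of full-length vNAR
#'   sequences.
#' @param calls optional precomputed \code{\link{classifyVnar}} table.
#' @inheritParams classifyVnar
#' @return list with \code{types} (data.frame type/count/percent, summing
#'   to 100 over classified sequences), \code{cysteines} (histogram of
#'   exact cysteine counts with percentages) and \code{unique_fraction}
#'   (distinct sequences / total).
#' @export
typeProfile <- function(sequences, calls = NULL,
                        reference = vnarReference(),
                        rules = defaultTypeRules()) {
  if (is.null(calls)) calls <- classifyVnar(sequences, reference, rules)
  cl <- calls[!is.na(calls$type), , drop = FALSE]
  if (!nrow(cl)) stop("no classified sequences")
  tt <- table(factor(cl$type, levels = c("I", "II", "III", "IV", "new")))
  types <- data.frame(type = names(tt), count = as.integer(tt),
                      percent = 100 * as.integer(tt) / sum(tt),
                      stringsAsFactors = FALSE)
  ct <- table(cl$cysteine_count)
  cysteines <- data.frame(cysteines = as.integer(names(ct)),
                          count = as.integer(ct),
                          percent = 100 * as.integer(ct) / sum(ct),
                          stringsAsFactors = FALSE)
  list(types = types, cysteines = cysteines,
       unique_fraction = unname(uniqueRatio(sequences)["distinct_fraction"]))
}
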