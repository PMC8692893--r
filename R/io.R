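#' Read sequence files (FASTA/FASTQ, optionally gzipped)
#'
#' FASTQ qualities are preserved in \code{mcols(x)$quality} as Phred+33
#' strings; \code{\link{writeSequences}} round-trips them losslessly. On a
#' malformed file the error names the offending line.
#'
#' @param path input file; format is detected from the extension
#'   (\code{.fq}/\code{.fastq} vs anything else) unless \code{format} is
#'   given.
#' @param format \code{"auto"}, \code{"fasta"} or \code{"fastq"}.
#' @return DNAStringSet (with a \code{quality} metadata column for FASTQ).
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  if (format == "fastq") validateFastq(path)   # fail early, by line number
  out <- tryCatch({
    if (format == "fastq") {
      x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
      S4Vectors::mcols(x)$quality <-
        as.character(S4Vectors::mcols(x)$qualities)
      S4Vectors::mcols(x)$qualities <- NULL
      x
    } else {
      Biostrings::readDNAStringSet(path)
    }
  }, error = function(e) e)
  if (methods::is(out, "error")) {
    reportMalformedLine(path, format, conditionMessage(out))
  }
  out
}

# structural check of a four-line-record FASTQ; stops naming the first
# offending line
validateFastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  i <- 1L
  bad <- NA_integer_
  while (i <= n) {
    if (!startsWith(lines[i], "@")) { bad <- i; break }
    if (i + 3L > n) { bad <- n; break }
    if (!startsWith(lines[i + 2L], "+")) { bad <- i + 2L; break }
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L])) { bad <- i + 3L; break }
    i <- i + 4L
  }
  if (!is.na(bad))
    stop("malformed fastq record in ", path, " at line ", bad,
         call. = FALSE)
  invisible(TRUE)
}

# locate the first structurally broken record and fail with its line number
reportMalformedLine <- function(path, format, original) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) character(0))
  bad <- if (format == "fasta" && length(lines) &&
               !startsWith(lines[1L], ">")) 1L else NA_integer_
  stop("malformed ", format, " record in ", path,
       if (!is.na(bad)) paste0(" at line ", bad),
       " (", original, ")", call. = FALSE)
}

#' @describeIn readSequences write sequences; FASTQ when a \code{quality}
#'   metadata column is present and \code{path} has a FASTQ extension.
#' @param x DNAStringSet (with optional \code{mcols(x)$quality}).
#' @return \code{writeSequences}: invisibly, \code{path}.
#' @export
writeSequences <- function(x, path) {
  fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path)
  if (fastq) {
    q <- S4Vectors::mcols(x)$quality
    if (is.null(q)) q <- strrep("I", Biostrings::width(x))
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(as.character(q)),
      compress = grepl("\\.gz$", path))
  } else {
    Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
  }
  invisible(path)
}

pipelineConfigKeys <- c("seed", "out_dir", "sample_id", "n_reads",
                        "n_library", "germline", "repertoire", "library",
                        "stats", "genome_fasta", "reads_fastq",
                        "stages")

#' Load and validate a pipeline configuration
#'
#' YAML with per-stage sections; unknown top-level keys are rejected so a
#' typo cannot silently change a run.
#'
#' @param path YAML file.
#' @return named list of configuration values with defaults filled in.
#' @export
loadPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), pipelineConfigKeys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$sample_id <- cfg$sample_id %||% "sample1"
  cfg$n_reads <- as.integer(cfg$n_reads %||% 5000L)
  cfg$n_library <- as.integer(cfg$n_library %||% 5000L)
  cfg$stages <- cfg$stages %||% c("simulate", "mine", "annotate", "stats",
                                  "typing")
  if (is.null(cfg$out_dir)) stop("configuration must set out_dir")
  cfg
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order - simulate (genome, repertoire
#' reads, vNAR library), germline mining, read annotation, repertoire
#' statistics and vNAR typing - writing every artefact plus the resolved
#' configuration into \code{out_dir}. Re-running with the same
#' configuration and seed reproduces every output byte-identically.
#'
#' @param config path to a YAML configuration or the list returned by
#'   \code{\link{loadPipelineConfig}} / a plain named list.
#' @return invisibly, a named list of the main in-memory results.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- loadPipelineConfig(config)
  if (is.null(config$out_dir)) stop("configuration must set out_dir")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(out, "config_resolved.yaml"))
  stages <- config$stages %||% c("simulate", "mine", "annotate", "stats",
                                 "typing")
  sc <- simConfig(seed = config$seed %||% 1L,
                  germline = config$germline %||% list(),
                  repertoire = config$repertoire %||% list(),
                  library = config$library %||% list())
  res <- list(config = config)
  log <- c(paste0("vnarseq ",
                  as.character(utils::packageVersion("vnarseq")),
                  " seed=", sc@seed))

  db <- makeGermlineReferences(sc)
  if ("simulate" %in% stages) {
    gen <- makeSyntheticGenome(sc, db = db, dir = file.path(out, "genome"))
    sim <- simulateRepertoire(sc, config$n_reads %||% 5000L, germline = db,
                              sampleID = config$sample_id %||% "sample1")
    writeSequences(sim$reads, file.path(out, "reads.fastq"))
    write.table(sim$truth, file.path(out, "truth_reads.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    lib <- simulateVnarLibrary(sc, config$n_library %||% 5000L)
    Biostrings::writeXStringSet(lib$sequences,
                                file.path(out, "library.fasta"))
    res$genome <- gen; res$sim <- sim; res$lib <- lib
    log <- c(log, "simulate: done")
  }
  if ("mine" %in% stages) {
    genome <- if (!is.null(res$genome)) res$genome$genome
      else readSequences(config$genome_fasta)
    rss <- findRSS(genome)
    segs <- scanSegments(genome, db$sequences, rss = rss)
    clusters <- assembleClusters(segs)
    exportGermline(clusters, file.path(out, "germline_db"))
    exportSegmentsGFF(clusters, file.path(out, "segments.gff3"), rss = rss)
    res$clusters <- clusters
    log <- c(log, paste0("mine: ", nrow(clusterTable(clusters)),
                         " clusters"))
  }
  if ("annotate" %in% stages) {
    reads <- if (!is.null(res$sim)) res$sim$reads
      else readSequences(config$reads_fastq)
    fq <- filterReads(reads)
    sample <- annotateReads(fq$reads, db,
                            sampleID = config$sample_id %||% "sample1")
    buildRearrangementTable(sample, file.path(out, "rearrangements.tsv"))
    jsonlite::write_json(fq$report, file.path(out, "qc_report.json"),
                         auto_unbox = TRUE)
    res$sample <- sample
    log <- c(log, paste0("annotate: ",
                         sum(rearrangements(sample)$pass_qc), "/",
                         nrow(rearrangements(sample)), " pass QC"))
  }
  if ("stats" %in% stages && !is.null(res$sample)) {
    vj <- vjPairMatrix(res$sample)
    stats <- list(
      shannon = as.list(shannonIndex(res$sample)),
      top100 = topNCumulative(res$sample, 100L),
      unique = as.list(uniqueRatio(res$sample)),
      v_usage = as.list(vj$v_usage),
      j_usage = as.list(vj$j_usage))
    jsonlite::write_json(stats, file.path(out, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    res$stats <- stats
    log <- c(log, "stats: done")
  }
  if ("typing" %in% stages && !is.null(res$lib)) {
    calls <- classifyVnar(res$lib$sequences)
    prof <- typeProfile(res$lib$sequences, calls = calls)
    write.table(calls, file.path(out, "type_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(types = prof$types, cysteines = prof$cysteines,
           unique_fraction = prof$unique_fraction),
      file.path(out, "type_profile.json"), auto_unbox = TRUE, digits = NA)
    res$typing <- prof
    log <- c(log, "typing: done")
  }
  writeLines(log, file.path(out, "pipeline.log"))
  invisible(res)
}
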