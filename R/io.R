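#' Read a protein FASTA file
#'
#' Reads protein sequences via \code{Biostrings::readAAStringSet} and
#' applies the package's input policy: duplicate identifiers and empty
#' files are errors; sequences with non-canonical residues are an error
#' or are skipped with a warning; sequences shorter than
#' \code{minLength} residues (default 10) are dropped.
#'
#' @param path FASTA file path.
#' @param nonCanonical \code{"error"} (default) or \code{"skip"}.
#' @param minLength minimum sequence length (default 10; set 1 to keep
#'   everything).
#' @return named character vector of sequences (first header token as
#'   name).
#' @export
readProteinFasta <- function(path, nonCanonical = c("error", "skip"),
                             minLength = 10L) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- screenCanonical(seqs, policy = match.arg(nonCanonical))
  short <- nchar(seqs) < minLength
  if (any(short)) {
    warning("dropping ", sum(short), " sequence(s) shorter than ",
            minLength, " residues")
    seqs <- seqs[!short]
  }
  if (length(seqs) == 0L) stop("no sequences left after filtering: ", path)
  seqs
}

#' Read a per-residue pLDDT table
#'
#' Accepts a TSV with columns protein_id, position, plddt (header
#' required) or a JSON object mapping protein ids to numeric vectors.
#'
#' @param path file path (.tsv/.txt or .json).
#' @return named list of numeric pLDDT vectors, one per protein, ordered
#'   by position.
#' @export
readPlddt <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(lapply(obj, as.numeric))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "plddt")
  if (!all(need %in% names(tab)))
    stop("pLDDT table must have columns: ", paste(need, collapse = ", "))
  lapply(split(tab, tab$protein_id),
         function(d) d$plddt[order(d$position)])
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write the standard output files of a capture run
#'
#' Creates \code{consensus.tsv} (rank, kmer, k, raw_score, s_k, score),
#' one \code{mappings/<rank>_<kmer>.tsv} and one
#' \code{pssm/<rank>_<kmer>.tsv} per reported consensus k-mer (1-based
#' inclusive coordinates throughout), and \code{manifest.json}
#' recording the configuration, seed, package version and input
#' checksum. The manifest deliberately carries no wall-clock timestamp
#' so reruns with identical inputs are byte-identical.
#'
#' @param run a \linkS4class{CaptureRun}.
#' @param dir output directory (created if needed).
#' @param topN how many consensus k-mers to report (defaults to the
#'   run's configured topN).
#' @param seed seed recorded in the manifest (informational).
#' @return \code{dir}, invisibly.
#' @export
writeCaptureRun <- function(run, dir, topN = NULL, seed = NULL) {
  if (is.null(topN)) topN <- run@config$topN
  dir.create(file.path(dir, "mappings"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "pssm"), showWarnings = FALSE)
  cons <- utils::head(run@consensus, topN)
  .writeTsv(cons, file.path(dir, "consensus.tsv"))
  for (r in seq_len(nrow(cons))) {
    m <- motifMappings(run, r)
    stem <- sprintf("%d_%s.tsv", r, cons$kmer[r])
    if (!is.null(m) && nrow(m)) {
      .writeTsv(m[, c("sequence_id", "mapped_kmer", "start", "end")],
                file.path(dir, "mappings", stem))
      P <- probabilityMatrix(m)
      .writeTsv(data.frame(position = seq_len(nrow(P)), P,
                           check.names = FALSE),
                file.path(dir, "pssm", stem))
    }
  }
  manifest <- list(
    tool = "kcapture",
    version = as.character(utils::packageVersion("kcapture")),
    seed = seed,
    config = run@config,
    n_sequences = length(run@sequences),
    sequence_ids = names(run@sequences),
    input_md5 = .sequenceChecksum(run@sequences),
    search_space = as.list(run@searchSpace))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

# md5 of the canonical "id\tsequence" rendering of the input set
.sequenceChecksum <- function(seqs) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(seqs), seqs, sep = "\t"), f)
  unname(tools::md5sum(f))
}

#' Read back a consensus table written by [writeCaptureRun()]
#'
#' @param dir run output directory.
#' @return the consensus data.frame.
#' @export
readConsensus <- function(dir)
  utils::read.delim(file.path(dir, "consensus.tsv"),
                    stringsAsFactors = FALSE)
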