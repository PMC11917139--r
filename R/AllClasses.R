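#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib kcapture, .registration = TRUE
NULL

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes, in alphabetical order.
#' All sequence containers in this package are restricted to this alphabet.
#'
#' @export
AA_CANONICAL <- c("A","C","D","E","F","G","H","I","K","L",
                  "M","N","P","Q","R","S","T","V","W","Y")

#' Amino-acid distance matrix
#'
#' A validated 20 x 20 symmetric matrix of non-negative physicochemical
#' distances between the canonical amino acids (zero diagonal). The bundled
#' default is Grantham's (1974) distance, which combines side-chain
#' composition, polarity and volume; its maximum is 215 (Cys-Trp).
#'
#' @slot matrix numeric 20 x 20 matrix with amino-acid dimnames.
#' @slot name identifier of the matrix (e.g. \code{"grantham"}).
#'
#' @seealso [granthamDistance()], [readDistanceMatrix()],
#'   [distanceToSimilarity()]
#' @export
setClass("AADistanceMatrix",
         representation(matrix = "matrix", name = "character"))

setValidity("AADistanceMatrix", function(object) {
  m <- object@matrix
  if (!is.numeric(m) || nrow(m) != 20L || ncol(m) != 20L)
    return("matrix must be numeric 20 x 20")
  lab <- rownames(m)
  if (is.null(lab) || !identical(lab, colnames(m)))
    return("row and column labels must be present and identical")
  missing <- setdiff(AA_CANONICAL, lab)
  extra <- setdiff(lab, AA_CANONICAL)
  if (length(missing) || length(extra))
    return(sprintf("labels must be the 20 canonical residues (missing: %s; extra: %s)",
                   paste(missing, collapse = ","), paste(extra, collapse = ",")))
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    return(sprintf("negative distance at (%s,%s)",
                   lab[neg[1, 1]], lab[neg[1, 2]]))
  asym <- which(abs(m - t(m)) > 1e-9, arr.ind = TRUE)
  if (nrow(asym))
    return(sprintf("matrix not symmetric at (%s,%s)",
                   lab[asym[1, 1]], lab[asym[1, 2]]))
  if (any(diag(m) != 0))
    return(sprintf("diagonal must be zero (offender: %s)",
                   lab[which(diag(m) != 0)[1]]))
  TRUE
})

#' Amino-acid similarity matrix
#'
#' Per-residue similarities in [0, 1] derived from an
#' \linkS4class{AADistanceMatrix}: identity scores exactly 1 and the most
#' distant pair scores 0. This is the score averaged position-wise to
#' compare k-mers.
#'
#' @slot matrix numeric 20 x 20 matrix in [0, 1] with unit diagonal.
#' @slot name identifier of the parent distance matrix.
#'
#' @seealso [distanceToSimilarity()], [granthamSimilarity()]
#' @export
setClass("AASimilarityMatrix",
         representation(matrix = "matrix", name = "character"))

setValidity("AASimilarityMatrix", function(object) {
  m <- object@matrix
  if (!is.numeric(m) || nrow(m) != 20L || ncol(m) != 20L)
    return("matrix must be numeric 20 x 20")
  if (!identical(rownames(m), colnames(m)) ||
      length(setdiff(AA_CANONICAL, rownames(m))))
    return("labels must be the 20 canonical residues")
  if (any(m < -1e-12) || any(m > 1 + 1e-12))
    return("similarities must lie in [0, 1]")
  if (any(diag(m) != 1))
    return("diagonal must be exactly 1")
  if (max(abs(m - t(m))) > 1e-12)
    return("matrix must be symmetric")
  TRUE
})

#' Per-sequence k-mer table
#'
#' Sliding-window decomposition of one protein sequence into overlapping
#' k-mers, with per-k-mer occurrence counts and 1-based start positions.
#' The counts sum to L - k + 1 for a sequence of length L.
#'
#' @slot sequenceId sequence identifier.
#' @slot k window length.
#' @slot kmers unique k-mer strings, in order of first occurrence.
#' @slot freq integer occurrence counts, parallel to \code{kmers}.
#' @slot positions list of integer vectors of 1-based start coordinates,
#'   parallel to \code{kmers}.
#'
#' @seealso [kmerTable()]
#' @export
setClass("KmerTable",
         representation(sequenceId = "character", k = "integer",
                        kmers = "character", freq = "integer",
                        positions = "list"))

setValidity("KmerTable", function(object) {
  if (length(object@kmers) != length(object@freq) ||
      length(object@kmers) != length(object@positions))
    return("kmers, freq and positions must be parallel")
  if (length(object@kmers) && any(nchar(object@kmers) != object@k))
    return("all k-mers must have length k")
  if (any(object@freq < 1L))
    return("frequencies must be >= 1")
  if (!all(lengths(object@positions) == object@freq))
    return("positions must list one start per occurrence")
  TRUE
})

#' A completed motif-capture run
#'
#' Holds the input sequences, the run configuration, the pooled search
#' space S_k per k-mer length, the reciprocal best-match events of every
#' sequence pair, and the ranked consensus k-mer table. Created by
#' [captureMotifs()]; interrogate with [consensusKmers()],
#' [motifMappings()], [probabilityMatrix()] and [searchSpace()].
#'
#' @slot sequences named character vector of input sequences.
#' @slot config list snapshot of the run parameters.
#' @slot consensus data.frame with columns rank, kmer, k, raw_score, s_k,
#'   score (full ranking; truncate for reporting with \code{topN}).
#' @slot events per-k list of data.frames of reciprocal best-match events
#'   (seq_i, seq_j, kmer_i, kmer_j, w).
#' @slot searchSpace named integer vector, S_k per k.
#'
#' @export
setClass("CaptureRun",
         representation(sequences = "character", config = "list",
                        consensus = "data.frame", events = "list",
                        searchSpace = "integer"))

#' Order/disorder segmentation of one protein
#'
#' Tiling of a protein into ordered and disordered segments derived from a
#' smoothed pLDDT track, plus the subset of disordered segments long
#' enough (>= 30 residues by default) to count as intrinsically
#' disordered regions (IDRs).
#'
#' @slot proteinId protein identifier.
#' @slot segments data.frame(start, end, label) tiling the protein;
#'   label is "ordered" or "disordered".
#' @slot idrs data.frame(start, end) of disordered segments passing the
#'   minimum-length rule.
#'
#' @seealso [segmentDisorder()], [extractIdrs()]
#' @export
setClass("DisorderSegmentation",
         representation(proteinId = "character", segments = "data.frame",
                        idrs = "data.frame"))

setValidity("DisorderSegmentation", function(object) {
  s <- object@segments
  if (nrow(s)) {
    if (s$start[1] != 1L) return("segments must start at residue 1")
    if (any(s$start[-1] != s$end[-nrow(s)] + 1L))
      return("segments must tile the protein without gaps or overlaps")
    if (!all(s$label %in% c("ordered", "disordered")))
      return("labels must be 'ordered' or 'disordered'")
  }
  TRUE
})
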