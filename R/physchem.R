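#' Bundled Grantham amino-acid distance matrix
#'
#' Returns the Grantham (1974) physicochemical distance matrix as a
#' validated \linkS4class{AADistanceMatrix}. Distances combine side-chain
#' composition, polarity and molecular volume; the scale runs from 5
#' (Leu-Ile, the most similar pair) to 215 (Cys-Trp, the most dissimilar).
#'
#' @return An \linkS4class{AADistanceMatrix} named \code{"grantham"}.
#' @examples
#' g <- granthamDistance()
#' distanceValues(g)["L", "I"]   # 5
#' @export
granthamDistance <- function() {
  path <- system.file("extdata", "grantham.tsv", package = "kcapture",
                      mustWork = TRUE)
  readDistanceMatrix(path, name = "grantham")
}

#' Read an amino-acid distance matrix from file
#'
#' Reads a labeled, whitespace- or tab-delimited square table over the 20
#' canonical residues (first row and first column are residue letters) and
#' validates it: symmetric, zero diagonal, non-negative, exactly the
#' canonical alphabet. Any matrix satisfying these invariants may replace
#' the default Grantham table.
#'
#' @param path path to the table, or the built-in name \code{"grantham"}.
#' @param name identifier stored with the matrix; defaults to the file
#'   base name.
#' @return An \linkS4class{AADistanceMatrix}.
#' @export
readDistanceMatrix <- function(path, name = NULL) {
  if (identical(path, "grantham")) return(granthamDistance())
  tab <- utils::read.table(path, header = TRUE, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m))
    stop("distance matrix must be square, got ", nrow(m), " x ", ncol(m))
  storage.mode(m) <- "double"
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  new("AADistanceMatrix",
      matrix = m[order(rownames(m)), order(colnames(m)), drop = FALSE],
      name = name)
}

#' @rdname granthamDistance
#' @param x an \linkS4class{AADistanceMatrix} or
#'   \linkS4class{AASimilarityMatrix}.
#' @export
distanceValues <- function(x) x@matrix

#' @rdname distanceToSimilarity
#' @export
similarityValues <- function(x) x@matrix

#' Convert distances to per-residue similarities
#'
#' Maps a distance matrix D' onto similarity scores
#' \deqn{D(a,b) = 1 - D'(a,b) / \max(D')}
#' so that identical residues score exactly 1 and the most distant pair
#' scores 0 (min-max scaling). For the bundled Grantham matrix the
#' divisor is 215. The normalization is pluggable: supply any function
#' mapping a non-negative matrix with zero diagonal onto [0, 1] with unit
#' diagonal to experiment with alternatives without touching downstream
#' code.
#'
#' @param dm an \linkS4class{AADistanceMatrix}.
#' @param normalize function from the raw distance matrix to a similarity
#'   matrix; the default implements min-max scaling.
#' @return An \linkS4class{AASimilarityMatrix}.
#' @examples
#' sm <- distanceToSimilarity(granthamDistance())
#' similarityValues(sm)["L", "I"]   # 1 - 5/215
#' @export
distanceToSimilarity <- function(dm, normalize = NULL) {
  stopifnot(is(dm, "AADistanceMatrix"))
  m <- dm@matrix
  if (is.null(normalize)) {
    mx <- max(m)
    if (mx == 0) stop("degenerate distance matrix: all entries are zero")
    s <- 1 - m / mx
  } else {
    s <- normalize(m)
  }
  diag(s) <- 1
  new("AASimilarityMatrix", matrix = s, name = dm@name)
}

#' @rdname distanceToSimilarity
#' @details `granthamSimilarity()` is a memoized shorthand for
#'   `distanceToSimilarity(granthamDistance())`, the default scoring
#'   scheme of the whole package.
#' @export
granthamSimilarity <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- distanceToSimilarity(granthamDistance())
    cache
  }
})

#' Screen sequences for non-canonical residues
#'
#' @param seqs named character vector of protein sequences.
#' @param policy \code{"error"} aborts naming the first offending
#'   sequence; \code{"skip"} drops offending sequences with a warning
#'   (mirrors curation that removes motifs with undefined or
#'   non-canonical amino acids).
#' @return the (possibly filtered) named character vector.
#' @export
screenCanonical <- function(seqs, policy = c("error", "skip")) {
  policy <- match.arg(policy)
  ok <- !grepl(sprintf("[^%s]", paste(AA_CANONICAL, collapse = "")), seqs)
  if (all(ok)) return(seqs)
  bad <- names(seqs)[!ok]
  if (is.null(bad)) bad <- which(!ok)
  if (policy == "error")
    stop("non-canonical residues in sequence(s): ",
         paste(bad, collapse = ", "))
  warning("dropping ", sum(!ok), " sequence(s) with non-canonical residues: ",
          paste(bad, collapse = ", "))
  seqs[ok]
}

#' @describeIn AADistanceMatrix-class compact display
#' @param object an \linkS4class{AADistanceMatrix}.
#' @export
setMethod("show", "AADistanceMatrix", function(object) {
  cat("AADistanceMatrix '", object@name, "': 20 x 20, range [",
      min(object@matrix), ", ", max(object@matrix), "]\n", sep = "")
})

#' @describeIn AASimilarityMatrix-class compact display
#' @param object an \linkS4class{AASimilarityMatrix}.
#' @export
setMethod("show", "AASimilarityMatrix", function(object) {
  off <- object@matrix[upper.tri(object@matrix)]
  cat("AASimilarityMatrix '", object@name,
      "': 20 x 20, off-diagonal range [",
      signif(min(off), 4), ", ", signif(max(off), 4), "]\n", sep = "")
})
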