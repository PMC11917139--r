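#' Decompose a sequence into overlapping k-mers
#'
#' Slides a window of length k along the sequence and records every
#' window with its occurrence count and 1-based start positions. All
#' L - k + 1 windows are counted, so the frequencies always sum to
#' L - k + 1. Overlapping occurrences are counted independently.
#'
#' @param seq a single protein sequence (character scalar).
#' @param k window length, 1 <= k.
#' @param id sequence identifier stored in the table.
#' @return A \linkS4class{KmerTable}; empty (with a warning) when
#'   \code{k > nchar(seq)} — the sequence is simply skipped for this k.
#' @examples
#' tab <- kmerTable("AAAA", 3)
#' kmerFreq(tab)        # AAA = 2
#' @export
kmerTable <- function(seq, k, id = "seq") {
  stopifnot(length(seq) == 1L, k >= 1L)
  k <- as.integer(k)
  L <- nchar(seq)
  if (k > L) {
    warning("k = ", k, " exceeds length of sequence '", id,
            "' (", L, "); skipped")
    return(new("KmerTable", sequenceId = id, k = k,
               kmers = character(), freq = integer(), positions = list()))
  }
  starts <- seq_len(L - k + 1L)
  kms <- substring(seq, starts, starts + k - 1L)
  uniq <- unique(kms)
  pos <- split(starts, factor(kms, levels = uniq))
  new("KmerTable", sequenceId = id, k = k, kmers = uniq,
      freq = lengths(pos), positions = unname(as.list(pos)))
}

#' @rdname kmerTable
#' @param x a \linkS4class{KmerTable}.
#' @export
kmerFreq <- function(x) stats::setNames(x@freq, x@kmers)

#' @rdname kmerTable
#' @export
kmerPositions <- function(x) stats::setNames(x@positions, x@kmers)

#' Physicochemical similarity of two equal-length k-mers
#'
#' The similarity w of k-mers x and y is the mean of their position-wise
#' residue similarities:
#' \deqn{w(x, y) = \frac{1}{k} \sum_{p=1}^{k} D(x_p, y_p)}
#' where D is a per-residue similarity in [0, 1] (see
#' [distanceToSimilarity()]). Identical k-mers score exactly 1; the score
#' is symmetric. Similarity is defined only within one k: unequal lengths
#' are an error.
#'
#' @param x,y k-mer strings of equal length.
#' @param sm an \linkS4class{AASimilarityMatrix}.
#' @return w in [0, 1].
#' @examples
#' kmerSimilarity("LIV", "IIV", granthamSimilarity())  # (1-5/215 + 1 + 1)/3
#' @export
kmerSimilarity <- function(x, y, sm = granthamSimilarity()) {
  if (nchar(x) != nchar(y))
    stop("k-mer similarity is defined only for equal lengths (",
         nchar(x), " vs ", nchar(y), ")")
  a <- strsplit(x, "", fixed = TRUE)[[1]]
  b <- strsplit(y, "", fixed = TRUE)[[1]]
  mean(sm@matrix[cbind(a, b)])
}

# Integer-encode the unique k-mers of a table as an n x k matrix of
# 1-based indices into the similarity matrix labels.
.encodeKmers <- function(tab, labels) {
  n <- length(tab@kmers)
  k <- tab@k
  if (n == 0L) return(matrix(integer(), 0L, k))
  chars <- matrix(unlist(strsplit(tab@kmers, "", fixed = TRUE),
                         use.names = FALSE), nrow = n, byrow = TRUE)
  matrix(match(chars, labels), nrow = n)
}

#' Pairwise k-mer similarity matrix of two sequences
#'
#' Compares all unique k-mers of sequence a against all unique k-mers of
#' sequence b, giving the complete |a| x |b| matrix M of similarities w.
#'
#' @param ta,tb \linkS4class{KmerTable}s with equal k.
#' @param sm an \linkS4class{AASimilarityMatrix}.
#' @return numeric matrix with the k-mers of \code{ta} as rownames and of
#'   \code{tb} as colnames; empty (with a message) if either table is
#'   empty.
#' @export
pairSimilarityMatrix <- function(ta, tb, sm = granthamSimilarity()) {
  if (ta@k != tb@k)
    stop("k-mer tables have different k (", ta@k, " vs ", tb@k, ")")
  lab <- rownames(sm@matrix)
  A <- .encodeKmers(ta, lab)
  B <- .encodeKmers(tb, lab)
  if (nrow(A) == 0L || nrow(B) == 0L) {
    message("empty k-mer table; returning empty similarity matrix")
    return(matrix(numeric(), nrow(A), nrow(B),
                  dimnames = list(ta@kmers, tb@kmers)))
  }
  S <- sm@matrix
  W <- matrix(0, nrow(A), nrow(B))
  for (p in seq_len(ta@k))
    W <- W + S[A[, p], B[, p], drop = FALSE]
  W <- W / ta@k
  dimnames(W) <- list(ta@kmers, tb@kmers)
  W
}

#' Frequency tie-break statistic for equally similar best matches
#'
#' When several candidate k-mers are equally similar to a query, the one
#' with the lowest LD value wins, where
#' \deqn{LD(q_i, t_j) = \frac{2 (q_i^2 + t_j^2)}{q_i + t_j}}
#' and q_i, t_j are the occurrence frequencies of the query and the
#' candidate. Lower LD favours candidate frequencies close to (and as
#' small as) the query's. Remaining ties are broken lexicographically on
#' the candidate k-mer so results are fully deterministic.
#'
#' @param q,t positive occurrence frequencies.
#' @return LD value (>= 0).
#' @examples
#' kmerFrequencyLD(1, 1)  # 2
#' kmerFrequencyLD(1, 3)  # 5
#' @export
kmerFrequencyLD <- function(q, t) 2 * (q^2 + t^2) / (q + t)

# Select, for each row of W, the best column under (max w, min LD,
# lexicographically smallest target). Vectorized; `lexRank` ranks the
# column k-mers alphabetically. Returns integer column indices.
.bestPerRow <- function(W, qRow, tCol, lexRank) {
  nr <- nrow(W); nc <- ncol(W)
  rowMax <- do.call(pmax, lapply(seq_len(nc), function(j) W[, j]))
  isMax <- W == rowMax
  LD <- matrix(kmerFrequencyLD(rep(qRow, nc), rep(tCol, each = nr)), nr, nc)
  LD[!isMax] <- Inf
  rowMinLD <- do.call(pmin, lapply(seq_len(nc), function(j) LD[, j]))
  cand <- isMax & (LD == rowMinLD)
  LR <- matrix(rep(lexRank, each = nr), nr, nc)
  LR[!cand] <- Inf
  rowMinLR <- do.call(pmin, lapply(seq_len(nc), function(j) LR[, j]))
  max.col(LR == rowMinLR, ties.method = "first")
}

#' Best matches between the k-mers of two sequences
#'
#' For every k-mer (row and column of M) selects the single most similar
#' k-mer of the other sequence. Ties on w are broken by the lowest
#' [kmerFrequencyLD()] value computed from the two k-mers' occurrence
#' frequencies, then lexicographically on the target k-mer.
#'
#' @param m similarity matrix from [pairSimilarityMatrix()].
#' @param ta,tb the \linkS4class{KmerTable}s the matrix was built from.
#' @return data.frame(source_kmer, target_kmer, w, ld, direction) with
#'   one row per source k-mer in each direction ("ab" rows of \code{ta},
#'   "ba" rows of \code{tb}).
#' @export
bestMatches <- function(m, ta, tb) {
  if (nrow(m) == 0L || ncol(m) == 0L)
    return(data.frame(source_kmer = character(), target_kmer = character(),
                      w = numeric(), ld = numeric(), direction = character()))
  lexB <- match(tb@kmers, sort(tb@kmers))
  lexA <- match(ta@kmers, sort(ta@kmers))
  jb <- .bestPerRow(m, ta@freq, tb@freq, lexB)
  ja <- .bestPerRow(t(m), tb@freq, ta@freq, lexA)
  rbind(
    data.frame(source_kmer = ta@kmers, target_kmer = tb@kmers[jb],
               w = m[cbind(seq_along(jb), jb)],
               ld = kmerFrequencyLD(ta@freq, tb@freq[jb]),
               direction = "ab", stringsAsFactors = FALSE),
    data.frame(source_kmer = tb@kmers, target_kmer = ta@kmers[ja],
               w = m[cbind(ja, seq_along(ja))],
               ld = kmerFrequencyLD(tb@freq, ta@freq[ja]),
               direction = "ba", stringsAsFactors = FALSE))
}

#' Reciprocal best matches between two sequences
#'
#' Intersects the two directions of [bestMatches()]: a k-mer pair (x, y)
#' is reciprocal when x's best match is y and y's best match is x — the
#' row and column maxima of M intersect. Reciprocal pairs are the unit of
#' conservation evidence counted by the capture engine.
#'
#' @param matches data.frame from [bestMatches()] (both directions).
#' @return data.frame(kmer_a, kmer_b, w), one row per reciprocal pair;
#'   kmer_a belongs to the first sequence.
#' @export
reciprocalBestMatches <- function(matches) {
  ab <- matches[matches$direction == "ab", , drop = FALSE]
  ba <- matches[matches$direction == "ba", , drop = FALSE]
  back <- ba$target_kmer[match(ab$target_kmer, ba$source_kmer)]
  keep <- !is.na(back) & back == ab$source_kmer
  data.frame(kmer_a = ab$source_kmer[keep], kmer_b = ab$target_kmer[keep],
             w = ab$w[keep], stringsAsFactors = FALSE)
}

#' @describeIn KmerTable-class compact display
#' @param object a \linkS4class{KmerTable}.
#' @export
setMethod("show", "KmerTable", function(object) {
  cat("KmerTable for '", object@sequenceId, "': k = ", object@k, ", ",
      length(object@kmers), " unique k-mers, ",
      sum(object@freq), " windows\n", sep = "")
})
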