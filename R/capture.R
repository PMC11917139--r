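#' Enumerate unordered sequence pairs, self-pairs included
#'
#' The all-vs-all comparison is symmetric, so each unordered pair is
#' compared once; self-comparisons are included. For n sequences this is
#' exactly n(n+1)/2 comparisons.
#'
#' @param n number of sequences (>= 1).
#' @return data.frame(i, j) with i <= j, one row per pair.
#' @examples
#' nrow(enumeratePairs(3))  # 6
#' @export
enumeratePairs <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("empty input set: n must be >= 1")
  n <- as.integer(n)
  idx <- which(upper.tri(matrix(0L, n, n), diag = TRUE), arr.ind = TRUE)
  data.frame(i = idx[, 1L], j = idx[, 2L])[order(idx[, 1L], idx[, 2L]), ,
                                           drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Cross-k weighting of raw reciprocal-hit counts
#'
#' Raw reciprocal-hit counts are only comparable within one k-mer length:
#' longer k-mers have a larger pool of unique k-mers to match against, so
#' a reciprocal hit is intrinsically rarer. The raw count is therefore
#' multiplied by a weighting factor that scales with the "search space"
#' S_k, the number of unique k-mers of length k pooled over the whole
#' input set. The default factor is S_k / 2 (a reciprocal hit's baseline
#' probability scales roughly as 1/S_k, making the product comparable
#' across k); \code{variant = "squared"} uses S_k^2 instead.
#'
#' @param raw raw reciprocal-hit count (>= 0).
#' @param s_k search-space size (>= 1).
#' @param variant \code{"half"} (default) or \code{"squared"}.
#' @return weighted capture score.
#' @export
weightScore <- function(raw, s_k, variant = c("half", "squared")) {
  variant <- match.arg(variant)
  if (any(s_k < 1)) stop("search space S_k must be >= 1")
  switch(variant, half = raw * s_k / 2, squared = raw * s_k^2)
}

# Reciprocal best-match events for one sequence pair at one k, via the
# compiled kernel. Self-comparisons reduce to each k-mer matching itself.
.pairEvents <- function(ta, tb, enc, sm) {
  A <- enc[[ta@sequenceId]]; B <- enc[[tb@sequenceId]]
  res <- .Call_best_match(A, B, sm,
                          ta@freq, tb@freq,
                          match(ta@kmers, sort(ta@kmers)),
                          match(tb@kmers, sort(tb@kmers)))
  i <- seq_len(nrow(A))
  rec <- res$colBest[res$rowBest] == i
  list(kmer_a = ta@kmers[rec], kmer_b = tb@kmers[res$rowBest[rec]],
       w = res$rowW[rec])
}

#' Detect conserved consensus k-mers in a set of related sequences
#'
#' The core capture algorithm. Each sequence is decomposed into
#' overlapping k-mers for every k in \code{kMin..kMax}. For every
#' unordered pair of sequences (self-pairs included; n(n+1)/2 pairs) all
#' unique k-mers are compared by mean position-wise physicochemical
#' similarity, each k-mer's single best match in the other sequence is
#' selected (ties broken by lowest [kmerFrequencyLD()], then
#' lexicographically), and reciprocal best-match pairs are recorded. A
#' k-mer's raw score is the number of reciprocal events it appears in
#' across all pairs; multiplying by the search-space weight
#' ([weightScore()]) gives the capture score, comparable across k.
#' Consensus k-mers are ranked by descending score, ties broken by larger
#' k then lexicographically.
#'
#' Sequences shorter than a given k are skipped for that k with a
#' warning. The result is independent of the input order of the
#' sequences and of \code{processes}.
#'
#' @param x sequences: a named character vector, a
#'   \code{Biostrings::AAStringSet}, or a path handled by
#'   [readProteinFasta()] upstream.
#' @param kMin,kMax k-mer length range (defaults 3 and 10).
#' @param topN number of consensus k-mers reported by [topConsensus()]
#'   and [writeCaptureRun()]; the full ranking is retained internally.
#' @param similarity an \linkS4class{AASimilarityMatrix}.
#' @param weighting search-space weighting variant, see [weightScore()].
#' @param scoreBy \code{"count"} (default; raw score = number of
#'   reciprocal events) or \code{"similarity"} (events weighted by w).
#' @param processes workers for the pair loop (forked; results are
#'   bitwise identical for any value).
#' @return A \linkS4class{CaptureRun}.
#' @examples
#' set.seed(1)
#' sim <- simulateOrthologSet("DEWFM", nSequences = 4, seqLength = 40)
#' run <- captureMotifs(sim$sequences, kMin = 3, kMax = 6)
#' head(consensusKmers(run), 3)
#' @export
captureMotifs <- function(x, kMin = 3L, kMax = 10L, topN = 10L,
                          similarity = granthamSimilarity(),
                          weighting = c("half", "squared"),
                          scoreBy = c("count", "similarity"),
                          processes = 1L) {
  weighting <- match.arg(weighting)
  scoreBy <- match.arg(scoreBy)
  seqs <- .asSequences(x)
  if (length(seqs) == 0L) stop("empty input set")
  stopifnot(kMin >= 1L, kMin <= kMax, topN >= 1L)
  seqs <- screenCanonical(seqs, policy = "error")
  sm <- similarity@matrix
  lab <- rownames(sm)

  events <- list()
  sk <- integer(0)
  for (k in seq(kMin, kMax)) {
    keep <- nchar(seqs) >= k
    if (!all(keep))
      warning(sum(!keep), " sequence(s) shorter than k = ", k, " skipped")
    if (!any(keep)) next
    ids <- names(seqs)[keep]
    tabs <- lapply(ids, function(id) kmerTable(seqs[[id]], k, id = id))
    names(tabs) <- ids
    enc <- lapply(tabs, .encodeKmers, labels = lab)
    sk[as.character(k)] <- length(unique(unlist(lapply(tabs, slot, "kmers"),
                                                use.names = FALSE)))
    pairs <- enumeratePairs(length(ids))
    worker <- function(p) {
      ev <- .pairEvents(tabs[[pairs$i[p]]], tabs[[pairs$j[p]]], enc, sm)
      ev$seq_i <- rep(ids[pairs$i[p]], length(ev$w))
      ev$seq_j <- rep(ids[pairs$j[p]], length(ev$w))
      ev
    }
    res <- if (processes > 1L)
      parallel::mclapply(seq_len(nrow(pairs)), worker, mc.cores = processes)
    else lapply(seq_len(nrow(pairs)), worker)
    events[[as.character(k)]] <- data.frame(
      seq_i = unlist(lapply(res, `[[`, "seq_i"), use.names = FALSE),
      seq_j = unlist(lapply(res, `[[`, "seq_j"), use.names = FALSE),
      kmer_i = unlist(lapply(res, `[[`, "kmer_a"), use.names = FALSE),
      kmer_j = unlist(lapply(res, `[[`, "kmer_b"), use.names = FALSE),
      w = unlist(lapply(res, `[[`, "w"), use.names = FALSE),
      stringsAsFactors = FALSE)
  }

  consensus <- .rankConsensus(events, sk, weighting, scoreBy)
  new("CaptureRun", sequences = seqs,
      config = list(kMin = as.integer(kMin), kMax = as.integer(kMax),
                    topN = as.integer(topN), matrix = similarity@name,
                    weighting = weighting, scoreBy = scoreBy),
      consensus = consensus, events = events, searchSpace = sk)
}

# Aggregate reciprocal events into the ranked consensus table. A k-mer
# appearing on both sides of one event (self-matches) counts once.
.rankConsensus <- function(events, sk, weighting, scoreBy) {
  rows <- lapply(names(events), function(kc) {
    ev <- events[[kc]]
    if (nrow(ev) == 0L) return(NULL)
    km <- c(ev$kmer_i, ev$kmer_j[ev$kmer_j != ev$kmer_i])
    raw <- if (scoreBy == "count") {
      tab <- table(km)
      stats::setNames(as.numeric(tab), names(tab))
    } else {
      wt <- c(ev$w, ev$w[ev$kmer_j != ev$kmer_i])
      # sort before summing so the result is permutation-invariant
      vapply(split(wt, km), function(v) sum(sort(v)), numeric(1))
    }
    data.frame(kmer = names(raw), k = nchar(names(raw)[1]),
               raw_score = unname(raw), s_k = sk[[kc]],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0L)
    return(data.frame(rank = integer(), kmer = character(), k = integer(),
                      raw_score = numeric(), s_k = integer(),
                      score = numeric()))
  tab$score <- weightScore(tab$raw_score, tab$s_k, weighting)
  tab <- tab[order(-tab$score, -tab$k, tab$kmer), , drop = FALSE]
  tab <- data.frame(rank = seq_len(nrow(tab)), tab, row.names = NULL)
  tab[, c("rank", "kmer", "k", "raw_score", "s_k", "score")]
}

.asSequences <- function(x) {
  if (inherits(x, "AAStringSet") || inherits(x, "XStringSet")) {
    s <- as.character(x)
    names(s) <- names(x)
  } else if (is.character(x)) {
    s <- x
  } else stop("cannot interpret 'x' as protein sequences")
  if (is.null(names(s)) || anyDuplicated(names(s)))
    stop("sequences must carry unique names")
  s
}

#' @rdname captureMotifs
#' @param run a \linkS4class{CaptureRun}.
#' @return `consensusKmers()`: the full ranked consensus data.frame
#'   (rank, kmer, k, raw_score, s_k, score).
#' @export
consensusKmers <- function(run) run@consensus

#' @rdname captureMotifs
#' @param n number of top consensus k-mers (defaults to the run's topN).
#' @export
topConsensus <- function(run, n = NULL) {
  if (is.null(n)) n <- run@config$topN
  utils::head(run@consensus, n)
}

#' @rdname captureMotifs
#' @export
searchSpace <- function(run) run@searchSpace

#' @rdname captureMotifs
#' @export
sequenceSet <- function(run) run@sequences

#' Map a consensus k-mer back onto the input sequences
#'
#' For each sequence, gathers all reciprocal events that pair the
#' consensus k-mer with a k-mer of that sequence and picks the partner
#' k-mer string with the highest event count (ties: higher mean w to the
#' consensus, then lexicographically smaller). All occurrence positions
#' of the chosen partner are reported — when there are multiple equally
#' similar matches in a sequence, every position is returned. Sequences
#' sharing no reciprocal event with the consensus contribute no rows.
#'
#' @param run a \linkS4class{CaptureRun}.
#' @param consensus consensus k-mer string, or an integer rank into
#'   [consensusKmers()]; default rank 1.
#' @return data.frame(consensus, sequence_id, mapped_kmer, start, end,
#'   support) with 1-based inclusive coordinates.
#' @export
motifMappings <- function(run, consensus = 1L) {
  if (is.numeric(consensus)) {
    if (nrow(run@consensus) < consensus)
      stop("no consensus k-mer at rank ", consensus)
    consensus <- run@consensus$kmer[consensus]
  }
  k <- nchar(consensus)
  ev <- run@events[[as.character(k)]]
  out <- lapply(names(run@sequences), function(id) {
    .mapOne(run, consensus, ev, id)
  })
  do.call(rbind, out)
}

.mapOne <- function(run, consensus, ev, id) {
  if (is.null(ev) || nrow(ev) == 0L) return(NULL)
  hit1 <- ev$kmer_i == consensus & ev$seq_j == id
  hit2 <- ev$kmer_j == consensus & ev$seq_i == id
  partners <- c(ev$kmer_j[hit1], ev$kmer_i[hit2])
  ws <- c(ev$w[hit1], ev$w[hit2])
  # a self-match event (kmer_i == kmer_j == consensus within the self
  # pair) satisfies both filters but is a single event
  dupSelf <- hit1 & hit2
  if (any(dupSelf)) {
    drop <- length(ev$w[hit1]) + which(dupSelf[hit2])
    partners <- partners[-drop]
    ws <- ws[-drop]
  }
  if (length(partners) == 0L) return(NULL)
  support <- table(partners)
  topCount <- max(support)
  cand <- names(support)[support == topCount]
  if (length(cand) > 1L) {
    meanW <- vapply(cand, function(p) mean(sort(ws[partners == p])),
                    numeric(1))
    cand <- cand[meanW == max(meanW)]
    cand <- sort(cand)[1L]
  }
  seqStr <- run@sequences[[id]]
  k <- nchar(consensus)
  starts <- seq_len(nchar(seqStr) - k + 1L)
  occ <- starts[substring(seqStr, starts, starts + k - 1L) == cand]
  if (length(occ) == 0L) return(NULL)
  data.frame(consensus = consensus, sequence_id = id, mapped_kmer = cand,
             start = occ, end = occ + k - 1L,
             support = as.integer(topCount), stringsAsFactors = FALSE)
}

#' Position probability matrix of a mapped consensus k-mer
#'
#' Empirical residue probabilities at each of the k positions across the
#' mapped k-mers (one vote per mapping row). Rows are positions, columns
#' the 20 canonical residues; each row sums to 1.
#'
#' @param mappings data.frame from [motifMappings()] (all mapped k-mers
#'   must share one length).
#' @return k x 20 numeric matrix.
#' @export
probabilityMatrix <- function(mappings) {
  if (is.null(mappings) || nrow(mappings) == 0L)
    stop("nothing to summarize: no mappings supplied")
  kms <- mappings$mapped_kmer
  k <- unique(nchar(kms))
  if (length(k) != 1L) stop("mapped k-mers must share one length")
  chars <- matrix(unlist(strsplit(kms, "", fixed = TRUE)),
                  nrow = length(kms), byrow = TRUE)
  P <- t(apply(chars, 2, function(col)
    table(factor(col, levels = AA_CANONICAL)) / length(col)))
  P <- matrix(P, nrow = k, dimnames = list(NULL, AA_CANONICAL))
  P
}

#' @describeIn CaptureRun-class run summary with the top consensus table
#' @param object a \linkS4class{CaptureRun}.
#' @export
setMethod("show", "CaptureRun", function(object) {
  cat("CaptureRun: ", length(object@sequences), " sequences, k = ",
      object@config$kMin, "..", object@config$kMax, ", matrix '",
      object@config$matrix, "', weighting '", object@config$weighting,
      "'\n", sep = "")
  if (nrow(object@consensus)) {
    cat("Top consensus k-mers:\n")
    print(utils::head(object@consensus, min(5L, object@config$topN)))
  } else cat("No conserved k-mers found.\n")
})
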