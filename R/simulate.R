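#' Residue background compositions for simulated sequences
#'
#' \code{"uniform"} draws all 20 canonical residues equally;
#' \code{"idr"} biases composition toward the disorder-promoting
#' residues P, R, G, Q, S, K, A, E (three-fold enrichment), emulating
#' the low-complexity composition of intrinsically disordered regions —
#' the hard case for motif detection because repetitive background
#' k-mers recur by chance.
#'
#' @param background \code{"uniform"} or \code{"idr"}.
#' @return named numeric probability vector over [AA_CANONICAL].
#' @export
backgroundFrequencies <- function(background = c("uniform", "idr")) {
  background <- match.arg(background)
  p <- stats::setNames(rep(1, 20), AA_CANONICAL)
  if (background == "idr")
    p[c("P", "R", "G", "Q", "S", "K", "A", "E")] <- 3
  p / sum(p)
}

# Substitute residues of a motif copy at `rate` per position.
# conservative: uniform draw among the 3 nearest residues by Grantham
# distance; radical: among the 3 farthest; uniform: any of the 19 others.
.mutateMotif <- function(motif, rate, mode, dm) {
  if (rate <= 0) return(motif)
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (!any(hit)) return(motif)
  D <- dm@matrix
  for (p in which(hit)) {
    d <- sort(D[chars[p], setdiff(colnames(D), chars[p])])
    pool <- switch(mode,
                   conservative = names(d)[1:3],
                   radical = names(rev(d))[1:3],
                   uniform = names(d))
    chars[p] <- sample(pool, 1L)
  }
  paste(chars, collapse = "")
}

# Apply insertions/deletions to a motif copy at `rate` per position.
.indelMotif <- function(motif, rate, freqs) {
  if (rate <= 0) return(motif)
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (ch in chars) {
    u <- stats::runif(1)
    if (u < rate / 2) next                       # deletion
    out <- c(out, ch)
    if (u >= rate / 2 && u < rate)               # insertion after
      out <- c(out, sample(names(freqs), 1L, prob = freqs))
  }
  if (length(out) == 0L) out <- chars[1L]        # keep at least one residue
  paste(out, collapse = "")
}

#' Generate an ortholog-like sequence set with planted motifs
#'
#' Builds \code{nSequences} random background sequences and plants one
#' copy of every motif in each, at independently drawn non-overlapping
#' positions, optionally permuting the motif order per sequence
#' (multivalent-motif fixture). Each planted copy can be degraded by
#' per-position substitutions — conservative (low Grantham distance),
#' radical (high distance) or uniform — and by insertions/deletions. The
#' emitted ground-truth table records the actually planted (possibly
#' mutated) instance and its exact 1-based coordinates, sufficient to
#' score any prediction without external data. Byte-reproducible under
#' \code{seed}.
#'
#' @param motifs character vector of motif strings to plant.
#' @param nSequences number of sequences (default 10).
#' @param seqLength background sequence length (default 150).
#' @param background see [backgroundFrequencies()].
#' @param substitutionRate per-position substitution probability
#'   (default 0).
#' @param substitutionMode \code{"uniform"}, \code{"conservative"} or
#'   \code{"radical"}.
#' @param indelRate per-position insertion/deletion probability
#'   (default 0).
#' @param shuffleMotifOrder permute motif order per sequence.
#' @param seed integer seed (optional).
#' @param dm distance matrix steering conservative/radical draws.
#' @return list(sequences = named character vector,
#'   truth = data.frame(sequence_id, motif, planted, start, end)).
#' @export
simulateOrthologSet <- function(motifs, nSequences = 10L, seqLength = 150L,
                                background = c("uniform", "idr"),
                                substitutionRate = 0,
                                substitutionMode = c("uniform",
                                                     "conservative",
                                                     "radical"),
                                indelRate = 0, shuffleMotifOrder = FALSE,
                                seed = NULL, dm = granthamDistance()) {
  substitutionMode <- match.arg(substitutionMode)
  stopifnot(nSequences >= 1L, all(nchar(motifs) >= 1L),
            substitutionRate >= 0, substitutionRate <= 1,
            indelRate >= 0, indelRate <= 1)
  if (sum(nchar(motifs) + 1L) > seqLength)
    stop("motifs do not fit into sequences of length ", seqLength)
  if (!is.null(seed)) set.seed(seed)
  freqs <- backgroundFrequencies(match.arg(background))
  seqs <- character(nSequences)
  truth <- vector("list", nSequences)
  ids <- sprintf("seq%03d", seq_len(nSequences))
  for (s in seq_len(nSequences)) {
    bg <- paste(sample(names(freqs), seqLength, replace = TRUE,
                       prob = freqs), collapse = "")
    order_ <- if (shuffleMotifOrder) sample(seq_along(motifs))
              else seq_along(motifs)
    planted <- vapply(motifs, function(m) {
      m <- .mutateMotif(m, substitutionRate, substitutionMode, dm)
      .indelMotif(m, indelRate, freqs)
    }, character(1))[order_]
    # carve non-overlapping slots left to right with jittered gaps
    total <- sum(nchar(planted))
    slack <- seqLength - total
    gaps <- if (slack > 0) {
      cuts <- sort(sample.int(slack + 1L, length(planted),
                              replace = TRUE) - 1L)
      diff(c(0L, cuts))
    } else rep(0L, length(planted))
    pos <- cumsum(gaps + c(0L, utils::head(nchar(planted), -1L))) + 1L
    seqStr <- bg
    rows <- data.frame(sequence_id = ids[s], motif = motifs[order_],
                       planted = planted, start = pos,
                       end = pos + nchar(planted) - 1L,
                       stringsAsFactors = FALSE)
    for (r in seq_len(nrow(rows)))
      substr(seqStr, rows$start[r], rows$end[r]) <- rows$planted[r]
    seqs[s] <- seqStr
    truth[[s]] <- rows
  }
  names(seqs) <- ids
  list(sequences = seqs, truth = do.call(rbind, truth))
}

#' Generate a synthetic per-residue pLDDT track
#'
#' High-confidence background (~90) with low-confidence blocks (~45)
#' standing in for disordered regions, plus optional Gaussian noise.
#' Blocks must not overlap.
#'
#' @param length protein length.
#' @param idrBlocks data.frame(start, end) of low-pLDDT blocks (may be
#'   empty).
#' @param high,low background and block mean pLDDT.
#' @param noiseSd standard deviation of added Gaussian noise (default
#'   0); values are clamped to [0, 100].
#' @param seed integer seed (optional).
#' @return numeric pLDDT vector of the requested length.
#' @export
simulatePlddtTrack <- function(length, idrBlocks = NULL, high = 90,
                               low = 45, noiseSd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- rep(high, length)
  if (!is.null(idrBlocks) && nrow(idrBlocks)) {
    b <- idrBlocks[order(idrBlocks$start), , drop = FALSE]
    stopifnot(all(b$start >= 1L), all(b$end <= length),
              all(b$start <= b$end))
    if (nrow(b) > 1L && any(b$start[-1L] <= b$end[-nrow(b)]))
      stop("idrBlocks overlap")
    for (r in seq_len(nrow(b))) v[b$start[r]:b$end[r]] <- low
  }
  if (noiseSd > 0) v <- pmin(100, pmax(0, v + stats::rnorm(length, 0,
                                                           noiseSd)))
  v
}
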