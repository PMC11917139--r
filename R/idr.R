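#' Smooth a per-residue pLDDT track
#'
#' Centered moving average with an odd window (default 15 residues). At
#' the termini the window shrinks to the available residues, so terminal
#' classifications rest on real data only (no padding).
#'
#' @param values numeric vector of per-residue pLDDT scores in [0, 100].
#' @param window odd window length >= 1.
#' @return smoothed numeric vector of the same length.
#' @export
smoothPlddt <- function(values, window = 15L) {
  if (length(values) == 0L) stop("empty pLDDT track")
  stopifnot(window >= 1L, window %% 2L == 1L)
  n <- length(values)
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(values))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Call per-residue disorder from a smoothed pLDDT track
#'
#' Residues with smoothed pLDDT <= 65 (inclusive) are considered
#' disordered.
#'
#' @param smoothed smoothed pLDDT values.
#' @param threshold disorder threshold (default 65).
#' @return logical mask, TRUE = disordered.
#' @export
callDisorder <- function(smoothed, threshold = 65) smoothed <= threshold

#' Reassign small order/disorder islands
#'
#' Two passes over the run-length encoding of the disorder mask: first,
#' ordered segments of length <= \code{maxLen} flanked by disorder on
#' both sides are flipped to disordered; then disordered segments of
#' length <= \code{maxLen} flanked by order on both sides are flipped to
#' ordered (set \code{first = "disordered"} for the opposite pass
#' order). Terminal segments have only one flank and are never flipped.
#'
#' @param mask logical disorder mask from [callDisorder()].
#' @param maxLen maximum island length to reassign (default 10).
#' @param first which label is reassigned in the first pass.
#' @return the reassigned logical mask.
#' @export
reassignSegments <- function(mask, maxLen = 10L,
                             first = c("ordered", "disordered")) {
  first <- match.arg(first)
  flip <- function(m, island) {   # island: mask value of segments to flip
    r <- rle(m)
    nr <- length(r$values)
    if (nr < 3L) return(m)
    idx <- which(r$values == island & r$lengths <= maxLen)
    idx <- idx[idx > 1L & idx < nr]   # need both flanks
    r$values[idx] <- !island
    inverse.rle(r)
  }
  if (first == "ordered") flip(flip(mask, FALSE), TRUE)
  else flip(flip(mask, TRUE), FALSE)
}

#' Extract IDRs from a reassigned disorder mask
#'
#' Maximal disordered runs of at least \code{minLen} residues (default
#' 30) become intrinsically disordered regions. The full ordered /
#' disordered tiling is retained alongside.
#'
#' @param mask reassigned logical disorder mask.
#' @param minLen minimal IDR length (default 30).
#' @param proteinId identifier stored in the result.
#' @return a \linkS4class{DisorderSegmentation}.
#' @export
extractIdrs <- function(mask, minLen = 30L, proteinId = "protein") {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segments <- data.frame(start = starts, end = ends,
                         label = ifelse(r$values, "disordered", "ordered"),
                         stringsAsFactors = FALSE)
  keep <- r$values & r$lengths >= minLen
  idrs <- data.frame(start = starts[keep], end = ends[keep])
  new("DisorderSegmentation", proteinId = proteinId, segments = segments,
      idrs = idrs)
}

#' Segment a protein into ordered and disordered regions
#'
#' Full pipeline: smooth the pLDDT track over a 15-residue window, call
#' residues with smoothed pLDDT <= 65 disordered, reassign islands of
#' <= 10 residues, and keep disordered runs >= 30 residues as IDRs.
#'
#' @param values per-residue pLDDT scores.
#' @param window,threshold,maxLen,minLen see the step functions.
#' @param first island-reassignment pass order, see
#'   [reassignSegments()].
#' @param proteinId identifier stored in the result.
#' @return a \linkS4class{DisorderSegmentation}.
#' @export
segmentDisorder <- function(values, window = 15L, threshold = 65,
                            maxLen = 10L, minLen = 30L,
                            first = "ordered", proteinId = "protein") {
  mask <- callDisorder(smoothPlddt(values, window), threshold)
  mask <- reassignSegments(mask, maxLen, first)
  extractIdrs(mask, minLen, proteinId)
}

#' @rdname extractIdrs
#' @param x a \linkS4class{DisorderSegmentation}.
#' @export
idrs <- function(x) x@idrs

#' @rdname extractIdrs
#' @export
segments <- function(x) x@segments

#' @describeIn DisorderSegmentation-class compact display
#' @param object a \linkS4class{DisorderSegmentation}.
#' @export
setMethod("show", "DisorderSegmentation", function(object) {
  n <- if (nrow(object@segments)) max(object@segments$end) else 0L
  cat("DisorderSegmentation '", object@proteinId, "': ", n, " residues, ",
      nrow(object@idrs), " IDR(s)\n", sep = "")
})

#' Filter proteome-run motif mappings by IDR context
#'
#' Keeps motifs that lie fully inside an IDR and more than
#' \code{minSeparation} residues away from any ordered segment of the
#' reassigned tiling (a motif with only a 2-residue gap to structure is
#' rejected). Retained motifs are then capped per protein at
#' \code{max(2, floor(2 * L_IDR / 100))} where L_IDR is the protein's
#' summed IDR length — two motifs per 100 residues of IDR. Capping works
#' on (k-mer, score) units ordered by descending score (ties: k-mer
#' lexicographically): equal-scoring duplicate positions of one k-mer
#' are all reported and count once against the cap.
#'
#' @param mappings data.frame(sequence_id, mapped_kmer or kmer, start,
#'   end, score).
#' @param segmentation a \linkS4class{DisorderSegmentation} for the
#'   protein the mappings refer to.
#' @param minSeparation required distance to structure (default 2;
#'   strict).
#' @param motifsPer100 motif budget per 100 IDR residues (default 2).
#' @return the filtered mapping data.frame (subset of the input).
#' @export
filterProteomeMotifs <- function(mappings, segmentation,
                                 minSeparation = 2L, motifsPer100 = 2) {
  km <- if (!is.null(mappings$kmer)) mappings$kmer else mappings$mapped_kmer
  idr <- segmentation@idrs
  if (nrow(idr) == 0L) {
    message("protein '", segmentation@proteinId,
            "' has no IDR; all motifs filtered out")
    return(mappings[0, , drop = FALSE])
  }
  ord <- segmentation@segments[segmentation@segments$label == "ordered", ,
                               drop = FALSE]
  inside <- vapply(seq_len(nrow(mappings)), function(r) {
    any(mappings$start[r] >= idr$start & mappings$end[r] <= idr$end)
  }, logical(1))
  farEnough <- vapply(seq_len(nrow(mappings)), function(r) {
    if (nrow(ord) == 0L) return(TRUE)
    gaps <- pmax(ord$start - mappings$end[r] - 1L,
                 mappings$start[r] - ord$end - 1L)
    all(gaps > minSeparation)
  }, logical(1))
  keep <- mappings[inside & farEnough, , drop = FALSE]
  km <- km[inside & farEnough]
  if (nrow(keep) == 0L) return(keep)
  cap <- max(2L, floor(motifsPer100 * sum(idr$end - idr$start + 1L) / 100))
  units <- unique(data.frame(kmer = km, score = keep$score))
  units <- units[order(-units$score, units$kmer), , drop = FALSE]
  units <- utils::head(units, cap)
  sel <- paste(km, keep$score) %in% paste(units$kmer, units$score)
  out <- keep[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Random same-protein control k-mers for proteome motifs
#'
#' For each retained motif, samples \code{times} windows of the same
#' length uniformly from the same protein sequence. Reproducible under
#' \code{seed}; proteins shorter than the motif length are skipped with
#' a warning.
#'
#' @param mappings filtered mapping data.frame (needs sequence_id,
#'   start, end).
#' @param sequences named character vector of protein sequences.
#' @param times controls per motif (default 5).
#' @param seed integer seed.
#' @return data.frame(sequence_id, source_start, control_kmer, start,
#'   end, replicate).
#' @export
randomControl <- function(mappings, sequences, times = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(mappings)), function(r) {
    id <- mappings$sequence_id[r]
    k <- mappings$end[r] - mappings$start[r] + 1L
    L <- nchar(sequences[[id]])
    if (L < k) {
      warning("protein '", id, "' shorter than k = ", k, "; skipped")
      return(NULL)
    }
    starts <- sample.int(L - k + 1L, times, replace = TRUE)
    data.frame(sequence_id = id, source_start = mappings$start[r],
               control_kmer = substring(sequences[[id]], starts,
                                        starts + k - 1L),
               start = starts, end = starts + k - 1L,
               replicate = seq_len(times), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(sequence_id = character(), source_start = integer(),
                      control_kmer = character(), start = integer(),
                      end = integer(), replicate = integer())
  res
}
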