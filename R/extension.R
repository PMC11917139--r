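#' Extend one top-ranked motif region with near-top overlapping matches
#'
#' The extension rule absorbs a candidate region into the top-ranked
#' region when (1) it overlaps the region by at least one residue and
#' (2) its capture score is strictly within 10\% of the top score, i.e.
#' score > 0.9 C by default. With \code{chain = TRUE} (default) newly
#' absorbed intervals can recruit further overlapping qualifying
#' candidates until a fixed point is reached; \code{chain = FALSE}
#' applies a single pass against the original top interval only. The
#' result always contains the original interval and is independent of
#' candidate ordering.
#'
#' @param top integer c(start, end) of the top-ranked region (1-based
#'   inclusive).
#' @param candidates data.frame(start, end, score, kmer optional) of
#'   candidate regions in the same sequence.
#' @param C the top-ranked capture score.
#' @param threshold fraction of C a candidate must strictly exceed
#'   (default 0.9).
#' @param chain iterate absorption to a fixed point (default TRUE).
#' @return list(start, end, merged_from = data.frame of contributors).
#' @examples
#' extendRegion(c(10, 13), data.frame(start = 12, end = 16, score = 9.5),
#'              C = 10)$end   # 16
#' @export
extendRegion <- function(top, candidates, C, threshold = 0.9,
                         chain = TRUE) {
  stopifnot(length(top) == 2L, top[1] <= top[2], threshold > 0,
            threshold <= 1)
  s <- top[1]; e <- top[2]
  if (is.null(candidates) || nrow(candidates) == 0L)
    return(list(start = s, end = e,
                merged_from = candidates[0, , drop = FALSE]))
  qual <- candidates[candidates$score > threshold * C, , drop = FALSE]
  used <- rep(FALSE, nrow(qual))
  repeat {
    hit <- !used & qual$start <= e & qual$end >= s
    if (!any(hit)) break
    used <- used | hit
    s <- min(s, qual$start[hit])
    e <- max(e, qual$end[hit])
    if (!chain) break
  }
  list(start = s, end = e, merged_from = qual[used, , drop = FALSE])
}

#' Extend the top-ranked motif of every sequence of a capture run
#'
#' Per sequence, the seed is the first mapped instance of the rank-1
#' consensus k-mer (sequences without a rank-1 mapping yield no extended
#' region); candidates are all mapped instances of the top
#' \code{pool} consensus k-mers in the same sequence, carrying their
#' consensus scores. Extended regions may exceed the run's maximum
#' k-mer length.
#'
#' @param run a \linkS4class{CaptureRun}.
#' @param threshold see [extendRegion()].
#' @param pool number of top consensus k-mers whose mappings are
#'   candidates (default 10).
#' @param chain see [extendRegion()].
#' @return data.frame(sequence_id, start, end, contributors) where
#'   contributors is a comma-separated "kmer@score" list.
#' @export
extendMotifs <- function(run, threshold = 0.9, pool = 10L, chain = TRUE) {
  cons <- utils::head(run@consensus, pool)
  if (nrow(cons) == 0L)
    return(data.frame(sequence_id = character(), start = integer(),
                      end = integer(), contributors = character()))
  maps <- lapply(seq_len(nrow(cons)), function(r) {
    m <- motifMappings(run, r)
    if (is.null(m) || nrow(m) == 0L) return(NULL)
    m$score <- cons$score[r]
    m
  })
  allMaps <- do.call(rbind, maps)
  topMap <- maps[[1L]]
  C <- cons$score[1L]
  out <- lapply(names(run@sequences), function(id) {
    seed <- topMap[topMap$sequence_id == id, , drop = FALSE]
    if (is.null(seed) || nrow(seed) == 0L) return(NULL)
    seed <- seed[1L, ]      # first instance of the top-ranked mapping
    cand <- allMaps[allMaps$sequence_id == id, , drop = FALSE]
    reg <- extendRegion(c(seed$start, seed$end),
                        cand[, c("start", "end", "score", "consensus")],
                        C, threshold = threshold, chain = chain)
    contrib <- reg$merged_from
    data.frame(sequence_id = id, start = reg$start, end = reg$end,
               contributors = paste(
                 sprintf("%s@%g", contrib$consensus, contrib$score),
                 collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), contributors = character())
  res
}
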