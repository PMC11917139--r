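#' @importFrom IRanges IRanges reduce intersect setdiff width countOverlaps
NULL

.toRanges <- function(df) IRanges::IRanges(start = df$start, end = df$end)

#' Curate annotated motif classes for benchmarking
#'
#' Applies the curation rules used before motif-detection benchmarking:
#' sites whose motif string contains non-canonical residues are dropped;
#' sites whose motif string fails the class's regular expression (when a
#' \code{regex} column is present) are dropped; sequences shorter than
#' \code{minLength} residues are dropped; classes retaining fewer than
#' \code{minSequences} unique sequences are dropped.
#'
#' @param annotations data.frame(class_id, sequence_id, start, end,
#'   motif optional, regex optional).
#' @param sequences named character vector of the class sequences.
#' @param minSequences minimum unique sequences per class (default 3).
#' @param minLength minimum sequence length (default 10).
#' @return the filtered annotation data.frame; zero rows with a message
#'   when nothing is evaluable.
#' @export
curateClasses <- function(annotations, sequences, minSequences = 3L,
                          minLength = 10L) {
  a <- annotations
  if (!is.null(a$motif)) {
    bad <- grepl(sprintf("[^%s]", paste(AA_CANONICAL, collapse = "")),
                 a$motif)
    a <- a[!bad | is.na(a$motif), , drop = FALSE]
  }
  if (!is.null(a$regex)) {
    ok <- is.na(a$regex) | mapply(grepl, a$regex, a$motif)
    a <- a[ok, , drop = FALSE]
  }
  keepSeq <- names(sequences)[nchar(sequences) >= minLength]
  a <- a[a$sequence_id %in% keepSeq, , drop = FALSE]
  nSeq <- tapply(a$sequence_id, a$class_id,
                 function(s) length(unique(s)))
  keepCls <- names(nSeq)[nSeq >= minSequences]
  a <- a[a$class_id %in% keepCls, , drop = FALSE]
  if (nrow(a) == 0L) message("no evaluable classes after curation")
  rownames(a) <- NULL
  a
}

#' Site-level confusion counts for one motif class
#'
#' A site is a continuous stretch of residues. A predicted site sharing
#' at least one residue with an annotated site is a true positive; one
#' prediction overlapping m annotated sites contributes m true positives
#' (unique sequences can harbor several instances of one motif class).
#' Annotated sites touched by no prediction are false negatives;
#' predicted sites touching no annotation are false positives. True
#' negatives are not defined at site level.
#'
#' @param pred data.frame(sequence_id, start, end) of predicted sites.
#' @param annot data.frame(sequence_id, start, end) of annotated sites.
#' @return list(tp, fp, fn).
#' @export
siteMetrics <- function(pred, annot) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (id in unique(c(pred$sequence_id, annot$sequence_id))) {
    p <- pred[pred$sequence_id == id, , drop = FALSE]
    a <- annot[annot$sequence_id == id, , drop = FALSE]
    if (nrow(p) == 0L) { fn <- fn + nrow(a); next }
    if (nrow(a) == 0L) { fp <- fp + nrow(p); next }
    hits <- IRanges::countOverlaps(.toRanges(p), .toRanges(a))
    tp <- tp + sum(hits)
    fp <- fp + sum(hits == 0L)
    fn <- fn + sum(IRanges::countOverlaps(.toRanges(a), .toRanges(p)) == 0L)
  }
  list(tp = tp, fp = fp, fn = fn)
}

#' Residue-level confusion counts for one motif class
#'
#' Residues are deduplicated across overlapping sites before counting:
#' predicted residues belonging to an annotated site are true positives,
#' predicted residues outside any annotation false positives, annotated
#' residues missed by the prediction false negatives, and everything
#' else true negatives. Counts are summed over all sequences of the
#' class before precision/recall are computed.
#'
#' @inheritParams siteMetrics
#' @param seqLengths named integer vector of sequence lengths.
#' @return list(tp, fp, fn, tn).
#' @export
residueMetrics <- function(pred, annot, seqLengths) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (id in names(seqLengths)) {
    L <- seqLengths[[id]]
    p <- IRanges::reduce(.toRanges(pred[pred$sequence_id == id, ,
                                        drop = FALSE]))
    a <- IRanges::reduce(.toRanges(annot[annot$sequence_id == id, ,
                                         drop = FALSE]))
    i <- sum(IRanges::width(IRanges::intersect(p, a)))
    wp <- sum(IRanges::width(p)); wa <- sum(IRanges::width(a))
    tp <- tp + i
    fp <- fp + (wp - i)
    fn <- fn + (wa - i)
    tn <- tn + (L - wp - wa + i)
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

.prf <- function(tp, fp, fn, printedRecall = FALSE) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (printedRecall) {
    if (fp + fn > 0) tp / (fp + fn) else 0
  } else {
    if (tp + fn > 0) tp / (tp + fn) else 0
  }
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' Site- and residue-level metrics for one class
#'
#' Wraps [siteMetrics()] and [residueMetrics()] and derives precision,
#' recall and F1 at both levels. Recall is TP/(TP+FN); set
#' \code{printedRecall = TRUE} for the alternative TP/(FP+FN)
#' convention. When no residues are predicted at all, precision and
#' recall are 0 by definition. F1 is 0 when precision + recall = 0.
#'
#' @inheritParams residueMetrics
#' @param class_id identifier stored in the result.
#' @param printedRecall use TP/(FP+FN) instead of TP/(TP+FN).
#' @return one-row data.frame of per-class counts and metrics.
#' @export
classMetrics <- function(pred, annot, seqLengths, class_id = "class",
                         printedRecall = FALSE) {
  s <- siteMetrics(pred, annot)
  r <- residueMetrics(pred, annot, seqLengths)
  sp <- .prf(s$tp, s$fp, s$fn, printedRecall)
  rp <- .prf(r$tp, r$fp, r$fn, printedRecall)
  data.frame(class_id = class_id,
             site_tp = s$tp, site_fp = s$fp, site_fn = s$fn,
             site_precision = sp$precision, site_recall = sp$recall,
             site_f1 = sp$f1,
             res_tp = r$tp, res_fp = r$fp, res_fn = r$fn, res_tn = r$tn,
             res_precision = rp$precision, res_recall = rp$recall,
             res_f1 = rp$f1, stringsAsFactors = FALSE)
}

#' Aggregate per-class benchmark metrics
#'
#' Unweighted mean of per-class precision, recall and F1 (F1 is computed
#' per class first, then averaged), so classes with many sequences or
#' sites do not bias the summary.
#'
#' @param perClass data.frame of rows from [classMetrics()].
#' @return one-row data.frame of mean metrics plus the class count.
#' @export
aggregateMetrics <- function(perClass) {
  stopifnot(nrow(perClass) >= 1L)
  cols <- c("site_precision", "site_recall", "site_f1",
            "res_precision", "res_recall", "res_f1")
  out <- as.data.frame(lapply(perClass[cols], mean))
  out$n_classes <- nrow(perClass)
  out
}

#' Combine the mapped sites of the top-ranked consensus k-mers
#'
#' Sensitivity-mode predictions: the union of the mapped sites of the
#' top \code{n} consensus k-mers of a run (fewer if the run found
#' fewer), one row per mapped site. At residue level overlapping sites
#' merge into their residue union during evaluation.
#'
#' @param run a \linkS4class{CaptureRun}.
#' @param n number of top consensus k-mers to combine (default 10).
#' @return data.frame(sequence_id, start, end, rank).
#' @export
combineTopK <- function(run, n = 10L) {
  cons <- utils::head(run@consensus, n)
  maps <- lapply(seq_len(nrow(cons)), function(r) {
    m <- motifMappings(run, r)
    if (is.null(m) || nrow(m) == 0L) return(NULL)
    data.frame(sequence_id = m$sequence_id, start = m$start, end = m$end,
               rank = r, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, maps)
  if (is.null(res))
    res <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), rank = integer())
  unique(res)
}

#' Top-ranked prediction per sequence of a capture run
#'
#' The stringent benchmark mode: only the rank-1 consensus k-mer's
#' mapping is used, and when a sequence carries several equally ranked
#' mapped positions the first instance in mapping-table order is taken.
#'
#' @param run a \linkS4class{CaptureRun}.
#' @return data.frame(sequence_id, start, end, rank = 1).
#' @export
topPrediction <- function(run) {
  m <- motifMappings(run, 1L)
  if (is.null(m) || nrow(m) == 0L)
    return(data.frame(sequence_id = character(), start = integer(),
                      end = integer(), rank = integer()))
  first <- m[!duplicated(m$sequence_id), , drop = FALSE]
  data.frame(sequence_id = first$sequence_id, start = first$start,
             end = first$end, rank = 1L, stringsAsFactors = FALSE)
}
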