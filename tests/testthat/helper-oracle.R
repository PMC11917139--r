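# Independent brute-force oracle for the capture algorithm.
#
# Deliberately naive: nested loops over explicit k-mer lists, no
# similarity matrices, no vectorization, no shared code with the package
# internals beyond the similarity table itself. Used to pin down raw
# scores, rankings and map-back coordinates on small instances.

oracleSimTable <- function() {
  m <- as.matrix(read.table(system.file("extdata", "grantham.tsv",
                                        package = "kcapture"),
                            header = TRUE, row.names = 1,
                            check.names = FALSE))
  1 - m / max(m)
}

oracleKmers <- function(seq, k) {
  L <- nchar(seq)
  if (k > L) return(list(kmers = character(), freq = integer(),
                         pos = list()))
  all <- character(L - k + 1)
  for (s in seq_len(L - k + 1)) all[s] <- substr(seq, s, s + k - 1)
  uniq <- unique(all)
  freq <- integer(length(uniq))
  pos <- vector("list", length(uniq))
  for (u in seq_along(uniq)) {
    where <- which(all == uniq[u])
    freq[u] <- length(where)
    pos[[u]] <- where
  }
  list(kmers = uniq, freq = freq, pos = pos)
}

# memoized so repeated brute-force scans stay affordable; the arithmetic
# (explicit per-position loop) is still independent of the package
.oracleWCache <- new.env(parent = emptyenv())
oracleW <- function(x, y, D) {
  key <- paste(x, y)
  hit <- .oracleWCache[[key]]
  if (!is.null(hit)) return(hit)
  s <- 0
  for (p in seq_len(nchar(x)))
    s <- s + D[substr(x, p, p), substr(y, p, p)]
  s <- s / nchar(x)
  .oracleWCache[[key]] <- s
  s
}

oracleLD <- function(q, t) 2 * (q^2 + t^2) / (q + t)

# best target index among `tb` for source kmer index si of `ta`
oracleBest <- function(ta, tb, si, D) {
  best <- NA_integer_
  for (j in seq_along(tb$kmers)) {
    if (is.na(best)) { best <- j; next }
    wj <- oracleW(ta$kmers[si], tb$kmers[j], D)
    wb <- oracleW(ta$kmers[si], tb$kmers[best], D)
    if (wj > wb) { best <- j; next }
    if (wj < wb) next
    lj <- oracleLD(ta$freq[si], tb$freq[j])
    lb <- oracleLD(ta$freq[si], tb$freq[best])
    if (lj < lb || (lj == lb && tb$kmers[j] < tb$kmers[best])) best <- j
  }
  best
}

# reciprocal best-match events of one sequence pair
oracleReciprocal <- function(seqA, seqB, k, D) {
  ta <- oracleKmers(seqA, k)
  tb <- oracleKmers(seqB, k)
  out <- list()
  if (length(ta$kmers) == 0 || length(tb$kmers) == 0) return(out)
  for (i in seq_along(ta$kmers)) {
    j <- oracleBest(ta, tb, i, D)
    if (oracleBest(tb, ta, j, D) == i)
      out[[length(out) + 1]] <- list(a = ta$kmers[i], b = tb$kmers[j],
                                     w = oracleW(ta$kmers[i], tb$kmers[j],
                                                 D))
  }
  out
}

# full capture pass at one k: raw scores and per-pair events
oracleCapture <- function(seqs, k, D) {
  n <- length(seqs)
  raw <- list()
  events <- list()
  for (i in seq_len(n)) for (j in i:n) {
    evs <- oracleReciprocal(seqs[[i]], seqs[[j]], k, D)
    for (e in evs) {
      e$si <- names(seqs)[i]; e$sj <- names(seqs)[j]
      events[[length(events) + 1]] <- e
      seen <- unique(c(e$a, e$b))
      for (x in seen) raw[[x]] <- (if (is.null(raw[[x]])) 0 else raw[[x]]) + 1
    }
  }
  list(raw = unlist(raw), events = events)
}

# map-back of a consensus kmer into sequence `id`, from oracle events
oracleMapBack <- function(consensus, id, seqs, events) {
  partners <- character(); ws <- numeric()
  for (e in events) {
    took <- FALSE
    if (e$a == consensus && e$sj == id) {
      partners <- c(partners, e$b); ws <- c(ws, e$w); took <- TRUE
    }
    if (!took && e$b == consensus && e$si == id) {
      partners <- c(partners, e$a); ws <- c(ws, e$w)
    }
  }
  if (length(partners) == 0) return(NULL)
  tab <- table(partners)
  cand <- names(tab)[tab == max(tab)]
  if (length(cand) > 1) {
    mw <- sapply(cand, function(p) mean(sort(ws[partners == p])))
    cand <- sort(cand[mw == max(mw)])[1]
  }
  k <- nchar(consensus)
  seqStr <- seqs[[id]]
  occ <- integer()
  for (s in seq_len(nchar(seqStr) - k + 1))
    if (substr(seqStr, s, s + k - 1) == cand) occ <- c(occ, s)
  list(kmer = cand, starts = occ, support = max(tab))
}

# uniform random canonical protein sequence
randomProtein <- function(L)
  paste(sample(kcapture::AA_CANONICAL, L, replace = TRUE), collapse = "")
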