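test_that("pLDDT smoothing is a shrinking-window centered average", {
  expect_equal(smoothPlddt(rep(70, 50)), rep(70, 50))
  x <- rep(90, 40)
  expect_equal(smoothPlddt(x)[1], 90)
  # single spike: spread over <= 15 positions, interior mass conserved
  sp <- rep(0, 60); sp[30] <- 15
  sm <- smoothPlddt(sp)
  expect_equal(sum(sm > 0), 15)
  expect_equal(sum(sm), 15)     # direct convolution mass
  expect_equal(sm[30], 1)       # 15 / window
  # edge shrink: position 1 averages positions 1..8 only
  y <- c(rep(0, 8), rep(80, 42))
  expect_equal(smoothPlddt(y)[1], 0)
  expect_error(smoothPlddt(numeric(0)), "empty")
  expect_error(smoothPlddt(1:10, window = 4), "window")
})

test_that("disorder call uses an inclusive 65 threshold", {
  expect_true(callDisorder(65.0))
  expect_false(callDisorder(65.01))
  expect_equal(callDisorder(c(50, 64.9, 65, 70)), c(TRUE, TRUE, TRUE, FALSE))
  # monotone: raising the threshold never shrinks the disordered set
  set.seed(4)
  v <- runif(200, 0, 100)
  for (th in c(50, 65, 80))
    expect_true(all(callDisorder(v, th) | !callDisorder(v, th - 10)))
})

test_that("small islands are reassigned; 11-mers and termini are not", {
  dis <- function(n) rep(TRUE, n); ord <- function(n) rep(FALSE, n)
  m <- c(dis(20), ord(8), dis(20))
  expect_true(all(reassignSegments(m)))
  m11 <- c(dis(20), ord(11), dis(20))
  expect_identical(reassignSegments(m11), m11)
  # disordered island flanked by order flips in the second pass
  m2 <- c(ord(15), dis(6), ord(15))
  expect_false(any(reassignSegments(m2)))
  # terminal short segment keeps its label (single flank)
  m3 <- c(dis(4), ord(30))
  expect_identical(reassignSegments(m3), m3)
})

test_that("alternating tiny segments resolve by documented pass order", {
  dis <- function(n) rep(TRUE, n); ord <- function(n) rep(FALSE, n)
  # hand-worked: D20 O5 D3 O5 D20
  #  pass 1 (ordered islands first): both O5 flip -> D51
  #  pass 2: nothing left to flip
  m <- c(dis(20), ord(5), dis(3), ord(5), dis(20))
  expect_true(all(reassignSegments(m)))
  # opposite pass order: D3 flips first -> O13 island too long to flip
  # back, leaving the middle ordered
  r <- reassignSegments(m, first = "disordered")
  expect_identical(r, c(dis(20), ord(13), dis(20)))
})

test_that("IDR extraction enforces the 30-residue minimum and tiling", {
  mask <- c(rep(FALSE, 10), rep(TRUE, 29), rep(FALSE, 10))
  seg <- extractIdrs(mask)
  expect_equal(nrow(idrs(seg)), 0L)
  mask30 <- c(rep(FALSE, 10), rep(TRUE, 30), rep(FALSE, 10))
  seg30 <- extractIdrs(mask30)
  expect_equal(nrow(idrs(seg30)), 1L)
  expect_equal(idrs(seg30)$start, 11L)
  expect_equal(idrs(seg30)$end, 40L)
  expect_equal(nrow(idrs(extractIdrs(rep(FALSE, 100)))), 0L)
  # segments tile the protein exactly
  s <- segments(seg30)
  expect_equal(s$start[1], 1L)
  expect_equal(s$end[nrow(s)], 50L)
  expect_true(all(s$start[-1] == s$end[-nrow(s)] + 1L))
})

test_that("full segmentation pipeline handles synthetic tracks", {
  # constant 90: fully ordered, no IDR
  expect_equal(nrow(idrs(segmentDisorder(rep(90, 100)))), 0L)
  # constant 50 of length 40: one IDR covering the protein
  seg <- segmentDisorder(rep(50, 40))
  expect_equal(nrow(idrs(seg)), 1L)
  expect_equal(unlist(idrs(seg)), c(start = 1L, end = 40L))
  # simulated low-pLDDT block of 50 recovered within window tolerance
  tr <- simulatePlddtTrack(200, data.frame(start = 76, end = 125))
  seg2 <- segmentDisorder(tr)
  expect_equal(nrow(idrs(seg2)), 1L)
  expect_lte(abs(idrs(seg2)$start - 76), 7)
  expect_lte(abs(idrs(seg2)$end - 125), 7)
})

test_that("proteome filter enforces IDR containment and separation", {
  mask <- c(rep(FALSE, 20), rep(TRUE, 100), rep(FALSE, 30))
  seg <- extractIdrs(mask)   # IDR 21..120, ordered 1..20 and 121..150
  maps <- data.frame(
    sequence_id = "p",
    kmer = c("AAAA", "CCCC", "GGGG", "HHHH"),
    start = c(22L, 24L, 50L, 110L),
    end = c(25L, 27L, 53L, 113L),
    score = c(9, 8, 7, 6))
  out <- filterProteomeMotifs(maps, seg)
  # start 22 is only 1 residue from ordered 1..20 -> rejected;
  # start 24 has a 3-residue gap -> kept; cap = max(2, floor(2)) = 2
  expect_setequal(out$kmer, c("CCCC", "GGGG"))
  # equal-scoring duplicate positions of one k-mer count once and are
  # all reported
  dup <- data.frame(sequence_id = "p", kmer = c("CCCC", "CCCC", "GGGG"),
                    start = c(30L, 60L, 80L), end = c(33L, 63L, 83L),
                    score = c(9, 9, 8))
  out2 <- filterProteomeMotifs(dup, seg)
  expect_equal(nrow(out2), 3L)
  # no IDR: everything filtered, with a message
  segNone <- extractIdrs(rep(FALSE, 150))
  expect_message(out3 <- filterProteomeMotifs(maps, segNone), "no IDR")
  expect_equal(nrow(out3), 0L)
  # output is always a subset of the input
  expect_true(all(paste(out$kmer, out$start) %in%
                    paste(maps$kmer, maps$start)))
})

test_that("per-protein cap follows max(2, floor(2 L_IDR / 100))", {
  mk <- function(L) extractIdrs(c(rep(TRUE, L), rep(FALSE, 40)))
  maps <- data.frame(sequence_id = "p",
                     kmer = paste0("K", 1:5), start = seq(5, 85, 20),
                     end = seq(8, 88, 20), score = 5:1)
  maps <- maps[maps$end <= 95, ]
  out100 <- filterProteomeMotifs(maps[1:4, ], mk(100))
  expect_equal(nrow(out100), 2L)           # cap 2 at L_IDR = 100
  out150 <- filterProteomeMotifs(maps[1:4, ], mk(150))
  expect_equal(nrow(out150), 3L)           # cap 3 at L_IDR = 150
  expect_equal(out150$kmer, paste0("K", 1:3))  # kept by descending score
})

test_that("random controls are reproducible and length-matched", {
  seqs <- c(p = randomProtein(80))
  maps <- data.frame(sequence_id = "p", start = c(10L, 40L),
                     end = c(14L, 46L))
  c1 <- randomControl(maps, seqs, seed = 5)
  c2 <- randomControl(maps, seqs, seed = 5)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 10L)   # 5 controls per motif
  expect_equal(nchar(c1$control_kmer),
               rep(c(5L, 7L), each = 5))
  expect_true(all(c1$end <= 80))
  short <- c(p = "MK")
  expect_warning(out <- randomControl(maps[1, ], short, seed = 1),
                 "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("planted motifs inside annotations beat random controls", {
  # enrichment harness: motifs planted inside "annotated" intervals
  # must overlap them more often than same-length random controls do
  set.seed(61)
  sim <- simulateOrthologSet("DEWFMRR", nSequences = 8, seqLength = 120,
                             seed = 61)
  run <- captureMotifs(sim$sequences, kMin = 4, kMax = 7)
  m <- motifMappings(run, 1L)
  annot <- sim$truth
  hit <- function(df) {
    mean(vapply(seq_len(nrow(df)), function(r) {
      a <- annot[annot$sequence_id == df$sequence_id[r], ]
      any(df$start[r] <= a$end & df$end[r] >= a$start)
    }, logical(1)))
  }
  ctrl <- randomControl(m, sim$sequences, seed = 62)
  expect_gt(hit(m), hit(ctrl))
})
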