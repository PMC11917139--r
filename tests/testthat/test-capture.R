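test_that("pair enumeration is n(n+1)/2 with self-pairs", {
  expect_equal(nrow(enumeratePairs(3)), 6L)
  p1 <- enumeratePairs(1)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$i, p1$j)
  expect_equal(nrow(enumeratePairs(200)), 20100L)
  expect_error(enumeratePairs(0), "empty input set")
  p <- enumeratePairs(5)
  expect_true(all(p$i <= p$j))
  expect_false(anyDuplicated(paste(p$i, p$j)) > 0)
})

test_that("search-space weighting follows the selected variant", {
  expect_equal(weightScore(6, 10), 30)
  expect_equal(weightScore(6, 10, "squared"), 600)
  expect_equal(weightScore(0, 1000), 0)
  expect_error(weightScore(5, 0), "S_k")
  # strictly increasing in S_k for fixed raw, both variants
  sk <- 1:50
  expect_true(all(diff(weightScore(3, sk)) > 0))
  expect_true(all(diff(weightScore(3, sk, "squared")) > 0))
})

test_that("single sequence: every unique k-mer scores its self-pair", {
  run <- captureMotifs(c(s1 = "MKVLWAAC"), kMin = 3, kMax = 3)
  cons <- consensusKmers(run)
  expect_setequal(cons$kmer, kmerTable("MKVLWAAC", 3)@kmers)
  expect_true(all(cons$raw_score == 1))
})

test_that("a motif planted verbatim in 3 unrelated sequences scores 6", {
  # flanks chosen aromatic/charged so background k-mers stay dissimilar
  seqs <- c(s1 = "WWDEWFMKKHH", s2 = "CCDEWFMRRYY", s3 = "GGDEWFMEEPP")
  run <- captureMotifs(seqs, kMin = 5, kMax = 5)
  cons <- consensusKmers(run)
  expect_equal(cons$raw_score[cons$kmer == "DEWFM"], 6)
  expect_equal(cons$kmer[1], "DEWFM")
  # absent k-mer absent from the table
  expect_false("AAAAA" %in% cons$kmer)
  # oracle agreement on the same instance
  orc <- oracleCapture(seqs, 5, oracleSimTable())
  expect_equal(orc$raw[["DEWFM"]], 6)
})

test_that("engine matches the brute-force oracle end to end", {
  D <- oracleSimTable()
  set.seed(2024)
  for (rep in 1:4) {
    n <- sample(2:4, 1)
    seqs <- setNames(sapply(sample(12:30, n, replace = TRUE),
                            randomProtein),
                     paste0("s", seq_len(n)))
    run <- captureMotifs(seqs, kMin = 3, kMax = 10)
    cons <- consensusKmers(run)
    for (k in 3:10) {
      orc <- oracleCapture(seqs, k, D)
      ours <- cons[cons$k == k, ]
      expect_equal(sort(names(orc$raw)), sort(ours$kmer))
      expect_equal(orc$raw[ours$kmer], setNames(ours$raw_score, ours$kmer))
      # search space = pooled unique k-mers
      sk <- length(unique(unlist(lapply(seqs, function(s)
        oracleKmers(s, k)$kmers))))
      expect_true(all(ours$s_k == sk))
      expect_equal(ours$score, ours$raw_score * sk / 2)
      # map-back coordinates agree for the top 3 k-mers of this k
      for (km in head(ours$kmer, 3)) {
        m <- motifMappings(run, km)
        for (id in names(seqs)) {
          om <- oracleMapBack(km, id, seqs, orc$events)
          mm <- m[m$sequence_id == id, , drop = FALSE]
          if (is.null(om)) {
            expect_equal(nrow(mm), 0L)
          } else {
            expect_identical(unique(mm$mapped_kmer), om$kmer)
            expect_equal(mm$start, om$starts)
            expect_equal(mm$end, om$starts + k - 1L)
          }
        }
      }
    }
  }
})

test_that("planted 5-mer ranks first and maps back to its position", {
  sim <- simulateOrthologSet("DEWFM", nSequences = 10, seqLength = 150,
                             seed = 301)
  run <- captureMotifs(sim$sequences)
  cons <- consensusKmers(run)
  expect_identical(cons$kmer[1], "DEWFM")
  m <- motifMappings(run, 1L)
  expect_identical(m$mapped_kmer, rep("DEWFM", 10))
  truth <- sim$truth[match(m$sequence_id, sim$truth$sequence_id), ]
  expect_equal(m$start, truth$start)
  expect_equal(m$end, truth$end)
})

test_that("ranking is deterministic: score desc, then larger k, then lex", {
  seqs <- c(s1 = "WWDEWFMKKHH", s2 = "CCDEWFMRRYY", s3 = "GGDEWFMEEPP")
  run <- captureMotifs(seqs, kMin = 3, kMax = 6)
  cons <- consensusKmers(run)
  expect_equal(cons$rank, seq_len(nrow(cons)))
  o <- order(-cons$score, -cons$k, cons$kmer)
  expect_equal(o, seq_len(nrow(cons)))
  expect_lte(nrow(topConsensus(run)), run@config$topN)
})

test_that("no conserved k-mers yields an empty consensus, not an error", {
  run <- suppressWarnings(captureMotifs(c(a = "MKV"), kMin = 4, kMax = 4))
  expect_equal(nrow(consensusKmers(run)), 0L)
  expect_output(show(run), "No conserved k-mers found")
})

test_that("scores and mappings are invariant to input order and workers", {
  sim <- simulateOrthologSet("RDYRA", nSequences = 6, seqLength = 80,
                             seed = 17)
  seqs <- sim$sequences
  run1 <- captureMotifs(seqs, kMin = 3, kMax = 6)
  perm <- seqs[c(4, 1, 6, 2, 5, 3)]
  run2 <- captureMotifs(perm, kMin = 3, kMax = 6)
  expect_identical(consensusKmers(run1), consensusKmers(run2))
  m1 <- motifMappings(run1, 1L)
  m2 <- motifMappings(run2, 1L)
  expect_identical(m1[order(m1$sequence_id), ],
                   data.frame(m2[order(m2$sequence_id), ],
                              row.names = NULL))
  run3 <- captureMotifs(seqs, kMin = 3, kMax = 6, processes = 2L)
  expect_identical(consensusKmers(run1), consensusKmers(run3))
  expect_identical(m1, motifMappings(run3, 1L))
})

test_that("adding a sequence containing the consensus never lowers raw", {
  sim <- simulateOrthologSet("DEWFM", nSequences = 5, seqLength = 60,
                             seed = 23)
  run1 <- captureMotifs(sim$sequences, kMin = 5, kMax = 5)
  raw1 <- consensusKmers(run1)
  raw1 <- raw1$raw_score[raw1$kmer == "DEWFM"]
  extra <- c(sim$sequences,
             new1 = paste0("HH", "DEWFM", randomProtein(20)))
  run2 <- captureMotifs(extra, kMin = 5, kMax = 5)
  raw2 <- consensusKmers(run2)
  raw2 <- raw2$raw_score[raw2$kmer == "DEWFM"]
  expect_gte(raw2, raw1)
})

test_that("map-back returns all positions of the chosen partner", {
  # consensus occurs twice in one sequence: both positions reported
  seqs <- c(s1 = "DEWFMWWDEWFM", s2 = "HHDEWFMHH", s3 = "PPDEWFMPP")
  run <- captureMotifs(seqs, kMin = 5, kMax = 5)
  m <- motifMappings(run, "DEWFM")
  s1 <- m[m$sequence_id == "s1", ]
  expect_equal(s1$start, c(1L, 8L))
  # a sequence with no reciprocal event involving the consensus (here:
  # too short to admit any length-5 window) yields no row rather than 0s
  far <- c(seqs, s4 = "KKKK")
  run2 <- suppressWarnings(captureMotifs(far, kMin = 5, kMax = 5))
  m2 <- motifMappings(run2, "DEWFM")
  expect_false("s4" %in% m2$sequence_id)
  expect_setequal(m2$sequence_id, c("s1", "s1", "s2", "s3"))
})

test_that("probability matrix gives empirical per-position frequencies", {
  maps <- data.frame(mapped_kmer = c("SLEE", "SLEE", "SLEE"))
  P <- probabilityMatrix(maps)
  expect_equal(dim(P), c(4L, 20L))
  expect_equal(unname(P[1, "S"]), 1)
  expect_equal(unname(P[2, "L"]), 1)
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  P2 <- probabilityMatrix(data.frame(mapped_kmer = c("AA", "AC")))
  expect_equal(unname(P2[2, "A"]), 0.5)
  expect_equal(unname(P2[2, "C"]), 0.5)
  expect_error(probabilityMatrix(NULL), "nothing to summarize")
})

test_that("conservative substitutions outrank radical ones", {
  # planted motif degraded at 20% per-position rate; low-Grantham
  # (conservative) noise must preserve top-3 recovery more often than
  # high-Grantham (radical) noise at the same rate
  recov <- function(mode, seeds) {
    hits <- 0L
    for (s in seeds) {
      sim <- simulateOrthologSet("DEWFM", nSequences = 6, seqLength = 60,
                                 substitutionRate = 0.2,
                                 substitutionMode = mode, seed = s)
      run <- captureMotifs(sim$sequences, kMin = 4, kMax = 6)
      if ("DEWFM" %in% head(consensusKmers(run)$kmer, 3)) hits <- hits + 1L
    }
    hits
  }
  seeds <- 1:25
  expect_gt(recov("conservative", seeds), recov("radical", seeds))
})
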