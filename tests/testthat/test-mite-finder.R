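# plant an element with perfect TIRs (and optional TSD) inside a random
# background; returns the sequence and the 1-based plant interval
plantElement <- function(bgLen, elem, at, tsd = "") {
  bg <- randomSeq(bgLen, seed = nchar(elem) + at)
  s <- paste0(substr(bg, 1, at - 1), tsd, elem, tsd,
              substr(bg, at, bgLen))
  list(seq = s, start = at + nchar(tsd),
       end = at + nchar(tsd) + nchar(elem) - 1)
}

mkMite <- function(len, tir, seed) {
  makeConsensus(FamilySpec("m", "MITE", len, tirLength = tir), seed)
}

test_that("a planted perfect TIR element is detected without mismatches", {
  elem <- mkMite(300L, 20L, seed = 61)
  pl <- plantElement(5000, elem, at = 2000)
  cand <- findInvertedRepeats(pl$seq, minTir = 15, maxMismatch = 0,
                              resolveOverlaps = FALSE)
  hit <- cand[cand$start == pl$start & cand$end == pl$end, ]
  expect_identical(nrow(hit), 1L)
  expect_gte(hit$tir_length, 20L)
  expect_identical(hit$tir_mismatches, 0L)
})

test_that("detection is strand-symmetric", {
  elem <- mkMite(200L, 18L, seed = 62)
  pl <- plantElement(3000, elem, at = 1200)
  fwd <- findInvertedRepeats(pl$seq, minTir = 15, maxMismatch = 0,
                             resolveOverlaps = FALSE)
  rcSeq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pl$seq)))
  rev <- findInvertedRepeats(rcSeq, minTir = 15, maxMismatch = 0,
                             resolveOverlaps = FALSE)
  n <- nchar(pl$seq)
  # mirrored coordinates of every forward hit appear in the reverse scan
  for (k in seq_len(nrow(fwd))) {
    ms <- n - fwd$end[k] + 1
    me <- n - fwd$start[k] + 1
    expect_true(any(rev$start == ms & rev$end == me))
  }
})

test_that("scan equals the double-loop oracle on short sequences with mismatches", {
  for (seed in c(71, 72)) {
    s <- randomSeq(260, seed)
    # embed a slightly degraded TIR element
    elem <- mkMite(120L, 14L, seed = seed + 5)
    v <- strsplit(elem, "")[[1]]
    v[5] <- setdiff(c("A", "C", "G", "T"), v[5])[1]
    s <- paste0(substr(s, 1, 60), paste(v, collapse = ""),
                substr(s, 181, 260))
    got <- findInvertedRepeats(s, minTir = 10, maxTir = 50, minLen = 50,
                               maxLen = 200, maxMismatch = 2,
                               resolveOverlaps = FALSE)
    want <- oracleTirScan(s, 10, 50, 50, 200, 2)
    expect_identical(got$start, want$start)
    expect_identical(got$end, want$end)
    expect_identical(got$tir_length, want$tir_length)
    expect_identical(got$tir_mismatches, want$tir_mismatches)
  }
})

test_that("exact-match scan agrees with the k-mer hash oracle on random sequence", {
  s <- randomSeq(20000, 81)
  got <- findInvertedRepeats(s, minTir = 15, maxMismatch = 0,
                             minLen = 50, maxLen = 800,
                             resolveOverlaps = FALSE)
  seeds <- oracleTirSeeds(s, 15, 50, 800)
  # every scan hit must have its 15-mer seed in the oracle set; random
  # sequence is expected to yield (near-)empty output
  expect_identical(nrow(got), nrow(unique(seeds)))
  if (nrow(got))
    expect_true(all(paste(got$start, got$end) %in%
                    paste(seeds$start, seeds$end)))
})

test_that("overlap resolution keeps the longest-TIR, leftmost candidate", {
  elem <- mkMite(200L, 25L, seed = 63)
  pl <- plantElement(2000, elem, at = 900)
  all <- findInvertedRepeats(pl$seq, minTir = 10, maxMismatch = 2,
                             resolveOverlaps = FALSE)
  res <- findInvertedRepeats(pl$seq, minTir = 10, maxMismatch = 2,
                             resolveOverlaps = TRUE)
  expect_lte(nrow(res), nrow(all))
  # no two kept candidates overlap
  if (nrow(res) > 1) {
    o <- order(res$start)
    expect_true(all(res$start[o][-1] > res$end[o][-nrow(res)]))
  }
  # the kept candidate covering the plant has the maximal TIR there
  over <- all[all$start <= pl$end & all$end >= pl$start, ]
  kept <- res[res$start <= pl$end & res$end >= pl$start, ]
  expect_identical(max(kept$tir_length), max(over$tir_length))
})

test_that("TSD validation records the largest matching flank and rejects strictly", {
  s <- paste0(randomSeq(100, 91), "TA", strrep("G", 0),
              mkMite(120L, 15L, 92), "TA", randomSeq(100, 93))
  cand <- data.frame(seq_id = "s", start = 103L, end = 222L,
                     element_length = 120L, tir_length = 15L,
                     tir_mismatches = 0L)
  got <- validateTsd(cand, s, strict = TRUE)
  expect_identical(got$tsd, "TA")

  # an 8-mer flank beats the shorter interpretations
  tsd8 <- "GGCCAAGT"
  s8 <- paste0(randomSeq(60, 94), tsd8, mkMite(100L, 15L, 95), tsd8,
               randomSeq(60, 96))
  cand8 <- data.frame(seq_id = "s", start = 69L, end = 168L,
                      element_length = 100L, tir_length = 15L,
                      tir_mismatches = 0L)
  expect_identical(validateTsd(cand8, s8, strict = TRUE)$tsd, tsd8)

  # mismatched flanks are rejected in strict mode with a reason kept in
  # non-strict mode
  sNo <- paste0("AC", mkMite(100L, 15L, 97), "GT", randomSeq(50, 98))
  candNo <- data.frame(seq_id = "s", start = 3L, end = 102L,
                       element_length = 100L, tir_length = 15L,
                       tir_mismatches = 0L)
  expect_identical(nrow(validateTsd(candNo, sNo, strict = TRUE)), 0L)
  loose <- validateTsd(candNo, sNo, strict = FALSE)
  expect_identical(loose$reason, "no matching TSD")

  # a candidate at the sequence edge has no flank at all
  sEdge <- paste0(mkMite(100L, 15L, 97), randomSeq(50, 98))
  candEdge <- data.frame(seq_id = "s", start = 1L, end = 100L,
                         element_length = 100L, tir_length = 15L,
                         tir_mismatches = 0L)
  expect_identical(nrow(validateTsd(candEdge, sEdge, strict = TRUE)), 0L)
  edge <- validateTsd(candEdge, sEdge, strict = FALSE)
  expect_identical(edge$reason, "flank unavailable")
})

test_that("greedy clustering groups identical sequences and separates random ones", {
  a <- mkMite(300L, 15L, 99)
  b <- randomSeq(300, 100)
  cl <- clusterMites(c(x1 = a, x2 = a, y = b))
  expect_identical(length(unique(cl$family)), 2L)
  expect_identical(cl$family[cl$member == "x1"],
                   cl$family[cl$member == "x2"])
  # identity of unrelated random sequences stays below the threshold
  al <- globalAlign(a, b)
  av <- strsplit(al$master, "")[[1]]; bv <- strsplit(al$slave, "")[[1]]
  expect_lt(sum(av == bv & av != "-") / length(av), 0.80)
  # deterministic given the ordering rule
  cl2 <- clusterMites(c(x1 = a, x2 = a, y = b))
  expect_identical(cl, cl2)
})

test_that("the default signature table reproduces the conventional labels", {
  expect_identical(assignSuperfamily("TA"), "Tc1/mariner")
  expect_identical(assignSuperfamily("TTAA"), "PiggyBac")
  expect_identical(assignSuperfamily("GGCCAAGT", "CAGTTT"), "hAT")
  expect_identical(assignSuperfamily("GGCCAAGT", "TTTTTT"), "P")
  expect_identical(assignSuperfamily("TAA"), "Pif-Harbinger")
  expect_identical(assignSuperfamily("GAC", "CACTTT"), "CACTA")
  expect_identical(assignSuperfamily("GACCC", "TTT"), "unclassified")
  expect_identical(assignSuperfamily(""), "unclassified")
})

test_that("miteScan recovers planted MITEs end to end with correct labels", {
  fams <- list(
    FamilySpec("miteTA", "MITE", 260L, tirLength = 18L, tsdLength = 2L,
               tsdMotif = "TA"),
    FamilySpec("mite8", "MITE", 320L, tirLength = 22L, tsdLength = 8L,
               tsdMotif = "random-8"))
  bursts <- list(BurstSpec("miteTA", 3L, 0), BurstSpec("mite8", 3L, 0))
  gspec <- GenomeSpec(c(chr = 60000), geneCount = 0L, seed = 13L)
  b <- buildGenome(gspec, fams, bursts)
  res <- miteScan(genomeSeq(b), minTir = 15, maxTir = 200, minLen = 50,
                  maxLen = 800, maxMismatch = 0)
  tr <- groundTruth(b)
  for (i in seq_len(nrow(tr))) {
    hit <- res$candidates[res$candidates$start == tr$start[i] &
                          res$candidates$end == tr$end[i], ]
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$tsd, tr$tsd[i])
    if (tr$family[i] == "miteTA")
      expect_identical(hit$superfamily, "Tc1/mariner")
  }
  # every reported candidate re-satisfies its structural predicate
  s <- as.character(genomeSeq(b)[["chr"]])
  for (k in seq_len(nrow(res$candidates))) {
    cd <- res$candidates[k, ]
    t <- cd$tir_length
    pre <- substr(s, cd$start, cd$start + t - 1)
    suf <- substr(s, cd$end - t + 1, cd$end)
    mism <- sum(strsplit(pre, "")[[1]] !=
                strsplit(as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(suf))), "")[[1]])
    expect_identical(mism, cd$tir_mismatches)
    expect_identical(substr(s, cd$start - nchar(cd$tsd), cd$start - 1),
                     substr(s, cd$end + 1, cd$end + nchar(cd$tsd)))
  }
})
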