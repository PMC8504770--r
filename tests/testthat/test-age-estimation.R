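# build a MasterSlaveMSA directly from row strings (consensus-width rows)
msaFromRows <- function(cons, rows) {
  mat <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(mat) <- names(rows)
  new("MasterSlaveMSA", consensusId = "fam", consensus = cons, mat = mat,
      insertions = data.frame(copy_id = names(rows),
                              inserted_bases = 0L))
}

test_that("p-distance follows the column-exclusion rule", {
  msa <- msaFromRows("ACGT", c(a = "ACGT", b = "ACGA", c = "AC-T",
                               d = "ACNT"))
  expect_identical(pDistance(msa, "a", "a", minSites = 1)[["distance"]], 0)
  pd <- pDistance(msa, "a", "b", minSites = 1)
  expect_identical(pd[["distance"]], 0.25)
  expect_identical(pd[["sites"]], 4)
  # gap column excluded: 3 compared sites, no mismatches
  pd2 <- pDistance(msa, "a", "c", minSites = 1)
  expect_identical(pd2[["sites"]], 3)
  expect_identical(pd2[["distance"]], 0)
  # N column excluded as well
  expect_identical(pDistance(msa, "a", "d", minSites = 1)[["sites"]], 3)
  # minSites flags the pair uncomparable
  expect_true(is.na(pDistance(msa, "a", "b", minSites = 5)[["distance"]]))
})

test_that("distance matrix is a symmetric premetric matching pDistance", {
  cons <- randomSeq(200, 10)
  set.seed(11)
  rows <- vapply(1:5, function(i) {
    v <- strsplit(cons, "")[[1]]
    idx <- sample(200, 20)
    v[idx] <- sample(c("A", "C", "G", "T"), 20, TRUE)
    v[sample(200, 5)] <- "-"
    paste(v, collapse = "")
  }, "")
  names(rows) <- paste0("r", 1:5)
  msa <- msaFromRows(cons, rows)
  D <- distanceMatrix(msa)
  expect_identical(matrix(D, 5, 5), matrix(t(D), 5, 5))
  expect_identical(unname(diag(D)), rep(0, 5))
  for (i in 1:4) for (j in (i + 1):5)
    expect_identical(D[i, j],
                     pDistance(msa, i, j)[["distance"]])
})

test_that("a two-copy family yields a single edge of total length d", {
  D <- matrix(c(0, 0.1, 0.1, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  tr <- buildFamilyTree(D)
  expect_identical(sum(tr$edge.length), 0.1)
  pairs <- terminalForkPairs(tr)
  expect_identical(nrow(pairs), 1L)
  expect_setequal(pairs[1, ], c("a", "b"))
  # fewer than two copies: skipped
  expect_message(expect_null(buildFamilyTree(D[1, 1, drop = FALSE])),
                 "skipped")
})

test_that("NJ recovers the additive quartet chosen by exhaustive least squares", {
  # tree ((a:1,b:2):1,(c:3,d:4)) -> additive distances
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 3
  D["a", "c"] <- D["c", "a"] <- 5
  D["a", "d"] <- D["d", "a"] <- 6
  D["b", "c"] <- D["c", "b"] <- 6
  D["b", "d"] <- D["d", "b"] <- 7
  D["c", "d"] <- D["d", "c"] <- 7
  splits <- list(list(c("a", "b"), c("c", "d")),
                 list(c("a", "c"), c("b", "d")),
                 list(c("a", "d"), c("b", "c")))
  rss <- vapply(splits, function(s) oracleQuartetRss(D, s), 0)
  best <- splits[[which.min(rss)]]
  expect_identical(best[[1]], c("a", "b"))   # oracle picks ab|cd

  tr <- buildFamilyTree(D)
  pairs <- terminalForkPairs(tr)
  key <- apply(pairs, 1, function(p) paste(sort(p), collapse = "|"))
  expect_setequal(key, c("a|b", "c|d"))

  # permuting the input order changes nothing topological
  perm <- c("c", "a", "d", "b")
  tr2 <- buildFamilyTree(D[perm, perm])
  key2 <- apply(terminalForkPairs(tr2), 1, function(p)
    paste(sort(p), collapse = "|"))
  expect_setequal(key2, key)
})

test_that("terminal forks are exactly the common-parent leaf pairs", {
  bal <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  key <- apply(terminalForkPairs(bal), 1, function(p)
    paste(sort(p), collapse = "|"))
  expect_setequal(key, c("a|b", "c|d"))

  cat4 <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,d:1);")
  pairs <- terminalForkPairs(cat4)
  expect_identical(nrow(pairs), 1L)
  expect_setequal(pairs[1, ], c("a", "b"))

  expect_identical(nrow(terminalForkPairs(NULL)), 0L)
})

test_that("cherry ages equal the distance-matrix entries and respect the structural bound", {
  cons <- makeConsensus(FamilySpec("f", "RLX", 1000L), seed = 12)
  copies <- setNames(lapply(1:10, function(i)
    evolveCopy(cons, BurstSpec("f", 1, 0.02), seed = 300 + i)$sequence),
    paste0("c", 1:10))
  msa <- alignFamily(cons, unlist(copies))
  D <- distanceMatrix(msa)
  tr <- buildFamilyTree(D)
  ages <- familyAges(msa, tr)
  expect_gt(nrow(ages), 0)
  expect_lte(nrow(ages), 5L)     # at most floor(n/2) cherries, n >= 4
  for (k in seq_len(nrow(ages)))
    expect_identical(ages$age[k], D[ages$copy_a[k], ages$copy_b[k]])
  # pairwise divergence of two copies at d from the consensus is ~2d
  bound <- 2 * 0.02 + 3 * sqrt(2 * 0.02 * 0.98 / 1000)
  expect_true(all(ages$age <= bound))
})

test_that("two identical copies produce one age of zero", {
  cons <- randomSeq(300, 13)
  msa <- alignFamily(cons, c(a = cons, b = cons))
  tr <- buildFamilyTree(distanceMatrix(msa))
  ages <- familyAges(msa, tr)
  expect_identical(ages$age, 0)
})

test_that("copy-consensus divergence recovers planted values", {
  cons <- makeConsensus(FamilySpec("f", "RLX", 1000L), seed = 14)
  ev <- evolveCopy(cons, BurstSpec("f", 1, 0.20), seed = 15)
  msa <- alignFamily(cons, c(cp = ev$sequence))
  div <- copyConsensusDivergence(msa)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.20) / 1000
  expect_gte(div[["cp"]], bounds[1])
  expect_lte(div[["cp"]], bounds[2])
  expect_identical(div[["cp"]], ev$record$divergence)

  # identical copy: zero divergence; all-gap row: uncomparable
  msa2 <- msaFromRows("ACGTACGT", c(same = "ACGTACGT",
                                    gone = "--------"))
  d2 <- copyConsensusDivergence(msa2, minSites = 4)
  expect_identical(d2[["same"]], 0)
  expect_true(is.na(d2[["gone"]]))
})

test_that("age histogram uses half-open bins and supports strata", {
  h <- burstHistogram(rep(0.015, 7))
  nz <- h$bins[h$bins$count > 0, ]
  expect_identical(nrow(nz), 1L)
  expect_identical(nz$start, 0.01)

  # boundary value 0.02 falls in [0.02, 0.03), not [0.01, 0.02)
  hb <- burstHistogram(c(0.02))
  expect_identical(hb$bins$count[hb$bins$start == 0.02], 1L)
  expect_identical(hb$bins$count[hb$bins$start == 0.01], 0L)

  he <- burstHistogram(numeric())
  expect_true(all(he$bins$count == 0))

  hs <- burstHistogram(c(0.01, 0.21, 0.21), labels = c("x", "y", "y"))
  expect_equal(unname(rowSums(hs$strata)), c(1, 2))
})

test_that("burst detection finds spikes, respects prominence and orders by recency", {
  h1 <- burstHistogram(rep(0.105, 20))
  p1 <- detectBursts(h1)
  expect_identical(nrow(p1), 1L)
  expect_equal(p1$mid, 0.105)

  # flat histogram: never more than one peak
  hflat <- burstHistogram(seq(0.005, 0.245, by = 0.01))
  expect_lte(nrow(detectBursts(hflat)), 1L)

  # all-zero histogram: no peaks
  expect_identical(nrow(detectBursts(burstHistogram(numeric()))), 0L)

  # constructed bimodal ages: exactly two peaks at the modes, recent first
  set.seed(20)
  ages <- c(pmax(0, rnorm(100, 0.02, 0.004)), rnorm(100, 0.20, 0.012))
  h2 <- burstHistogram(ages)
  p2 <- detectBursts(h2)
  expect_identical(nrow(p2), 2L)
  expect_lt(abs(p2$mid[1] - 0.02), 0.015 + 1e-9)
  expect_lt(abs(p2$mid[2] - 0.20), 0.015 + 1e-9)
  expect_true(p2$mid[1] < p2$mid[2])
  # the two modes are separated by at least 5 empty bins
  gapBins <- h2$bins$count[h2$bins$start > 0.05 & h2$bins$start < 0.15]
  expect_gte(sum(gapBins == 0), 5)
})

test_that("bimodal synthetic families yield peaks at the planted divergences", {
  b <- burstSweepBundle(seed = 77L, nPerBurst = 8L)
  peaks <- bundleBurstPeaks(b)
  expect_identical(nrow(peaks), 2L)
  # planted value inside the peak bin or an adjacent bin
  expect_lte(abs(peaks$mid[1] - 0.02), 0.015 + 1e-9)
  expect_lte(abs(peaks$mid[2] - 0.20), 0.015 + 1e-9)
})
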