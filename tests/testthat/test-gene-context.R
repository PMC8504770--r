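# quick constructors for single-interval GRanges
teGr <- function(seqn, start, end, strand = "+", id = "te1") {
  GenomicRanges::GRanges(seqn, IRanges::IRanges(start, end), strand,
                         ID = id, family = "fam", class = "DTX")
}
geneGr <- function(seqn, start, end, strand = "+", id = "g1",
                   exons = NULL) {
  g <- GenomicRanges::GRanges(seqn, IRanges::IRanges(start, end), strand,
                              gene_id = id)
  ex <- if (is.null(exons))
    GenomicRanges::GRanges(seqn, IRanges::IRanges(start, end), strand,
                           gene_id = id)
  else
    GenomicRanges::GRanges(seqn, IRanges::IRanges(exons[, 1], exons[, 2]),
                           strand, gene_id = id)
  S4Vectors::mcols(g)$exons <- S4Vectors::split(
    ex, factor(ex$gene_id, levels = id))
  g
}

test_that("nearest gene distances follow edge-to-edge gap semantics", {
  genes <- c(geneGr("c", 150, 400, id = "gA"),
             geneGr("c", 301, 400, id = "gB"))
  # overlap -> distance 0
  nn <- nearestGene(teGr("c", 100, 200), genes[1])
  expect_identical(nn$distance, 0L)
  # TE [101,200], gene [301,400]: gap of 100 intervening bases
  nn2 <- nearestGene(teGr("c", 101, 200), genes[2])
  expect_identical(nn2$distance, 100L)
  # different sequence: no result
  expect_identical(nrow(nearestGene(teGr("other", 1, 50), genes)), 0L)
})

test_that("equidistant genes on both sides are both reported", {
  genes <- c(geneGr("c", 1, 100, id = "left"),
             geneGr("c", 401, 500, id = "right"))
  nn <- nearestGene(teGr("c", 201, 300), genes)
  expect_identical(nrow(nn), 2L)
  expect_setequal(nn$gene_id, c("left", "right"))
  expect_identical(unique(nn$distance), 100L)
})

test_that("nearest gene equals the all-pairs brute force on random fixtures", {
  for (seed in 1:30) {
    set.seed(seed)
    nT <- sample(5:25, 1); nG <- sample(3:15, 1)
    teS <- sample(1:9000, nT); teE <- teS + sample(50:500, nT, TRUE)
    gS <- sample(1:9000, nG);  gE <- gS + sample(100:800, nG, TRUE)
    teSeq <- sample(c("c1", "c2"), nT, TRUE)
    gSeq <- sample(c("c1", "c2"), nG, TRUE)
    tes <- GenomicRanges::GRanges(teSeq, IRanges::IRanges(teS, teE),
                                  ID = paste0("t", seq_len(nT)),
                                  family = "f", class = "DTX")
    genes <- GenomicRanges::GRanges(gSeq, IRanges::IRanges(gS, gE),
                                    gene_id = paste0("g", seq_len(nG)))
    got <- nearestGene(tes, genes)
    want <- oracleNearest(teS, teE, teSeq, gS, gE, gSeq)
    gotKey <- sort(paste(got$te_idx, got$gene_idx, got$distance))
    wantKey <- sort(paste(want$te, want$gene, want$distance))
    expect_identical(gotKey, wantKey, info = paste("seed", seed))
  }
})

test_that("positional categories follow the documented evaluation order", {
  # TE inside gene, overlapping the first exon, same strand
  g <- geneGr("c", 1000, 3000, "+", exons = cbind(c(1000, 2500),
                                                  c(1400, 2700)))
  r <- classifyInsertion(teGr("c", 1100, 1300, "+"), g)
  expect_identical(r$category, "te_inside_gene_exonic")
  expect_identical(r$orientation, "sense")
  expect_identical(r$gap_distance, 0)
  # intronic when no exon is touched
  r2 <- classifyInsertion(teGr("c", 1500, 2400, "-"), g)
  expect_identical(r2$category, "te_inside_gene_intronic")
  expect_identical(r2$orientation, "antisense")
  # TE spanning the start coordinate of a + strand gene
  r3 <- classifyInsertion(teGr("c", 900, 1200), g)
  expect_identical(r3$category, "overlap_5prime")
  # same geometry on a - strand gene is the 3' side
  gm <- geneGr("c", 1000, 3000, "-", exons = cbind(1000, 3000))
  r4 <- classifyInsertion(teGr("c", 900, 1200), gm)
  expect_identical(r4$category, "overlap_3prime")
  # and the gene-end overlap of a - strand gene is its 5' side
  r5 <- classifyInsertion(teGr("c", 2900, 3200), gm)
  expect_identical(r5$category, "overlap_5prime")
  # gene fully inside the TE wins over the overlap categories
  r6 <- classifyInsertion(teGr("c", 900, 3100), g)
  expect_identical(r6$category, "gene_inside_te")
  # abutting boundaries
  r7 <- classifyInsertion(teGr("c", 700, 999), g)
  expect_identical(r7$category, "boundary_gene_start_eq_te_end")
  expect_identical(r7$gap_distance, 0)
  r8 <- classifyInsertion(teGr("c", 3001, 3300), g)
  expect_identical(r8$category, "boundary_gene_end_eq_te_start")
  # near (strictly inside 2 kb) vs away
  r9 <- classifyInsertion(teGr("c", 4000, 4100), g)   # gap 999
  expect_identical(r9$category, "next_to_gene")
  expect_identical(r9$gap_distance, 999)
  r10 <- classifyInsertion(teGr("c", 5001, 5100), g)  # gap 2000
  expect_identical(r10$category, "none")
  r11 <- classifyInsertion(teGr("c", 5000, 5100), g)  # gap 1999
  expect_identical(r11$category, "next_to_gene")
  # unknown TE strand
  r12 <- classifyInsertion(teGr("c", 1100, 1300, "*"), g)
  expect_identical(r12$orientation, "undetermined")
  # no gene at all
  expect_identical(classifyInsertion(teGr("c", 1, 10), NULL)$category,
                   "none")
})

test_that("every TE-gene pair maps to exactly one category on a synthetic bundle", {
  b <- miniBundle(seed = 61L)
  ctx <- classifyContexts(teCopies(b), geneFeatures(b))
  expect_identical(length(unique(ctx$te_id)), length(teCopies(b)))
  expect_true(all(ctx$category %in% contextCategories()))
  # planted context plan recovered exactly from the annotations alone
  tr <- groundTruth(b)
  plan <- b@specs$genome@teGeneDistancePlan
  for (k in seq_len(nrow(plan))) {
    expect_identical(
      sum(ctx$category == plan$category[k] & !duplicated(ctx$te_id)),
      plan$count[k],
      info = plan$category[k])
  }
})

test_that("per-category chi-square matches the hand Pearson formula", {
  even <- orientationChiSquare(matrix(c(30, 30), 1,
                                      dimnames = list("x", NULL)))
  expect_identical(even$per_category$statistic, 0)
  expect_identical(even$per_category$p_value, 1)

  pub <- publishedOrientationCounts()
  res <- orientationChiSquare(pub)
  five <- res$per_category[res$per_category$category == "five_prime", ]
  expect_equal(five$statistic, (304 - 239)^2 / (304 + 239))
  expect_equal(five$statistic, 7.7808, tolerance = 1e-4)
  expect_lt(five$p_value, 0.01)

  expect_equal(res$omnibus$df, 4)
  expect_equal(res$omnibus$statistic, 10.1407, tolerance = 1e-4)
  expect_lte(res$omnibus$p_value, 0.05)
})

test_that("omnibus p-values match numerical integration of the density", {
  for (df in c(1, 2, 4, 7, 10)) {
    for (q in c(0.5, 3.2, 10.14)) {
      expect_equal(pchisq(q, df, lower.tail = FALSE),
                   oracleChisqSf(q, df), tolerance = 1e-8)
    }
  }
})

test_that("zero-total categories are excluded from the tests", {
  m <- matrix(c(10, 5, 0, 0, 8, 12), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  expect_message(res <- orientationChiSquare(m), "b")
  expect_identical(nrow(res$per_category), 2L)
  expect_equal(res$omnibus$df, 1)
})

test_that("recent-insertion report applies the strict divergence cutoff", {
  ctx <- data.frame(
    te_id = paste0("t", 1:4),
    family = c("mite1", "mite1", "hat1", "hat1"),
    class = "DTX",
    gene_id = "g",
    category = c("te_inside_gene_exonic", "next_to_gene",
                 "overlap_5prime", "overlap_3prime"),
    orientation = c("sense", "antisense", "sense", "sense"),
    gap_distance = c(0, 100, 0, 0),
    divergence = c(0.01, 0.02, 0.019, 0.05))
  rep <- recentInsertionReport(ctx)
  # divergence 0.02 exactly and 0.05 are excluded
  expect_identical(rep$total_sites[rep$label == "Total"], 2L)
  expect_identical(rep$inside_exonic[rep$label == "mite1"], 1L)
  expect_identical(rep$five_prime[rep$label == "hat1"], 1L)

  empty <- recentInsertionReport(ctx[0, ])
  expect_identical(empty$total_sites[empty$label == "Total"], 0L)
})

test_that("summing the published per-superfamily recent counts gives the printed total", {
  pub <- publishedRecentInsertionCounts()
  expect_identical(sum(pub$n_sites), 86L)
})
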