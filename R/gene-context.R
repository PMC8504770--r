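## TE-gene insertion context: nearest-gene search, positional
## classification, orientation chi-square tests, recent-insertion report.

#' Read gene annotations (gene + exon features) from GFF3
#'
#' Genes are \code{type == "gene"} rows with an \code{ID} attribute;
#' exons are \code{type == "exon"} rows linked by \code{Parent}.
#'
#' @param path GFF3 file path.
#' @return \code{GRanges} of genes with \code{gene_id} and an
#'   \code{exons} \code{GRangesList} metadata column.
#' @export
readGeneGff <- function(path) {
  df <- .readGff3(path)
  g <- df[df$type == "gene", , drop = FALSE]
  e <- df[df$type == "exon", , drop = FALSE]
  gid <- vapply(lapply(g$attributes, .parseGffAttrs),
                function(a) unname(a["ID"] %0% ""), "")
  pid <- vapply(lapply(e$attributes, .parseGffAttrs),
                function(a) unname(a["Parent"] %0% ""), "")
  genes <- GenomicRanges::GRanges(
    seqnames = g$seqid, ranges = IRanges::IRanges(g$start, g$end),
    strand = ifelse(g$strand %in% c("+", "-"), g$strand, "*"),
    gene_id = gid)
  exons <- GenomicRanges::GRanges(
    seqnames = e$seqid, ranges = IRanges::IRanges(e$start, e$end),
    strand = ifelse(e$strand %in% c("+", "-"), e$strand, "*"),
    gene_id = pid)
  S4Vectors::mcols(genes)$exons <-
    S4Vectors::split(exons, factor(exons$gene_id, levels = gid))
  genes
}

#' Write gene annotations (gene + exon features) to GFF3
#'
#' @param genes \code{GRanges} as returned by \code{\link{readGeneGff}}
#'   or \code{\link{geneFeatures}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeGeneGff <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(genes)) {
    g <- genes[i]
    writeLines(sprintf("%s\tTEmobilome\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       as.character(GenomicRanges::seqnames(g)),
                       GenomicRanges::start(g), GenomicRanges::end(g),
                       as.character(GenomicRanges::strand(g)),
                       g$gene_id), con)
    ex <- g$exons[[1]]
    if (length(ex))
      writeLines(sprintf(
        "%s\tTEmobilome\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
        as.character(GenomicRanges::seqnames(ex)),
        GenomicRanges::start(ex), GenomicRanges::end(ex),
        as.character(GenomicRanges::strand(ex)), ex$gene_id), con)
  }
  invisible(path)
}

#' Nearest gene(s) for each TE copy
#'
#' Minimal edge-to-edge gap on the same sequence, 0 on overlap or
#' abutment; a TE equidistant from genes on both sides yields one row
#' per tied gene.  TEs with no gene on their sequence are omitted.
#'
#' @param tes \code{GRanges} of TE copies (with an \code{ID} column).
#' @param genes \code{GRanges} of genes (with \code{gene_id}).
#' @return data.frame with \code{te_idx}, \code{te_id}, \code{gene_idx},
#'   \code{gene_id}, \code{distance}.
#' @export
nearestGene <- function(tes, genes) {
  teSeq <- as.character(GenomicRanges::seqnames(tes))
  gSeq <- as.character(GenomicRanges::seqnames(genes))
  empty <- data.frame(te_idx = integer(), te_id = character(),
                      gene_idx = integer(), gene_id = character(),
                      distance = integer())
  out <- list(empty)
  for (sq in unique(teSeq)) {
    ti <- which(teSeq == sq)
    gi <- which(gSeq == sq)
    if (!length(gi)) next
    ts <- GenomicRanges::start(tes)[ti]
    te_ <- GenomicRanges::end(tes)[ti]
    gs <- GenomicRanges::start(genes)[gi]
    ge <- GenomicRanges::end(genes)[gi]
    # gap matrix (TE rows x gene cols): intervening bases, 0 on overlap
    # or abutment
    D <- pmax(outer(ts, ge, "-"), -outer(te_, gs, "-")) - 1L
    D[D < 0L] <- 0L
    dim(D) <- c(length(ti), length(gi))
    for (r in seq_along(ti)) {
      best <- min(D[r, ])
      hit <- which(D[r, ] == best)
      out[[length(out) + 1L]] <- data.frame(
        te_idx = ti[r], te_id = tes$ID[ti[r]],
        gene_idx = gi[hit], gene_id = genes$gene_id[gi[hit]],
        distance = as.integer(best))
    }
  }
  res <- do.call(rbind, out)
  res[order(res$te_idx, res$gene_idx), , drop = FALSE]
}

#' Classify one TE-gene pair into a positional category
#'
#' Categories are evaluated in a fixed order: gene contained in the TE;
#' TE contained in the gene (sub-typed \code{exonic} if the TE overlaps
#' any exon, else \code{intronic}); TE overlapping the strand-aware
#' transcription start (\code{overlap_5prime}) or end
#' (\code{overlap_3prime}); exact abutment (\code{boundary_*}); TE
#' within \code{nearThreshold} of the gene (\code{next_to_gene},
#' strict \code{0 < gap < nearThreshold}); otherwise \code{none}.
#' Orientation is \code{sense} when TE and gene strands agree,
#' \code{antisense} when they differ, \code{undetermined} when the TE
#' strand is unknown.
#'
#' @param te \code{GRanges} of length 1.
#' @param gene \code{GRanges} of length 1 (with \code{exons} metadata),
#'   or \code{NULL}.
#' @param nearThreshold proximity threshold in bases (default 2000).
#' @return List with \code{category}, \code{orientation},
#'   \code{gap_distance}.
#' @export
classifyInsertion <- function(te, gene, nearThreshold = 2000) {
  if (is.null(gene) || length(gene) == 0L)
    return(list(category = "none", orientation = "undetermined",
                gap_distance = NA_real_))
  if (as.character(GenomicRanges::seqnames(te)) !=
      as.character(GenomicRanges::seqnames(gene)))
    stop("TE and gene must lie on the same sequence")
  ts <- GenomicRanges::start(te); te_ <- GenomicRanges::end(te)
  gs <- GenomicRanges::start(gene); ge <- GenomicRanges::end(gene)
  gStrand <- as.character(GenomicRanges::strand(gene))
  tStrand <- as.character(GenomicRanges::strand(te))
  orientation <- if (tStrand %in% c("+", "-"))
    if (tStrand == gStrand) "sense" else "antisense" else "undetermined"
  overlap <- ts <= ge && gs <= te_
  gap <- if (overlap) 0 else max(gs - te_, ts - ge) - 1
  category <- if (ts <= gs && ge <= te_) {
    "gene_inside_te"
  } else if (gs <= ts && te_ <= ge) {
    exons <- if (!is.null(gene$exons)) gene$exons[[1]] else NULL
    hasExon <- !is.null(exons) && length(exons) &&
      any(GenomicRanges::start(exons) <= te_ &
          ts <= GenomicRanges::end(exons))
    if (hasExon) "te_inside_gene_exonic" else "te_inside_gene_intronic"
  } else if (overlap) {
    tss <- if (gStrand == "-") ge else gs
    tts <- if (gStrand == "-") gs else ge
    if (ts <= tss && tss <= te_) "overlap_5prime"
    else if (ts <= tts && tts <= te_) "overlap_3prime"
    else stop("inconsistent overlap geometry")   # unreachable
  } else if (te_ + 1L == gs) {
    "boundary_gene_start_eq_te_end"
  } else if (ge + 1L == ts) {
    "boundary_gene_end_eq_te_start"
  } else if (gap > 0 && gap < nearThreshold) {
    "next_to_gene"
  } else {
    "none"
  }
  list(category = category, orientation = orientation,
       gap_distance = if (overlap || te_ + 1L == gs || ge + 1L == ts) 0
                      else gap)
}

#' Insertion contexts of all TE copies relative to their nearest genes
#'
#' Runs \code{\link{nearestGene}} and \code{\link{classifyInsertion}}
#' over a full annotation; TEs without a same-sequence gene get category
#' \code{none}.  When per-copy divergences are supplied, copies strictly
#' below \code{recencyThreshold} are flagged recent.
#'
#' @param tes \code{GRanges} of TE copies (\code{ID}, \code{family},
#'   \code{class} metadata).
#' @param genes \code{GRanges} of genes with \code{exons}.
#' @param nearThreshold proximity threshold (default 2000).
#' @param divergences optional named vector (by TE \code{ID}) of
#'   copy-consensus divergences.
#' @param recencyThreshold strict recency cutoff (default 0.02).
#' @return data.frame with one row per (TE, nearest gene) pair:
#'   \code{te_id}, \code{family}, \code{class}, \code{gene_id},
#'   \code{category}, \code{orientation}, \code{gap_distance},
#'   \code{divergence}, \code{recent}.
#' @export
classifyContexts <- function(tes, genes, nearThreshold = 2000,
                             divergences = NULL,
                             recencyThreshold = 0.02) {
  nn <- nearestGene(tes, genes)
  rows <- vector("list", 0L)
  for (i in seq_along(tes)) {
    gidx <- nn$gene_idx[nn$te_idx == i]
    if (!length(gidx)) {
      cl <- classifyInsertion(tes[i], NULL, nearThreshold)
      gid <- NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        te_id = tes$ID[i], family = tes$family[i], class = tes$class[i],
        gene_id = gid, category = cl$category,
        orientation = cl$orientation, gap_distance = cl$gap_distance)
    } else {
      for (g in gidx) {
        cl <- classifyInsertion(tes[i], genes[g], nearThreshold)
        rows[[length(rows) + 1L]] <- data.frame(
          te_id = tes$ID[i], family = tes$family[i], class = tes$class[i],
          gene_id = genes$gene_id[g], category = cl$category,
          orientation = cl$orientation, gap_distance = cl$gap_distance)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(divergences)) {
    out$divergence <- unname(divergences[out$te_id])
    out$recent <- !is.na(out$divergence) &
      out$divergence < recencyThreshold
  }
  out
}

#' Orientation bias chi-square tests
#'
#' For each positional category, a Pearson goodness-of-fit test of the
#' sense/antisense counts against 50:50 (df 1, no continuity
#' correction); plus an omnibus Pearson independence test on the full
#' categories-by-orientation table (df = categories - 1).  Categories
#' with zero total are excluded with a message.
#'
#' @param counts matrix or data.frame with one row per category and two
#'   columns (sense, antisense); row names are category labels.
#' @return List with \code{per_category} (data.frame: category, sense,
#'   antisense, statistic, df, p_value) and \code{omnibus} (list:
#'   statistic, df, p_value).
#' @export
orientationChiSquare <- function(counts) {
  m <- as.matrix(counts)
  if (ncol(m) != 2) stop("counts must have two columns (sense, antisense)")
  if (any(m < 0)) stop("counts must be non-negative")
  zero <- rowSums(m) == 0
  if (any(zero)) {
    message("excluding zero-total category(ies): ",
            paste(rownames(m)[zero], collapse = ", "))
    m <- m[!zero, , drop = FALSE]
  }
  per <- data.frame(
    category = rownames(m) %||% as.character(seq_len(nrow(m))),
    sense = m[, 1], antisense = m[, 2],
    statistic = (m[, 1] - m[, 2])^2 / (m[, 1] + m[, 2]),
    df = 1L, row.names = NULL)
  per$p_value <- pchisq(per$statistic, df = 1, lower.tail = FALSE)
  omnibus <- if (nrow(m) >= 2) {
    ct <- suppressWarnings(chisq.test(m, correct = FALSE))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value))
  } else {
    list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
  }
  list(per_category = per, omnibus = omnibus)
}

#' Recent-insertion report by superfamily and insertion site
#'
#' Filters contexts to copies with divergence strictly below
#' \code{maxDivergence} (a copy at exactly the cutoff is excluded) and
#' tabulates counts by TE label across the gene-relative site groups:
#' next to the gene, included inside the gene (exonic / intronic),
#' 5' side and 3' side.  A \code{Total} row sums the label rows; an
#' \code{orientation} attribute carries sense/antisense totals per
#' group.
#'
#' @param contexts data.frame from \code{\link{classifyContexts}} (must
#'   carry \code{divergence}).
#' @param maxDivergence strict divergence cutoff (default 0.02).
#' @param labelCol column of \code{contexts} used as the report label
#'   (default \code{"family"}).
#' @return data.frame: \code{label}, \code{next_to_gene},
#'   \code{inside_exonic}, \code{inside_intronic}, \code{five_prime},
#'   \code{three_prime}, \code{total_sites}.
#' @export
recentInsertionReport <- function(contexts, maxDivergence = 0.02,
                                  labelCol = "family") {
  stopifnot("divergence" %in% names(contexts))
  rec <- contexts[!is.na(contexts$divergence) &
                  contexts$divergence < maxDivergence, , drop = FALSE]
  siteCats <- c(next_to_gene = "next_to_gene",
                inside_exonic = "te_inside_gene_exonic",
                inside_intronic = "te_inside_gene_intronic",
                five_prime = "overlap_5prime",
                three_prime = "overlap_3prime")
  rec <- rec[rec$category %in% siteCats, , drop = FALSE]
  labels <- sort(unique(rec[[labelCol]]))
  tab <- vapply(names(siteCats), function(sc)
    vapply(labels, function(l)
      sum(rec[[labelCol]] == l & rec$category == siteCats[[sc]]), 0L),
    integer(length(labels)))
  if (length(labels) == 1L) tab <- matrix(tab, nrow = 1L,
                                          dimnames = list(labels,
                                                          names(siteCats)))
  storage.mode(tab) <- "integer"
  out <- data.frame(label = labels, tab, row.names = NULL)
  out$total_sites <- as.integer(rowSums(tab))
  total <- data.frame(label = "Total",
                      t(as.integer(colSums(tab))) |>
                        `colnames<-`(names(siteCats)),
                      total_sites = as.integer(sum(tab)))
  out <- rbind(out, total)
  orient <- vapply(names(siteCats), function(sc) c(
    sense = sum(rec$orientation == "sense" &
                rec$category == siteCats[[sc]]),
    antisense = sum(rec$orientation == "antisense" &
                    rec$category == siteCats[[sc]])), numeric(2))
  attr(out, "orientation") <- orient
  out
}
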