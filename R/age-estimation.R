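## Copy ages in substitutions per base pair: p-distances on the
## master-slave alignment, neighbor-joining family trees, terminal-fork
## (cherry) pairs, age histograms and burst detection.

.rowChars <- function(msa, id) {
  m <- msaMatrix(msa)
  if (is.character(id) && !(id %in% rownames(m)))
    stop("no MSA row named '", id, "'")
  m[id, ]
}

#' p-distance between two aligned copies
#'
#' Proportion of mismatching sites over the columns where both rows carry
#' an unambiguous base; any column with \code{"-"} or \code{"N"} in
#' either row is excluded.  Pairs sharing fewer than \code{minSites}
#' comparable sites are uncomparable and get distance \code{NA}.
#'
#' @param msa a \code{\link{MasterSlaveMSA}}.
#' @param i,j row names or indices.
#' @param minSites minimum comparable sites (default 50).
#' @return Named numeric vector \code{c(distance, sites)}.
#' @export
pDistance <- function(msa, i, j, minSites = 50) {
  a <- .rowChars(msa, i)
  b <- .rowChars(msa, j)
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n <- sum(ok)
  d <- if (n < minSites) NA_real_ else sum(a[ok] != b[ok]) / n
  c(distance = d, sites = n)
}

#' All pairwise p-distances of an alignment
#'
#' @inheritParams pDistance
#' @return Symmetric matrix of p-distances (zero diagonal, \code{NA} for
#'   uncomparable pairs) with a \code{"sites"} attribute holding the
#'   matrix of compared-site counts.
#' @export
distanceMatrix <- function(msa, minSites = 50) {
  m <- msaMatrix(msa)
  n <- nrow(m)
  base <- m %in% c("A", "C", "G", "T")
  dim(base) <- dim(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  S <- matrix(0L, n, n, dimnames = dimnames(D))
  if (n >= 2) for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ok <- base[i, ] & base[j, ]
    s <- sum(ok)
    d <- if (s < minSites) NA_real_ else sum(m[i, ok] != m[j, ok]) / s
    D[i, j] <- D[j, i] <- d
    S[i, j] <- S[j, i] <- s
  }
  attr(D, "sites") <- S
  D
}

#' Neighbor-joining tree of a family's copies
#'
#' Builds an unrooted NJ tree from a p-distance matrix.  Copies involved
#' in uncomparable (\code{NA}) pairs are dropped greedily (most-NA
#' first) until the matrix is complete.  Negative branch lengths are
#' clamped to zero.  With exactly two copies the tree is a single edge
#' whose total length is their distance; with fewer than two comparable
#' copies the family is skipped (returns \code{NULL} with a message).
#'
#' @param dm distance matrix from \code{\link{distanceMatrix}}.
#' @return An \code{ape} \code{phylo} object, or \code{NULL}.
#' @export
buildFamilyTree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  while (anyNA(dm) && nrow(dm) > 2) {
    nNA <- rowSums(is.na(dm))
    dm <- dm[-which.max(nNA), -which.max(nNA), drop = FALSE]
  }
  if (anyNA(dm)) dm <- dm[0, 0, drop = FALSE]
  if (nrow(dm) < 2) {
    message("fewer than 2 comparable copies; family skipped")
    return(NULL)
  }
  if (nrow(dm) == 2) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               tip.label = rownames(dm),
               edge.length = rep(dm[1, 2] / 2, 2),
               Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Terminal-fork (cherry) pairs of a tree
#'
#' Returns every pair of leaves whose connecting path contains exactly
#' one internal node, i.e. both leaves hang off the same internal node.
#' These pairs date the most recent transposition events.
#'
#' @param tree an \code{ape} \code{phylo} object.
#' @return Two-column character matrix of leaf-label pairs (possibly
#'   zero rows).
#' @export
terminalForkPairs <- function(tree) {
  if (is.null(tree)) return(matrix(character(), 0, 2))
  nTip <- length(tree$tip.label)
  leafParent <- tree$edge[tree$edge[, 2] <= nTip, , drop = FALSE]
  out <- list()
  for (v in unique(leafParent[, 1])) {
    leaves <- leafParent[leafParent[, 1] == v, 2]
    if (length(leaves) >= 2) {
      cmb <- utils::combn(sort(leaves), 2)
      for (k in seq_len(ncol(cmb)))
        out[[length(out) + 1L]] <- tree$tip.label[cmb[, k]]
    }
  }
  if (!length(out)) return(matrix(character(), 0, 2))
  do.call(rbind, out)
}

#' Cherry ages of one family
#'
#' One age per terminal fork: the raw p-distance of the leaf pair (in
#' substitutions per base pair, uncorrected).  Cherries whose pair is
#' uncomparable at \code{minSites} are dropped with a message.
#'
#' @param msa a \code{\link{MasterSlaveMSA}}.
#' @param tree tree over (a subset of) the MSA rows, as returned by
#'   \code{\link{buildFamilyTree}}.
#' @param familyId optional label copied into the result.
#' @param minSites minimum comparable sites.
#' @return data.frame with \code{copy_a}, \code{copy_b}, \code{age},
#'   \code{sites}, \code{family}.
#' @export
familyAges <- function(msa, tree, familyId = consensusId(msa),
                       minSites = 50) {
  pairs <- terminalForkPairs(tree)
  res <- data.frame(copy_a = character(), copy_b = character(),
                    age = numeric(), sites = integer(),
                    family = character())
  for (k in seq_len(nrow(pairs))) {
    pd <- pDistance(msa, pairs[k, 1], pairs[k, 2], minSites = minSites)
    if (is.na(pd[["distance"]])) {
      message("cherry ", pairs[k, 1], "/", pairs[k, 2],
              " uncomparable; dropped")
      next
    }
    res[nrow(res) + 1L, ] <- list(pairs[k, 1], pairs[k, 2],
                                  pd[["distance"]],
                                  as.integer(pd[["sites"]]), familyId)
  }
  res
}

#' Divergence of each copy from the family consensus
#'
#' p-distance of every MSA row against the consensus (master) sequence,
#' with the same column-exclusion rule as \code{\link{pDistance}}.  This
#' is the per-copy age statistic: recent copies have low divergence from
#' their putative ancestral sequence.
#'
#' @inheritParams pDistance
#' @return Named numeric vector of divergences (\code{NA} where fewer
#'   than \code{minSites} sites are comparable), with a \code{"sites"}
#'   attribute.
#' @export
copyConsensusDivergence <- function(msa, minSites = 50) {
  m <- msaMatrix(msa)
  cons <- strsplit(consensusSeq(msa), "", fixed = TRUE)[[1]]
  consOk <- cons %in% c("A", "C", "G", "T")
  d <- numeric(nrow(m)); s <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    ok <- consOk & m[i, ] %in% c("A", "C", "G", "T")
    s[i] <- sum(ok)
    d[i] <- if (s[i] < minSites) NA_real_ else sum(m[i, ok] != cons[ok]) / s[i]
  }
  names(d) <- rownames(m)
  attr(d, "sites") <- setNames(s, rownames(m))
  d
}

#' Histogram of copy ages
#'
#' Half-open bins \code{[k*w, (k+1)*w)}.  When \code{labels} is supplied
#' (one label per age, e.g. the superfamily), per-label counts are
#' returned alongside the pooled counts.
#'
#' @param ages numeric vector of ages in \code{[0, 1]}; \code{NA}s are
#'   dropped.
#' @param binWidth bin width in divergence units (default 0.01).
#' @param labels optional character vector along \code{ages}.
#' @return An object of class \code{"ageHistogram"}: list with
#'   \code{bins} (data.frame \code{start}, \code{mid}, \code{count}),
#'   \code{binWidth} and optional \code{strata} (label-by-bin matrix).
#' @export
burstHistogram <- function(ages, binWidth = 0.01, labels = NULL) {
  if (!is.null(labels)) labels <- labels[!is.na(ages)]
  ages <- ages[!is.na(ages)]
  stopifnot(all(ages >= 0), all(ages <= 1))
  upper <- max(c(ages, 0.25)) + binWidth
  nBins <- ceiling(upper / binWidth)
  starts <- (seq_len(nBins) - 1L) * binWidth
  bin <- pmin(floor(ages / binWidth), nBins - 1L) + 1L
  counts <- tabulate(bin, nbins = nBins)
  out <- list(bins = data.frame(start = starts, mid = starts + binWidth / 2,
                                count = counts),
              binWidth = binWidth)
  if (!is.null(labels)) {
    strata <- vapply(sort(unique(labels)), function(l)
      tabulate(bin[labels == l], nbins = nBins), integer(nBins))
    out$strata <- t(strata)
  }
  class(out) <- "ageHistogram"
  out
}

#' Detect transposition bursts in an age histogram
#'
#' Smooths the counts with a centred moving average (window
#' \code{smoothWindow} bins, truncated at the edges), then reports local
#' maxima of the smoothed profile whose height reaches
#' \code{minProminenceFraction} of the smoothed maximum.  Plateaus of
#' equal smoothed values count as a single peak, located at the raw-count
#' maximum of the run (leftmost on ties).  Peaks are returned sorted by
#' recency (lowest divergence first).
#'
#' @param hist an \code{"ageHistogram"} from \code{\link{burstHistogram}}.
#' @param minProminenceFraction height threshold relative to the highest
#'   smoothed bin (default 0.1).
#' @param smoothWindow moving-average window in bins (odd; default 3).
#' @return data.frame with \code{mid} (bin centre), \code{count} (raw)
#'   and \code{smoothed}; zero rows for an all-zero histogram.
#' @export
detectBursts <- function(hist, minProminenceFraction = 0.1,
                         smoothWindow = 3) {
  stopifnot(inherits(hist, "ageHistogram"), smoothWindow %% 2 == 1)
  c0 <- hist$bins$count
  n <- length(c0)
  if (!n || all(c0 == 0))
    return(data.frame(mid = numeric(), count = integer(),
                      smoothed = numeric()))
  h <- (smoothWindow - 1) / 2
  s <- vapply(seq_len(n), function(i)
    mean(c0[max(1, i - h):min(n, i + h)]), 0)
  thr <- minProminenceFraction * max(s)
  # plateau-aware local maxima on the smoothed profile
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  startsIdx <- ends - runs$lengths + 1L
  peaks <- integer()
  for (r in seq_along(runs$values)) {
    left <- if (r == 1) -Inf else runs$values[r - 1]
    right <- if (r == length(runs$values)) -Inf else runs$values[r + 1]
    if (runs$values[r] > left && runs$values[r] > right &&
        runs$values[r] >= thr) {
      idx <- startsIdx[r]:ends[r]
      peaks <- c(peaks, idx[which.max(c0[idx])])
    }
  }
  peaks <- sort(peaks)
  data.frame(mid = hist$bins$mid[peaks], count = c0[peaks],
             smoothed = s[peaks])
}
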