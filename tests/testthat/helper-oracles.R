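# Independent brute-force oracles used across the suite.  None of these
# share code paths with the package implementation.

# Exhaustive global-alignment score: enumerate every alignment of a and b
# by recursion over the three moves, scoring incrementally with the same
# cost convention as scoringScheme (gap run costs open + L * extend).
oracleAlignScore <- function(a, b, scoring = scoringScheme()) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  subScore <- function(x, y) {
    if (x == "N" || y == "N") 0
    else if (x == y) scoring$match else scoring$mismatch
  }
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, subScore(av[i], bv[j]) + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(av)) {  # gap in b
      open <- if (last != "X") scoring$gapOpen else 0
      best <- max(best, open + scoring$gapExtend + rec(i + 1, j, "X"))
    }
    if (j <= length(bv)) {  # gap in a
      open <- if (last != "Y") scoring$gapOpen else 0
      best <- max(best, open + scoring$gapExtend + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "none")
}

# Per-base boolean-mask union coverage, grouped.
oracleCoverage <- function(starts, ends, seqnames, genomeLengths) {
  masks <- lapply(genomeLengths, function(L) logical(L))
  for (k in seq_along(starts)) {
    masks[[seqnames[k]]][starts[k]:ends[k]] <- TRUE
  }
  sum(vapply(masks, sum, 0))
}

# All-pairs nearest gene: minimal edge gap per TE, ties kept.
oracleNearest <- function(teStart, teEnd, teSeq, gStart, gEnd, gSeq) {
  out <- list()
  for (i in seq_along(teStart)) {
    same <- which(gSeq == teSeq[i])
    if (!length(same)) next
    gaps <- vapply(same, function(g) {
      if (teStart[i] <= gEnd[g] && gStart[g] <= teEnd[i]) 0
      else max(gStart[g] - teEnd[i], teStart[i] - gEnd[g]) - 1
    }, 0)
    best <- min(gaps)
    out[[i]] <- data.frame(te = i, gene = same[gaps == best],
                           distance = best)
  }
  do.call(rbind, out)
}

# Chi-square survival function by numerical integration of the density
# written from the formula (independent of pchisq).
oracleChisqSf <- function(q, df) {
  dens <- function(x) x^(df / 2 - 1) * exp(-x / 2) /
    (2^(df / 2) * gamma(df / 2))
  stats::integrate(dens, q, Inf, rel.tol = 1e-12)$value
}

# Double-loop TIR scan for short sequences (mirrors the definition, not
# the C++ code): returns all (start, end, tir, mism) rows, 1-based.
oracleTirScan <- function(s, minTir, maxTir, minLen, maxLen, maxMismatch) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  rows <- list()
  for (i in seq_len(n)) {
    for (j in seq(i + minLen - 1, min(n, i + maxLen - 1))) {
      if (j > n) break
      len <- j - i + 1
      tcap <- min(maxTir, len %/% 2)
      mism <- 0L; bt <- 0L; bm <- 0L
      for (k in seq_len(tcap)) {
        a <- v[i + k - 1]
        b <- comp[v[j - k + 1]]
        if (a == "N" || b == "N" || a != b) mism <- mism + 1L
        if (mism > maxMismatch) break
        bt <- k; bm <- mism
      }
      if (bt >= minTir)
        rows[[length(rows) + 1L]] <- data.frame(start = i, end = j,
                                                tir_length = bt,
                                                tir_mismatches = bm)
    }
  }
  if (!length(rows)) return(data.frame(start = integer(), end = integer(),
                                       tir_length = integer(),
                                       tir_mismatches = integer()))
  do.call(rbind, rows)
}

# Exact-match TIR pairing via k-mer hashing: positions i where the
# minTir-mer at i equals the reverse complement of the minTir-mer ending
# at j, with element length in range.  Used for max_mismatch = 0 scans.
oracleTirSeeds <- function(s, minTir, minLen, maxLen) {
  n <- nchar(s)
  if (n < minLen) return(data.frame(start = integer(), end = integer()))
  starts <- seq_len(n - minTir + 1)
  kmers <- substring(s, starts, starts + minTir - 1)
  rc <- vapply(kmers, function(k)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(k))),
    "")
  hits <- list()
  idx <- split(seq_along(kmers), kmers)
  for (i in seq_along(kmers)) {
    js <- idx[[rc[i]]]          # suffix k-mer start positions
    if (is.null(js)) next
    ends <- js + minTir - 1
    keep <- ends - i + 1 >= minLen & ends - i + 1 <= maxLen
    if (any(keep))
      hits[[length(hits) + 1L]] <- data.frame(start = i, end = ends[keep])
  }
  if (!length(hits)) return(data.frame(start = integer(), end = integer()))
  do.call(rbind, hits)
}

# Least-squares branch fit of a 4-taxon topology; returns RSS.  Used to
# pick the best quartet topology by exhaustive enumeration.
oracleQuartetRss <- function(D, split) {
  # split: list(c(x, y), c(z, w)) of leaf names forming the cherries
  taxa <- rownames(D)
  x <- split[[1]][1]; y <- split[[1]][2]
  z <- split[[2]][1]; w <- split[[2]][2]
  # design matrix over edges (ex, ey, ez, ew, mid) for the 6 distances
  pairs <- t(combn(taxa, 2))
  A <- matrix(0, nrow(pairs), 5,
              dimnames = list(NULL, c(x, y, z, w, "mid")))
  d <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    p <- pairs[r, ]
    d[r] <- D[p[1], p[2]]
    A[r, p[1]] <- 1
    A[r, p[2]] <- 1
    onLeft <- p %in% c(x, y)
    if (sum(onLeft) == 1) A[r, "mid"] <- 1
  }
  fit <- lm.fit(A, d)
  sum(fit$residuals^2)
}
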