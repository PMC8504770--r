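## Structural MITE discovery: TIR scan, TSD validation, greedy family
## clustering and superfamily assignment from a TSD/TIR signature table.

#' Scan a sequence for TIR-bounded element candidates
#'
#' Finds every interval of length \code{[minLen, maxLen]} whose prefix of
#' some length \code{t} in \code{[minTir, maxTir]} matches the reverse
#' complement of its suffix of length \code{t} with at most
#' \code{maxMismatch} mismatches (the longest such \code{t} is kept per
#' interval; \code{N} always mismatches).  Overlapping candidates are
#' resolved greedily, longest TIR first, then leftmost.  The TIR
#' structure is strand-symmetric, so elements on either strand are found
#' by one forward scan.
#'
#' @param sequence character string or \code{DNAString} over
#'   \code{A C G T N}.
#' @param seqId sequence name recorded on the candidates.
#' @param minTir,maxTir TIR length bounds in bases.
#' @param minLen,maxLen element length bounds in bases.
#' @param maxMismatch maximum mismatches within the TIR.
#' @param resolveOverlaps drop lower-ranked overlapping candidates
#'   (default TRUE).
#' @return data.frame of candidates: \code{seq_id}, \code{start},
#'   \code{end} (1-based inclusive), \code{element_length},
#'   \code{tir_length}, \code{tir_mismatches}.
#' @export
findInvertedRepeats <- function(sequence, seqId = "seq",
                                minTir = 10L, maxTir = 200L,
                                minLen = 50L, maxLen = 800L,
                                maxMismatch = 2L,
                                resolveOverlaps = TRUE) {
  s <- toupper(as.character(sequence))
  if (grepl("[^ACGTN]", s))
    stop("sequence must be over the alphabet {A,C,G,T,N}")
  cand <- .tir_scan_cpp(s, as.integer(minTir), as.integer(maxTir),
                        as.integer(minLen), as.integer(maxLen),
                        as.integer(maxMismatch))
  cand <- as.data.frame(cand)
  if (!nrow(cand))
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), element_length = integer(),
                      tir_length = integer(), tir_mismatches = integer()))
  # 0-based [start, end) from the scanner -> 1-based inclusive
  out <- data.frame(seq_id = seqId, start = cand$start + 1L,
                    end = cand$end, element_length = cand$end - cand$start,
                    tir_length = cand$tir_length,
                    tir_mismatches = cand$tir_mismatches)
  if (resolveOverlaps) {
    out <- out[order(-out$tir_length, out$start, out$end), , drop = FALSE]
    taken <- rep(FALSE, nchar(s))
    keep <- logical(nrow(out))
    for (k in seq_len(nrow(out))) {
      span <- out$start[k]:out$end[k]
      if (!any(taken[span])) {
        keep[k] <- TRUE
        taken[span] <- TRUE
      }
    }
    out <- out[keep, , drop = FALSE]
    out <- out[order(out$start), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Validate target-site duplications of candidates
#'
#' For each candidate, the largest \code{k} in \code{kRange} such that
#' the \code{k} bases immediately left of the element equal the
#' \code{k} bases immediately right of it is recorded as the TSD.  In
#' strict mode candidates with no matching flank of at least
#' \code{min(kRange)} bases are rejected, as are candidates whose flanks
#' fall off the sequence end.
#'
#' @param candidates data.frame from \code{\link{findInvertedRepeats}}.
#' @param sequence the sequence the candidates were found on.
#' @param kRange integer range of TSD lengths to test (default 2..10).
#' @param strict drop candidates without a TSD (default TRUE).
#' @return The candidate data.frame with \code{tsd} and, for rejected
#'   rows in non-strict mode, empty \code{tsd}; a \code{reason} column
#'   explains rejections when \code{strict = FALSE}.
#' @export
validateTsd <- function(candidates, sequence, kRange = 2:10,
                        strict = TRUE) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  kMax <- max(kRange)
  tsd <- character(nrow(candidates))
  reason <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    st <- candidates$start[i]; en <- candidates$end[i]
    if (st - max(kRange) < 1L || en + max(kRange) > n) {
      # still try smaller k that fit, but min(kRange) must fit
      if (st - min(kRange) < 1L || en + min(kRange) > n) {
        reason[i] <- "flank unavailable"
        next
      }
    }
    for (k in sort(kRange, decreasing = TRUE)) {
      if (st - k < 1L || en + k > n) next
      left <- substr(s, st - k, st - 1L)
      right <- substr(s, en + 1L, en + k)
      if (left == right && !grepl("N", left, fixed = TRUE)) {
        tsd[i] <- left
        break
      }
    }
    if (!nzchar(tsd[i]) && !nzchar(reason[i])) reason[i] <- "no matching TSD"
  }
  candidates$tsd <- tsd
  if (strict) {
    candidates[nzchar(tsd), , drop = FALSE]
  } else {
    candidates$reason <- reason
    candidates
  }
}

#' Greedy centroid clustering of MITE candidates
#'
#' Candidates are processed by decreasing length (ties: input order); a
#' candidate joins the first existing centroid to which its global
#' alignment identity (matching columns over alignment length) reaches
#' \code{identityThreshold}, otherwise it founds a new family whose
#' centroid it becomes.  Deterministic given the ordering rule.
#'
#' @param sequences named character vector (or \code{DNAStringSet}) of
#'   candidate sequences.
#' @param identityThreshold minimum identity to join a family
#'   (default 0.80).
#' @param scoring alignment scoring scheme.
#' @return data.frame with \code{member}, \code{family} (centroid name)
#'   and \code{identity} to the centroid.
#' @export
clusterMites <- function(sequences, identityThreshold = 0.80,
                         scoring = scoringScheme()) {
  if (methods::is(sequences, "XStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- paste0("cand", seq_along(sequences))
  ord <- order(-nchar(sequences), seq_along(sequences))
  centroids <- character()
  rows <- vector("list", length(sequences))
  for (i in ord) {
    assigned <- FALSE
    for (ct in centroids) {
      al <- globalAlign(sequences[[ct]], sequences[[i]], scoring)
      a <- strsplit(al$master, "")[[1]]; b <- strsplit(al$slave, "")[[1]]
      ident <- sum(a == b & a != "-") / length(a)
      if (ident >= identityThreshold) {
        rows[[i]] <- data.frame(member = names(sequences)[i], family = ct,
                                identity = ident)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      centroids <- c(centroids, names(sequences)[i])
      rows[[i]] <- data.frame(member = names(sequences)[i],
                              family = names(sequences)[i], identity = 1)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default TSD/TIR signature table for MITE superfamilies
#'
#' Ordered rules mapping TSD (exact motif or length) and optional TIR
#' terminal motif to a superfamily label.  The defaults encode standard
#' TE-biology conventions: \code{TA} TSD for Tc1/mariner, \code{TTAA}
#' for PiggyBac, 8-bp TSDs for hAT (TIR starting \code{CAG}) or P,
#' 3-bp \code{TAA}/\code{TTA} for Pif-Harbinger, and short TSDs with a
#' \code{CACT} TIR start for CACTA.  Rules are evaluated top to bottom;
#' the first match wins and no match yields \code{"unclassified"}.
#'
#' @return data.frame with columns \code{tsd_motif}, \code{tsd_length},
#'   \code{tir_prefix}, \code{label}.
#' @export
defaultSignatureTable <- function() {
  data.frame(
    tsd_motif = c("TA", "TTAA", NA, NA, "TAA", "TTA", NA),
    tsd_length = c(NA, NA, 8L, 8L, NA, NA, NA),
    tir_prefix = c(NA, NA, "CAG", NA, NA, NA, "CACT"),
    tsd_length_min = c(NA, NA, NA, NA, NA, NA, 2L),
    tsd_length_max = c(NA, NA, NA, NA, NA, NA, 4L),
    label = c("Tc1/mariner", "PiggyBac", "hAT", "P", "Pif-Harbinger",
              "Pif-Harbinger", "CACTA"))
}

#' Assign a superfamily from TSD and TIR evidence
#'
#' @param tsd TSD text (may be \code{""}).
#' @param tirSeq TIR sequence (element prefix), used for terminal-motif
#'   rules.
#' @param table signature table (see \code{\link{defaultSignatureTable}}).
#' @return Single superfamily label (\code{"unclassified"} if no rule
#'   matches).
#' @export
assignSuperfamily <- function(tsd, tirSeq = "",
                              table = defaultSignatureTable()) {
  tsd <- toupper(tsd); tirSeq <- toupper(tirSeq)
  for (r in seq_len(nrow(table))) {
    rule <- table[r, ]
    if (!is.na(rule$tsd_motif) && !identical(tsd, rule$tsd_motif)) next
    if (!is.na(rule$tsd_length) && nchar(tsd) != rule$tsd_length) next
    if (!is.na(rule$tsd_length_min) &&
        (nchar(tsd) < rule$tsd_length_min ||
         nchar(tsd) > rule$tsd_length_max)) next
    if (!is.na(rule$tir_prefix) && !startsWith(tirSeq, rule$tir_prefix))
      next
    return(rule$label)
  }
  "unclassified"
}

#' Full structural MITE scan of a genome
#'
#' Runs \code{\link{findInvertedRepeats}} on every sequence, validates
#' TSDs, clusters the surviving candidates into families and assigns a
#' superfamily to each family from its centroid's TSD and TIR.
#'
#' The structural scan is run \emph{without} overlap resolution: a
#' TSD-flanked element always admits a spurious wider candidate whose
#' TIR absorbs the TSD on both sides, and longest-TIR-first resolution
#' would prefer that wider call before the TSD is known.  Strict TSD
#' validation removes the nested redundancy instead; candidates that
#' still overlap afterwards are genuinely ambiguous boundary calls and
#' are all reported.
#'
#' @param genome \code{DNAStringSet}.
#' @param ... scan parameters passed to \code{\link{findInvertedRepeats}}.
#' @param kRange TSD lengths to test.
#' @param strict drop candidates without a TSD.
#' @param identityThreshold clustering identity threshold.
#' @param signatureTable superfamily signature rules.
#' @return List with \code{candidates} (per-candidate table including
#'   \code{family} and \code{superfamily}) and \code{families}
#'   (per-family summary).
#' @export
miteScan <- function(genome, ..., kRange = 2:10, strict = TRUE,
                     identityThreshold = 0.80,
                     signatureTable = defaultSignatureTable()) {
  cands <- do.call(rbind, lapply(names(genome), function(nm) {
    s <- as.character(genome[[nm]])
    validateTsd(findInvertedRepeats(s, seqId = nm, ...,
                                    resolveOverlaps = FALSE), s,
                kRange = kRange, strict = strict)
  }))
  if (is.null(cands) || !nrow(cands))
    return(list(candidates = data.frame(), families = data.frame()))
  cands$cand_id <- sprintf("%s:%d-%d", cands$seq_id, cands$start,
                           cands$end)
  seqs <- setNames(
    vapply(seq_len(nrow(cands)), function(i)
      substr(as.character(genome[[cands$seq_id[i]]]),
             cands$start[i], cands$end[i]), ""),
    cands$cand_id)
  clust <- clusterMites(seqs, identityThreshold = identityThreshold)
  cands$family <- clust$family[match(cands$cand_id, clust$member)]
  # classify each candidate from its own TSD/TIR; the family label is the
  # majority vote of its members (robust to boundary-variant members)
  cands$superfamily <- vapply(seq_len(nrow(cands)), function(i)
    assignSuperfamily(cands$tsd[i],
                      substr(seqs[[cands$cand_id[i]]], 1,
                             cands$tir_length[i]),
                      table = signatureTable), "")
  famIds <- unique(cands$family)
  famSf <- vapply(famIds, function(f) {
    votes <- table(cands$superfamily[cands$family == f])
    names(votes)[which.max(votes)]
  }, "")
  fams <- data.frame(
    family = famIds,
    size = vapply(famIds, function(f) sum(cands$family == f), 0L),
    superfamily = unname(famSf),
    tsd = cands$tsd[match(famIds, cands$cand_id)],
    tir_length = cands$tir_length[match(famIds, cands$cand_id)],
    row.names = NULL)
  list(candidates = cands, families = fams)
}
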