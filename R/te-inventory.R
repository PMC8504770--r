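## TE copy annotation I/O, full-length-copy filtering and coverage tables.

.parseGffAttrs <- function(x) {
  pairs <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- vapply(pairs, function(p) if (length(p) >= 2) p[2] else "", "")
  names(vals) <- vapply(pairs, `[[`, "", 1)
  vals
}

.readGff3 <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed GFF3 line ", idx[which(nf != 9L)[1]], " in ", path,
         ": expected 9 tab-separated fields, found ", nf[nf != 9L][1])
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (length(idx) && (anyNA(start) || anyNA(end) || any(start > end)))
    stop("malformed GFF3 line ", idx[which(is.na(start) | is.na(end) |
         start > end)[1]], " in ", path, ": bad coordinates")
  data.frame(seqid = m[, 1], source = m[, 2], type = m[, 3],
             start = start, end = end, score = m[, 6], strand = m[, 7],
             phase = m[, 8], attributes = m[, 9], line = idx)
}

#' Read TE copy annotations from GFF3
#'
#' Expects one feature line per TE copy with \code{ID}, \code{Target}
#' (family identifier) and \code{class} (Wicker order code) attributes.
#' GFF3 coordinates (1-based, inclusive) are kept in the returned
#' \code{GRanges}, so interval lengths equal feature widths.  Features
#' lacking a family attribute are reported via a warning and skipped;
#' malformed lines raise an error naming the line number.
#'
#' @param path GFF3 file path.
#' @return \code{GRanges} with \code{ID}, \code{family} and \code{class}
#'   metadata columns.
#' @export
readTeGff <- function(path) {
  df <- .readGff3(path)
  if (!nrow(df))
    return(GenomicRanges::GRanges(ID = character(), family = character(),
                                  class = character()))
  attrs <- lapply(df$attributes, .parseGffAttrs)
  fam <- vapply(attrs, function(a) unname(a["Target"] %0% a["family"]), "")
  noFam <- is.na(fam) | !nzchar(fam)
  if (any(noFam)) {
    warning(sum(noFam), " feature(s) lack a family attribute and were ",
            "skipped (lines ", paste(df$line[noFam], collapse = ", "), ")")
    df <- df[!noFam, , drop = FALSE]
    attrs <- attrs[!noFam]
    fam <- fam[!noFam]
  }
  # Target values may carry alignment coordinates ("fam 1 100"); keep the id
  fam <- vapply(strsplit(fam, " ", fixed = TRUE), `[[`, "", 1)
  GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"),
    ID = vapply(attrs, function(a) unname(a["ID"] %0% ""), ""),
    family = fam,
    class = vapply(attrs, function(a) unname(a["class"] %0% ""), ""))
}

# first non-missing of two scalar lookups
`%0%` <- function(a, b) if (is.na(a) || is.null(a)) b else a

#' Write TE copy annotations to GFF3
#'
#' @param copies \code{GRanges} with \code{ID}, \code{family}, \code{class}
#'   metadata columns.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeTeGff <- function(copies, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(copies)) {
    strand <- as.character(GenomicRanges::strand(copies))
    strand[strand == "*"] <- "."
    writeLines(sprintf(
      "%s\tTEmobilome\tmatch\t%d\t%d\t.\t%s\t.\tID=%s;Target=%s;class=%s",
      as.character(GenomicRanges::seqnames(copies)),
      GenomicRanges::start(copies), GenomicRanges::end(copies),
      strand, copies$ID, copies$family, copies$class), con)
  }
  invisible(path)
}

#' Flag full-length copies (FLC)
#'
#' A copy is full-length when it covers strictly more than
#' \code{threshold} (default 95\%) of its family consensus.  A copy at
#' exactly the threshold is \emph{not} full-length; a copy longer than
#' its consensus is.
#'
#' @param copies \code{GRanges} with a \code{family} metadata column.
#' @param consensusLengths named numeric vector of consensus lengths.
#' @param threshold coverage fraction that must be exceeded.
#' @return Logical vector along \code{copies}.
#' @export
flagFullLength <- function(copies, consensusLengths, threshold = 0.95) {
  fam <- copies$family
  unknown <- setdiff(unique(fam), names(consensusLengths))
  if (length(unknown))
    stop("no consensus length for family(ies): ",
         paste(unknown, collapse = ", "))
  GenomicRanges::width(copies) >
    threshold * unname(consensusLengths[fam])
}

#' Census of a consensus library against its annotated copies
#'
#' @param copies \code{GRanges} with \code{family} metadata.
#' @param consensusLengths named numeric vector.
#' @param classification named character vector: classification of each
#'   family (a Wicker code, \code{"SSR"}, \code{"noCat"} or \code{"PHG"});
#'   defaults to the \code{class} metadata seen on the copies.
#' @param threshold FLC threshold passed to \code{\link{flagFullLength}}.
#' @return data.frame with \code{family_id}, \code{classification},
#'   \code{copy_count}, \code{flc_count}.
#' @export
consensusCensus <- function(copies, consensusLengths,
                            classification = NULL, threshold = 0.95) {
  fams <- names(consensusLengths)
  flc <- if (length(copies)) flagFullLength(copies, consensusLengths,
                                            threshold) else logical()
  if (is.null(classification)) {
    classification <- setNames(rep(NA_character_, length(fams)), fams)
    if (length(copies)) {
      first <- !duplicated(copies$family)
      classification[copies$family[first]] <- copies$class[first]
    }
  }
  data.frame(
    family_id = fams,
    classification = unname(classification[fams]),
    copy_count = vapply(fams, function(f) sum(copies$family == f), 0L),
    flc_count = vapply(fams, function(f)
      sum(flc[copies$family == f]), 0L),
    row.names = NULL)
}

#' Filter a consensus library for the final annotation round
#'
#' Applies, in order: drop consensuses classified as \code{SSR}; drop
#' \code{noCat} consensuses generated from fewer than
#' \code{minNoCatCopies} copies; drop any consensus without a single
#' full-length copy.
#'
#' @param census data.frame as produced by \code{\link{consensusCensus}}.
#' @param minNoCatCopies minimum copy count for unclassified consensuses.
#' @return List with \code{kept} (filtered census) and \code{removed}
#'   (census rows with a \code{rule} column naming the rule that fired).
#' @export
filterConsensusLibrary <- function(census, minNoCatCopies = 10L) {
  if (!nrow(census))
    return(list(kept = census, removed = cbind(census, rule = character())))
  rule <- rep(NA_character_, nrow(census))
  rule[is.na(rule) & census$classification %in% "SSR"] <- "SSR"
  rule[is.na(rule) & census$classification %in% "noCat" &
       census$copy_count < minNoCatCopies] <- "noCat_low_copy"
  rule[is.na(rule) & census$flc_count == 0L] <- "no_full_length_copy"
  drop <- !is.na(rule)
  list(kept = census[!drop, , drop = FALSE],
       removed = cbind(census[drop, , drop = FALSE],
                       rule = rule[drop]))
}

#' Genome coverage table of TE copies
#'
#' For each group, coverage is the length of the \emph{union} of its
#' copy intervals (overlapping copies of the same group are counted
#' once); \code{method = "sum"} instead sums raw fragment lengths.
#' Percentages divide by the total assembly length.
#'
#' @param copies \code{GRanges} with \code{family} and \code{class}
#'   metadata columns.
#' @param genomeLengths named numeric vector of sequence lengths; every
#'   copy must sit on a known sequence.
#' @param groupBy one of \code{"class"} (TE Class I/II), \code{"order"}
#'   (Wicker code), \code{"family"}, \code{"chromosome"}.
#' @param chromosomes for \code{groupBy = "chromosome"}: names of
#'   anchored chromosomes; sequences not listed are pooled into an
#'   \code{"Un"} pseudo-chromosome of unplaced scaffolds.  Default: every
#'   sequence is its own chromosome.
#' @param method \code{"union"} (default) or \code{"sum"}.
#' @return data.frame with \code{group}, \code{consensus_count},
#'   \code{coverage_bp}, \code{coverage_pct}.
#' @export
coverageTable <- function(copies, genomeLengths,
                          groupBy = c("class", "order", "family",
                                      "chromosome"),
                          chromosomes = NULL,
                          method = c("union", "sum")) {
  groupBy <- match.arg(groupBy)
  method <- match.arg(method)
  unknown <- setdiff(unique(as.character(GenomicRanges::seqnames(copies))),
                     names(genomeLengths))
  if (length(unknown))
    stop("copies reference unknown sequence(s): ",
         paste(unknown, collapse = ", "))
  gTotal <- sum(genomeLengths)
  grp <- switch(groupBy,
    class = teClass(copies$class),
    order = copies$class,
    family = copies$family,
    chromosome = {
      sq <- as.character(GenomicRanges::seqnames(copies))
      if (is.null(chromosomes)) sq else ifelse(sq %in% chromosomes, sq, "Un")
    })
  grp[is.na(grp)] <- "other"
  groups <- sort(unique(grp))
  bp <- vapply(groups, function(g) {
    sub <- copies[grp == g]
    if (method == "union")
      sum(GenomicRanges::width(GenomicRanges::reduce(sub,
                                                     ignore.strand = TRUE)))
    else sum(GenomicRanges::width(sub))
  }, 0)
  data.frame(
    group = groups,
    consensus_count = vapply(groups, function(g)
      length(unique(copies$family[grp == g])), 0L),
    coverage_bp = unname(bp),
    coverage_pct = unname(100 * bp / gTotal),
    row.names = NULL)
}

#' Aggregate a per-order coverage table into class and grand totals
#'
#' Totals are sums of their constituent rows.  When \code{genomeLength}
#' is supplied the total percentages are recomputed from the summed base
#' pairs; otherwise the printed per-row percentages are summed.  Display
#' rounding is conventional half-up (\code{\link{roundHalfUp}}); raw
#' values are returned unrounded.
#'
#' @param rows data.frame with columns \code{code} (order code or a
#'   non-TE classification such as \code{PHG}, \code{noCat}, \code{SSR}),
#'   \code{consensus_count}, \code{coverage_pct}, \code{coverage_bp}.
#' @param genomeLength optional assembly length in bp.
#' @return data.frame with rows \code{Total Class I},
#'   \code{Total Class II} and \code{Total}.
#' @export
aggregateCoverage <- function(rows, genomeLength = NULL) {
  cls <- teClass(rows$code)
  mk <- function(label, sel) {
    bp <- sum(rows$coverage_bp[sel])
    pct <- if (is.null(genomeLength)) sum(rows$coverage_pct[sel])
           else 100 * bp / genomeLength
    data.frame(label = label,
               consensus_count = sum(rows$consensus_count[sel]),
               coverage_pct = pct, coverage_bp = bp)
  }
  rbind(mk("Total Class I", !is.na(cls) & cls == "I"),
        mk("Total Class II", !is.na(cls) & cls == "II"),
        mk("Total", rep(TRUE, nrow(rows))))
}
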