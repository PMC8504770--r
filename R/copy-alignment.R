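## Pairwise global alignment of copies against their family consensus and
## stacking into a master-slave multiple alignment.

#' Affine-gap scoring scheme
#'
#' A gap run of length L costs \code{gapOpen + L * gapExtend}: the open
#' penalty is charged once per run, the extend penalty for every gapped
#' column including the first.  \code{N} scores 0 against any base.
#' Defaults (+1 / -1 / -4 / -1) favour one long deletion over many short
#' ones, which suits decayed TE copies carrying large internal deletions.
#'
#' @param match match score (> mismatch).
#' @param mismatch mismatch score.
#' @param gapOpen gap-open penalty (<= 0), charged per gap run.
#' @param gapExtend gap-extension penalty (<= 0), charged per gapped column.
#' @return A named list used by \code{\link{globalAlign}}.
#' @export
scoringScheme <- function(match = 1, mismatch = -1, gapOpen = -4,
                          gapExtend = -1) {
  if (match <= mismatch) stop("match score must exceed mismatch score")
  if (gapOpen > 0 || gapExtend > 0) stop("gap penalties must be <= 0")
  list(match = match, mismatch = mismatch,
       gapOpen = gapOpen, gapExtend = gapExtend)
}

#' Keep copies long enough to align
#'
#' Retains copies strictly longer than \code{minLength} bases (a copy of
#' exactly \code{minLength} is dropped).
#'
#' @param copies \code{GRanges} of TE copies, or a \code{DNAStringSet}.
#' @param minLength length threshold in bases (default 100).
#' @return The filtered object.
#' @export
filterCopiesByLength <- function(copies, minLength = 100) {
  len <- if (methods::is(copies, "GRanges")) GenomicRanges::width(copies)
         else Biostrings::width(copies)
  copies[len > minLength]
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment of a slave sequence against a master under
#' the affine-gap scheme of \code{\link{scoringScheme}}.  Traceback ties
#' are broken deterministically: diagonal first, then a gap in the slave,
#' then a gap in the master.
#'
#' @param master,slave sequences (character strings or \code{DNAString}),
#'   alphabet \code{A C G T N}; must be non-empty.
#' @param scoring a \code{\link{scoringScheme}}.
#' @return List with \code{score}, \code{master} and \code{slave} (the
#'   two gapped sequences, equal length; removing \code{"-"} reproduces
#'   the inputs exactly).
#' @export
globalAlign <- function(master, slave, scoring = scoringScheme()) {
  master <- toupper(as.character(master))
  slave <- toupper(as.character(slave))
  if (!nzchar(master) || !nzchar(slave))
    stop("both sequences must be non-empty")
  if (grepl("[^ACGTN]", master) || grepl("[^ACGTN]", slave))
    stop("sequences must be over the alphabet {A,C,G,T,N}")
  .nw_align_cpp(master, slave, scoring$match, scoring$mismatch,
                scoring$gapOpen, scoring$gapExtend)
}

#' Stack pairwise alignments into a master-slave multiple alignment
#'
#' Builds a matrix whose columns are the consensus positions.  Slave
#' characters that align to master gaps (slave-only insertions) are
#' dropped from the matrix but counted per copy in the insertion log;
#' consensus positions outside a truncated or deleted slave region appear
#' as \code{"-"}.
#'
#' @param consensus the master sequence (character string).
#' @param alignments named list of \code{\link{globalAlign}} results; the
#'   degapped master of each must reproduce \code{consensus} exactly.
#' @param consensusId identifier stored on the object.
#' @return A \code{\link{MasterSlaveMSA}}.
#' @export
stackAlignments <- function(consensus, alignments,
                            consensusId = "consensus") {
  consensus <- toupper(as.character(consensus))
  L <- nchar(consensus)
  ids <- names(alignments) %||% paste0("copy", seq_along(alignments))
  mat <- matrix("-", nrow = length(alignments), ncol = L,
                dimnames = list(ids, NULL))
  ins <- integer(length(alignments))
  for (k in seq_along(alignments)) {
    al <- alignments[[k]]
    mch <- strsplit(al$master, "", fixed = TRUE)[[1]]
    sch <- strsplit(al$slave, "", fixed = TRUE)[[1]]
    isBase <- mch != "-"
    if (paste(mch[isBase], collapse = "") != consensus)
      stop("alignment '", ids[k],
           "': master does not degap to the consensus")
    mat[k, ] <- sch[isBase]
    ins[k] <- sum(!isBase & sch != "-")
  }
  new("MasterSlaveMSA", consensusId = consensusId, consensus = consensus,
      mat = mat,
      insertions = data.frame(copy_id = ids, inserted_bases = ins))
}

#' Align a family's copies to the consensus and stack them
#'
#' Convenience wrapper: length-filters the copies, aligns each to the
#' consensus with \code{\link{globalAlign}} and stacks the results.
#'
#' @param consensus consensus sequence (character or \code{DNAString}).
#' @param copies named character vector or \code{DNAStringSet} of copy
#'   sequences, already oriented like the consensus.
#' @param scoring a \code{\link{scoringScheme}}.
#' @param minLength copy length filter (strict; default 100).
#' @param consensusId identifier stored on the MSA.
#' @return A \code{\link{MasterSlaveMSA}}.
#' @export
alignFamily <- function(consensus, copies, scoring = scoringScheme(),
                        minLength = 100, consensusId = "consensus") {
  consensus <- toupper(as.character(consensus))
  if (methods::is(copies, "XStringSet"))
    copies <- setNames(as.character(copies), names(copies))
  copies <- copies[nchar(copies) > minLength]
  alignments <- lapply(copies, function(s)
    globalAlign(consensus, s, scoring))
  stackAlignments(consensus, alignments, consensusId = consensusId)
}

#' Write a master-slave alignment as gapped FASTA
#'
#' The consensus is the first record; matrix rows follow in order.
#'
#' @param msa a \code{\link{MasterSlaveMSA}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeMsaFasta <- function(msa, path) {
  rows <- apply(msaMatrix(msa), 1, paste, collapse = "")
  seqs <- c(setNames(consensusSeq(msa), consensusId(msa)), rows)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    writeLines(substring(seqs[i], seq(1, nchar(seqs[i]), 60),
                         pmin(nchar(seqs[i]), seq(60, nchar(seqs[i]) + 59,
                                                  60))), con)
  }
  invisible(path)
}
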