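## S4 classes for the synthetic-mobilome generator and the alignment stage.

#' Wicker-style order codes understood by the package
#'
#' Three-letter codes for TE orders: Class I retrotransposons
#' (\code{RLX} LTR, \code{RIX} LINE, \code{RSX} SINE, \code{RPX} Penelope,
#' \code{RXX} other retrotransposons / TRIM) and Class II DNA transposons
#' (\code{DTX} TIR elements, \code{MITE} miniature inverted-repeat
#' elements, \code{DHX} Helitron, \code{DMX} Maverick, \code{DXX} other).
#'
#' @return Character vector of valid codes.
#' @export
wickerCodes <- function() {
  c("RLX", "RIX", "RSX", "RPX", "RXX",
    "DTX", "MITE", "DHX", "DMX", "DXX")
}

#' TE class ("I" or "II") of a Wicker order code
#'
#' @param code character vector of order codes.
#' @return Character vector: \code{"I"}, \code{"II"} or \code{NA} for
#'   non-TE classifications (SSR, noCat, PHG).
#' @export
teClass <- function(code) {
  ifelse(substr(code, 1, 1) == "R", "I",
         ifelse(substr(code, 1, 1) == "D" | code == "MITE", "II",
                NA_character_))
}

#' @rdname FamilySpec
#' @export
setClass("FamilySpec",
  representation(
    familyId = "character",
    wickerCode = "character",
    consensusLength = "integer",
    tirLength = "integer",
    tsdLength = "integer",
    tsdMotif = "character"
  )
)

setValidity("FamilySpec", function(object) {
  msg <- character()
  if (length(object@familyId) != 1L || !nzchar(object@familyId))
    msg <- c(msg, "familyId must be a non-empty string")
  if (!(object@wickerCode %in% wickerCodes()))
    msg <- c(msg, sprintf("wickerCode '%s' is not a recognised order code",
                          object@wickerCode))
  if (object@consensusLength < 1L)
    msg <- c(msg, "consensusLength must be positive")
  if (object@tirLength < 0L)
    msg <- c(msg, "tirLength must be >= 0")
  if (object@consensusLength < 2L * object@tirLength)
    msg <- c(msg, "consensusLength must be at least twice tirLength")
  if (object@tsdLength < 0L || object@tsdLength > 10L)
    msg <- c(msg, "tsdLength must lie in [0, 10]")
  if (nzchar(object@tsdMotif) && !grepl("^random-\\d+$", object@tsdMotif) &&
      nchar(object@tsdMotif) != object@tsdLength)
    msg <- c(msg, "tsdMotif length must equal tsdLength")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic TE family
#'
#' Describes the consensus of one TE family used by the synthetic-mobilome
#' generator: its order code, length, terminal-inverted-repeat (TIR)
#' length (0 for Class I elements) and target-site-duplication (TSD)
#' behaviour on insertion.
#'
#' @param familyId family identifier.
#' @param wickerCode order code, one of \code{wickerCodes()}.
#' @param consensusLength consensus length in bases.
#' @param tirLength TIR length in bases; 0 means no TIR.
#' @param tsdLength TSD length in bases (0--10); 0 means no TSD.
#' @param tsdMotif fixed TSD motif (e.g. \code{"TA"}), or \code{""} /
#'   \code{"random-k"} to draw a random k-mer at each insertion.
#' @return A \code{FamilySpec} object.
#' @export
#' @examples
#' FamilySpec("mariner1", "DTX", 1300, tirLength = 28, tsdLength = 2,
#'            tsdMotif = "TA")
FamilySpec <- function(familyId, wickerCode, consensusLength,
                       tirLength = 0L, tsdLength = 0L, tsdMotif = "") {
  new("FamilySpec", familyId = as.character(familyId),
      wickerCode = as.character(wickerCode),
      consensusLength = as.integer(consensusLength),
      tirLength = as.integer(tirLength),
      tsdLength = as.integer(tsdLength),
      tsdMotif = as.character(tsdMotif))
}

#' @rdname BurstSpec
#' @export
setClass("BurstSpec",
  representation(
    familyId = "character",
    nCopies = "integer",
    targetDivergence = "numeric",
    deletionProb = "numeric",
    deletionFractionRange = "numeric",
    truncationProb = "numeric"
  )
)

setValidity("BurstSpec", function(object) {
  msg <- character()
  if (object@nCopies < 1L) msg <- c(msg, "nCopies must be >= 1")
  if (object@targetDivergence < 0 || object@targetDivergence >= 0.75)
    msg <- c(msg, "targetDivergence must lie in [0, 0.75) (saturation)")
  if (object@deletionProb < 0 || object@deletionProb > 1)
    msg <- c(msg, "deletionProb must be a probability")
  if (object@truncationProb < 0 || object@truncationProb > 1)
    msg <- c(msg, "truncationProb must be a probability")
  if (length(object@deletionFractionRange) != 2L ||
      any(object@deletionFractionRange <= 0) ||
      any(object@deletionFractionRange >= 1) ||
      diff(object@deletionFractionRange) < 0)
    msg <- c(msg, "deletionFractionRange must be an increasing pair in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Specification of one transposition burst
#'
#' A burst plants \code{nCopies} copies of a family, each mutated away
#' from the consensus at \code{targetDivergence} substitutions per base
#' pair, with optional internal deletions and terminal truncations that
#' mimic the fragmented state of genomic TE copies.
#'
#' @param familyId family the burst belongs to.
#' @param nCopies number of copies to plant.
#' @param targetDivergence per-site substitution probability in
#'   \code{[0, 0.75)}.
#' @param deletionProb probability that a copy receives one internal
#'   deletion.
#' @param deletionFractionRange range (increasing pair in (0,1)) of the
#'   fraction of the copy removed by a deletion.
#' @param truncationProb probability that a copy is truncated at one end.
#' @return A \code{BurstSpec} object.
#' @export
BurstSpec <- function(familyId, nCopies, targetDivergence,
                      deletionProb = 0, deletionFractionRange = c(0.1, 0.5),
                      truncationProb = 0) {
  new("BurstSpec", familyId = as.character(familyId),
      nCopies = as.integer(nCopies),
      targetDivergence = as.numeric(targetDivergence),
      deletionProb = as.numeric(deletionProb),
      deletionFractionRange = as.numeric(deletionFractionRange),
      truncationProb = as.numeric(truncationProb))
}

#' @rdname GenomeSpec
#' @export
setClass("GenomeSpec",
  representation(
    chromosomeLengths = "numeric",
    geneCount = "integer",
    exonsPerGene = "integer",
    teGeneDistancePlan = "data.frame",
    seed = "integer"
  )
)

setValidity("GenomeSpec", function(object) {
  msg <- character()
  if (length(object@chromosomeLengths) < 1L ||
      any(object@chromosomeLengths <= 0))
    msg <- c(msg, "all chromosome lengths must be positive")
  if (is.null(names(object@chromosomeLengths)) ||
      anyDuplicated(names(object@chromosomeLengths)))
    msg <- c(msg, "chromosomeLengths must have unique names")
  if (object@geneCount < 0L) msg <- c(msg, "geneCount must be >= 0")
  if (length(object@exonsPerGene) != 2L || any(object@exonsPerGene < 1L) ||
      diff(object@exonsPerGene) < 0L)
    msg <- c(msg, "exonsPerGene must be an increasing integer pair >= 1")
  plan <- object@teGeneDistancePlan
  if (nrow(plan) &&
      (!all(c("category", "count") %in% names(plan)) ||
       any(plan$count < 0)))
    msg <- c(msg, "teGeneDistancePlan needs 'category' and 'count' columns")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic genome layout
#'
#' Chromosome sizes (named; unplaced scaffolds are just more, shorter
#' sequences), the number of genes and their exon structure, a plan of
#' TE-gene positional contexts to realise, and the master seed from which
#' all randomness derives.
#'
#' @param chromosomeLengths named numeric vector of sequence lengths.
#' @param geneCount number of genes to place.
#' @param exonsPerGene integer pair: min and max exons per gene.
#' @param teGeneDistancePlan data.frame with columns \code{category}
#'   (a positional category of \code{\link{classifyInsertion}}) and
#'   \code{count}; these TE copies are placed in that relation to a gene.
#' @param seed master integer seed.
#' @return A \code{GenomeSpec} object.
#' @export
GenomeSpec <- function(chromosomeLengths, geneCount = 0L,
                       exonsPerGene = c(2L, 5L),
                       teGeneDistancePlan = data.frame(
                         category = character(), count = integer()),
                       seed = 1L) {
  new("GenomeSpec",
      chromosomeLengths = chromosomeLengths,
      geneCount = as.integer(geneCount),
      exonsPerGene = as.integer(exonsPerGene),
      teGeneDistancePlan = teGeneDistancePlan,
      seed = as.integer(seed))
}

#' Synthetic mobilome bundle
#'
#' Output of \code{\link{buildGenome}}: the genome sequences, the family
#' consensus library, planted TE copies and genes as \code{GRanges}, and
#' a ground-truth table with one row per planted copy (true divergence,
#' deletion state, TSD text, planned gene context).
#'
#' Accessors: \code{\link{genomeSeq}}, \code{\link{consensusLibrary}},
#' \code{\link{teCopies}}, \code{\link{geneFeatures}},
#' \code{\link{groundTruth}}.
#'
#' @name MobilomeBundle
#' @aliases MobilomeBundle-class
#' @export
setClass("MobilomeBundle",
  representation(
    genome = "DNAStringSet",
    consensi = "DNAStringSet",
    teCopies = "GRanges",
    genes = "GRanges",
    truth = "data.frame",
    specs = "list"
  )
)

setValidity("MobilomeBundle", function(object) {
  msg <- character()
  if (length(object@teCopies) != nrow(object@truth))
    msg <- c(msg, "each TE feature needs exactly one ground-truth record")
  if (length(object@teCopies) &&
      !all(as.character(GenomicRanges::seqnames(object@teCopies)) %in%
           names(object@genome)))
    msg <- c(msg, "TE copies must sit on genome sequences")
  if (length(msg)) msg else TRUE
})

#' Master-slave multiple alignment of a TE family
#'
#' Columns index consensus positions 1..L; each row is one copy's symbols
#' after pairwise global alignment to the consensus, with slave-only
#' insertions dropped from the matrix (and counted in the insertion log)
#' and positions outside a truncated copy shown as \code{"-"}.
#'
#' Built by \code{\link{stackAlignments}} or \code{\link{alignFamily}}.
#' Accessors: \code{\link{msaMatrix}}, \code{\link{consensusId}},
#' \code{\link{consensusSeq}}, \code{\link{insertionLog}}.
#'
#' @name MasterSlaveMSA
#' @aliases MasterSlaveMSA-class
#' @export
setClass("MasterSlaveMSA",
  representation(
    consensusId = "character",
    consensus = "character",
    mat = "matrix",
    insertions = "data.frame"
  )
)

setValidity("MasterSlaveMSA", function(object) {
  msg <- character()
  w <- nchar(object@consensus)
  if (ncol(object@mat) != w && nrow(object@mat) > 0L)
    msg <- c(msg, "matrix width must equal the consensus length")
  if (nrow(object@mat) && is.null(rownames(object@mat)))
    msg <- c(msg, "rows must be named by copy id")
  ok <- object@mat %in% c("A", "C", "G", "T", "N", "-")
  if (nrow(object@mat) && !all(ok))
    msg <- c(msg, "matrix symbols must be A, C, G, T, N or -")
  if (length(msg)) msg else TRUE
})

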