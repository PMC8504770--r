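## Accessor generics and show methods.

#' @describeIn MobilomeBundle genome sequences as a \code{DNAStringSet}.
#' @param x a \code{MobilomeBundle} (or \code{MasterSlaveMSA} where noted).
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @export
setMethod("genomeSeq", "MobilomeBundle", function(x) x@genome)

#' @describeIn MobilomeBundle consensus library as a \code{DNAStringSet}.
#' @export
setGeneric("consensusLibrary", function(x) standardGeneric("consensusLibrary"))
#' @export
setMethod("consensusLibrary", "MobilomeBundle", function(x) x@consensi)

#' @describeIn MobilomeBundle planted TE copies as a \code{GRanges} with
#'   \code{ID}, \code{family} and \code{class} metadata columns.
#' @export
setGeneric("teCopies", function(x) standardGeneric("teCopies"))
#' @export
setMethod("teCopies", "MobilomeBundle", function(x) x@teCopies)

#' @describeIn MobilomeBundle gene features as a \code{GRanges} with an
#'   \code{exons} \code{GRangesList} metadata column.
#' @export
setGeneric("geneFeatures", function(x) standardGeneric("geneFeatures"))
#' @export
setMethod("geneFeatures", "MobilomeBundle", function(x) x@genes)

#' @describeIn MobilomeBundle ground-truth table, one row per planted copy.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @export
setMethod("groundTruth", "MobilomeBundle", function(x) x@truth)

#' @describeIn MasterSlaveMSA character matrix of the alignment
#'   (rows = copies, columns = consensus positions).
#' @param x a \code{MasterSlaveMSA}.
#' @export
setGeneric("msaMatrix", function(x) standardGeneric("msaMatrix"))
#' @export
setMethod("msaMatrix", "MasterSlaveMSA", function(x) x@mat)

#' @describeIn MasterSlaveMSA identifier of the consensus (master).
#' @export
setGeneric("consensusId", function(x) standardGeneric("consensusId"))
#' @export
setMethod("consensusId", "MasterSlaveMSA", function(x) x@consensusId)

#' @describeIn MasterSlaveMSA consensus sequence as a plain string.
#' @export
setGeneric("consensusSeq", function(x) standardGeneric("consensusSeq"))
#' @export
setMethod("consensusSeq", "MasterSlaveMSA", function(x) x@consensus)

#' @describeIn MasterSlaveMSA per-copy log of dropped slave-only
#'   insertion bases.
#' @export
setGeneric("insertionLog", function(x) standardGeneric("insertionLog"))
#' @export
setMethod("insertionLog", "MasterSlaveMSA", function(x) x@insertions)

setMethod("show", "FamilySpec", function(object) {
  cat("FamilySpec", object@familyId, sprintf("(%s)", object@wickerCode),
      "\n  consensus:", object@consensusLength, "bp",
      if (object@tirLength > 0) sprintf("; TIR %d bp", object@tirLength),
      if (object@tsdLength > 0) sprintf("; TSD %d bp %s", object@tsdLength,
        if (nzchar(object@tsdMotif)) object@tsdMotif else "(random)"),
      "\n")
})

setMethod("show", "BurstSpec", function(object) {
  cat(sprintf(
    "BurstSpec %s: %d copies at %.3f subst/bp (del p=%.2f, trunc p=%.2f)\n",
    object@familyId, object@nCopies, object@targetDivergence,
    object@deletionProb, object@truncationProb))
})

setMethod("show", "MobilomeBundle", function(object) {
  cat("MobilomeBundle:",
      length(object@genome), "sequences,",
      length(object@consensi), "consensi,",
      length(object@teCopies), "TE copies,",
      length(object@genes), "genes\n")
  cat("  genome:", sum(Biostrings::width(object@genome)), "bp\n")
})

setMethod("show", "MasterSlaveMSA", function(object) {
  cat("MasterSlaveMSA on", object@consensusId, ":",
      nrow(object@mat), "copies x", nchar(object@consensus), "columns\n")
})
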