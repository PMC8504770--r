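## Synthetic mobilome generator: seeded genomes with planted TE copies,
## MITE-like elements and genes, plus a ground-truth table.

#' Generate a family consensus sequence
#'
#' Draws a uniform random DNA sequence of the specified length.  When the
#' family has terminal inverted repeats (\code{tirLength > 0}) the last
#' \code{tirLength} bases are forced to be the reverse complement of the
#' first \code{tirLength} bases, the structural hallmark of TIR-order
#' DNA transposons and MITEs.
#'
#' @param spec a \code{\link{FamilySpec}}.
#' @param seed integer seed; the same (spec, seed) always yields the same
#'   sequence.
#' @return A character string of exactly \code{consensusLength} bases.
#' @export
#' @examples
#' sp <- FamilySpec("mite1", "MITE", 300, tirLength = 20, tsdLength = 2,
#'                  tsdMotif = "TA")
#' cs <- makeConsensus(sp, seed = 1)
#' substr(cs, 281, 300) == revcomp(substr(cs, 1, 20))
makeConsensus <- function(spec, seed) {
  validObject(spec)
  withSeed(seed, {
    s <- randomDna(spec@consensusLength)
    t <- spec@tirLength
    if (t > 0L) {
      prefix <- substr(s, 1L, t)
      substr(s, spec@consensusLength - t + 1L, spec@consensusLength) <-
        revcomp(prefix)
    }
    s
  })
}

# transition partner of each base (HKY85-style weighting uses only the
# transition/transversion split; base frequencies are uniform)
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

#' Mutate a consensus into one genomic copy
#'
#' Applies a single-hit substitution process: each site is substituted
#' independently with probability \code{targetDivergence}; substituted
#' sites become the transition partner with probability
#' \code{kappa / (kappa + 2)} and one of the two transversions otherwise.
#' Because each site is hit at most once, the realised proportion of
#' changed sites estimates the target divergence directly, matching an
#' age statistic expressed in raw substitutions per base pair.
#' Optionally one internal deletion (contiguous, never touching the ends)
#' and/or one terminal truncation is applied after substitution.
#'
#' @param consensus consensus sequence (character string).
#' @param burst a \code{\link{BurstSpec}} providing divergence, deletion
#'   and truncation parameters.
#' @param kappa transition/transversion rate ratio (> 0); default 2.
#' @param seed integer seed.
#' @return A list with \code{sequence} (the copy) and \code{record}, a
#'   one-row data.frame: realised substitution count and divergence
#'   (both measured before any deletion), deletion/truncation state and
#'   final copy length.
#' @export
evolveCopy <- function(consensus, burst, kappa = 2, seed = 1L) {
  stopifnot(nchar(consensus) > 0L, kappa > 0)
  validObject(burst)
  d <- burst@targetDivergence
  if (d >= 0.75)
    stop("targetDivergence >= 0.75 is saturated and rejected")
  withSeed(seed, {
    bases <- strsplit(consensus, "", fixed = TRUE)[[1]]
    L <- length(bases)
    hit <- which(runif(L) < d)
    nSubs <- length(hit)
    if (nSubs) {
      isTs <- runif(nSubs) < kappa / (kappa + 2)
      newBase <- character(nSubs)
      newBase[isTs] <- .TRANSITION[bases[hit[isTs]]]
      if (any(!isTs)) {
        tv <- hit[!isTs]
        pick <- runif(length(tv)) < 0.5
        newBase[!isTs] <- mapply(function(b, p) .TRANSVERSIONS[[b]][p + 1L],
                                 bases[tv], pick)
      }
      bases[hit] <- newBase
    }
    delApplied <- FALSE; delStart <- NA_integer_; delLen <- 0L
    if (runif(1) < burst@deletionProb && L > 10L) {
      f <- runif(1, burst@deletionFractionRange[1],
                 burst@deletionFractionRange[2])
      delLen <- min(floor(f * L), L - 4L)
      if (delLen >= 1L) {
        delStart <- sample(seq(2L, L - delLen), 1L)
        bases <- bases[-seq(delStart, delStart + delLen - 1L)]
        delApplied <- TRUE
      }
    }
    truncApplied <- FALSE
    if (runif(1) < burst@truncationProb && length(bases) > 10L) {
      f <- runif(1, 0.1, 0.4)
      cut <- floor(f * length(bases))
      if (cut >= 1L) {
        if (runif(1) < 0.5) bases <- bases[-seq_len(cut)]
        else bases <- bases[seq_len(length(bases) - cut)]
        truncApplied <- TRUE
      }
    }
    list(sequence = paste(bases, collapse = ""),
         record = data.frame(
           n_subs = nSubs,
           divergence = nSubs / L,
           deletion = delApplied,
           deletion_start = delStart,
           deletion_length = delLen,
           truncation = truncApplied,
           copy_length = length(bases)))
  })
}

## ---- context unit geometry ------------------------------------------------

#' Positional context categories understood by the generator and classifier
#' @return Character vector of category names.
#' @export
contextCategories <- function() {
  c("next_to_gene", "te_inside_gene_exonic", "te_inside_gene_intronic",
    "gene_inside_te", "overlap_5prime", "overlap_3prime",
    "boundary_gene_start_eq_te_end", "boundary_gene_end_eq_te_start",
    "none")
}

# Lay out one TE (+ optionally one gene) inside a fresh local segment.
# Coordinates are 1-based local; returns the unit's total length, the TE
# interval, and gene/exon intervals (NULL for standalone TEs).
# Call inside withSeed().
.layoutContext <- function(category, teLen, exonRange) {
  pad <- 30L
  mkGene <- function(exonLens, intronLens) {
    # alternating exon/intron lengths -> exon intervals relative to gene
    starts <- integer(length(exonLens)); cur <- 1L
    for (i in seq_along(exonLens)) {
      starts[i] <- cur
      cur <- cur + exonLens[i] + if (i < length(exonLens)) intronLens[i] else 0L
    }
    list(len = sum(exonLens) + sum(intronLens),
         exons = cbind(starts, starts + exonLens - 1L))
  }
  plainGene <- function(minExon = 120L) {
    k <- sample(seq(exonRange[1], exonRange[2]), 1L)
    exonLens <- sample(seq(minExon, 400L), k, replace = TRUE)
    intronLens <- if (k > 1L) sample(seq(80L, 600L), k - 1L, replace = TRUE)
                  else integer()
    mkGene(exonLens, intronLens)
  }
  strand <- if (runif(1) < 0.5) "+" else "-"
  teStrand <- if (runif(1) < 0.5) "+" else "-"
  out <- function(total, te, gene = NULL, exons = NULL) {
    list(length = as.integer(total), te = as.integer(te),
         gene = if (is.null(gene)) NULL else as.integer(gene),
         exons = exons, geneStrand = strand, teStrand = teStrand)
  }
  switch(category,
    none = out(teLen + 2L * pad, c(pad + 1L, pad + teLen)),
    next_to_gene = {
      g <- plainGene()
      gap <- sample(100:1900, 1L)
      gs <- pad + 1L
      teS <- gs + g$len + gap
      out(pad + g$len + gap + teLen + pad, c(teS, teS + teLen - 1L),
          c(gs, gs + g$len - 1L), g$exons + gs - 1L)
    },
    te_inside_gene_exonic = {
      # first exon swallows the TE with margins
      exon1 <- teLen + 80L
      g <- mkGene(c(exon1, 150L), 300L)
      gs <- pad + 1L
      teS <- gs + 40L
      out(pad + g$len + pad, c(teS, teS + teLen - 1L),
          c(gs, gs + g$len - 1L), g$exons + gs - 1L)
    },
    te_inside_gene_intronic = {
      g <- mkGene(c(150L, 150L), teLen + 80L)
      gs <- pad + 1L
      teS <- gs + 150L + 40L
      out(pad + g$len + pad, c(teS, teS + teLen - 1L),
          c(gs, gs + g$len - 1L), g$exons + gs - 1L)
    },
    gene_inside_te = {
      if (teLen < 160L) stop("TE too short to contain a gene")
      gLen <- max(60L, min(teLen - 60L, 250L))
      teS <- pad + 1L
      gs <- teS + 30L
      out(pad + teLen + pad, c(teS, teS + teLen - 1L),
          c(gs, gs + gLen - 1L), cbind(gs, gs + gLen - 1L))
    },
    overlap_5prime = ,
    overlap_3prime = {
      g <- plainGene(minExon = 200L)
      gs <- pad + teLen + 1L                # room for TE on the left
      ge <- gs + g$len - 1L
      # TE must cross the transcription start (5') or end (3') coordinate
      wantStart <- (category == "overlap_5prime") == (strand == "+")
      anchor <- if (wantStart) gs else ge
      inGene <- min(max(20L, teLen %/% 3L), g$len - 10L, teLen - 10L)
      teS <- anchor - (teLen - inGene)
      if (!wantStart) teS <- anchor - inGene + 1L
      te <- c(teS, teS + teLen - 1L)
      total <- max(ge, te[2]) + pad
      out(total, te, c(gs, ge), g$exons + gs - 1L)
    },
    boundary_gene_start_eq_te_end = {
      g <- plainGene()
      teS <- pad + 1L
      gs <- teS + teLen                      # gene starts right after TE
      out(pad + teLen + g$len + pad, c(teS, teS + teLen - 1L),
          c(gs, gs + g$len - 1L), g$exons + gs - 1L)
    },
    boundary_gene_end_eq_te_start = {
      g <- plainGene()
      gs <- pad + 1L
      teS <- gs + g$len                      # TE starts right after gene
      out(pad + g$len + teLen + pad, c(teS, teS + teLen - 1L),
          c(gs, gs + g$len - 1L), g$exons + gs - 1L)
    },
    stop("unknown context category: ", category)
  )
}

## ---- genome assembly ------------------------------------------------------

#' Build a synthetic genome bundle with known ground truth
#'
#' Generates family consensi, mutates copies according to the burst
#' specifications, and places copies and genes on the chromosomes of
#' \code{gspec} without overlap between placement units.  Class II copies
#' (families with \code{tsdLength > 0}) are flanked on both sides by an
#' identical target-site duplication.  Copies planned into a TE-gene
#' context (per \code{teGeneDistancePlan}) are laid out jointly with a
#' tailored gene; all other copies are placed more than 2 kb away from
#' any gene.  All randomness derives from \code{gspec@seed}, so the same
#' specifications always produce a byte-identical bundle.
#'
#' @param gspec a \code{\link{GenomeSpec}}.
#' @param families list of \code{\link{FamilySpec}} objects.
#' @param bursts list of \code{\link{BurstSpec}} objects; every
#'   \code{familyId} must appear among \code{families}.
#' @param kappa transition/transversion ratio for the mutation process.
#' @return A \code{\link{MobilomeBundle}}.
#' @export
buildGenome <- function(gspec, families, bursts, kappa = 2) {
  validObject(gspec)
  for (f in families) validObject(f)
  for (b in bursts) validObject(b)
  famIds <- vapply(families, function(f) f@familyId, "")
  if (anyDuplicated(famIds)) stop("duplicate family ids")
  names(families) <- famIds
  bad <- setdiff(vapply(bursts, function(b) b@familyId, ""), famIds)
  if (length(bad)) stop("bursts reference unknown families: ",
                        paste(bad, collapse = ", "))
  seed <- gspec@seed

  consensi <- setNames(
    vapply(seq_along(families),
           function(i) makeConsensus(families[[i]], childSeed(seed, i)), ""),
    famIds)

  # mutate all copies up front so lengths are known before placement
  copies <- list(); ci <- 0L
  for (bi in seq_along(bursts)) {
    b <- bursts[[bi]]
    for (k in seq_len(b@nCopies)) {
      ci <- ci + 1L
      ev <- evolveCopy(consensi[[b@familyId]], b, kappa,
                       childSeed(seed, 1000L + ci))
      fam <- families[[b@familyId]]
      nInFam <- if (ci > 1L)
        sum(vapply(copies[seq_len(ci - 1L)],
                   function(x) x$family == b@familyId, TRUE)) else 0L
      copies[[ci]] <- list(
        id = sprintf("%s_copy%04d", b@familyId, nInFam + 1L),
        family = b@familyId, code = fam@wickerCode,
        seq = ev$sequence, record = ev$record,
        tsdLength = fam@tsdLength, tsdMotif = fam@tsdMotif,
        target_divergence = b@targetDivergence)
    }
  }
  nCopies <- length(copies)

  plan <- gspec@teGeneDistancePlan
  planCats <- if (nrow(plan)) rep(plan$category, plan$count) else character()
  if (length(planCats) > nCopies)
    stop("context plan asks for more TE copies than the bursts provide")
  # interleave copies across families so contexts spread over families
  famOf <- vapply(copies, function(x) x$family, "")
  withinIdx <- stats::ave(seq_len(nCopies), famOf, FUN = seq_along)
  ord <- order(withinIdx, seq_len(nCopies))
  ctxOf <- rep("none", nCopies)
  ctxOf[ord[seq_along(planCats)]] <- planCats

  nStandaloneGenes <- max(0L, gspec@geneCount - length(planCats))

  withSeed(childSeed(seed, 999983L), {
    chromNames <- names(gspec@chromosomeLengths)
    chromLen <- as.integer(gspec@chromosomeLengths)
    cursor <- rep(1L, length(chromLen))

    teRows <- vector("list", nCopies)
    geneRows <- list()
    exonRows <- list()
    pieces <- lapply(chromNames, function(x) list())  # sequence patches
    gi <- 0L

    placeUnit <- function(unitLen) {
      gap <- sample(2050:4000, 1L)
      fits <- which(cursor + gap + unitLen - 1L <= chromLen)
      if (!length(fits)) {
        worst <- chromNames[which.max(chromLen - cursor)]
        stop("cannot place a ", unitLen, " bp unit on any chromosome (",
             "most space left on ", worst, "); enlarge the genome")
      }
      # rotate across chromosomes deterministically
      ch <- fits[(sum(cursor) %% length(fits)) + 1L]
      at <- cursor[ch] + gap
      cursor[ch] <<- at + unitLen
      list(chrom = ch, at = at)
    }

    for (i in seq_len(nCopies)) {
      cp <- copies[[i]]
      teLen <- nchar(cp$seq)
      lay <- .layoutContext(ctxOf[i], teLen, gspec@exonsPerGene)
      pos <- placeUnit(lay$length + 2L * cp$tsdLength)
      off <- pos$at - 1L + cp$tsdLength
      teS <- lay$te[1] + off; teE <- lay$te[2] + off
      teSeq <- if (lay$teStrand == "-") revcomp(cp$seq) else cp$seq
      tsd <- ""
      if (cp$tsdLength > 0L) {
        tsd <- if (nzchar(cp$tsdMotif) && !grepl("^random-", cp$tsdMotif))
          cp$tsdMotif else randomDna(cp$tsdLength)
        pieces[[pos$chrom]][[length(pieces[[pos$chrom]]) + 1L]] <-
          list(at = teS - cp$tsdLength, seq = tsd)
        pieces[[pos$chrom]][[length(pieces[[pos$chrom]]) + 1L]] <-
          list(at = teE + 1L, seq = tsd)
      }
      pieces[[pos$chrom]][[length(pieces[[pos$chrom]]) + 1L]] <-
        list(at = teS, seq = teSeq)

      geneId <- NA_character_
      if (!is.null(lay$gene)) {
        gi <- gi + 1L
        geneId <- sprintf("gene%04d", gi)
        geneRows[[length(geneRows) + 1L]] <- data.frame(
          seqnames = chromNames[pos$chrom], start = lay$gene[1] + off,
          end = lay$gene[2] + off, strand = lay$geneStrand, gene_id = geneId)
        exonRows[[length(exonRows) + 1L]] <- data.frame(
          seqnames = chromNames[pos$chrom],
          start = lay$exons[, 1] + off, end = lay$exons[, 2] + off,
          strand = lay$geneStrand, gene_id = geneId)
      }
      teRows[[i]] <- cbind(
        data.frame(copy_id = cp$id, family = cp$family, code = cp$code,
                   seqnames = chromNames[pos$chrom], start = teS, end = teE,
                   strand = lay$teStrand,
                   target_divergence = cp$target_divergence),
        cp$record,
        data.frame(tsd = tsd, context = ctxOf[i], gene_id = geneId))
    }

    for (g in seq_len(nStandaloneGenes)) {
      lay <- .layoutContext("next_to_gene", 60L, gspec@exonsPerGene)
      # reuse the gene part only; drop its TE
      pos <- placeUnit(lay$gene[2] + 30L)
      off <- pos$at - 1L
      gi <- gi + 1L
      geneId <- sprintf("gene%04d", gi)
      geneRows[[length(geneRows) + 1L]] <- data.frame(
        seqnames = chromNames[pos$chrom], start = lay$gene[1] + off,
        end = lay$gene[2] + off, strand = lay$geneStrand, gene_id = geneId)
      exonRows[[length(exonRows) + 1L]] <- data.frame(
        seqnames = chromNames[pos$chrom],
        start = lay$exons[, 1] + off, end = lay$exons[, 2] + off,
        strand = lay$geneStrand, gene_id = geneId)
    }

    # materialise chromosome sequences: random background + patches
    seqs <- vapply(seq_along(chromNames), function(ch) {
      s <- randomDna(chromLen[ch])
      for (p in pieces[[ch]])
        substr(s, p$at, p$at + nchar(p$seq) - 1L) <- p$seq
      s
    }, "")
    genome <- Biostrings::DNAStringSet(setNames(seqs, chromNames))

    truth <- do.call(rbind, c(teRows, list(data.frame(
      copy_id = character(), family = character(), code = character(),
      seqnames = character(), start = integer(), end = integer(),
      strand = character(), target_divergence = numeric(),
      n_subs = integer(), divergence = numeric(), deletion = logical(),
      deletion_start = integer(), deletion_length = integer(),
      truncation = logical(), copy_length = integer(), tsd = character(),
      context = character(), gene_id = character()))))
    truth <- truth[order(match(truth$seqnames, chromNames), truth$start), ,
                   drop = FALSE]
    rownames(truth) <- NULL

    teGr <- GenomicRanges::GRanges(
      seqnames = truth$seqnames,
      ranges = IRanges::IRanges(truth$start, truth$end),
      strand = truth$strand,
      ID = truth$copy_id, family = truth$family, class = truth$code,
      seqlengths = setNames(chromLen, chromNames))

    genes <- do.call(rbind, c(geneRows,
      list(data.frame(seqnames = character(), start = integer(),
                      end = integer(), strand = character(),
                      gene_id = character()))))
    exons <- do.call(rbind, c(exonRows,
      list(data.frame(seqnames = character(), start = integer(),
                      end = integer(), strand = character(),
                      gene_id = character()))))
    geneGr <- GenomicRanges::GRanges(
      seqnames = genes$seqnames,
      ranges = IRanges::IRanges(genes$start, genes$end),
      strand = genes$strand, gene_id = genes$gene_id,
      seqlengths = setNames(chromLen, chromNames))
    exonGr <- GenomicRanges::GRanges(
      seqnames = exons$seqnames,
      ranges = IRanges::IRanges(exons$start, exons$end),
      strand = exons$strand, gene_id = exons$gene_id,
      seqlengths = setNames(chromLen, chromNames))
    exonsByGene <- S4Vectors::split(
      exonGr, factor(exonGr$gene_id, levels = geneGr$gene_id))
    S4Vectors::mcols(geneGr)$exons <- exonsByGene

    new("MobilomeBundle", genome = genome,
        consensi = Biostrings::DNAStringSet(consensi),
        teCopies = teGr, genes = geneGr, truth = truth,
        specs = list(genome = gspec, families = families, bursts = bursts,
                     kappa = kappa))
  })
}

#' Extract planted (or annotated) copy sequences from a genome
#'
#' Minus-strand copies are reverse-complemented so every returned
#' sequence reads in the orientation of its family consensus.
#'
#' @param genome a \code{DNAStringSet}.
#' @param copies a \code{GRanges} with an \code{ID} metadata column.
#' @return A \code{DNAStringSet} named by copy ID.
#' @export
extractCopySequences <- function(genome, copies) {
  if (!length(copies)) return(Biostrings::DNAStringSet())
  bad <- setdiff(unique(as.character(GenomicRanges::seqnames(copies))),
                 names(genome))
  if (length(bad)) stop("copies reference unknown sequences: ",
                        paste(bad, collapse = ", "))
  seqs <- Biostrings::DNAStringSet(genome[as.character(
    GenomicRanges::seqnames(copies))])
  out <- Biostrings::subseq(seqs, GenomicRanges::start(copies),
                            GenomicRanges::end(copies))
  neg <- as.character(GenomicRanges::strand(copies)) == "-"
  if (any(neg)) out[neg] <- Biostrings::reverseComplement(out[neg])
  names(out) <- copies$ID
  out
}

#' Default study-scale synthetic mobilome specifications
#'
#' Ten 1-kb TE families (five Class I, five Class II including two
#' MITE-like families), each hit by two transposition bursts of 15 copies
#' at 0.02 and 0.20 substitutions per base pair, on a small multi-
#' chromosome genome (four chromosomes plus two unplaced scaffolds) with
#' genes placed in a mix of positional contexts.  These defaults define
#' the simulated study conditions used throughout the package's tests
#' and examples; the vignette discusses how they were chosen.
#'
#' @param seed master seed.
#' @param nPerBurst copies per family per burst (default 15).
#' @param deletionProb,truncationProb per-copy structural decay rates.
#' @return List with \code{genome}, \code{families}, \code{bursts},
#'   ready for \code{\link{buildGenome}}.
#' @export
defaultMobilomeSpecs <- function(seed = 1L, nPerBurst = 15L,
                                 deletionProb = 0.15,
                                 truncationProb = 0.05) {
  families <- list(
    FamilySpec("gypsy1",   "RLX", 1000L),
    FamilySpec("copia1",   "RLX", 1000L),
    FamilySpec("jockey1",  "RIX", 1000L),
    FamilySpec("sine1",    "RSX", 1000L),
    FamilySpec("penelope1","RPX", 1000L),
    FamilySpec("mariner1", "DTX", 1000L, tirLength = 28L, tsdLength = 2L,
               tsdMotif = "TA"),
    FamilySpec("hat1",     "DTX", 1000L, tirLength = 15L, tsdLength = 8L,
               tsdMotif = "random-8"),
    FamilySpec("harb1",    "DTX", 1000L, tirLength = 40L, tsdLength = 3L,
               tsdMotif = "TAA"),
    FamilySpec("mite1",    "MITE", 1000L, tirLength = 20L, tsdLength = 2L,
               tsdMotif = "TA"),
    FamilySpec("mite2",    "MITE", 1000L, tirLength = 35L, tsdLength = 8L,
               tsdMotif = "random-8")
  )
  bursts <- unlist(lapply(families, function(f) list(
    BurstSpec(f@familyId, nPerBurst, 0.02, deletionProb = deletionProb,
              truncationProb = truncationProb),
    BurstSpec(f@familyId, nPerBurst, 0.20, deletionProb = deletionProb,
              truncationProb = truncationProb))), recursive = FALSE)
  plan <- data.frame(
    category = c("next_to_gene", "te_inside_gene_exonic",
                 "te_inside_gene_intronic", "gene_inside_te",
                 "overlap_5prime", "overlap_3prime",
                 "boundary_gene_start_eq_te_end",
                 "boundary_gene_end_eq_te_start"),
    count = c(8L, 6L, 6L, 4L, 5L, 5L, 2L, 2L))
  genome <- GenomeSpec(
    chromosomeLengths = c(A1 = 600000, A2 = 600000, X1 = 500000,
                          X2 = 500000, scaffold_1 = 150000,
                          scaffold_2 = 150000),
    geneCount = 60L, exonsPerGene = c(2L, 5L),
    teGeneDistancePlan = plan, seed = seed)
  list(genome = genome, families = families, bursts = bursts)
}

#' Write a mobilome bundle to disk
#'
#' Writes the genome and consensus FASTA (60-column wrapped), TE and gene
#' GFF3, and the ground-truth table as TSV.  Output is byte-identical for
#' identical bundles.
#'
#' @param bundle a \code{\link{MobilomeBundle}}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             consensi = file.path(dir, "consensi.fa"),
             te = file.path(dir, "te_copies.gff3"),
             genes = file.path(dir, "genes.gff3"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(genomeSeq(bundle), paths["genome"], width = 60L)
  Biostrings::writeXStringSet(consensusLibrary(bundle), paths["consensi"],
                              width = 60L)
  writeTeGff(teCopies(bundle), paths["te"])
  writeGeneGff(geneFeatures(bundle), paths["genes"])
  truth <- groundTruth(bundle)
  write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
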