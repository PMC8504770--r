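## Pipeline orchestration: configuration object and end-to-end run.

#' @rdname pipelineConfig
#' @export
setClass("PipelineConfig",
  representation(
    genomePath = "character",
    tePath = "character",
    genePath = "character",
    consensusPath = "character",
    outDir = "character",
    flcThreshold = "numeric",
    minCopyLength = "numeric",
    ageBinWidth = "numeric",
    recencyThreshold = "numeric",
    nearGeneThreshold = "numeric",
    miteParams = "list",
    seed = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  thr <- c(flc = object@flcThreshold, minLen = object@minCopyLength,
           bin = object@ageBinWidth, recent = object@recencyThreshold,
           near = object@nearGeneThreshold)
  if (any(thr <= 0)) msg <- c(msg, "all thresholds must be positive")
  if (object@flcThreshold >= 1)
    msg <- c(msg, "flcThreshold must be a fraction below 1")
  if (length(msg)) msg else TRUE
})

#' Pipeline configuration
#'
#' Holds input paths and the analysis thresholds: FLC consensus-coverage
#' fraction (default 0.95, strict \dQuote{more than}), minimum copy
#' length for alignment (100 bp, strict), age-histogram bin width (0.01
#' substitutions/bp), recency cutoff (0.02, strict \dQuote{less than}),
#' and near-gene distance (2000 bp, strict).  The configuration is
#' serialized into every report's provenance header.
#'
#' @param genomePath,tePath,genePath,consensusPath input files (genome
#'   FASTA, TE GFF3, gene GFF3, consensus FASTA).
#' @param outDir output directory.
#' @param flcThreshold,minCopyLength,ageBinWidth,recencyThreshold,nearGeneThreshold
#'   analysis thresholds (see description).
#' @param miteParams named list passed to \code{\link{findInvertedRepeats}}.
#' @param seed integer seed for any randomized step.
#' @return A \code{PipelineConfig}.
#' @export
pipelineConfig <- function(genomePath, tePath, genePath, consensusPath,
                           outDir, flcThreshold = 0.95,
                           minCopyLength = 100, ageBinWidth = 0.01,
                           recencyThreshold = 0.02,
                           nearGeneThreshold = 2000,
                           miteParams = list(), seed = 1L) {
  new("PipelineConfig", genomePath = genomePath, tePath = tePath,
      genePath = genePath, consensusPath = consensusPath, outDir = outDir,
      flcThreshold = flcThreshold, minCopyLength = minCopyLength,
      ageBinWidth = ageBinWidth, recencyThreshold = recencyThreshold,
      nearGeneThreshold = nearGeneThreshold, miteParams = miteParams,
      seed = as.integer(seed))
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(
    config@flcThreshold, config@minCopyLength, config@ageBinWidth,
    config@recencyThreshold, config@nearGeneThreshold, config@seed,
    paste(names(config@miteParams), unlist(config@miteParams),
          collapse = ","), sep = "|"), tmp)
  unname(substr(tools::md5sum(tmp), 1, 12))
}

.writeReport <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# TEmobilome config ", hash), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  path
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full mobilome survey pipeline
#'
#' Executes inventory, per-family alignment and age estimation, MITE
#' scan and gene-context classification, writing a report bundle into
#' \code{config@outDir}.  Stages fail with an error message naming the
#' stage; outputs are deterministic for a fixed configuration and seed.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return Invisibly, a list with the in-memory results and the written
#'   file paths.
#' @export
runPipeline <- function(config) {
  validObject(config)
  hash <- .configHash(config)
  dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(config@outDir, name)
  paths <- character()

  inputs <- .stage("input", {
    list(genome = Biostrings::readDNAStringSet(config@genomePath),
         tes = readTeGff(config@tePath),
         genes = readGeneGff(config@genePath),
         consensi = Biostrings::readDNAStringSet(config@consensusPath))
  })

  inventory <- .stage("te_inventory", {
    genomeLengths <- setNames(Biostrings::width(inputs$genome),
                              names(inputs$genome))
    bad <- setdiff(unique(as.character(
      GenomicRanges::seqnames(inputs$tes))), names(inputs$genome))
    if (length(bad))
      stop("TE annotation references absent sequence(s): ",
           paste(bad, collapse = ", "))
    consensusLengths <- setNames(Biostrings::width(inputs$consensi),
                                 names(inputs$consensi))
    census <- consensusCensus(inputs$tes, consensusLengths,
                              threshold = config@flcThreshold)
    filt <- filterConsensusLibrary(census)
    byOrder <- coverageTable(inputs$tes, genomeLengths, "order")
    byClass <- coverageTable(inputs$tes, genomeLengths, "class")
    byChrom <- coverageTable(inputs$tes, genomeLengths, "chromosome")
    paths["census"] <- .writeReport(census, outfile("census.tsv"), hash)
    paths["coverage_order"] <- .writeReport(
      byOrder, outfile("coverage_by_order.tsv"), hash)
    paths["coverage_class"] <- .writeReport(
      byClass, outfile("coverage_by_class.tsv"), hash)
    paths["coverage_chrom"] <- .writeReport(
      byChrom, outfile("coverage_by_chromosome.tsv"), hash)
    list(census = census, filtered = filt, byOrder = byOrder,
         byClass = byClass, byChrom = byChrom)
  })

  ages <- .stage("age_estimation", {
    copySeqs <- extractCopySequences(inputs$genome, inputs$tes)
    famOf <- setNames(inputs$tes$family, inputs$tes$ID)
    allAges <- list(); allDiv <- numeric()
    for (fam in intersect(unique(inputs$tes$family),
                          names(inputs$consensi))) {
      ids <- names(famOf)[famOf == fam]
      msa <- alignFamily(as.character(inputs$consensi[[fam]]),
                         copySeqs[intersect(ids, names(copySeqs))],
                         minLength = config@minCopyLength,
                         consensusId = fam)
      if (!nrow(msaMatrix(msa))) next
      div <- copyConsensusDivergence(msa)
      allDiv <- c(allDiv, div)
      tree <- buildFamilyTree(distanceMatrix(msa))
      if (!is.null(tree))
        allAges[[fam]] <- familyAges(msa, tree, familyId = fam)
    }
    ageTab <- do.call(rbind, c(allAges, list(data.frame(
      copy_a = character(), copy_b = character(), age = numeric(),
      sites = integer(), family = character()))))
    hist <- burstHistogram(allDiv[!is.na(allDiv)],
                           binWidth = config@ageBinWidth)
    peaks <- detectBursts(hist)
    paths["ages"] <- .writeReport(ageTab, outfile("cherry_ages.tsv"),
                                   hash)
    paths["histogram"] <- .writeReport(
      hist$bins, outfile("age_histogram.tsv"), hash)
    paths["peaks"] <- outfile("burst_peaks.json")
    jsonlite::write_json(list(config = hash, peaks = peaks),
                         paths["peaks"], dataframe = "columns",
                         auto_unbox = TRUE, digits = NA)
    list(cherries = ageTab, divergences = allDiv, histogram = hist,
         peaks = peaks)
  })

  mites <- .stage("mite_finder", {
    res <- do.call(miteScan, c(list(inputs$genome), config@miteParams))
    if (nrow(res$families))
      paths["mite_families"] <- .writeReport(
        res$families, outfile("mite_families.tsv"), hash)
    res
  })

  context <- .stage("gene_context", {
    ctx <- classifyContexts(inputs$tes, inputs$genes,
                            nearThreshold = config@nearGeneThreshold,
                            divergences = ages$divergences,
                            recencyThreshold = config@recencyThreshold)
    counts <- do.call(rbind, lapply(
      split(ctx, ctx$category), function(d)
        c(sense = sum(d$orientation == "sense"),
          antisense = sum(d$orientation == "antisense"))))
    test <- orientationChiSquare(counts)
    recent <- recentInsertionReport(ctx,
                                    maxDivergence = config@recencyThreshold)
    paths["contexts"] <- .writeReport(ctx, outfile("contexts.tsv"), hash)
    paths["recent"] <- .writeReport(
      recent, outfile("recent_insertions.tsv"), hash)
    paths["orientation"] <- outfile("orientation_tests.json")
    jsonlite::write_json(
      list(config = hash, per_category = test$per_category,
           omnibus = test$omnibus),
      paths["orientation"], dataframe = "columns", auto_unbox = TRUE,
      digits = NA)
    list(contexts = ctx, test = test, recent = recent)
  })

  invisible(list(inventory = inventory, ages = ages, mites = mites,
                 context = context, paths = paths, config_hash = hash))
}
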