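## Published survey values shipped as plain-text fixtures.  These are the
## printed summary tables of the Hessian fly (Mayetiola destructor)
## mobilome survey; the package treats them as *inputs* for arithmetic
## checks (class totals, orientation tests, recent-insertion totals).

#' Published per-order TE coverage of the Hessian fly assembly
#'
#' Per-order consensus counts and genome coverage (percent and bp) from
#' the published survey, for both annotation rounds: all copies (r1) and
#' the full-length-copy-filtered library (flc).
#'
#' @return data.frame with one row per order code or non-TE
#'   classification (PHG, noCat, SSR).
#' @export
publishedCoverageByOrder <- function() {
  read.delim(system.file("extdata", "mdes_te_order_coverage.tsv",
                         package = "TEmobilome"),
             stringsAsFactors = FALSE)
}

#' Published sense/antisense insertion counts by positional category
#'
#' @return Matrix with categories as rows and sense/antisense columns.
#' @export
publishedOrientationCounts <- function() {
  df <- read.delim(system.file("extdata", "mdes_orientation_counts.tsv",
                               package = "TEmobilome"),
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, c("sense", "antisense")])
  rownames(m) <- df$category
  m
}

#' Published recent-insertion site counts by superfamily
#'
#' Counts of insertion sites of TE copies below 2\% divergence, by
#' superfamily, from the published survey.
#'
#' @return data.frame with \code{superfamily} and \code{n_sites}.
#' @export
publishedRecentInsertionCounts <- function() {
  read.delim(system.file("extdata", "mdes_recent_insertions.tsv",
                         package = "TEmobilome"),
             stringsAsFactors = FALSE)
}
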