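# Test-retest reproducibility statistics over paired GABA/NAA sessions.

#' Reference 7 T test-retest GABA/NAA table
#'
#' Published per-subject test-retest GABA/NAA ratios, CRLBs and printed
#' CVs from the 7 T BASING-PRESS reproducibility experiment this package
#' models: five subjects scanned twice in three regions (anterior
#' cingulate cortex ACC, right caudate RCaud, left superior temporal
#' gyrus LSTG). Shipped as a plain-text fixture; used as the input for
#' the reproducibility-statistics regression checks. Note one known
#' internal inconsistency of the printed source: the ACC subject-3 CV
#' (4.5%) does not match its own ratio pair (0.098, 0.102 -> 2.8%);
#' the row is kept verbatim.
#'
#' @return data.frame with columns `roi`, `subject`, `crlb_scan1_pct`,
#'   `crlb_scan2_pct`, `ratio_scan1`, `ratio_scan2`, `cv_printed_pct`
#' @export
testRetestTable <- function() {
  path <- system.file("extdata", "test_retest_gaba.csv",
                      package = "gabedit", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reproducibility statistics for paired sessions
#'
#' Computes the per-pair two-point CV ([cvTwo()]) of a ratio column and
#' the ROI-averaged CV, plus CRLB-based inclusion flags for both scans.
#'
#' @param table data.frame in the layout of [testRetestTable()]
#' @param crlb_threshold_pct inclusion threshold (strictly lower), %
#' @return list with `per_pair` (the table plus `cv_pct` and inclusion
#'   columns) and `averaged` (named vector of mean CV per ROI, computed
#'   over all pairs)
#' @export
reproducibilityStats <- function(table = testRetestTable(),
                                 crlb_threshold_pct = 20) {
  stopifnot(all(c("roi", "ratio_scan1", "ratio_scan2") %in% names(table)))
  table$cv_pct <- cvTwo(table$ratio_scan1, table$ratio_scan2)
  if (all(c("crlb_scan1_pct", "crlb_scan2_pct") %in% names(table))) {
    table$included_scan1 <- table$crlb_scan1_pct < crlb_threshold_pct
    table$included_scan2 <- table$crlb_scan2_pct < crlb_threshold_pct
  }
  avg <- tapply(table$cv_pct, table$roi, averagedCv)
  list(per_pair = table, averaged = avg[unique(table$roi)])
}
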