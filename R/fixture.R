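# Transcribed cohort marginal counts for desk-scale reproduction.
#
# The published individual-level patient data are not deposited; what the
# study prints are marginal counts (baseline characteristics, PD-L1 TPS
# categories, alteration frequencies, processing-mutation and epitope-fate
# totals). Those counts are transcribed verbatim into a packaged
# tab-delimited fixture so that the summary stage can recompute every
# printed percentage. One transcribed statement (distant metastases,
# printed 41.2%) is internally inconsistent with its own printed counts
# (74/177 = 41.8%); the counts are transcribed as printed.

#' The transcribed cohort count fixture
#'
#' @return Data frame with columns `table`, `variable`, `category`,
#'   `count`, `denominator`, `digits` (decimals the source prints the
#'   percentage at) and `printed_pct` (the percentage as printed, `NA`
#'   where none is printed).
#' @export
paper_fixture <- function() {
  path <- system.file("extdata", "psc_cohort_counts.tsv",
                      package = "procescape", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Re-emit the cohort count fixture to a directory
#'
#' Writes `psc_cohort_counts.tsv` in the cohort-summary input format;
#' re-emission is idempotent (byte-identical content).
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path written.
#' @export
write_paper_fixture <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  src <- system.file("extdata", "psc_cohort_counts.tsv",
                     package = "procescape", mustWork = TRUE)
  dst <- file.path(dir, "psc_cohort_counts.tsv")
  file.copy(src, dst, overwrite = TRUE)
  invisible(dst)
}
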