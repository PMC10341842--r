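# Somatic variant intake and evidence filtering.
#
# Coordinates: VCF positions are 1-based (VCF standard) and kept 1-based in
# every table this module produces.

#' Evidence-filter configuration
#'
#' Thresholds applied to somatic calls before the processing analysis. All
#' four thresholds are strict inequalities ("above"/"below"): a call passes
#' only with total depth > `min_total_depth`, variant-supporting depth >
#' `min_alt_depth` and `vaf_lower` < VAF < `vaf_upper`; calls then enter the
#' processing analysis only with VAF > `processing_vaf`. The upper VAF bound
#' excludes fixation artifacts.
#'
#' @param min_total_depth Minimum total read depth (exclusive). Default 500.
#' @param min_alt_depth Minimum variant-supporting read depth (exclusive).
#'   Default 20.
#' @param vaf_lower Lower VAF bound (exclusive). Default 0.03.
#' @param vaf_upper Upper VAF bound (exclusive). Default 0.90.
#' @param processing_vaf VAF bound (exclusive) for selection into the
#'   processing analysis. Default 0.25.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_total_depth = 500, min_alt_depth = 20,
                          vaf_lower = 0.03, vaf_upper = 0.90,
                          processing_vaf = 0.25) {
  stopifnot_scalar_prob(vaf_lower, "vaf_lower")
  stopifnot_scalar_prob(vaf_upper, "vaf_upper")
  stopifnot_scalar_prob(processing_vaf, "processing_vaf")
  if (!(vaf_lower < processing_vaf && processing_vaf < vaf_upper)) {
    stop("required ordering: vaf_lower < processing_vaf < vaf_upper",
         call. = FALSE)
  }
  if (min_total_depth < 0 || min_alt_depth < 0) {
    stop("depth thresholds must be non-negative", call. = FALSE)
  }
  structure(list(min_total_depth = min_total_depth,
                 min_alt_depth = min_alt_depth,
                 vaf_lower = vaf_lower, vaf_upper = vaf_upper,
                 processing_vaf = processing_vaf),
            class = "filter_config")
}

#' @keywords internal
empty_variant_calls <- function() {
  data.frame(variant_id = character(), contig = character(),
             position = integer(), ref_allele = character(),
             alt_allele = character(), total_depth = numeric(),
             alt_depth = numeric(), vaf = numeric(),
             stringsAsFactors = FALSE)
}

#' Read somatic variant calls from a VCF file
#'
#' Parses a VCF (v4.x) via \pkg{vcfR} and returns one row per ALT allele
#' (multi-allelic records are split). Depth evidence is taken from the first
#' sample's `DP` and `AD` FORMAT fields; when `AD` is absent, the allele
#' fraction `AF` is used to reconstruct the variant depth. VAF is always
#' recomputed as `alt_depth / total_depth` when both depths are available,
#' since depth evidence is what the downstream filters act on. Records
#' lacking usable depth fields are skipped with a warning.
#'
#' @param path Path to a VCF file.
#' @return Data frame with columns `variant_id`, `contig`, `position`
#'   (1-based), `ref_allele`, `alt_allele`, `total_depth`, `alt_depth`,
#'   `vaf`.
#' @export
read_variant_calls <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) return(empty_variant_calls())
  has_gt <- ncol(v@gt) >= 2L
  dp <- if (has_gt) suppressWarnings(
    as.numeric(vcfR::extract.gt(v, element = "DP")[, 1])) else rep(NA_real_, n)
  ad <- if (has_gt) vcfR::extract.gt(v, element = "AD")[, 1] else rep(NA_character_, n)
  af <- if (has_gt) vcfR::extract.gt(v, element = "AF")[, 1] else rep(NA_character_, n)

  rows <- vector("list", n)
  skipped <- 0L
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    if (is.na(dp[i])) { skipped <- skipped + 1L; next }
    ad_i <- if (!is.na(ad[i])) suppressWarnings(
      as.numeric(strsplit(ad[i], ",", fixed = TRUE)[[1]])) else NULL
    af_i <- if (!is.na(af[i])) suppressWarnings(
      as.numeric(strsplit(af[i], ",", fixed = TRUE)[[1]])) else NULL
    alt_depths <- if (!is.null(ad_i) && length(ad_i) >= length(alts) + 1L) {
      ad_i[-1][seq_along(alts)]
    } else if (!is.null(af_i) && length(af_i) >= length(alts)) {
      round(af_i[seq_along(alts)] * dp[i])
    } else {
      skipped <- skipped + 1L; next
    }
    rows[[i]] <- data.frame(
      contig = unname(fix[i, "CHROM"]),
      position = as.integer(unname(fix[i, "POS"])),
      ref_allele = unname(fix[i, "REF"]), alt_allele = unname(alts),
      total_depth = dp[i], alt_depth = alt_depths,
      stringsAsFactors = FALSE)
  }
  if (skipped > 0L) {
    warning(skipped, " VCF record(s) lacked depth evidence and were skipped",
            call. = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(empty_variant_calls())
  out$vaf <- out$alt_depth / out$total_depth
  out$variant_id <- sprintf("%s:%d:%s>%s", out$contig, out$position,
                            out$ref_allele, out$alt_allele)
  out[, c("variant_id", "contig", "position", "ref_allele", "alt_allele",
          "total_depth", "alt_depth", "vaf")]
}

#' Apply the evidence filters to variant calls
#'
#' Retains calls that strictly exceed all thresholds: total depth above
#' `min_total_depth`, variant depth above `min_alt_depth`, and VAF strictly
#' between `vaf_lower` and `vaf_upper`. Input order is preserved and the
#' operation is idempotent.
#'
#' @param calls Data frame as returned by [read_variant_calls()].
#' @param cfg A [filter_config()].
#' @return Filtered data frame (possibly zero rows).
#' @export
filter_variants <- function(calls, cfg = filter_config()) {
  if (nrow(calls) == 0L) return(calls)
  keep <- calls$total_depth > cfg$min_total_depth &
    calls$alt_depth > cfg$min_alt_depth &
    calls$vaf > cfg$vaf_lower & calls$vaf < cfg$vaf_upper
  calls[keep, , drop = FALSE]
}

#' Select variants for the processing analysis
#'
#' Keeps calls with tumour allele frequency strictly above
#' `cfg$processing_vaf` (default 25\%), the subset investigated for altered
#' epitope processing.
#'
#' @inheritParams filter_variants
#' @return Filtered data frame.
#' @export
select_for_processing <- function(calls, cfg = filter_config()) {
  if (nrow(calls) == 0L) return(calls)
  calls[calls$vaf > cfg$processing_vaf, , drop = FALSE]
}
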