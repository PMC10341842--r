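# Patient-level aggregation and cohort statistics.

#' Group a UICC/TNM stage label into early vs advanced
#'
#' Early = stages I-IIIA, advanced = IIIB-IV.
#'
#' @param stage Character vector of stage labels (e.g. `"IA2"`, `"IIIB"`,
#'   `"IVA"`).
#' @return Character vector: `"early"`, `"advanced"` or `NA`.
#' @export
stage_group <- function(stage) {
  out <- rep(NA_character_, length(stage))
  adv <- grepl("^IV", stage) | grepl("^IIIB", stage) | grepl("^IIIC", stage)
  early <- !adv & grepl("^I", stage)
  out[which(adv)] <- "advanced"
  out[which(early)] <- "early"
  out
}

#' Dichotomize the processing-mutation burden
#'
#' Patients with more than one processing mutation are `"high"`, with
#' exactly one `"low"`, with none `"none"`. The merged two-level view
#' ([burden_two_level()]) pools `low` and `none` against `high`.
#'
#' @param processing_count Non-negative integer vector.
#' @return Character vector over `{none, low, high}`.
#' @export
dichotomize_burden <- function(processing_count) {
  if (any(processing_count < 0, na.rm = TRUE)) {
    stop("processing counts must be non-negative", call. = FALSE)
  }
  ifelse(processing_count >= 2, "high",
         ifelse(processing_count == 1, "low", "none"))
}

#' @rdname dichotomize_burden
#' @export
burden_two_level <- function(processing_count) {
  ifelse(processing_count >= 2, "high", "low_none")
}

#' Categorize a PD-L1 Tumour Proportion Score
#'
#' `< 1`\% is negative, 1-49\% low, `>= 50`\% high; missing values map to
#' `"unknown"` and are excluded from TPS denominators.
#'
#' @param tps Numeric vector of TPS percentages in \[0, 100\].
#' @return Character vector over `{negative, low, high, unknown}`.
#' @export
tps_category <- function(tps) {
  if (any(tps < 0 | tps > 100, na.rm = TRUE)) {
    stop("TPS must lie in [0, 100]", call. = FALSE)
  }
  ifelse(is.na(tps), "unknown",
         ifelse(tps < 1, "negative", ifelse(tps < 50, "low", "high")))
}

#' Aggregate mutation and processing calls to patient records
#'
#' Counts, per patient, the distinct missense mutations (mutational load;
#' de-duplicated by genomic variant, so a mutation annotated on several
#' transcripts counts once) and the distinct processing mutations, then
#' derives the burden groups and TPS category.
#'
#' @param clinical Data frame with one row per patient; must contain
#'   `patient_id`, and uses `stage`, `tps`, survival and therapy columns
#'   when present.
#' @param mutations Data frame with `patient_id` and `variant_id` (one row
#'   per (variant, transcript) missense annotation).
#' @param processing_mutations Data frame with `variant_id` and
#'   `is_processing` ([call_processing()]`$mutations`); every row must match
#'   a mutation.
#' @return `clinical` with `mutational_load`, `processing_count`,
#'   `burden_group`, `burden_two`, and (when `tps`/`stage` are present)
#'   `tps_group`/`stage_group` columns added.
#' @export
aggregate_patients <- function(clinical, mutations, processing_mutations) {
  if (!"patient_id" %in% names(clinical)) {
    stop("clinical table must have a patient_id column", call. = FALSE)
  }
  unmatched <- setdiff(processing_mutations$variant_id, mutations$variant_id)
  if (length(unmatched)) {
    stop("processing call(s) without matching mutation: ",
         paste(head(unmatched, 3), collapse = ", "), call. = FALSE)
  }
  proc_ids <- processing_mutations$variant_id[processing_mutations$is_processing]
  per_pat <- split(mutations$variant_id, mutations$patient_id)
  load <- vapply(per_pat, function(v) length(unique(v)), integer(1))
  pcount <- vapply(per_pat, function(v)
    length(intersect(unique(v), proc_ids)), integer(1))
  clinical$mutational_load <-
    unname(ifelse(is.na(match(clinical$patient_id, names(per_pat))), 0L,
                  load[match(clinical$patient_id, names(per_pat))]))
  clinical$processing_count <-
    unname(ifelse(is.na(match(clinical$patient_id, names(per_pat))), 0L,
                  pcount[match(clinical$patient_id, names(per_pat))]))
  clinical$burden_group <- dichotomize_burden(clinical$processing_count)
  clinical$burden_two <- burden_two_level(clinical$processing_count)
  if ("tps" %in% names(clinical)) {
    clinical$tps_group <- tps_category(clinical$tps)
  }
  if ("stage" %in% names(clinical) && !"stage_group" %in% names(clinical)) {
    clinical$stage_group <- stage_group(clinical$stage)
  }
  clinical
}

#' Cohort summary table of counts and percentages
#'
#' Two input forms are accepted. Given patient records and a set of
#' categorical variables, tabulates per-category counts against the
#' evaluable denominator (records with a missing or `"unknown"` value are
#' excluded from that variable's denominator). Given a pre-tabulated count
#' table (columns `count` and `denominator`, e.g. [paper_fixture()]), only
#' the percentage is computed. Percentages are rounded half-up to `digits`
#' decimals (a `digits` column in a count table overrides the argument
#' row-wise, matching the precision tables are printed at).
#'
#' @param records Patient records data frame, or a count table with
#'   `count` and `denominator` columns.
#' @param variables Character vector of column names to summarize (records
#'   form only).
#' @param digits Decimal places for percentages (default 1).
#' @return Data frame with `variable`, `category`, `count`, `denominator`,
#'   `percentage`.
#' @export
cohort_summary <- function(records, variables = NULL, digits = 1) {
  if (all(c("count", "denominator") %in% names(records))) {
    out <- as.data.frame(records)
    d <- if ("digits" %in% names(out)) out$digits else digits
    out$percentage <- round_half_up(100 * out$count / out$denominator, d)
    return(out)
  }
  if (nrow(records) == 0L) stop("no patient records", call. = FALSE)
  if (is.null(variables)) {
    stop("'variables' is required for the records form", call. = FALSE)
  }
  rows <- lapply(variables, function(v) {
    x <- records[[v]]
    if (is.null(x)) stop("no column '", v, "' in records", call. = FALSE)
    x <- as.character(x)
    x[x == "unknown"] <- NA
    x <- x[!is.na(x)]
    denom <- length(x)
    tab <- table(x)
    data.frame(variable = v, category = names(tab),
               count = as.integer(tab), denominator = denom,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$percentage <- round_half_up(100 * out$count / out$denominator, digits)
  rownames(out) <- NULL
  out
}

#' Fisher's exact test with sample odds ratio for a 2x2 table
#'
#' The odds ratio is the sample cross-product `(a*d)/(b*c)` (optionally the
#' conditional maximum-likelihood estimate); the two-sided p-value is
#' computed by hypergeometric enumeration, summing the probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param or_method `"sample"` (cross-product, default) or `"cmle"`
#'   (conditional MLE).
#' @param haldane Apply the Haldane-Anscombe 0.5 correction to the sample
#'   odds ratio when a cell is zero (default `FALSE`).
#' @return List of class `fisher_or` with `odds_ratio`, `p_value`,
#'   `table`, `or_method`, `or_defined`.
#' @export
fisher_or <- function(table, or_method = c("sample", "cmle"),
                      haldane = FALSE) {
  or_method <- match.arg(or_method)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) ||
      any(table != round(table))) {
    stop("a 2x2 matrix of non-negative integer counts is required",
         call. = FALSE)
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  r1 <- a + b; c1 <- a + c; c2 <- b + d; N <- sum(table)
  or_defined <- TRUE
  if (or_method == "sample") {
    if (haldane && any(table == 0)) {
      or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    } else if (b * c == 0 && a * d == 0) {
      or <- NA_real_; or_defined <- FALSE
    } else {
      or <- (a * d) / (b * c)  # Inf when only b*c == 0
    }
  } else {
    or <- cmle_odds_ratio(a, r1, c1, N)
  }
  # enumeration over the hypergeometric support of cell (1,1)
  lo <- max(0L, r1 - c2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- dhyper(support, c1, c2, r1)
  p_obs <- dhyper(a, c1, c2, r1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  structure(list(odds_ratio = or, p_value = p, table = table,
                 or_method = or_method, or_defined = or_defined),
            class = "fisher_or")
}

# Conditional MLE of the odds ratio given all margins (mean of the
# noncentral hypergeometric distribution matched to the observed cell).
#' @keywords internal
cmle_odds_ratio <- function(a, r1, c1, N) {
  lo <- max(0L, r1 + c1 - N); hi <- min(r1, c1)
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  support <- lo:hi
  logbase <- dhyper(support, c1, N - c1, r1, log = TRUE)
  mean_at <- function(logpsi) {
    lw <- logbase + support * logpsi
    w <- exp(lw - max(lw))  # stable against overflow at extreme psi
    sum(support * w) / sum(w) - a
  }
  exp(stats::uniroot(mean_at, c(-40, 40), tol = 1e-10)$root)
}

#' @export
print.fisher_or <- function(x, ...) {
  cat(sprintf("<fisher_or> OR (%s) = %s, two-sided p = %.4g\n",
              x$or_method,
              if (x$or_defined) format(x$odds_ratio, digits = 4) else "undefined",
              x$p_value))
  invisible(x)
}

#' Compare processing-mutation prevalence between two cohorts
#'
#' Builds the double-dichotomous 2x2 table (patients with vs without
#' processing mutations, cohort A vs cohort B) and applies [fisher_or()].
#' The odds ratio is the factor by which the chance of encountering a
#' patient with processing mutations is increased in cohort A.
#'
#' @param with_a,n_a Patients with processing mutations / total, cohort A.
#' @param with_b,n_b Same for cohort B.
#' @param ... Passed to [fisher_or()].
#' @return A `fisher_or` object.
#' @export
compare_processing_prevalence <- function(with_a, n_a, with_b, n_b, ...) {
  tab <- matrix(c(with_a, with_b, n_a - with_a, n_b - with_b), nrow = 2,
                dimnames = list(cohort = c("A", "B"),
                                processing = c("with", "without")))
  fisher_or(tab, ...)
}

#' Discrete density summary of per-patient burden counts
#'
#' Tabulates the frequency of every integer count from 0 to the maximum,
#' and reports the median and the local maxima (modes) of the discrete
#' distribution (a count is a mode when its frequency is positive and not
#' smaller than either neighbour's).
#'
#' @param counts Non-negative integer vector of per-patient counts.
#' @return List of class `burden_density` with `freq` (data frame `count`,
#'   `n`, `proportion`), `median`, `modes`.
#' @export
burden_density <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  mx <- max(counts)
  n <- vapply(0:mx, function(k) sum(counts == k), integer(1))
  freq <- data.frame(count = 0:mx, n = n, proportion = n / length(counts))
  padded <- c(0L, n, 0L)
  is_mode <- n > 0L & n >= padded[seq_along(n)] & n >= padded[seq_along(n) + 2L]
  structure(list(freq = freq, median = median(counts),
                 modes = (0:mx)[is_mode]),
            class = "burden_density")
}

#' @export
print.burden_density <- function(x, ...) {
  cat(sprintf("<burden_density> median %s, mode(s) at %s\n",
              format(x$median), paste(x$modes, collapse = ", ")))
  print(x$freq, row.names = FALSE)
  invisible(x)
}
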