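# Internal helpers shared across modules.

#' @keywords internal
logistic <- function(x) 1 / (1 + exp(-x))

#' Round half away from zero
#'
#' Base `round()` rounds half to even; clinical tables round half up.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @keywords internal
check_peptide <- function(x, what = "peptide") {
  bad <- setdiff(strsplit(x, "")[[1]], AA20)
  if (length(bad)) {
    stop(sprintf("%s contains non-standard residue(s): %s",
                 what, paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# Deterministic sub-seed derivation: one user-facing seed governs all stages.
# Kept below 2^31 so it is always a valid R integer seed.
#' @keywords internal
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage)) * 1009L
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483647)
}
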