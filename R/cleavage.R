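# Proteasomal cleavage scoring and the processing-mutation call.
#
# The scorer is a position-weight model: the cleavage probability after
# residue i is logistic(bias + sum over offsets o of weight[o, residue at
# i+o]), offsets outside the context being skipped. Two backends share this
# contract: the internal matrix model below, and a reader for externally
# produced per-position score tables. A mutation is a "processing mutation"
# when, for at least one of its epitope windows, the wildtype and mutant
# cleavage probabilities at the assessed site differ by at least the
# threshold (default 0.50, absolute difference).

#' Construct a cleavage scoring model
#'
#' @param weights Numeric matrix, one row per offset and one column per
#'   amino acid (columns named with the 20 one-letter codes).
#' @param offsets Integer offsets relative to the scored position, one per
#'   matrix row (e.g. `-2:2`; offset 0 is the residue after which cleavage
#'   occurs).
#' @param bias Scalar intercept on the logit scale.
#' @param backend_id Identifier recorded on profiles produced by the model.
#' @return An object of class `cleavage_model`.
#' @export
cleavage_model <- function(weights, offsets, bias = 0,
                           backend_id = "internal_cterm_like") {
  weights <- as.matrix(weights)
  if (nrow(weights) != length(offsets)) {
    stop("one weight row per offset required", call. = FALSE)
  }
  if (!setequal(colnames(weights), AA20)) {
    stop("weight columns must be the 20 standard amino acids", call. = FALSE)
  }
  weights <- weights[, AA20, drop = FALSE]
  structure(list(weights = weights, offsets = as.integer(offsets),
                 bias = bias, backend_id = backend_id),
            class = "cleavage_model")
}

# Residues the default model treats as favoured C-terminal cleavage
# residues (hydrophobic/aromatic/basic side chains, after which the
# proteasome's beta-subunits preferentially cut).
#' @keywords internal
CLEAVAGE_STRONG <- c("F", "L", "I", "V", "M", "W", "Y", "K", "R")

#' Default internal cleavage model
#'
#' A deterministic matrix model with a strong preference for cleavage after
#' hydrophobic, aromatic and basic residues and a mild damping contribution
#' from neighbouring positions. The weights are a documented in-package
#' scoring scheme, not the trained weights of any external neural-network
#' predictor; they are co-designed with the synthetic cohort generator so
#' that cross-class substitutions at a window's C-terminal position flip the
#' cleavage probability by more than 0.5 while same-class substitutions
#' leave every profile unchanged.
#'
#' @param strong_logit Logit weight of favoured residues at offset 0
#'   (default 3; unfavoured residues get its negative).
#' @param neighbour_logit Magnitude of the neighbour-offset weights
#'   (default 0.1).
#' @return A [cleavage_model()].
#' @export
default_cleavage_model <- function(strong_logit = 3, neighbour_logit = 0.1) {
  offsets <- -2:2
  w <- matrix(0, nrow = length(offsets), ncol = 20,
              dimnames = list(as.character(offsets), AA20))
  strong <- AA20 %in% CLEAVAGE_STRONG
  w["0", ] <- ifelse(strong, strong_logit, -strong_logit)
  for (o in c("-2", "-1", "1", "2")) {
    w[o, ] <- ifelse(strong, -neighbour_logit, neighbour_logit)
  }
  cleavage_model(w, offsets, bias = 0, backend_id = "internal_cterm_like")
}

#' Score per-position cleavage probabilities of a flanked peptide
#'
#' @param context Peptide string (flanks + epitope) in one-letter codes.
#' @param model A [cleavage_model()].
#' @param on_unknown What to do with non-standard residues: `"error"`
#'   (default) or `"zero"` (zero weight, with a warning).
#' @return An object of class `cleavage_profile`: list with `context`,
#'   `prob` (one probability in \[0, 1\] per residue) and `backend_id`.
#' @export
score_cleavage <- function(context, model = default_cleavage_model(),
                           on_unknown = c("error", "zero")) {
  on_unknown <- match.arg(on_unknown)
  aa <- strsplit(context, "")[[1]]
  unknown <- !aa %in% AA20
  if (any(unknown)) {
    if (on_unknown == "error") check_peptide(context, "cleavage context")
    warning("non-standard residue(s) scored with zero weight", call. = FALSE)
  }
  n <- length(aa)
  logit <- rep(model$bias, n)
  for (r in seq_along(model$offsets)) {
    o <- model$offsets[r]
    idx <- seq_len(n) + o
    ok <- idx >= 1L & idx <= n & !unknown[pmin(pmax(idx, 1L), n)]
    wr <- model$weights[r, ]
    logit[ok] <- logit[ok] + wr[aa[idx[ok]]]
  }
  structure(list(context = context, prob = unname(logistic(logit)),
                 backend_id = model$backend_id),
            class = "cleavage_profile")
}

#' @export
print.cleavage_profile <- function(x, ...) {
  cat(sprintf("<cleavage_profile> %d residues, backend %s\n",
              nchar(x$context), x$backend_id))
  cat(" ", x$context, "\n ", paste(sprintf("%.2f", x$prob), collapse = " "),
      "\n")
  invisible(x)
}

#' Parse an externally produced cleavage score table
#'
#' Reads a whitespace- or tab-delimited table with `position`, `residue` and
#' `score` columns (header detected automatically) such as those written by
#' external cleavage predictors. Scores are clipped to \[0, 1\] with a
#' warning; the residue column must agree with the supplied context at every
#' position, and every context position must be present.
#'
#' @param path Path to the score table.
#' @param context The peptide context the scores belong to.
#' @return A `cleavage_profile` with `backend_id = "parsed_external"`.
#' @export
parse_external_cleavage <- function(path, context) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]{2,}", first)
  tab <- read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (has_header) {
    names(tab) <- tolower(names(tab))
    need <- c("position", "residue", "score")
    if (!all(need %in% names(tab))) {
      stop("expected columns position, residue, score", call. = FALSE)
    }
    tab <- tab[, need]
  } else {
    if (ncol(tab) < 3L) stop("expected 3 columns", call. = FALSE)
    names(tab)[1:3] <- c("position", "residue", "score")
  }
  n <- nchar(context)
  tab <- tab[order(tab$position), ]
  if (!identical(as.integer(tab$position), seq_len(n))) {
    stop("score table does not cover positions 1..", n, " exactly",
         call. = FALSE)
  }
  ctx <- strsplit(context, "")[[1]]
  if (!identical(toupper(tab$residue), ctx)) {
    bad <- which(toupper(tab$residue) != ctx)[1]
    stop(sprintf("residue mismatch at position %d: table has %s, context has %s",
                 bad, tab$residue[bad], ctx[bad]), call. = FALSE)
  }
  sc <- as.numeric(tab$score)
  if (any(sc < 0 | sc > 1)) {
    warning("scores outside [0, 1] clipped", call. = FALSE)
    sc <- pmin(1, pmax(0, sc))
  }
  structure(list(context = context, prob = sc, backend_id = "parsed_external"),
            class = "cleavage_profile")
}

#' Compare wildtype and mutant cleavage profiles of one epitope window
#'
#' Computes the cleavage-probability difference at the assessed site(s) and
#' flags the window as having altered processing when any assessed
#' difference reaches the threshold. The default site policy assesses only
#' the epitope's C-terminal cleavage position (the proteasome fixes epitope
#' C-termini); `sites = "all"` assesses every context position. The default
#' rule is the absolute probability difference; `rule = "relative"` divides
#' by the wildtype probability.
#'
#' @param wt,mut `cleavage_profile` objects over positionally aligned
#'   contexts of equal length.
#' @param epitope_start 1-based position of the epitope's first residue
#'   within the context.
#' @param epitope_len Epitope length.
#' @param threshold Difference needed to call the window altered
#'   (default 0.50).
#' @param sites `"cterm"` (default) or `"all"`.
#' @param rule `"absolute"` (default) or `"relative"`.
#' @return List with `delta` (maximum assessed difference) and `altered`.
#' @export
call_processing_mutation <- function(wt, mut, epitope_start, epitope_len,
                                     threshold = 0.50,
                                     sites = c("cterm", "all"),
                                     rule = c("absolute", "relative")) {
  sites <- match.arg(sites); rule <- match.arg(rule)
  if (nchar(wt$context) != nchar(mut$context)) {
    stop("wildtype and mutant contexts differ in length", call. = FALSE)
  }
  idx <- if (sites == "cterm") epitope_start + epitope_len - 1L
         else seq_along(wt$prob)
  d <- abs(wt$prob[idx] - mut$prob[idx])
  if (rule == "relative") d <- d / pmax(wt$prob[idx], .Machine$double.eps)
  dmax <- max(d)
  list(delta = dmax, altered = dmax >= threshold)
}

#' Call processing mutations over an epitope space
#'
#' Scores wildtype and mutant flanked peptides for every epitope pair with
#' the chosen backend, applies the difference rule per window, and
#' aggregates to one verdict per mutation (a mutation is a processing
#' mutation when any of its windows, on any transcript, is altered).
#'
#' @param epitopes Epitope-space data frame ([build_epitope_space()]).
#' @param model A [cleavage_model()], or a function `(context) ->
#'   cleavage_profile` for externally parsed backends.
#' @param threshold,sites,rule Passed to [call_processing_mutation()].
#' @return List of class `processing_calls` with `epitopes` (input plus
#'   `delta` and `altered` columns) and `mutations` (one row per
#'   `variant_id`: `max_abs_delta`, `is_processing`, `n_altered_epitopes`).
#' @export
call_processing <- function(epitopes, model = default_cleavage_model(),
                            threshold = 0.50, sites = "cterm",
                            rule = "absolute") {
  score_fun <- if (is.function(model)) model else
    function(ctx) score_cleavage(ctx, model)
  n <- nrow(epitopes)
  delta <- numeric(n); altered <- logical(n)
  for (i in seq_len(n)) {
    e <- epitopes[i, ]
    wt_ctx <- paste0(e$n_flank, e$wildtype_peptide, e$c_flank)
    mut_ctx <- paste0(e$n_flank, e$mutant_peptide, e$c_flank)
    res <- call_processing_mutation(
      score_fun(wt_ctx), score_fun(mut_ctx),
      epitope_start = nchar(e$n_flank) + 1L, epitope_len = e$length,
      threshold = threshold, sites = sites, rule = rule)
    delta[i] <- res$delta; altered[i] <- res$altered
  }
  epitopes$delta <- delta
  epitopes$altered <- altered
  if (n > 0L) {
    agg_max <- tapply(delta, epitopes$variant_id, max)
    agg_n <- tapply(altered, epitopes$variant_id, sum)
    mutations <- data.frame(
      variant_id = names(agg_max),
      max_abs_delta = unname(agg_max),
      n_altered_epitopes = as.integer(unname(agg_n)),
      stringsAsFactors = FALSE)
    mutations$is_processing <- mutations$n_altered_epitopes > 0L
    mutations <- mutations[order(mutations$variant_id), ]
    rownames(mutations) <- NULL
  } else {
    mutations <- data.frame(variant_id = character(),
                            max_abs_delta = numeric(),
                            n_altered_epitopes = integer(),
                            is_processing = logical(),
                            stringsAsFactors = FALSE)
  }
  structure(list(epitopes = epitopes, mutations = mutations),
            class = "processing_calls")
}

#' @export
print.processing_calls <- function(x, ...) {
  cat(sprintf(
    "<processing_calls> %d epitope pairs, %d mutations, %d processing (%.1f%%)\n",
    nrow(x$epitopes), nrow(x$mutations), sum(x$mutations$is_processing),
    if (nrow(x$mutations)) 100 * mean(x$mutations$is_processing) else 0))
  invisible(x)
}

#' Write / read a cleavage model as delimited text
#'
#' Plain-text round trip for cleavage models (versioned header line,
#' tab-delimited weight matrix).
#'
#' @param model A [cleavage_model()].
#' @param path Output/input path.
#' @return `write_cleavage_model` invisibly returns `path`;
#'   `read_cleavage_model` returns a [cleavage_model()].
#' @export
write_cleavage_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# procescape cleavage_model v1 backend=%s bias=%.17g",
                     model$backend_id, model$bias), con)
  writeLines(paste(c("offset", AA20), collapse = "\t"), con)
  for (r in seq_along(model$offsets)) {
    writeLines(paste(c(model$offsets[r],
                       sprintf("%.17g", model$weights[r, ])), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' @rdname write_cleavage_model
#' @export
read_cleavage_model <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!grepl("^# procescape cleavage_model v1", hdr)) {
    stop("not a procescape cleavage_model file", call. = FALSE)
  }
  backend <- sub(".*backend=([^ ]+).*", "\\1", hdr)
  bias <- as.numeric(sub(".*bias=([-0-9.eE+]+).*", "\\1", hdr))
  tab <- read.delim(path, skip = 1L, check.names = FALSE)
  w <- as.matrix(tab[, AA20])
  rownames(w) <- tab$offset
  cleavage_model(w, as.integer(tab$offset), bias = bias, backend_id = backend)
}
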