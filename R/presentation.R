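# MHC class I presentation and immunogenicity of altered epitopes.
#
# Binding is scored with additive position-specific matrices on the
# log10-IC50 scale, one matrix per supertype-representative allele and
# peptide length; a peptide binds an allele when its predicted IC50 is at
# or below the binder threshold (default 500 nM). The shipped panel covers
# the 12 canonical class I supertypes with motif-style anchor preferences
# (positions 2 and the C-terminus); it is a deterministic in-package scoring
# scheme, not a trained affinity predictor. Immunogenicity is a masked
# positional weight x amino-acid enrichment sum with the anchor positions
# (1, 2 and the C-terminus) masked.

#' Construct an allele scoring matrix
#'
#' @param allele Allele/supertype name.
#' @param matrix Numeric matrix (`length` rows x 20 amino-acid columns) of
#'   additive contributions on the log10-IC50 scale.
#' @param intercept Scalar added to the positional sum (log10 nM).
#' @return Object of class `allele_matrix`.
#' @export
allele_matrix <- function(allele, matrix, intercept) {
  matrix <- as.matrix(matrix)
  if (!setequal(colnames(matrix), AA20)) {
    stop("matrix columns must be the 20 standard amino acids", call. = FALSE)
  }
  structure(list(allele = allele, length = nrow(matrix),
                 matrix = matrix[, AA20, drop = FALSE],
                 intercept = intercept),
            class = "allele_matrix")
}

# Anchor preferences (log10-IC50 contributions) of the 12 supertype
# representatives: position 2 and the C-terminal position.
#' @keywords internal
SUPERTYPE_MOTIFS <- list(
  A01 = list(p2 = c(T = -1.8, S = -1.8), pC = c(Y = -1.8, F = -1.2)),
  A02 = list(p2 = c(L = -1.8, M = -1.8, I = -1.2),
             pC = c(V = -1.8, L = -1.4, I = -1.2)),
  A03 = list(p2 = c(L = -1.4, V = -1.4, M = -1.2),
             pC = c(K = -1.8, R = -1.6)),
  A24 = list(p2 = c(Y = -1.8, F = -1.6), pC = c(F = -1.6, L = -1.4, I = -1.4)),
  A26 = list(p2 = c(E = -1.8, D = -1.4, T = -1.2), pC = c(Y = -1.6, F = -1.4)),
  B07 = list(p2 = c(P = -1.8), pC = c(L = -1.6, F = -1.4)),
  B08 = list(p2 = c(K = -1.6, R = -1.4), pC = c(L = -1.6, F = -1.2)),
  B27 = list(p2 = c(R = -1.8), pC = c(K = -1.4, R = -1.4, L = -1.4)),
  B39 = list(p2 = c(R = -1.6, H = -1.6, K = -1.4), pC = c(L = -1.6)),
  B44 = list(p2 = c(E = -1.8, D = -1.6), pC = c(F = -1.4, Y = -1.4, W = -1.2)),
  B58 = list(p2 = c(A = -1.6, S = -1.4, T = -1.4), pC = c(F = -1.6, W = -1.4)),
  B62 = list(p2 = c(Q = -1.6, L = -1.4), pC = c(F = -1.6, Y = -1.4)))

#' Default 12-supertype allele panel
#'
#' Builds motif-style matrices for the representative alleles A01, A02,
#' A03, A24, A26, B07, B08, B27, B39, B44, B58 and B62, one matrix per
#' requested peptide length. The intercept of log10(50000) nM makes a
#' peptide with no anchor match a clear non-binder; matching both anchor
#' positions brings the predicted IC50 below the default 500 nM cut-off.
#'
#' @param lengths Peptide lengths to cover (default 8:11).
#' @param intercept Baseline log10 IC50 (default `log10(5e4)`).
#' @return List of [allele_matrix()] objects.
#' @export
default_allele_panel <- function(lengths = 8:11, intercept = log10(5e4)) {
  out <- list()
  for (al in names(SUPERTYPE_MOTIFS)) {
    mot <- SUPERTYPE_MOTIFS[[al]]
    for (k in lengths) {
      m <- matrix(0, nrow = k, ncol = 20, dimnames = list(NULL, AA20))
      m[2L, names(mot$p2)] <- mot$p2
      m[k, names(mot$pC)] <- mot$pC
      out[[sprintf("%s_%d", al, k)]] <- allele_matrix(al, m, intercept)
    }
  }
  out
}

#' Score peptide binding to one allele matrix
#'
#' `log10(IC50) = intercept + sum over positions of matrix[position,
#' residue]`; the predicted IC50 is `10^` that sum (nM), and the peptide is
#' a binder when IC50 is at or below `binder_threshold`.
#'
#' @param peptide Peptide string; length must equal the matrix length.
#' @param matrix An [allele_matrix()].
#' @param binder_threshold Binder cut-off in nM (default 500).
#' @return List with `peptide`, `allele`, `predicted_ic50`, `is_binder`.
#' @export
score_binding <- function(peptide, matrix, binder_threshold = 500) {
  aa <- strsplit(peptide, "")[[1]]
  if (length(aa) != matrix$length) {
    stop(sprintf("peptide length %d does not match matrix length %d",
                 length(aa), matrix$length), call. = FALSE)
  }
  check_peptide(peptide)
  log_ic50 <- matrix$intercept +
    sum(matrix$matrix[cbind(seq_along(aa), match(aa, AA20))])
  ic50 <- 10^log_ic50
  list(peptide = peptide, allele = matrix$allele, predicted_ic50 = ic50,
       is_binder = ic50 <= binder_threshold)
}

#' Alleles of a panel that bind a peptide
#'
#' @param peptide Peptide string.
#' @param panel List of [allele_matrix()] objects (matrices whose length
#'   differs from the peptide are ignored).
#' @param binder_threshold Binder cut-off in nM (default 500).
#' @return Character vector of bound allele names (empty when the peptide
#'   is no longer bound by any known supertype).
#' @export
classify_binders <- function(peptide, panel, binder_threshold = 500) {
  if (length(panel) == 0L) stop("empty allele panel", call. = FALSE)
  k <- nchar(peptide)
  panel <- panel[vapply(panel, function(m) m$length == k, logical(1))]
  if (length(panel) == 0L) {
    stop("no allele matrix for peptides of length ", k, call. = FALSE)
  }
  hits <- vapply(panel, function(m)
    score_binding(peptide, m, binder_threshold)$is_binder, logical(1))
  sort(unique(vapply(panel[hits], `[[`, "", "allele")))
}

# Positional importance of the interior (non-anchor) residues of a 9-mer
# for T-cell receptor recognition, and per-amino-acid enrichment scores in
# the style of positional-weight immunogenicity schemes (aromatic and large
# hydrophobic residues enriched among immunogenic ligands).
#' @keywords internal
IMM_POS_WEIGHTS_9 <- c(0, 0, 0.10, 0.31, 0.30, 0.29, 0.26, 0.18, 0)
#' @keywords internal
IMM_ENRICHMENT <- c(
  A = -0.127, C = -0.175, D =  0.072, E =  0.325, F =  0.380,
  G =  0.110, H =  0.105, I =  0.432, K = -0.700, L = -0.036,
  M = -0.570, N = -0.021, P = -0.036, Q = -0.376, R =  0.168,
  S = -0.537, T =  0.126, V =  0.134, W =  0.719, Y = -0.012)

#' Immunogenicity scoring model
#'
#' Positional weights with masked anchor positions (1, 2 and the
#' C-terminus contribute zero) and per-amino-acid enrichment scores. For
#' lengths other than 9 the interior weight vector is truncated or padded
#' with its last value.
#'
#' @param length Peptide length (default 9).
#' @param masked Masked (zero-weight) positions; default `c(1, 2, length)`.
#' @return Object of class `immunogenicity_model` with `weights` (length
#'   `length`) and `enrichment` (named, 20 values).
#' @export
immunogenicity_model <- function(length = 9L, masked = c(1L, 2L, length)) {
  interior9 <- IMM_POS_WEIGHTS_9[3:8]
  n_int <- length - 3L
  w <- numeric(length)
  if (n_int > 0L) {
    vals <- if (n_int <= length(interior9)) interior9[seq_len(n_int)]
            else c(interior9, rep(interior9[length(interior9)],
                                  n_int - length(interior9)))
    w[setdiff(seq_len(length), masked)] <- vals
  }
  w[masked] <- 0
  structure(list(length = length, masked = sort(unique(masked)),
                 weights = w, enrichment = IMM_ENRICHMENT),
            class = "immunogenicity_model")
}

#' Score the immunogenicity of a peptide
#'
#' Sum over non-masked positions of positional weight times the residue's
#' enrichment score; higher scores indicate greater TCR-activation
#' potential.
#'
#' @param peptide Peptide string matching the model length.
#' @param model An [immunogenicity_model()].
#' @return Scalar score.
#' @export
immunogenicity_score <- function(peptide, model = immunogenicity_model()) {
  aa <- strsplit(peptide, "")[[1]]
  if (length(aa) != model$length) {
    stop("peptide length does not match the immunogenicity model",
         call. = FALSE)
  }
  check_peptide(peptide)
  sum(model$weights * model$enrichment[aa])
}

#' TCR-activation rule
#'
#' A mutant epitope is TCR-activating when its immunogenicity score
#' strictly exceeds the mean of its wildtype correspondents' scores minus
#' twice their standard deviation. The wildtype correspondent set is the
#' mutation's full set of wildtype epitope windows (all windows, all
#' transcripts); the population standard deviation (denominator n) is used,
#' so a single wildtype score degenerates to `mut_score > wt_score`.
#'
#' @param mut_score Mutant epitope immunogenicity score.
#' @param wt_scores Non-empty numeric vector of wildtype scores.
#' @return Logical.
#' @export
call_tcr_activation <- function(mut_score, wt_scores) {
  if (length(wt_scores) == 0L) {
    stop("wildtype score set must be non-empty", call. = FALSE)
  }
  m <- mean(wt_scores)
  sdp <- sqrt(mean((wt_scores - m)^2))
  mut_score > m - 2 * sdp
}

#' Classify the fate of one altered epitope
#'
#' @param bound_alleles Character vector of alleles binding the mutant
#'   peptide (possibly empty).
#' @param tcr_activating Logical from [call_tcr_activation()].
#' @return One of `"lost_binding"`, `"bound_not_immunogenic"`,
#'   `"bound_immunogenic"`.
#' @export
classify_epitope_fate <- function(bound_alleles, tcr_activating) {
  if (length(bound_alleles) == 0L) return("lost_binding")
  if (!tcr_activating) return("bound_not_immunogenic")
  "bound_immunogenic"
}

#' Classify fates of all altered epitopes in a processing result
#'
#' For every epitope window flagged as altered, predicts mutant-peptide
#' binding across the panel, scores immunogenicity, applies the TCR rule
#' against the mutation's wildtype window set, and assigns exactly one of
#' the three fates. The three fate counts always partition the altered
#' epitope total.
#'
#' @param processing A `processing_calls` object ([call_processing()]).
#' @param panel Allele panel (default [default_allele_panel()]).
#' @param binder_threshold Binder cut-off in nM (default 500).
#' @return Data frame with one row per altered epitope: `epitope_id`,
#'   `variant_id`, `bound_alleles` (comma-separated), `n_bound`,
#'   `immunogenicity_score`, `tcr_activating`, `fate`.
#' @export
classify_fates <- function(processing, panel = default_allele_panel(),
                           binder_threshold = 500) {
  ep <- processing$epitopes
  altered <- ep[ep$altered, , drop = FALSE]
  out <- data.frame(epitope_id = character(), variant_id = character(),
                    bound_alleles = character(), n_bound = integer(),
                    immunogenicity_score = numeric(),
                    tcr_activating = logical(), fate = character(),
                    stringsAsFactors = FALSE)
  if (nrow(altered) == 0L) return(out)
  imm_models <- lapply(unique(ep$length), immunogenicity_model)
  names(imm_models) <- as.character(unique(ep$length))
  # wildtype correspondent scores per mutation, over ALL of its windows
  wt_scores <- lapply(split(ep, ep$variant_id), function(d)
    vapply(seq_len(nrow(d)), function(i)
      immunogenicity_score(d$wildtype_peptide[i],
                           imm_models[[as.character(d$length[i])]]),
      numeric(1)))
  rows <- lapply(seq_len(nrow(altered)), function(i) {
    e <- altered[i, ]
    bound <- classify_binders(e$mutant_peptide, panel, binder_threshold)
    ms <- immunogenicity_score(e$mutant_peptide,
                               imm_models[[as.character(e$length)]])
    act <- call_tcr_activation(ms, wt_scores[[e$variant_id]])
    data.frame(epitope_id = e$epitope_id, variant_id = e$variant_id,
               bound_alleles = paste(bound, collapse = ","),
               n_bound = length(bound), immunogenicity_score = ms,
               tcr_activating = act,
               fate = classify_epitope_fate(bound, act),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate the three-way epitope fate partition
#'
#' @param fates Data frame from [classify_fates()].
#' @return Named integer vector over the three fates (sums to `nrow(fates)`).
#' @export
fate_partition <- function(fates) {
  lv <- c("lost_binding", "bound_not_immunogenic", "bound_immunogenic")
  table(factor(fates$fate, levels = lv))
}
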