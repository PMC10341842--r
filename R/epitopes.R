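# Epitope-window enumeration around missense positions. Every k-mer window
# that lies fully inside the protein and covers the mutated residue is a
# candidate epitope; flanking residues on both sides are carried along
# because they influence proteasomal cleavage.

#' Enumerate wildtype/mutant epitope windows covering a mutated residue
#'
#' For each requested length `k`, emits every `k`-mer window fully contained
#' in the protein that covers position `pos`. For a mid-protein position
#' there are exactly `k` such windows; near the termini the count follows
#' the closed form `min(k, pos, L - pos + 1, L - k + 1)` (0 when negative).
#'
#' @param protein Wildtype protein sequence (one-letter codes).
#' @param pos 1-based position of the substituted residue.
#' @param mut_aa Mutant amino acid placed at `pos` in the mutant peptides.
#' @param lengths Integer vector of epitope lengths (default 9).
#' @return Data frame with one row per window: `window_start`, `length`,
#'   `wildtype_peptide`, `mutant_peptide`, `mut_offset` (1-based position of
#'   the substitution inside the window).
#' @export
enumerate_epitope_windows <- function(protein, pos, mut_aa, lengths = 9L) {
  L <- nchar(protein)
  if (pos < 1L || pos > L) stop("position outside the protein", call. = FALSE)
  empty <- data.frame(window_start = integer(), length = integer(),
                      wildtype_peptide = character(),
                      mutant_peptide = character(), mut_offset = integer(),
                      stringsAsFactors = FALSE)
  if (L < min(lengths)) {
    warning("protein shorter than the smallest epitope length; no windows",
            call. = FALSE)
    return(empty)
  }
  mutant_protein <- protein
  substr(mutant_protein, pos, pos) <- mut_aa
  out <- empty
  for (k in sort(as.integer(lengths))) {
    s0 <- max(1L, pos - k + 1L)
    s1 <- min(pos, L - k + 1L)
    if (s1 < s0) next
    starts <- s0:s1
    out <- rbind(out, data.frame(
      window_start = starts, length = k,
      wildtype_peptide = substring(protein, starts, starts + k - 1L),
      mutant_peptide = substring(mutant_protein, starts, starts + k - 1L),
      mut_offset = pos - starts + 1L, stringsAsFactors = FALSE))
  }
  out
}

#' Attach N- and C-terminal flanking regions to epitope windows
#'
#' Adds up to `flank_len` residues on each side of every window, truncated
#' silently at the protein termini. Flanks are taken from the wildtype
#' protein; the substitution itself always lies inside the window, never in
#' a flank.
#'
#' @param windows Data frame from [enumerate_epitope_windows()].
#' @param protein Wildtype protein sequence.
#' @param flank_len Maximum flank length per side (default 10 residues).
#' @return `windows` with `n_flank` and `c_flank` columns added.
#' @export
attach_flanks <- function(windows, protein, flank_len = 10L) {
  if (nrow(windows) == 0L) {
    windows$n_flank <- character(0); windows$c_flank <- character(0)
    return(windows)
  }
  L <- nchar(protein)
  ns <- pmax(1L, windows$window_start - flank_len)
  windows$n_flank <- substring(protein, ns, windows$window_start - 1L)
  we <- windows$window_start + windows$length - 1L
  ce <- pmin(L, we + flank_len)
  windows$c_flank <- substring(protein, we + 1L, ce)
  windows
}

#' Build the epitope space for a set of protein mutations
#'
#' Union over mutations and transcripts of [enumerate_epitope_windows()] +
#' [attach_flanks()], in deterministic (mutation, transcript, window_start,
#' length) order. Each row carries a stable `epitope_id`.
#'
#' @param mutations Data frame of protein mutations ([annotate_variants()]).
#' @param proteins Named character vector or list of wildtype protein
#'   sequences keyed by `transcript_id`.
#' @param lengths Epitope lengths (default 9).
#' @param flank_len Flank length per side (default 10).
#' @return Data frame with one row per epitope pair, including `variant_id`,
#'   `transcript_id`, `gene`, `protein_position`.
#' @export
build_epitope_space <- function(mutations, proteins, lengths = 9L,
                                flank_len = 10L) {
  cols <- c("variant_id", "transcript_id", "gene", "protein_position",
            "window_start", "length", "wildtype_peptide", "mutant_peptide",
            "mut_offset", "n_flank", "c_flank")
  if (nrow(mutations) == 0L) {
    out <- do.call(data.frame, c(setNames(rep(list(character(0)), length(cols)),
                                          cols), stringsAsFactors = FALSE))
    out$epitope_id <- character(0)
    return(out)
  }
  ord <- order(mutations$variant_id, mutations$transcript_id)
  mutations <- mutations[ord, , drop = FALSE]
  res <- lapply(seq_len(nrow(mutations)), function(i) {
    m <- mutations[i, ]
    prot <- proteins[[m$transcript_id]]
    if (is.null(prot)) {
      stop("no protein sequence for transcript ", m$transcript_id,
           call. = FALSE)
    }
    if (m$protein_position > nchar(prot)) {
      stop(sprintf("mutation position %d beyond protein length %d (%s)",
                   m$protein_position, nchar(prot), m$transcript_id),
           call. = FALSE)
    }
    if (substr(prot, m$protein_position, m$protein_position) != m$wildtype_aa) {
      stop(sprintf("wildtype residue mismatch at %s position %d",
                   m$transcript_id, m$protein_position), call. = FALSE)
    }
    w <- enumerate_epitope_windows(prot, m$protein_position, m$mutant_aa,
                                   lengths)
    w <- attach_flanks(w, prot, flank_len)
    if (nrow(w) == 0L) return(NULL)
    cbind(data.frame(variant_id = m$variant_id,
                     transcript_id = m$transcript_id, gene = m$gene,
                     protein_position = m$protein_position,
                     stringsAsFactors = FALSE)[rep(1L, nrow(w)), ],
          w)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) out <- build_epitope_space(mutations[0, ], proteins)
  rownames(out) <- NULL
  out <- out[order(out$variant_id, out$transcript_id, out$window_start,
                   out$length), , drop = FALSE]
  rownames(out) <- NULL
  out$epitope_id <- sprintf("%s|%s|%d|%d", out$variant_id, out$transcript_id,
                            out$window_start, out$length)
  out
}
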