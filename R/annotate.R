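# Protein-level annotation of SNVs against transcript models. Only missense
# consequences are emitted: the processing analysis works on single
# amino-acid substitutions; synonymous, nonsense and non-coding changes are
# dropped, and indels/fusions are expected to enter the clinical tables as
# pre-made annotations, not through this code path.

#' @keywords internal
empty_protein_mutations <- function() {
  data.frame(variant_id = character(), transcript_id = character(),
             gene = character(), protein_position = integer(),
             wildtype_aa = character(), mutant_aa = character(),
             stringsAsFactors = FALSE)
}

#' Annotate a single SNV as protein-level missense change(s)
#'
#' Projects a single-nucleotide variant onto every supplied transcript model
#' whose CDS covers it. For each transcript in which the substituted codon
#' translates to a different (non-stop) amino acid, one row is emitted;
#' transcript variants of the same gene are annotated independently.
#' Minus-strand transcripts are handled by complementing the genomic alleles
#' before codon substitution. Non-SNV alleles yield no rows.
#'
#' @param call A single-row data frame (or list) with `contig`, `position`,
#'   `ref_allele`, `alt_allele`, and optionally `variant_id`.
#' @param transcripts List of [transcript_model()] objects.
#' @return Data frame with columns `variant_id`, `transcript_id`, `gene`,
#'   `protein_position` (1-based, `ceiling(cds_pos / 3)`), `wildtype_aa`,
#'   `mutant_aa`.
#' @export
annotate_missense <- function(call, transcripts) {
  ref <- toupper(call$ref_allele); alt <- toupper(call$alt_allele)
  out <- empty_protein_mutations()
  if (nchar(ref) != 1L || nchar(alt) != 1L ||
      !ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T")) {
    return(out)
  }
  vid <- if (!is.null(call$variant_id)) call$variant_id else
    sprintf("%s:%d:%s>%s", call$contig, call$position, ref, alt)
  for (tm in transcripts) {
    if (!identical(tm$contig, call$contig)) next
    cpos <- cds_position(tm, call$position)
    if (is.na(cpos)) next
    ref_t <- if (tm$strand == "+") ref else chartr("ACGT", "TGCA", ref)
    alt_t <- if (tm$strand == "+") alt else chartr("ACGT", "TGCA", alt)
    if (substr(tm$cds, cpos, cpos) != ref_t) {
      stop(sprintf(
        "reference allele mismatch at %s:%d for transcript %s (CDS has %s, VCF says %s)",
        call$contig, call$position, tm$transcript_id,
        substr(tm$cds, cpos, cpos), ref_t), call. = FALSE)
    }
    codon_idx <- ceiling(cpos / 3)
    cstart <- (codon_idx - 1L) * 3L + 1L
    wt_codon <- substr(tm$cds, cstart, cstart + 2L)
    mut_codon <- wt_codon
    substr(mut_codon, cpos - cstart + 1L, cpos - cstart + 1L) <- alt_t
    wt_aa <- unname(Biostrings::GENETIC_CODE[wt_codon])
    mut_aa <- unname(Biostrings::GENETIC_CODE[mut_codon])
    if (wt_aa == mut_aa || wt_aa == "*" || mut_aa == "*") next
    out <- rbind(out, data.frame(
      variant_id = vid, transcript_id = tm$transcript_id, gene = tm$gene,
      protein_position = codon_idx, wildtype_aa = wt_aa, mutant_aa = mut_aa,
      stringsAsFactors = FALSE))
  }
  out
}

#' Annotate a table of variant calls
#'
#' Applies [annotate_missense()] to every row; one output row per
#' (variant, transcript) missense consequence. De-duplication across
#' transcripts is deliberately deferred to patient-level aggregation.
#'
#' @param calls Data frame of variant calls ([read_variant_calls()]).
#' @param transcripts List of [transcript_model()] objects.
#' @return Data frame of protein mutations.
#' @export
annotate_variants <- function(calls, transcripts) {
  if (nrow(calls) == 0L) return(empty_protein_mutations())
  res <- lapply(seq_len(nrow(calls)), function(i)
    annotate_missense(calls[i, , drop = FALSE], transcripts))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
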