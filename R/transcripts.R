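# Transcript models: CDS sequence plus an ordered genomic map, the minimal
# structure needed to project genomic SNVs onto codons. Coordinates are
# 1-based throughout (VCF convention genomically, 1-based CDS/protein
# positions internally).

#' Construct a transcript model
#'
#' A transcript model couples a coding sequence (in coding orientation,
#' length divisible by 3, no internal stop codon) with the genomic interval(s)
#' it occupies. For minus-strand transcripts the CDS is the reverse complement
#' of the genomic plus-strand sequence and the genomic map runs high-to-low.
#'
#' @param transcript_id Transcript identifier.
#' @param gene Gene symbol.
#' @param contig Chromosome/contig name.
#' @param strand `"+"` or `"-"`.
#' @param cds Coding sequence (A/C/G/T string, coding orientation).
#' @param genomic_start 1-based genomic start (lowest coordinate) of a
#'   single contiguous CDS block. Mutually exclusive with `blocks`.
#' @param blocks Optional data frame with columns `gstart`, `gend`
#'   (1-based inclusive, `gstart <= gend`) listing CDS blocks in coding order
#'   (ascending for `+`, descending for `-`).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene, contig, strand, cds,
                             genomic_start = NULL, blocks = NULL) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length must be divisible by 3 for ", transcript_id, call. = FALSE)
  }
  if (grepl("[^ACGT]", cds)) {
    stop("CDS contains non-ACGT characters for ", transcript_id, call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (is.null(blocks)) {
    if (is.null(genomic_start)) {
      stop("either 'genomic_start' or 'blocks' is required", call. = FALSE)
    }
    blocks <- data.frame(gstart = genomic_start,
                         gend = genomic_start + nchar(cds) - 1L)
  }
  blocks <- as.data.frame(blocks)
  if (sum(blocks$gend - blocks$gstart + 1L) != nchar(cds)) {
    stop("genomic blocks do not cover the CDS length for ", transcript_id,
         call. = FALSE)
  }
  aa <- translate_cds(cds)
  body <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("\\*", body)) {
    stop("CDS of ", transcript_id, " contains an internal stop codon",
         call. = FALSE)
  }
  structure(
    list(transcript_id = transcript_id, gene = gene, contig = contig,
         strand = strand, cds = cds, blocks = blocks),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s strand %s, CDS %d nt / %d aa\n",
              x$transcript_id, x$gene, x$contig,
              paste(sprintf("%d-%d", x$blocks$gstart, x$blocks$gend),
                    collapse = ","),
              x$strand, nchar(x$cds), nchar(x$cds) / 3L - 1L))
  invisible(x)
}

#' @keywords internal
revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Translate a coding sequence
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @return Amino-acid string (stop codons as `*`).
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3", call. = FALSE)
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

#' Protein sequence of a transcript model
#'
#' Translation of the CDS without the terminal stop.
#' @param tm A `transcript_model`.
#' @return Amino-acid string.
#' @export
protein_sequence <- function(tm) {
  aa <- translate_cds(tm$cds)
  sub("\\*$", "", aa)
}

#' Map a genomic position to a CDS position
#'
#' @param tm A `transcript_model`.
#' @param gpos 1-based genomic position.
#' @return 1-based CDS position, or `NA_integer_` if the position is outside
#'   the transcript's CDS blocks.
#' @export
cds_position <- function(tm, gpos) {
  cum <- 0L
  for (i in seq_len(nrow(tm$blocks))) {
    gs <- tm$blocks$gstart[i]; ge <- tm$blocks$gend[i]
    if (gpos >= gs && gpos <= ge) {
      return(if (tm$strand == "+") cum + (gpos - gs + 1L)
             else cum + (ge - gpos + 1L))
    }
    cum <- cum + (ge - gs + 1L)
  }
  NA_integer_
}

#' Map a CDS position to a genomic position
#'
#' Inverse of [cds_position()].
#' @inheritParams cds_position
#' @param cpos 1-based CDS position.
#' @return 1-based genomic position.
#' @export
genomic_position <- function(tm, cpos) {
  if (cpos < 1L || cpos > nchar(tm$cds)) stop("CDS position out of range", call. = FALSE)
  cum <- 0L
  for (i in seq_len(nrow(tm$blocks))) {
    gs <- tm$blocks$gstart[i]; ge <- tm$blocks$gend[i]
    w <- ge - gs + 1L
    if (cpos <= cum + w) {
      off <- cpos - cum
      return(if (tm$strand == "+") gs + off - 1L else ge - off + 1L)
    }
    cum <- cum + w
  }
  stop("CDS position out of range", call. = FALSE)
}

#' Write transcript models as FASTA plus a map table
#'
#' Emits `<prefix>.fa` (CDS sequences keyed by transcript id) and
#' `<prefix>.map.tsv` (transcript_id, gene, contig, strand and comma-separated
#' block starts/ends).
#'
#' @param transcripts List of `transcript_model` objects.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_transcriptome <- function(transcripts, prefix) {
  seqs <- Biostrings::DNAStringSet(vapply(transcripts, `[[`, "", "cds"))
  names(seqs) <- vapply(transcripts, `[[`, "", "transcript_id")
  fa <- paste0(prefix, ".fa")
  map <- paste0(prefix, ".map.tsv")
  Biostrings::writeXStringSet(seqs, fa)
  tab <- data.frame(
    transcript_id = names(seqs),
    gene = vapply(transcripts, `[[`, "", "gene"),
    contig = vapply(transcripts, `[[`, "", "contig"),
    strand = vapply(transcripts, `[[`, "", "strand"),
    block_starts = vapply(transcripts, function(t)
      paste(t$blocks$gstart, collapse = ","), ""),
    block_ends = vapply(transcripts, function(t)
      paste(t$blocks$gend, collapse = ","), ""))
  write.table(tab, map, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, map = map))
}

#' Read transcript models from FASTA plus a map table
#'
#' @param fasta Path to the CDS FASTA.
#' @param map Path to the tab-delimited map table written by
#'   [write_transcriptome()].
#' @return Named list of `transcript_model` objects.
#' @export
read_transcriptome <- function(fasta, map) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  tab <- read.delim(map, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene", "contig", "strand",
            "block_starts", "block_ends")
  if (!all(need %in% names(tab))) {
    stop("map table must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$transcript_id[i]
    if (!id %in% names(seqs)) {
      stop("transcript ", id, " in map table but absent from FASTA",
           call. = FALSE)
    }
    blocks <- data.frame(
      gstart = as.integer(strsplit(as.character(tab$block_starts[i]), ",")[[1]]),
      gend = as.integer(strsplit(as.character(tab$block_ends[i]), ",")[[1]]))
    transcript_model(id, tab$gene[i], tab$contig[i], tab$strand[i],
                     as.character(seqs[[id]]), blocks = blocks)
  })
  names(out) <- tab$transcript_id
  out
}
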