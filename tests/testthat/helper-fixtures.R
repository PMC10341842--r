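# Shared in-code fixtures: tiny transcripts, VCF writers, toy scoring
# models. Everything is built at test time; nothing binary on disk.

# A deterministic 29-codon transcript (ATG + 27 sense codons + TAA) on the
# plus strand at genomic position 101; translates to a 28-residue protein.
toy_cds <- function() {
  paste0("ATG",
         "GCTAAACTTGGGTTTCCCGATGAAATCGTGCATAGCACCTGGTACAAGCGG",
         "AATCAGTTGATGTTCGCCGACGAATTAAGA",
         "TAA")
}

toy_transcript <- function(id = "TX1", gene = "G1", strand = "+",
                           genomic_start = 101L) {
  transcript_model(id, gene, "chr1", strand, toy_cds(),
                   genomic_start = genomic_start)
}

# Write a small single-sample VCF with GT:DP:AD records.
# records: data.frame(contig, pos, ref, alt, dp, ad_ref, ad_alt)
write_test_vcf <- function(records, path = tempfile(fileext = ".vcf"),
                           format = "GT:DP:AD") {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
           "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  writeLines(c(hdr, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\t%s\t%s",
                            records$contig, records$pos, records$ref,
                            records$alt, format, records$sample)),
             path)
  path
}

# Random peptide of length n from the 20-letter alphabet.
random_peptide <- function(n) {
  paste(sample(procescape:::AA20, n, replace = TRUE), collapse = "")
}

# A single-offset cleavage model with hand-specified weights.
toy_cleavage_model <- function(weights0, bias = 0, offsets = 0L,
                               extra = NULL) {
  w <- matrix(0, nrow = length(offsets), ncol = 20,
              dimnames = list(as.character(offsets), procescape:::AA20))
  w[1, names(weights0)] <- weights0
  if (!is.null(extra)) {
    for (r in names(extra)) w[r, names(extra[[r]])] <- extra[[r]]
  }
  cleavage_model(w, offsets, bias = bias)
}
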