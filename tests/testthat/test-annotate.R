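# Protein-level missense annotation against transcript models.

test_that("a codon substitution is annotated as the expected missense change", {
  tm <- toy_transcript()  # codon 2 is GCT (Ala) at CDS 4-6, genomic 104-106
  call <- list(contig = "chr1", position = 105L, ref_allele = "C",
               alt_allele = "A", variant_id = "v1")
  res <- annotate_missense(call, list(tm))
  expect_equal(nrow(res), 1L)
  expect_equal(res$protein_position, 2L)
  expect_equal(res$wildtype_aa, "A")   # GCT -> GAT
  expect_equal(res$mutant_aa, "D")
})

test_that("synonymous and stop-involving changes yield no annotation", {
  tm <- toy_transcript()
  syn <- list(contig = "chr1", position = 106L, ref_allele = "T",
              alt_allele = "A")  # GCT -> GCA, still Ala
  expect_equal(nrow(annotate_missense(syn, list(tm))), 0L)
  # codon 3 AAA (CDS 7-9): AAA -> TAA nonsense, excluded from missense
  non <- list(contig = "chr1", position = 107L, ref_allele = "A",
              alt_allele = "T")
  expect_equal(nrow(annotate_missense(non, list(tm))), 0L)
})

test_that("a variant hitting two transcript variants is annotated on both", {
  tms <- list(toy_transcript("TX1"), toy_transcript("TX2"))
  call <- list(contig = "chr1", position = 105L, ref_allele = "C",
               alt_allele = "A")
  res <- annotate_missense(call, tms)
  expect_equal(nrow(res), 2L)
  expect_setequal(res$transcript_id, c("TX1", "TX2"))
  expect_equal(unique(res$wildtype_aa), "A")
})

test_that("minus-strand transcripts complement the genomic alleles", {
  tm <- toy_transcript(strand = "-", genomic_start = 201L)
  # CDS position 5 (the C of codon 2, GCT) sits at genomic gend - 5 + 1
  gend <- tm$blocks$gend
  gpos <- gend - 5L + 1L
  call <- list(contig = "chr1", position = gpos,
               ref_allele = "G",   # complement of CDS C
               alt_allele = "T")   # complement of CDS A -> GAT (Asp)
  res <- annotate_missense(call, list(tm))
  expect_equal(nrow(res), 1L)
  expect_equal(res$wildtype_aa, "A")
  expect_equal(res$mutant_aa, "D")
  expect_equal(res$protein_position, 2L)
})

test_that("a reference-allele mismatch raises a data error", {
  tm <- toy_transcript()
  call <- list(contig = "chr1", position = 105L, ref_allele = "T",
               alt_allele = "A")
  expect_error(annotate_missense(call, list(tm)), "mismatch")
})

test_that("annotation agrees with exhaustive translation on a toy transcript", {
  # Oracle: substitute every CDS position with every base, translate the
  # whole mutant CDS with Biostrings, and classify by comparing proteins.
  tm <- toy_transcript()
  cds <- tm$cds
  wt_prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                                no.init.codon = TRUE))
  for (p in seq_len(nchar(cds))) {
    ref <- substr(cds, p, p)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      mut_cds <- cds
      substr(mut_cds, p, p) <- alt
      mut_prot <- as.character(
        Biostrings::translate(Biostrings::DNAString(mut_cds),
                              no.init.codon = TRUE))
      diff_pos <- which(strsplit(wt_prot, "")[[1]] != strsplit(mut_prot, "")[[1]])
      is_missense <- length(diff_pos) == 1L &&
        substr(wt_prot, diff_pos, diff_pos) != "*" &&
        substr(mut_prot, diff_pos, diff_pos) != "*"
      call <- list(contig = "chr1", position = 101L + p - 1L,
                   ref_allele = ref, alt_allele = alt)
      res <- annotate_missense(call, list(tm))
      if (is_missense) {
        expect_equal(nrow(res), 1L)
        expect_equal(res$protein_position, diff_pos)
        expect_equal(res$wildtype_aa, substr(wt_prot, diff_pos, diff_pos))
        expect_equal(res$mutant_aa, substr(mut_prot, diff_pos, diff_pos))
      } else {
        expect_equal(nrow(res), 0L)
      }
    }
  }
})

test_that("annotated wildtype residues round-trip through the CDS", {
  transcripts <- generate_transcriptome(n_genes = 6, seed = 11)
  set.seed(11)
  for (rep in 1:40) {
    tm <- transcripts[[sample(length(transcripts), 1)]]
    cpos <- sample(nchar(tm$cds), 1)
    gpos <- genomic_position(tm, cpos)
    ref_cds <- substr(tm$cds, cpos, cpos)
    ref_g <- if (tm$strand == "+") ref_cds else chartr("ACGT", "TGCA", ref_cds)
    alt_g <- sample(setdiff(c("A", "C", "G", "T"), ref_g), 1)
    res <- annotate_missense(
      list(contig = tm$contig, position = gpos, ref_allele = ref_g,
           alt_allele = alt_g), transcripts)
    prot <- protein_sequence(tm)
    for (i in seq_len(nrow(res))) {
      expect_equal(substr(prot, res$protein_position[i],
                          res$protein_position[i]), res$wildtype_aa[i])
    }
  }
})

test_that("genomic/CDS coordinate mapping inverts on both strands", {
  for (strand in c("+", "-")) {
    tm <- toy_transcript(strand = strand)
    for (cpos in c(1L, 2L, 44L, nchar(tm$cds))) {
      expect_equal(cds_position(tm, genomic_position(tm, cpos)), cpos)
    }
  }
  expect_true(is.na(cds_position(toy_transcript(), 100L)))
})
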