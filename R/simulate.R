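# Synthetic cohort generator.
#
# Produces fully self-contained inputs for every pipeline stage: a random
# transcriptome (FASTA + map table), per-patient somatic variant calls
# (VCF) with planted processing ground truth, and a clinical/survival
# table whose hazard depends on the planted burden, stage and therapy.
#
# Ground truth is exact by construction, not probabilistic: the default
# cleavage model weights every residue by its class (strong vs weak
# C-terminal cleavage residues) identically at every offset, so a
# substitution that crosses classes flips the cleavage probability at the
# window's C-terminal site by >= 0.5, while a within-class substitution
# leaves every cleavage profile bit-identical (delta exactly 0).
# Processing-positive mutations are therefore planted as cross-class
# single-nucleotide missense changes and negatives as within-class ones.

#' Simulation configuration
#'
#' Defaults mirror the study cohort's published marginals (cohort size,
#' missense-count distribution concentrated at 0/1/2, 146/302 processing
#' fraction, TPS category fractions 32/41/106 of 179, roughly even
#' early/advanced stage split) without claiming to reproduce patient-level
#' data. Survival times are exponential with a log-linear hazard in the
#' planted covariates; censoring is administrative-uniform.
#'
#' @param seed Integer seed governing every stage (sub-seeds are derived
#'   deterministically).
#' @param n_patients Cohort size (default 179).
#' @param missense_dist Named probability vector over per-patient missense
#'   counts ("0", "1", ...).
#' @param processing_fraction Fraction of missense mutations planted as
#'   processing mutations (default 146/302).
#' @param tps_probs Probabilities of the negative/low/high TPS categories.
#' @param stage_advanced Probability of advanced stage (IIIB-IV).
#' @param therapy_rates Named rates: `surgery_early`, `surgery_advanced`,
#'   `chemotherapy`, `radiation`, `immunotherapy`.
#' @param age_gt60,male Probabilities of the respective categories.
#' @param baseline_hazard Baseline exponential hazard per month (default
#'   `log(2)/20`: reference median survival 20 months).
#' @param log_hr Named log hazard ratios: `burden_high`, `stage_advanced`,
#'   `chemotherapy`, `surgery`, `immunotherapy`, `load_high`.
#' @param load_cut Mutational-load count above which load is "high"
#'   (default 1; exposed because the study states the rule only for
#'   processing mutations).
#' @param censor_max Upper bound (months) of uniform administrative
#'   censoring; `NULL` disables censoring.
#' @param noise_variants Mean number of sub-threshold decoy variants per
#'   patient (fail the evidence filters; default 1).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_patients = 179L,
    missense_dist = c("0" = 0.25, "1" = 0.28, "2" = 0.27, "3" = 0.10,
                      "4" = 0.06, "5" = 0.04),
    processing_fraction = 146 / 302,
    tps_probs = c(negative = 32, low = 41, high = 106) / 179,
    stage_advanced = 0.508,
    therapy_rates = c(surgery_early = 0.85, surgery_advanced = 0.10,
                      chemotherapy = 0.60, radiation = 0.30,
                      immunotherapy = 0.07),
    age_gt60 = 125 / 179, male = 105 / 179,
    baseline_hazard = log(2) / 20,
    log_hr = c(burden_high = log(2), stage_advanced = log(2.2),
               chemotherapy = -log(1.5), surgery = -log(1.8),
               immunotherapy = -log(1.3), load_high = 0.2),
    load_cut = 1L,
    censor_max = 120,
    noise_variants = 1) {
  if (abs(sum(missense_dist) - 1) > 1e-8) {
    stop("missense_dist probabilities must sum to 1", call. = FALSE)
  }
  if (abs(sum(tps_probs) - 1) > 1e-8) {
    stop("tps_probs must sum to 1", call. = FALSE)
  }
  stopifnot_scalar_prob(processing_fraction, "processing_fraction")
  stopifnot_scalar_prob(stage_advanced, "stage_advanced")
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0", call. = FALSE)
  structure(as.list(environment()), class = "simulation_config")
}

# Codons for amino acids, inverse of the genetic code (internal).
#' @keywords internal
aa_cleavage_class <- function(aa) {
  ifelse(aa %in% CLEAVAGE_STRONG, "strong", "weak")
}

#' Generate a random translatable transcriptome
#'
#' Random coding sequences (ATG start, no internal stop, terminal stop)
#' laid out on one contig with intergenic gaps; a fraction of genes get a
#' second transcript variant sharing the same CDS region (isoforms), and a
#' fraction are placed on the minus strand.
#'
#' @param n_genes Number of genes (default 20).
#' @param cds_length_range Range of CDS lengths in nt; lengths are rounded
#'   down to multiples of 3 (default 300-600).
#' @param seed Integer seed.
#' @param isoform_frac Fraction of genes with a duplicate transcript
#'   variant (default 0.2).
#' @param minus_frac Fraction of genes on the minus strand (default 0.3).
#' @return Named list of [transcript_model()] objects.
#' @export
generate_transcriptome <- function(n_genes = 20L,
                                   cds_length_range = c(300L, 600L),
                                   seed = 1L, isoform_frac = 0.2,
                                   minus_frac = 0.3) {
  set.seed(derive_seed(seed, "transcriptome"))
  if (n_genes == 0L) return(list())
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  sense <- setdiff(sense, "ATG")  # internal ATG is fine, but keep start unique-ish
  stops <- c("TAA", "TGA", "TAG")
  out <- list()
  gpos <- 1000L
  for (g in seq_len(n_genes)) {
    cand <- seq(cds_length_range[1], cds_length_range[2])
    len <- cand[sample.int(length(cand), 1L)]
    len <- (len %/% 3L) * 3L
    n_mid <- len / 3L - 2L
    cds <- paste0("ATG", paste(sample(sense, n_mid, replace = TRUE),
                               collapse = ""), sample(stops, 1L))
    strand <- if (runif(1) < minus_frac) "-" else "+"
    gene <- sprintf("GENE%02d", g)
    tid <- sprintf("TX%02d.1", g)
    out[[tid]] <- transcript_model(tid, gene, "chr1", strand, cds,
                                   genomic_start = gpos)
    if (runif(1) < isoform_frac) {
      tid2 <- sprintf("TX%02d.2", g)
      out[[tid2]] <- transcript_model(tid2, gene, "chr1", strand, cds,
                                      genomic_start = gpos)
    }
    gpos <- gpos + nchar(cds) + 1000L
  }
  out
}

# Enumerate single-nucleotide missense substitutions of a transcript whose
# codon lies in the "safe" interior (full 9-mer window set exists), split
# by whether the amino-acid change crosses the cleavage class boundary.
#' @keywords internal
missense_catalog <- function(tm, margin = 12L) {
  n_codons <- nchar(tm$cds) / 3L - 1L  # exclude the stop codon
  lo <- margin; hi <- n_codons - margin
  if (hi < lo) return(NULL)
  gc <- Biostrings::GENETIC_CODE
  rows <- list()
  for (ci in lo:hi) {
    cstart <- (ci - 1L) * 3L + 1L
    codon <- substr(tm$cds, cstart, cstart + 2L)
    wt_aa <- unname(gc[codon])
    for (off in 1:3) {
      ref_base <- substr(codon, off, off)
      for (nb in setdiff(c("A", "C", "G", "T"), ref_base)) {
        mut_codon <- codon
        substr(mut_codon, off, off) <- nb
        mut_aa <- unname(gc[mut_codon])
        if (mut_aa == wt_aa || mut_aa == "*" || wt_aa == "*") next
        rows[[length(rows) + 1L]] <- data.frame(
          codon_idx = ci, cds_pos = cstart + off - 1L,
          ref_cds = ref_base, alt_cds = nb,
          wt_aa = wt_aa, mut_aa = mut_aa,
          cross = aa_cleavage_class(wt_aa) != aa_cleavage_class(mut_aa),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient clinical covariates, missense mutations with planted
#' processing ground truth embedded in the transcriptome (see the module
#' note on exact co-design with the default cleavage model), and
#' exponential survival times with log-hazard
#' `baseline + sum(covariate effects)`.
#'
#' @param cfg A [simulation_config()].
#' @param transcripts Optional transcriptome (list of [transcript_model()]);
#'   generated from the config seed when `NULL`.
#' @param clinical_only If `TRUE`, skip mutation generation (fast; burden
#'   covariates are then drawn from the missense/processing distributions
#'   directly).
#' @return Object of class `synthetic_cohort`: list with `clinical`,
#'   `variants` (per-call evidence rows incl. `patient_id`), `truth`
#'   (planted processing flags per variant), `transcripts`, `config`.
#' @export
generate_cohort <- function(cfg = simulation_config(), transcripts = NULL,
                            clinical_only = FALSE) {
  if (!inherits(cfg, "simulation_config")) {
    stop("cfg must be a simulation_config", call. = FALSE)
  }
  if (cfg$processing_fraction > 1) {
    stop("processing fraction cannot exceed 1", call. = FALSE)
  }
  if (is.null(transcripts) && !clinical_only) {
    transcripts <- generate_transcriptome(seed = cfg$seed)
  }
  set.seed(derive_seed(cfg$seed, "cohort"))
  n <- cfg$n_patients
  pid <- sprintf("P%04d", seq_len(n))
  counts <- as.integer(names(cfg$missense_dist))[
    sample.int(length(cfg$missense_dist), n, replace = TRUE,
               prob = cfg$missense_dist)]
  stage_adv <- runif(n) < cfg$stage_advanced
  stage <- ifelse(stage_adv, "IVA", "IIA")
  tr <- cfg$therapy_rates
  surgery <- runif(n) < ifelse(stage_adv, tr["surgery_advanced"],
                               tr["surgery_early"])
  chemo <- runif(n) < tr["chemotherapy"]
  radiation <- runif(n) < tr["radiation"]
  immuno <- runif(n) < tr["immunotherapy"]
  tps_cat <- sample(names(cfg$tps_probs), n, replace = TRUE,
                    prob = cfg$tps_probs)
  tps <- numeric(n)
  tps[tps_cat == "negative"] <- round(runif(sum(tps_cat == "negative"),
                                            0, 0.9), 1)
  tps[tps_cat == "low"] <- sample(1:49, sum(tps_cat == "low"), replace = TRUE)
  tps[tps_cat == "high"] <- sample(50:100, sum(tps_cat == "high"),
                                   replace = TRUE)
  age_group <- ifelse(runif(n) < cfg$age_gt60, ">60", "<=60")
  sex <- ifelse(runif(n) < cfg$male, "male", "female")

  # planted mutations
  variants <- NULL; truth <- NULL
  proc_count <- integer(n)
  mut_count <- integer(n)
  if (!clinical_only) {
    catalogs <- lapply(transcripts, missense_catalog)
    # one catalog per genomic locus: isoforms share coordinates, keep the
    # first transcript of each gene for planting (annotation will pick up
    # both isoforms by position)
    first_tx <- !duplicated(vapply(transcripts, `[[`, "", "gene"))
    plantable <- names(transcripts)[first_tx &
                                      !vapply(catalogs, is.null, logical(1))]
    vrows <- list(); trows <- list()
    for (i in seq_len(n)) {
      used <- integer(0)
      m <- counts[i]
      if (m == 0L && cfg$noise_variants == 0) next
      for (j in seq_len(m)) {
        planted <- runif(1) < cfg$processing_fraction
        for (attempt in 1:50) {
          tid <- sample(plantable, 1L)
          tm <- transcripts[[tid]]
          cat_t <- catalogs[[tid]]
          pool <- cat_t[cat_t$cross == planted, , drop = FALSE]
          if (nrow(pool) == 0L) next
          sub <- pool[sample.int(nrow(pool), 1L), ]
          gpos <- genomic_position(tm, sub$cds_pos)
          if (gpos %in% used) next
          used <- c(used, gpos)
          ref_g <- if (tm$strand == "+") sub$ref_cds else
            chartr("ACGT", "TGCA", sub$ref_cds)
          alt_g <- if (tm$strand == "+") sub$alt_cds else
            chartr("ACGT", "TGCA", sub$alt_cds)
          dp <- sample(600:2000, 1L)
          vaf <- runif(1, 0.30, 0.85)
          ad <- round(vaf * dp)
          vid <- sprintf("%s:%d:%s>%s", tm$contig, gpos, ref_g, alt_g)
          vrows[[length(vrows) + 1L]] <- data.frame(
            patient_id = pid[i], contig = tm$contig, position = gpos,
            ref_allele = ref_g, alt_allele = alt_g, total_depth = dp,
            alt_depth = ad, stringsAsFactors = FALSE)
          trows[[length(trows) + 1L]] <- data.frame(
            patient_id = pid[i], variant_id = vid, gene = tm$gene,
            planted_processing = planted, stringsAsFactors = FALSE)
          if (planted) proc_count[i] <- proc_count[i] + 1L
          mut_count[i] <- mut_count[i] + 1L
          break
        }
      }
      # decoy variants failing the evidence filters (intergenic, low depth
      # or low VAF)
      n_noise <- rbinom(1L, 3L, min(1, cfg$noise_variants / 3))
      for (k in seq_len(n_noise)) {
        gpos <- sample(1:900, 1L)  # upstream intergenic gap
        low_depth <- runif(1) < 0.5
        dp <- if (low_depth) sample(50:480, 1L) else sample(600:2000, 1L)
        vaf <- if (low_depth) runif(1, 0.3, 0.6) else runif(1, 0.04, 0.20)
        vrows[[length(vrows) + 1L]] <- data.frame(
          patient_id = pid[i], contig = "chr1", position = gpos,
          ref_allele = "A", alt_allele = "T", total_depth = dp,
          alt_depth = round(vaf * dp), stringsAsFactors = FALSE)
      }
    }
    variants <- if (length(vrows)) do.call(rbind, vrows) else
      cbind(patient_id = character(0), empty_variant_calls()[, -1])
    truth <- if (length(trows)) do.call(rbind, trows) else
      data.frame(patient_id = character(), variant_id = character(),
                 gene = character(), planted_processing = logical(),
                 stringsAsFactors = FALSE)
  } else {
    proc_count <- rbinom(n, counts, cfg$processing_fraction)
    mut_count <- counts
  }

  # survival
  lhr <- cfg$log_hr
  lp <- lhr["burden_high"] * (proc_count > 1) +
    lhr["stage_advanced"] * stage_adv +
    lhr["chemotherapy"] * chemo +
    lhr["surgery"] * surgery +
    lhr["immunotherapy"] * immuno +
    lhr["load_high"] * (mut_count > cfg$load_cut)
  t_event <- rexp(n, rate = cfg$baseline_hazard * exp(lp))
  if (is.null(cfg$censor_max)) {
    os_time <- t_event; os_event <- rep(TRUE, n)
  } else {
    c_time <- runif(n, 0, cfg$censor_max)
    os_time <- pmin(t_event, c_time)
    os_event <- t_event <= c_time
  }

  clinical <- data.frame(
    patient_id = pid, age_group = age_group, sex = sex, stage = stage,
    stage_group = ifelse(stage_adv, "advanced", "early"), tps = tps,
    surgery = surgery, chemotherapy = chemo, radiation = radiation,
    immunotherapy = immuno, os_time = os_time, os_event = os_event,
    missense_count_true = mut_count, processing_count_true = proc_count,
    stringsAsFactors = FALSE)
  structure(list(clinical = clinical, variants = variants, truth = truth,
                 transcripts = transcripts, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d planted mutations (%d processing)\n",
              nrow(x$clinical),
              if (is.null(x$truth)) 0L else nrow(x$truth),
              if (is.null(x$truth)) 0L else sum(x$truth$planted_processing)))
  invisible(x)
}

# Minimal single-sample VCFv4.2 emitter for generator output (reading
# always goes through vcfR).
#' @keywords internal
write_patient_vcf <- function(rows, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=procescape-simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR")
  rows <- rows[order(rows$contig, rows$position), , drop = FALSE]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP:AD\t0/1:%d:%d,%d",
                  rows$contig, rows$position, rows$ref_allele,
                  rows$alt_allele, rows$total_depth,
                  rows$total_depth - rows$alt_depth, rows$alt_depth)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Emits the exact formats the pipeline consumes: `clinical.tsv`,
#' `truth.tsv`, `transcriptome.fa` + `transcriptome.map.tsv`, and one
#' `vcf/<patient>.vcf` per patient with at least one call. Output is
#' deterministic given the cohort object (same seed, same bytes).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(cohort$clinical, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth)) {
    write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cohort$transcripts)) {
    write_transcriptome(cohort$transcripts, file.path(dir, "transcriptome"))
  }
  if (!is.null(cohort$variants) && nrow(cohort$variants)) {
    vdir <- file.path(dir, "vcf")
    if (!dir.exists(vdir)) dir.create(vdir)
    for (p in unique(cohort$variants$patient_id)) {
      write_patient_vcf(
        cohort$variants[cohort$variants$patient_id == p, , drop = FALSE],
        file.path(vdir, paste0(p, ".vcf")))
    }
  }
  invisible(dir)
}
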