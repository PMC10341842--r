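# End-to-end orchestration: annotate -> epitopes -> processing ->
# presentation -> aggregate -> statistics/survival, with a validated
# config, persisted intermediate tables and a run manifest.

#' Pipeline configuration
#'
#' @param input_dir Directory in the [write_cohort()] layout
#'   (`clinical.tsv`, `transcriptome.fa`/`.map.tsv`, `vcf/<patient>.vcf`).
#' @param out_dir Output directory for persisted tables.
#' @param filters A [filter_config()].
#' @param lengths Epitope lengths (default 9).
#' @param flank_len Flank length per side (default 10).
#' @param backend Cleavage backend: `"internal"` (matrix model) only;
#'   externally parsed profiles enter via [parse_external_cleavage()].
#' @param cleavage_model A [cleavage_model()] (default
#'   [default_cleavage_model()]).
#' @param threshold Cleavage-difference threshold (default 0.50).
#' @param sites Site policy, `"cterm"` or `"all"`.
#' @param rule Difference rule, `"absolute"` or `"relative"`.
#' @param binder_threshold Binder cut-off in nM (default 500).
#' @param panel Allele panel (default [default_allele_panel()]).
#' @param survival_covariates Covariates of the cohort-wide Cox model.
#' @param seed Seed recorded in the manifest.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir = NULL,
                            filters = filter_config(),
                            lengths = 9L, flank_len = 10L,
                            backend = "internal",
                            cleavage_model = default_cleavage_model(),
                            threshold = 0.50, sites = "cterm",
                            rule = "absolute", binder_threshold = 500,
                            panel = default_allele_panel(),
                            survival_covariates = c("burden_two",
                                                    "stage_group",
                                                    "chemotherapy",
                                                    "surgery",
                                                    "immunotherapy"),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks paths, ranges and enumerations; never throws — failures are
#' listed in the returned report.
#'
#' @param cfg A [pipeline_config()].
#' @return Data frame with `field` and `message`, zero rows when valid.
#' @export
validate_config <- function(cfg) {
  fail <- list()
  add <- function(field, message) {
    fail[[length(fail) + 1L]] <<- data.frame(field = field,
                                             message = message,
                                             stringsAsFactors = FALSE)
  }
  if (!is.null(cfg$input_dir)) {
    if (!dir.exists(cfg$input_dir)) {
      add("input_dir", "directory does not exist")
    } else {
      for (f in c("clinical.tsv", "transcriptome.fa",
                  "transcriptome.map.tsv")) {
        if (!file.exists(file.path(cfg$input_dir, f))) {
          add("input_dir", paste("missing file:", f))
        }
      }
    }
  } else {
    add("input_dir", "not set")
  }
  if (!inherits(cfg$filters, "filter_config")) add("filters", "not a filter_config")
  if (!all(cfg$lengths %in% 8:11)) add("lengths", "epitope lengths must be within 8-11")
  if (cfg$flank_len < 0) add("flank_len", "flank length must be >= 0")
  if (!cfg$backend %in% "internal") add("backend", paste("unknown backend:", cfg$backend))
  if (!is.numeric(cfg$threshold) || cfg$threshold < 0 || cfg$threshold > 1) {
    add("threshold", "cleavage-difference threshold must lie in [0, 1]")
  }
  if (!cfg$sites %in% c("cterm", "all")) add("sites", "unknown site policy")
  if (!cfg$rule %in% c("absolute", "relative")) add("rule", "unknown difference rule")
  if (!is.numeric(cfg$binder_threshold) || cfg$binder_threshold < 0) {
    add("binder_threshold", "must be a non-negative IC50 in nM")
  }
  if (length(fail)) do.call(rbind, fail) else
    data.frame(field = character(), message = character(),
               stringsAsFactors = FALSE)
}

#' In-memory cohort analysis
#'
#' The computational core of [run_pipeline()]: filters calls, annotates
#' missense changes, builds the epitope space, calls processing mutations,
#' classifies altered-epitope fates, aggregates patient burden and runs
#' the burden/survival statistics.
#'
#' @param clinical Clinical table (one row per patient).
#' @param variants Variant evidence rows with `patient_id` (as in
#'   `synthetic_cohort$variants`, or read from per-patient VCFs).
#' @param transcripts List of [transcript_model()] objects.
#' @param cfg A [pipeline_config()] (paths ignored).
#' @return Object of class `escape_report`.
#' @export
analyze_cohort <- function(clinical, variants, transcripts,
                           cfg = pipeline_config()) {
  variants$vaf <- variants$alt_depth / variants$total_depth
  if (is.null(variants$variant_id)) {
    variants$variant_id <- sprintf("%s:%d:%s>%s", variants$contig,
                                   variants$position, variants$ref_allele,
                                   variants$alt_allele)
  }
  kept <- filter_variants(variants, cfg$filters)
  selected <- select_for_processing(kept, cfg$filters)
  # patient-scoped mutation ids: the same genomic variant in two patients
  # is two mutations
  selected$variant_id <- paste(selected$patient_id, selected$variant_id,
                               sep = "::")
  mutations <- annotate_variants(selected, transcripts)
  mutations$patient_id <- sub("::.*$", "", mutations$variant_id)
  proteins <- lapply(transcripts, protein_sequence)
  epitopes <- build_epitope_space(mutations, proteins,
                                  lengths = cfg$lengths,
                                  flank_len = cfg$flank_len)
  processing <- call_processing(epitopes, cfg$cleavage_model,
                                threshold = cfg$threshold,
                                sites = cfg$sites, rule = cfg$rule)
  fates <- classify_fates(processing, cfg$panel, cfg$binder_threshold)
  records <- aggregate_patients(
    clinical, mutations[, c("patient_id", "variant_id")],
    processing$mutations)
  records$burden_two <- factor(records$burden_two,
                               levels = c("low_none", "high"))
  if ("stage_group" %in% names(records)) {
    records$stage_group <- factor(records$stage_group,
                                  levels = c("early", "advanced"))
  }
  burden <- burden_density(records$processing_count)
  km <- lapply(split(records, records$burden_two), function(d)
    if (nrow(d)) km_estimate(d$os_time, d$os_event) else NULL)
  lr <- if (nlevels(droplevels(records$burden_two)) >= 2L) {
    logrank_test(records$burden_two, records$os_time, records$os_event)
  } else NULL
  covs <- intersect(cfg$survival_covariates, names(records))
  covs <- covs[vapply(covs, function(v)
    length(unique(records[[v]][!is.na(records[[v]])])) > 1L, logical(1))]
  cox_all <- tryCatch(coxph_fit(records, covs), error = function(e) NULL)
  adv <- !is.na(records$stage_group) & records$stage_group == "advanced"
  covs_adv <- setdiff(covs, c("surgery", "stage_group"))
  cox_advanced <- tryCatch(
    coxph_fit(records, covs_adv, subset = adv), error = function(e) NULL)
  # FDR over the per-covariate p-values within each model
  for (fit in c("cox_all", "cox_advanced")) {
    f <- get(fit)
    if (!is.null(f) && nrow(f$coefficients)) {
      f$coefficients$q <- fdr_adjust(f$coefficients$p)
      assign(fit, f)
    }
  }
  summary_vars <- intersect(c("age_group", "sex", "stage_group", "tps_group",
                              "burden_group"), names(records))
  structure(list(
    records = records, mutations = mutations,
    processing = processing$mutations, epitopes = processing$epitopes,
    fates = fates, fate_partition = fate_partition(fates),
    burden = burden, km = km, logrank = lr,
    cox_all = cox_all, cox_advanced = cox_advanced,
    summary = cohort_summary(records, summary_vars), config = cfg),
    class = "escape_report")
}

#' @export
print.escape_report <- function(x, ...) {
  cat("<escape_report>\n")
  cat(sprintf("  patients: %d; missense mutations: %d; processing: %d (%.1f%%)\n",
              nrow(x$records), nrow(x$processing),
              sum(x$processing$is_processing),
              if (nrow(x$processing)) 100 * mean(x$processing$is_processing)
              else 0))
  fp <- x$fate_partition
  cat(sprintf("  altered epitopes: %d (lost binding %d, bound/not immunogenic %d, bound/immunogenic %d)\n",
              sum(fp), fp["lost_binding"], fp["bound_not_immunogenic"],
              fp["bound_immunogenic"]))
  if (!is.null(x$logrank)) {
    cat(sprintf("  burden (high vs low/none) logrank p = %.4g\n",
                x$logrank$p_value))
  }
  if (!is.null(x$cox_all)) {
    cat(sprintf("  cohort Cox model: score-logrank p = %.4g\n",
                x$cox_all$tests["score_logrank"]))
  }
  invisible(x)
}

#' Read cohort inputs from a directory
#'
#' @param input_dir Directory in the [write_cohort()] layout.
#' @return List with `clinical`, `variants`, `transcripts`.
#' @export
read_cohort_inputs <- function(input_dir) {
  clinical <- read.delim(file.path(input_dir, "clinical.tsv"),
                         stringsAsFactors = FALSE)
  transcripts <- read_transcriptome(
    file.path(input_dir, "transcriptome.fa"),
    file.path(input_dir, "transcriptome.map.tsv"))
  vcfs <- sort(list.files(file.path(input_dir, "vcf"), pattern = "\\.vcf$",
                          full.names = TRUE))
  variants <- do.call(rbind, lapply(vcfs, function(f) {
    calls <- read_variant_calls(f)
    if (nrow(calls)) {
      cbind(patient_id = sub("\\.vcf$", "", basename(f)), calls)
    } else NULL
  }))
  if (is.null(variants)) {
    variants <- cbind(patient_id = character(0), empty_variant_calls())
  }
  list(clinical = clinical, variants = variants, transcripts = transcripts)
}

#' Run the full pipeline from a validated configuration
#'
#' Validates the configuration (aborting before any stage on failure),
#' executes the stages in order, persists every intermediate table as
#' tab-delimited text under `cfg$out_dir`, and writes a run manifest with
#' the configuration hash and seed. Re-running with an identical
#' configuration reproduces byte-identical tables.
#'
#' @param cfg A [pipeline_config()] with `input_dir` and `out_dir` set.
#' @return An `escape_report` (invisibly also persisted).
#' @export
run_pipeline <- function(cfg) {
  report <- validate_config(cfg)
  if (nrow(report)) {
    stop("invalid pipeline configuration:\n",
         paste(sprintf("  %s: %s", report$field, report$message),
               collapse = "\n"), call. = FALSE)
  }
  inputs <- read_cohort_inputs(cfg$input_dir)
  res <- analyze_cohort(inputs$clinical, inputs$variants,
                        inputs$transcripts, cfg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(d, name) write.table(
      d, file.path(cfg$out_dir, name), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(res$records, "records.tsv")
    wt(res$mutations, "mutations.tsv")
    wt(res$processing, "processing.tsv")
    wt(res$epitopes, "epitopes.tsv")
    wt(res$fates, "fates.tsv")
    wt(res$summary, "summary.tsv")
    for (fit in c("cox_all", "cox_advanced")) {
      if (!is.null(res[[fit]])) wt(res[[fit]]$coefficients,
                                   paste0(fit, ".tsv"))
    }
    for (g in names(res$km)) {
      k <- res$km[[g]]
      if (!is.null(k)) wt(data.frame(time = k$time, surv = k$surv,
                                     n_risk = k$n_risk, n_event = k$n_event),
                          sprintf("km_%s.tsv", g))
    }
    # manifest: config hash (md5 of the deparsed config), seed, versions
    tmp <- file.path(cfg$out_dir, ".config_dump")
    writeLines(deparse(cfg[setdiff(names(cfg),
                                   c("panel", "cleavage_model", "out_dir"))]),
               tmp)
    hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
    writeLines(c(
      sprintf("config_md5\t%s", hash),
      sprintf("seed\t%d", cfg$seed),
      sprintf("package_version\t%s",
              as.character(utils::packageVersion("procescape"))),
      sprintf("r_version\t%s", R.version.string)),
      file.path(cfg$out_dir, "manifest.tsv"))
  }
  invisible(res)
}
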