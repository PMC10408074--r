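# End-to-end pipeline orchestration: stages run in dependency order
# (simulate -> drivers -> cooccupancy -> signatures -> germline ->
# survival), each emitting TSV outputs under one output directory,
# with a checksum manifest and a per-stage log recording counts in/out
# for every filter.

#' Default run configuration
#'
#' Thresholds mirror the documented defaults of every stage:
#' amplification frequency >= 0.05, DE FDR < 0.1, correlation
#' FDR < 0.05, promoter flank 5 kb, LD r-squared >= 0.5, differential
#' peaks at p < 1e-4 and fold change > 4, 1000 permutations.
#'
#' @param seed master seed.
#' @param ... overrides for thresholds or [sim_config()] fields (under
#'   `sim`).
#' @return nested list of class `RunConfig`.
#' @export
default_run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    thresholds = list(freq_min = 0.05, fdr_corr = 0.05, fdr_de = 0.1,
                      promoter_flank = 5000L, r2_min = 0.5,
                      p_max = 1e-4, fc_min = 4, n_perm = 1000L),
    sim = list())
  over <- list(...)
  for (nm in names(over)) {
    if (nm %in% names(cfg$thresholds)) cfg$thresholds[[nm]] <- over[[nm]]
    else if (nm == "sim") cfg$sim <- over[[nm]]
    else stop("unknown config field: ", nm, call. = FALSE)
  }
  validate_run_config(cfg)
  structure(cfg, class = c("RunConfig", "list"))
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML path with optional top-level keys `seed`,
#'   `thresholds`, `sim`.
#' @return a validated `RunConfig`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = raw$seed %||% 1L)
  for (nm in names(raw$thresholds %||% list())) {
    if (!nm %in% names(cfg$thresholds))
      stop("unknown threshold in config: ", nm, call. = FALSE)
    cfg$thresholds[[nm]] <- raw$thresholds[[nm]]
  }
  cfg$sim <- raw$sim %||% list()
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  th <- cfg$thresholds
  ok <- th$freq_min >= 0 && th$freq_min <= 1 &&
    th$fdr_corr > 0 && th$fdr_corr <= 1 &&
    th$fdr_de > 0 && th$fdr_de <= 1 &&
    th$promoter_flank > 0 && th$r2_min >= 0 && th$r2_min <= 1 &&
    th$p_max > 0 && th$p_max <= 1 && th$fc_min >= 0 && th$n_perm >= 1
  if (!ok) stop("config error: threshold out of documented range",
                call. = FALSE)
  invisible(TRUE)
}

.pipeline_stages <- c("simulate", "drivers", "cooccupancy",
                      "signatures", "germline", "survival")

#' Run the analysis pipeline on a synthetic cohort
#'
#' Executes the requested stages in dependency order against data
#' generated by the synthetic-cohort module, writing per-stage TSV/BED
#' outputs, a human-readable `run.log`, and a `manifest.tsv` listing
#' every output file with its MD5 checksum.  Rerunning with an
#' identical configuration reproduces byte-identical outputs.
#'
#' @param config a `RunConfig` (see [default_run_config()]) or a YAML
#'   path.
#' @param outdir output directory (created if absent).
#' @param stages subset of
#'   `c("simulate","drivers","cooccupancy","signatures","germline","survival")`;
#'   analysis stages require `"simulate"` outputs and regenerate them
#'   in-memory from the same seed if the stage is not requested.
#' @return invisible manifest `data.frame` (file, md5).
#' @export
run_pipeline <- function(config, outdir, stages = .pipeline_stages) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  logfile <- file.path(outdir, "run.log")
  cat(sprintf("pipeline seed=%d stages=%s\n", config$seed,
              paste(stages, collapse = ",")), file = logfile)
  note <- function(...) cat(sprintf(...), file = logfile, append = TRUE)

  scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  cohort <- gen_cohort(scfg)
  ps <- gen_peaksets(scfg)
  kd <- gen_knockdown_experiment(scfg)

  emit <- function(obj, name) {
    path <- file.path(outdir, name)
    if (inherits(obj, "PeakSet")) write_bed(obj, path)
    else if (is.matrix(obj))
      write_tsv(data.frame(gene = rownames(obj), obj,
                           check.names = FALSE), path)
    else write_tsv(obj, path)
    path
  }

  if ("simulate" %in% stages) {
    emit(cohort$cn, "sim_copy_number.tsv")
    emit(cohort$expr, "sim_expression.tsv")
    emit(data.frame(gene = names(cohort$ess),
                    essentiality = unname(cohort$ess)),
         "sim_essentiality.tsv")
    emit(cohort$clinical, "sim_clinical.tsv")
    emit(ps$peaks_a, "sim_peaks_a.bed")
    emit(ps$peaks_b, "sim_peaks_b.bed")
    emit(kd$de_a, "sim_de_a.tsv")
    emit(kd$de_b, "sim_de_b.tsv")
    emit(kd$annotation, "sim_gene_annotation.tsv")
    emit(data.frame(key = c("drivers", "top_driver", "joint_targets"),
                    value = c(paste(cohort$truth$drivers, collapse = ","),
                              cohort$truth$top_driver,
                              paste(kd$truth$joint_targets, collapse = ","))),
         "sim_truth.tsv")
    note("simulate: %d genes x %d samples; peaks %d/%d; kd genes %d\n",
         nrow(cohort$cn), ncol(cohort$cn), nrow(ps$peaks_a),
         nrow(ps$peaks_b), nrow(kd$de_a))
  }

  if ("drivers" %in% stages) {
    freq <- amplification_frequency(cohort$cn)
    corr <- cn_expression_correlation(cohort$cn, cohort$expr)
    cand <- select_candidates(freq, corr, freq_min = th$freq_min,
                              fdr_max = th$fdr_corr)
    ranked <- rank_by_essentiality(cand, cohort$ess)
    emit(ranked, "driver_candidates.tsv")
    note("drivers: %d tested -> %d pass freq>=%.2f & r>0 & FDR<%.2f\n",
         nrow(corr), nrow(cand), th$freq_min, th$fdr_corr)
  }

  cooc <- NULL
  if (any(c("cooccupancy", "germline") %in% stages)) {
    cooc <- classify_cooccupancy(ps$peaks_a, ps$peaks_b)
    if ("cooccupancy" %in% stages) {
      emit(data.frame(
        set = c("A", "B"), n = c(cooc$n_a, cooc$n_b),
        n_common = c(cooc$n_common_a, cooc$n_common_b),
        fraction_common = c(cooc$fraction_a, cooc$fraction_b)),
        "cooccupancy_summary.tsv")
      emit(cooccupancy_regions(cooc), "cooccupancy_regions.tsv")
      note("cooccupancy: %d/%d B regions common (%.3f)\n",
           cooc$n_common_b, cooc$n_b, cooc$fraction_b)
    }
  }

  if ("signatures" %in% stages) {
    sel_a <- select_de_genes(kd$de_a, fdr_max = th$fdr_de)
    sel_b <- select_de_genes(kd$de_b, fdr_max = th$fdr_de)
    com <- common_de_genes(sel_a, sel_b)
    targets <- joint_direct_targets(com$common, kd$peaks_a, kd$peaks_b,
                                    kd$annotation,
                                    flank = th$promoter_flank)
    sig <- joint_target_signature(targets, kd$de_a, kd$de_b)
    emit(data.frame(gene = sig$genes, weight = sig$weights),
         "joint_target_signature.tsv")
    note("signatures: DE %d/%d selected (FDR<%.2f); common %d; joint targets %d\n",
         nrow(sel_a), nrow(sel_b), th$fdr_de, length(com$common),
         length(targets))
  }

  if ("germline" %in% stages) {
    regions <- cooccupancy_regions(cooc)
    germ <- gen_germline(scfg, regions = regions)
    enr <- snp_peak_enrichment(germ$snps, regions, germ$background,
                               n_perm = th$n_perm,
                               seed = substream_seed(config$seed, "perm"))
    emit(enr, "snp_enrichment.tsv")
    prox <- expand_proxies(germ$tags, germ$block_snps,
                           genotypes = germ$genotypes,
                           r2_min = th$r2_min)
    common_ps <- {
      cm <- regions[regions$category == "common", , drop = FALSE]
      peak_set(cm$chrom, cm$start, cm$end)
    }
    prox$in_common <- assign_points_to_peaks(prox$chrom, prox$pos, common_ps)
    prox$category <- ifelse(prox$in_common, "common", "outside")
    report <- map_eqtl_genes(prox, germ$eqtl)
    emit(prox, "ld_proxies.tsv")
    emit(report, "risk_locus_report.tsv")
    ai <- allelic_imbalance(germ$allele_counts$count_risk,
                            germ$allele_counts$count_other)
    mm <- germ$motif
    pd <- pwm_allele_delta(mm$pwm, mm$sequence, mm$snp_pos, mm$ref,
                           mm$alt, mm$risk_allele)
    emit(data.frame(site = germ$allele_counts$site,
                    ratio_risk = ai$ratio_risk, p_value = ai$p_value,
                    pwm_delta = pd$delta,
                    preferred_allele = pd$preferred_allele),
         "allele_specific.tsv")
    note("germline: %d proxies (r2>=%.2f) from %d tags; enrichment folds %s\n",
         nrow(prox), th$r2_min, nrow(germ$tags),
         paste(sprintf("%s=%.2f", enr$category, enr$fold), collapse = " "))
  }

  if ("survival" %in% stages) {
    top <- cohort$truth$top_driver
    expr_top <- cohort$expr[top, cohort$clinical$sample]
    lab <- stratify_samples("median_split", expression = expr_top)
    lr <- logrank_test(lab, cohort$clinical$time, cohort$clinical$event)
    cx <- cox_hr(lab == "high", cohort$clinical$time,
                 cohort$clinical$event)
    gl <- stratify_samples("gleason_subgroup",
                           gleason = setNames(cohort$clinical$gleason,
                                              cohort$clinical$sample))
    lr_gl <- logrank_test(gl, cohort$clinical$time, cohort$clinical$event)
    emit(data.frame(
      analysis = c("median_split_top_driver", "gleason_subgroup"),
      chi2 = c(lr$chi2, lr_gl$chi2), df = c(lr$df, lr_gl$df),
      p_logrank = c(lr$p_value, lr_gl$p_value),
      hr = c(cx$hr, NA), hr_lo = c(cx$ci95[1], NA),
      hr_hi = c(cx$ci95[2], NA)), "survival_results.tsv")
    note("survival: median-split HR=%.2f [%.2f, %.2f], logrank p=%.3g\n",
         cx$hr, cx$ci95[1], cx$ci95[2], lr$p_value)
  }

  files <- setdiff(list.files(outdir, full.names = TRUE),
                   file.path(outdir, "manifest.tsv"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(manifest)
}
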