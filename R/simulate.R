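# Synthetic-cohort generators.  Every input the analysis modules
# consume can be generated here with planted ground truth, so the whole
# pipeline is testable without external downloads.  All generators are
# pure functions of (config, seed): the master seed fans out to named
# substreams so adding one generator never perturbs another.

#' Simulation configuration with the package's stated-world defaults
#'
#' Defaults encode the regimes the analyses are validated in: a
#' 200-sample cohort with 20 planted amplified drivers
#' (copy-number/expression r = 0.4, 10\% amplification frequency),
#' paper-scale peak sets (7321 regions for factor B, planted
#' co-occupancy fraction 0.655), 50 planted joint direct targets among
#' 5000 genes, LD blocks targeting r-squared ~ 0.8, 3x risk-SNP
#' enrichment in common binding regions, a 0.7 allelic ratio at depth
#' 500, and proportional-hazards survival with true HR 2 and 30\%
#' censoring.
#'
#' @param seed mandatory integer master seed.
#' @param ... overrides for any default field.
#' @return named list of class `SimConfig`.
#' @export
sim_config <- function(seed, ...) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- list(
    seed = as.integer(seed),
    # cohort
    n_samples = 200L, n_genes = 2000L, n_driver_genes = 20L,
    amp_frequency = 0.10, cn_expr_effect = 0.4,
    expr_noise_sd = 1.0,
    # toy genome (chromosome name -> length)
    genome = c(chrS1 = 10e6, chrS2 = 10e6, chrS3 = 10e6),
    # peak sets
    n_peaks_a = 10000L, n_peaks_b = 7321L,
    cooccupancy_fraction = 0.655,
    peak_width_meanlog = log(300), peak_width_sdlog = 0.3,
    # knockdown experiment
    n_kd_genes = 5000L, n_joint_targets = 50L,
    n_de_only = 100L, n_bound_only = 100L, n_single_bound = 200L,
    de_effect = 1.5, promoter_flank = 5000L,
    # germline
    n_individuals = 200L, n_tag_snps = 10L, ld_block_size = 10L,
    ld_noise = 0.027,  # per-haplotype flip prob; ~r2 0.8 within blocks
    n_background_snps = 4000L, n_risk_snps = 200L,
    enrichment_factor = 3,
    allelic_ratio = 0.7, read_depth = 500L,
    # survival
    true_hr = 2.0, censoring_fraction = 0.30,
    baseline_hazard = 0.02)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  for (f in c("amp_frequency", "cooccupancy_fraction",
              "censoring_fraction", "allelic_ratio"))
    stopifnot(cfg[[f]] >= 0, cfg[[f]] <= 1)
  stopifnot(cfg$n_driver_genes <= cfg$n_genes,
            cfg$n_joint_targets <= cfg$n_kd_genes)
  if (cfg$n_driver_genes > 0 && cfg$amp_frequency == 0)
    stop("infeasible: drivers requested with zero amplification frequency",
         call. = FALSE)
  structure(cfg, class = c("SimConfig", "list"))
}

#' Generate a linked copy-number / expression / essentiality / clinical
#' cohort
#'
#' Driver genes receive GISTIC-style codes with the configured
#' amplification frequency (gain and amplification in equal shares) and
#' expression `baseline + beta * code + noise`, with `beta` solved so
#' the population copy-number/expression Pearson correlation equals
#' `cn_expr_effect`.  Non-driver genes have the same marginal code
#' distribution but code-independent expression.  The designated top
#' driver (the first planted driver) has a strongly negative
#' essentiality score.  Survival times are exponential with the hazard
#' multiplied by the true HR for samples above the top driver's
#' expression median, with independent exponential censoring tuned to
#' the target censoring fraction.
#'
#' @param cfg a [sim_config()].
#' @return list with `cn`, `expr` (genes x samples matrices), `ess`
#'   (named vector), `clinical` (`data.frame`), and `truth`.
#' @export
gen_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_stream_seed(cfg$seed, "cohort", {
    ng <- cfg$n_genes; ns <- cfg$n_samples
    genes <- sprintf("GENE%04d", seq_len(ng))
    samples <- sprintf("S%03d", seq_len(ns))
    drivers <- genes[seq_len(cfg$n_driver_genes)]
    f <- cfg$amp_frequency
    # codes: 0 diploid, +1/+2 with prob f/2 each (pooled gain/amp)
    cn <- matrix(sample(c(0L, 1L, 2L), ng * ns, replace = TRUE,
                        prob = c(1 - f, f / 2, f / 2)),
                 nrow = ng, dimnames = list(genes, samples))
    # beta achieving target r given code variance and noise sd
    v <- (f / 2 + 4 * f / 2) - (1.5 * f)^2
    r <- cfg$cn_expr_effect
    beta <- if (r == 0 || v == 0) 0 else
      cfg$expr_noise_sd / sqrt(v) * r / sqrt(1 - r^2)
    expr <- matrix(rnorm(ng * ns, sd = cfg$expr_noise_sd), nrow = ng,
                   dimnames = list(genes, samples)) + 5
    expr[drivers, ] <- expr[drivers, ] + beta * cn[drivers, ]
    ess <- setNames(rnorm(ng), genes)
    top <- drivers[1L]
    if (length(top)) ess[top] <- rnorm(1, mean = -5, sd = 0.25)
    # survival driven by top-driver expression median split
    x <- as.numeric(expr[top, ] > median(expr[top, ]))
    h <- cfg$baseline_hazard * cfg$true_hr^x
    t_event <- rexp(ns, rate = h)
    cf <- cfg$censoring_fraction
    h_marg <- cfg$baseline_hazard * (1 + cfg$true_hr) / 2
    t_cens <- if (cf > 0) rexp(ns, rate = h_marg * cf / (1 - cf))
              else rep(Inf, ns)
    clinical <- data.frame(
      sample = samples,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      gleason = sample(c(6L, 7L, 8L, 9L), ns, replace = TRUE,
                       prob = c(0.3, 0.4, 0.2, 0.1)),
      genotype = sample(c("TT", "TC", "CC"), ns, replace = TRUE,
                        prob = c(0.16, 0.48, 0.36)),
      stringsAsFactors = FALSE)
    list(cn = cn, expr = expr, ess = ess, clinical = clinical,
         truth = list(drivers = drivers, top_driver = top, beta = beta,
                      target_r = r, true_hr = cfg$true_hr,
                      exposure = setNames(x, samples)))
  })
}

# slot-based non-overlapping placement on the toy genome: each peak
# lives in its own 2 kb slot, so emitted sets are merged by construction
.genome_slots <- function(genome, slot = 2000) {
  chrom <- rep(names(genome), floor(genome / slot))
  offs <- unlist(lapply(genome, function(L) (seq_len(floor(L / slot)) - 1) * slot),
                 use.names = FALSE)
  data.frame(chrom = chrom, slot_start = offs, stringsAsFactors = FALSE)
}

#' Generate two peak sets with a planted co-occupancy fraction
#'
#' Factor A peaks occupy random non-overlapping slots of the toy
#' genome; a planted fraction of B peaks is placed to overlap a
#' distinct A peak each (random offset, guaranteed >= 1 bp overlap) and
#' the remainder in A-free slots.  Widths are lognormal.  Both sets are
#' emitted sorted and non-overlapping (merged by construction).
#'
#' @param cfg a [sim_config()].
#' @return list with `peaks_a`, `peaks_b` ([peak_set()]) and `truth`
#'   (planted fraction and the common B count).
#' @export
gen_peaksets <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_stream_seed(cfg$seed, "peaks", {
    slots <- .genome_slots(cfg$genome)
    n_a <- cfg$n_peaks_a; n_b <- cfg$n_peaks_b
    n_common <- round(cfg$cooccupancy_fraction * n_b)
    if (n_common > n_a)
      stop("co-occupancy fraction infeasible: more common B peaks than A peaks",
           call. = FALSE)
    n_free <- n_b - n_common
    if (n_a + n_free > nrow(slots))
      stop("toy genome too small for the requested peak counts",
           call. = FALSE)
    rw <- function(n) pmin(800, pmax(50, round(
      rlnorm(n, cfg$peak_width_meanlog, cfg$peak_width_sdlog))))
    pick <- sample.int(nrow(slots), n_a + n_free)
    sa <- slots[pick[seq_len(n_a)], ]
    sf <- slots[pick[n_a + seq_len(n_free)], , drop = FALSE]
    wa <- rw(n_a)
    a_start <- sa$slot_start + sample(800:1000, n_a, replace = TRUE)
    peaks_a <- peak_set(sa$chrom, a_start, a_start + wa,
                        label = "factorA", merged = TRUE)
    # common B: overlap a distinct A peak each by >= 1 bp
    ci <- sample.int(n_a, n_common)
    wb_c <- rw(n_common)
    lo <- a_start[ci] - wb_c + 1L
    hi <- a_start[ci] + wa[ci] - 1L
    b_start_c <- lo + floor(runif(n_common) * (hi - lo + 1))
    b_chrom_c <- sa$chrom[ci]
    wb_f <- rw(n_free)
    b_start_f <- sf$slot_start + sample(800:1000, n_free, replace = TRUE)
    peaks_b <- peak_set(c(b_chrom_c, sf$chrom),
                        c(b_start_c, b_start_f),
                        c(b_start_c + wb_c, b_start_f + wb_f),
                        label = "factorB", merged = TRUE)
    list(peaks_a = peaks_a, peaks_b = peaks_b,
         truth = list(fraction_b = cfg$cooccupancy_fraction,
                      n_common_b = n_common))
  })
}

#' Generate paired knockdown DE tables with planted joint targets
#'
#' Genes are laid on a toy genome sized to hold `n_kd_genes` promoter
#' windows without collision (spacing `2 * flank + 2000`).  Planted
#' joint targets respond concordantly in both knockdown tables with
#' tiny p-values (FDR < 0.1 after BH over all genes by construction)
#' and carry one peak of each factor inside their promoter window.
#' Decoys: genes DE in both tables but unbound (`n_de_only`), genes
#' bound by both factors but not DE (`n_bound_only`), and genes bound
#' by a single factor (`n_single_bound`, half A, half B).
#'
#' @param cfg a [sim_config()].
#' @return list with `de_a`, `de_b` (DE tables), `annotation` (gene,
#'   chrom, tss, strand), `peaks_a`, `peaks_b`, and `truth`.
#' @export
gen_knockdown_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_stream_seed(cfg$seed, "knockdown", {
    ng <- cfg$n_kd_genes
    flank <- cfg$promoter_flank
    spacing <- 2 * flank + 2000
    genes <- sprintf("KD%05d", seq_len(ng))
    n_chrom <- 3L
    per_chrom <- ceiling(ng / n_chrom)
    chrom <- rep(sprintf("chrK%d", seq_len(n_chrom)), each = per_chrom)[seq_len(ng)]
    tss <- (((seq_len(ng) - 1L) %% per_chrom) + 1L) * spacing
    ann <- data.frame(gene = genes, chrom = chrom, tss = tss,
                      strand = sample(c("+", "-"), ng, TRUE),
                      stringsAsFactors = FALSE)
    idx <- seq_len(ng)
    joint <- genes[idx[seq_len(cfg$n_joint_targets)]]
    rest <- setdiff(genes, joint)
    de_only <- head(rest, cfg$n_de_only)
    rest <- setdiff(rest, de_only)
    bound_only <- head(rest, cfg$n_bound_only)
    rest <- setdiff(rest, bound_only)
    single_a <- head(rest, cfg$n_single_bound %/% 2)
    rest <- setdiff(rest, single_a)
    single_b <- head(rest, cfg$n_single_bound - length(single_a))

    de_table <- function(planted) {
      lfc <- rnorm(ng, sd = 0.1)
      p <- runif(ng)
      ip <- match(planted$gene, genes)
      lfc[ip] <- planted$sign * (cfg$de_effect + abs(rnorm(length(ip), sd = 0.3)))
      p[ip] <- 10^-runif(length(ip), 4, 8)
      data.frame(gene = genes, log2fc = lfc, p_value = p,
                 fdr = p.adjust(p, "BH"),
                 mean_count = round(rlnorm(ng, log(500), 1)),
                 stringsAsFactors = FALSE)
    }
    de_sign <- sample(c(-1, 1), cfg$n_joint_targets + cfg$n_de_only,
                      replace = TRUE)
    planted <- data.frame(gene = c(joint, de_only), sign = de_sign)
    de_a <- de_table(planted)
    de_b <- de_table(planted)  # concordant: same planted signs

    peak_in_promoter <- function(gs) {
      i <- match(gs, genes)
      w <- pmin(800, pmax(50, round(rlnorm(length(i),
                                           cfg$peak_width_meanlog,
                                           cfg$peak_width_sdlog))))
      off <- floor(runif(length(i), -flank + 1, flank - w))
      start <- pmax(0, ann$tss[i] + off)
      data.frame(chrom = ann$chrom[i], start = start, end = start + w)
    }
    pa <- rbind(peak_in_promoter(c(joint, bound_only, single_a)))
    pb <- rbind(peak_in_promoter(c(joint, bound_only, single_b)))
    peaks_a <- merge_intervals(peak_set(pa$chrom, pa$start, pa$end,
                                        label = "factorA:kd"))
    peaks_b <- merge_intervals(peak_set(pb$chrom, pb$start, pb$end,
                                        label = "factorB:kd"))
    list(de_a = de_a, de_b = de_b, annotation = ann,
         peaks_a = peaks_a, peaks_b = peaks_b,
         truth = list(joint_targets = joint, de_only = de_only,
                      bound_only = bound_only,
                      single_bound = c(single_a, single_b)))
  })
}

#' Generate the germline layer with planted LD, enrichment, imbalance
#' and motif structure
#'
#' LD blocks are built from a per-block core haplotype pair: each
#' individual draws two haplotypes carrying the block allele with the
#' block's frequency, and each SNP copies the core haplotypes with a
#' per-haplotype flip probability `ld_noise` (0 gives r-squared exactly
#' 1 within blocks; the default targets ~0.8).  Risk SNPs fall inside
#' common binding regions with probability
#' `min(1, enrichment_factor x coverage)`, the remainder outside.  One
#' designated SNP is embedded in a GATA-like motif such that the risk
#' allele (T) completes the consensus.  Allele counts are binomial at
#' the configured ratio and depth.  eQTL rows link each tag's first
#' proxy to a named eGene.
#'
#' @param cfg a [sim_config()].
#' @param regions three-way region table (from
#'   [cooccupancy_regions()]); generated internally from
#'   [gen_peaksets()] when `NULL`.
#' @return list with `snps` (risk SNPs), `background` (pool),
#'   `tags`, `block_snps`, `genotypes` (SNPs x individuals dosages),
#'   `eqtl`, `allele_counts`, `motif` (list: pwm, sequence, snp_pos,
#'   ref, alt, risk_allele), `regions`, and `truth`.
#' @export
gen_germline <- function(cfg, regions = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (is.null(regions)) {
    ps <- gen_peaksets(cfg)
    regions <- cooccupancy_regions(
      classify_cooccupancy(ps$peaks_a, ps$peaks_b))
  }
  with_stream_seed(cfg$seed, "germline", {
    genome <- cfg$genome
    common <- regions[regions$category == "common", , drop = FALSE]
    if (nrow(common) == 0L)
      stop("no common regions available for SNP placement", call. = FALSE)
    cov_bp <- sum(common$end - common$start)
    coverage <- cov_bp / sum(genome)
    p_in <- cfg$enrichment_factor * coverage
    if (p_in > 1)
      stop("enrichment factor incompatible with common-region coverage",
           call. = FALSE)
    rand_pos <- function(n) {
      ch <- sample(names(genome), n, replace = TRUE,
                   prob = genome / sum(genome))
      data.frame(chrom = ch,
                 pos = floor(runif(n) * genome[ch]),
                 stringsAsFactors = FALSE)
    }
    pos_in_common <- function(n) {
      i <- sample.int(nrow(common), n, replace = TRUE,
                      prob = common$end - common$start)
      data.frame(chrom = common$chrom[i],
                 pos = common$start[i] +
                   floor(runif(n) * (common$end[i] - common$start[i])),
                 stringsAsFactors = FALSE)
    }
    # background pool: uniform over the genome
    bg <- rand_pos(cfg$n_background_snps)
    bg$rsid <- sprintf("bg%05d", seq_len(nrow(bg)))
    # risk SNPs: enriched placement
    inside <- runif(cfg$n_risk_snps) < p_in
    rp <- rbind(if (any(inside)) pos_in_common(sum(inside)),
                if (any(!inside)) {
                  out <- rand_pos(sum(!inside))
                  flag <- assign_points_to_peaks(
                    out$chrom, out$pos,
                    peak_set(common$chrom, common$start, common$end))
                  while (any(flag)) {  # resample strays off-region
                    out[flag, ] <- rand_pos(sum(flag))
                    flag <- assign_points_to_peaks(
                      out$chrom, out$pos,
                      peak_set(common$chrom, common$start, common$end))
                  }
                  out
                })
    alle <- t(vapply(seq_len(nrow(rp)), function(i)
      sample(c("A", "C", "G", "T"), 2), c("", "")))
    snps <- data.frame(rsid = sprintf("rs%05d", seq_len(nrow(rp))),
                       chrom = rp$chrom, pos = rp$pos,
                       ref = alle[, 1], alt = alle[, 2],
                       risk_allele = alle[, 2], is_tag = FALSE,
                       stringsAsFactors = FALSE)
    # LD blocks: tag = first member
    n_ind <- cfg$n_individuals
    blocks <- list(); geno <- list()
    for (b in seq_len(cfg$n_tag_snps)) {
      q <- runif(1, 0.2, 0.8)
      ch <- sample(names(genome), 1)
      base <- floor(runif(1, 0, genome[ch] - 6e4))
      posb <- sort(base + sample.int(5e4, cfg$ld_block_size))
      ids <- sprintf("tag%02d_snp%02d", b, seq_len(cfg$ld_block_size))
      core <- matrix(rbinom(2 * n_ind, 1, q), nrow = 2)  # 2 haplotypes
      g <- t(vapply(seq_len(cfg$ld_block_size), function(k) {
        flip <- matrix(rbinom(2 * n_ind, 1, cfg$ld_noise), nrow = 2)
        colSums((core + flip) %% 2)
      }, numeric(n_ind)))
      rownames(g) <- ids
      geno[[b]] <- g
      blocks[[b]] <- data.frame(rsid = ids, chrom = ch, pos = posb,
                                block = b, stringsAsFactors = FALSE)
    }
    block_snps <- do.call(rbind, blocks)
    genotypes <- do.call(rbind, geno)
    colnames(genotypes) <- sprintf("IND%03d", seq_len(n_ind))
    tags <- do.call(rbind, lapply(blocks, function(bk) bk[1L, ]))
    # eQTL: each tag's block linked to a named eGene via its 2nd member
    eqtl <- data.frame(rsid = vapply(blocks, function(bk) bk$rsid[2L], ""),
                       egene = sprintf("EGENE%02d", seq_along(blocks)),
                       source = "synthetic-eqtl",
                       stringsAsFactors = FALSE)
    # designated motif SNP: GATA-like consensus AGATAA completed by T
    consensus <- c("A", "G", "A", "T", "A", "A")
    ppm <- matrix(0.05, nrow = 6, ncol = 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    for (i in seq_along(consensus)) ppm[i, consensus[i]] <- 0.85
    pwm <- pwm_model(ppm, id = "GATA_like")
    flankseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                  collapse = "")
    # risk allele T sits at motif position 4; ref allele C breaks it
    seq_risk <- paste0(flankseq(7), paste(consensus, collapse = ""),
                       flankseq(7))
    snp_pos <- 7L + 4L
    seq_ref <- seq_risk
    substr(seq_ref, snp_pos, snp_pos) <- "C"
    motif <- list(pwm = pwm, sequence = seq_ref, snp_pos = snp_pos,
                  ref = "C", alt = "T", risk_allele = "T")
    depth <- cfg$read_depth
    k <- rbinom(1, depth, cfg$allelic_ratio)
    allele_counts <- data.frame(site = "designated_snp",
                                count_risk = k, count_other = depth - k)
    list(snps = snps, background = bg, tags = tags,
         block_snps = block_snps, genotypes = genotypes, eqtl = eqtl,
         allele_counts = allele_counts, motif = motif, regions = regions,
         truth = list(enrichment_factor = cfg$enrichment_factor,
                      p_in = p_in, coverage = coverage,
                      n_risk_in_common = sum(inside),
                      allelic_ratio = cfg$allelic_ratio,
                      ld_noise = cfg$ld_noise,
                      eqtl_links = eqtl))
  })
}
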