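# Survival estimators and cohort stratification schemes.  The
# estimators are delegated to the survival package (product-limit,
# log-rank, Cox partial likelihood with Breslow ties) behind thin
# contract-checked wrappers; the stratification logic is bespoke.

#' Kaplan-Meier product-limit estimate
#'
#' @param times nonnegative follow-up times.
#' @param events 0/1 event indicators (0 = censored).
#' @return object of class `KMCurve`: list with `time` (ordered event
#'   times), `surv` (S(t), non-increasing), `n_risk`, `n_event`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1)
  if (any(times < 0)) stop("negative follow-up time", call. = FALSE)
  stopifnot(all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, surv = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event),
            class = "KMCurve")
}

#' Evaluate a KM curve at arbitrary times
#'
#' Right-continuous step-function evaluation; S = 1 before the first
#' event time.
#'
#' @param km a [km_estimate()] result.
#' @param t numeric times.
#' @return survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(ti) {
    i <- which(km$time <= ti & km$n_event > 0)
    if (!length(i)) 1.0 else km$surv[max(i)]
  }, 0)
}

#' Log-rank test across two or more groups
#'
#' @param groups group labels (>= 2 distinct, each with >= 1 subject).
#' @param times,events follow-up times and 0/1 event indicators.
#' @return list with `chi2`, `df` (= groups - 1), `p_value`.
#' @export
logrank_test <- function(groups, times, events) {
  stopifnot(length(groups) == length(times),
            length(times) == length(events))
  ok <- !is.na(groups) & !is.na(times) & !is.na(events)
  groups <- factor(groups[ok]); times <- times[ok]; events <- events[ok]
  g <- nlevels(droplevels(groups))
  if (g < 2L) stop("log-rank needs at least 2 groups", call. = FALSE)
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- g - 1L
  list(chi2 = unname(sd_$chisq), df = df,
       p_value = pchisq(sd_$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional-hazards ratio for a binary grouping
#'
#' Single binary covariate, Breslow tie handling, Wald confidence
#' interval and p-value.  Complete separation of events (monotone
#' partial likelihood) is flagged and the HR reported as
#' non-convergent.
#'
#' @param group binary exposure indicator (logical or 0/1; `TRUE`/1 is
#'   the exposed group).
#' @param times,events follow-up times and 0/1 event indicators.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return list of class `CoxResult`: `log_hr`, `hr`, `se`, `ci95`
#'   (length-2), `p_value`, `converged`.
#' @export
cox_hr <- function(group, times, events, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  x <- as.numeric(as.logical(group))
  ok <- !is.na(x) & !is.na(times) & !is.na(events)
  x <- x[ok]; times <- times[ok]; events <- events[ok]
  if (sum(events[x == 1]) < 1 || sum(events[x == 0]) < 1)
    stop("both groups need at least one event", call. = FALSE)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(times, events) ~ x, ties = ties,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  converged <- is.finite(beta) && is.finite(se) && abs(beta) < 15
  structure(list(
    log_hr = beta, hr = exp(beta), se = se,
    ci95 = exp(beta + c(-1, 1) * qnorm(0.975) * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    converged = converged,
    flag = if (converged) "none" else "non-convergent (separation)"),
    class = "CoxResult")
}

#' Stratify cohort samples for survival comparison
#'
#' Implements the stratification schemes used for prognosis analyses:
#' \describe{
#'   \item{`median_split`}{`"high"` iff expression strictly greater
#'     than the cohort median (median ties go to `"low"`).}
#'   \item{`cn_split`}{`"gain_amp"` (copy-number code >= 1) vs
#'     `"diploid"` (code 0); losses are set `NA`.}
#'   \item{`joint_high`}{four groups from two genes' median splits,
#'     labels `"A_high.B_high"` etc.; both-high is the exposure group.}
#'   \item{`genotype_within_stratum`}{median-split on the gene, then
#'     within the requested stratum compare homozygous-risk `"TT"`
#'     against `"TC"`/`"CC"` (other-stratum samples are `NA`).}
#'   \item{`gleason_subgroup`}{three groups `"<=6"`, `"7"`, `">=8"`.}
#' }
#' When `deep_loss_cn` is supplied, samples with code -2 are excluded
#' (label `NA`) before any median is computed.
#'
#' @param scheme one of the scheme names above.
#' @param expression named per-sample expression vector of the
#'   stratifying gene (schemes `median_split`, `joint_high`,
#'   `genotype_within_stratum`).
#' @param expression_b second gene's expression (`joint_high`).
#' @param cn named copy-number code vector (`cn_split`).
#' @param genotype named genotype vector, values `"TT"`, `"TC"`,
#'   `"CC"` (`genotype_within_stratum`).
#' @param gleason named integer Gleason scores (`gleason_subgroup`).
#' @param deep_loss_cn optional named copy-number code vector of a gene
#'   whose deep loss (code -2) excludes samples up front.
#' @param stratum which expression stratum to analyze in
#'   `genotype_within_stratum` (`"high"` or `"low"`).
#' @param genotype_mode `"TT_vs_rest"` (default) or `"TT_vs_CC"`.
#' @return named character label vector (`NA` = excluded), with
#'   attribute `"flag"` when a stratum is empty or degenerate.
#' @export
stratify_samples <- function(scheme = c("median_split", "cn_split",
                                        "joint_high",
                                        "genotype_within_stratum",
                                        "gleason_subgroup"),
                             expression = NULL, expression_b = NULL,
                             cn = NULL, genotype = NULL, gleason = NULL,
                             deep_loss_cn = NULL,
                             stratum = c("high", "low"),
                             genotype_mode = c("TT_vs_rest", "TT_vs_CC")) {
  scheme <- match.arg(scheme)
  stratum <- match.arg(stratum)
  genotype_mode <- match.arg(genotype_mode)
  base <- switch(scheme,
                 median_split = expression, cn_split = cn,
                 joint_high = expression,
                 genotype_within_stratum = expression,
                 gleason_subgroup = gleason)
  if (is.null(base))
    stop("missing required input for scheme '", scheme, "'", call. = FALSE)
  samples <- names(base)
  if (is.null(samples)) stop("inputs must be named by sample", call. = FALSE)
  keep <- rep(TRUE, length(samples))
  if (!is.null(deep_loss_cn))
    keep <- keep & !(deep_loss_cn[samples] %in% -2)
  flag <- NULL
  med_split <- function(x, k) {
    m <- median(x[k], na.rm = TRUE)
    out <- ifelse(x > m, "high", "low")
    out[!k | is.na(x)] <- NA
    out
  }
  labels <- switch(scheme,
    median_split = {
      lab <- med_split(expression, keep)
      if (length(unique(stats::na.omit(lab))) < 2L)
        flag <- "degenerate split (all values tie at the median)"
      lab
    },
    cn_split = {
      lab <- ifelse(cn >= 1, "gain_amp", ifelse(cn == 0, "diploid", NA))
      lab[!keep] <- NA
      lab
    },
    joint_high = {
      stopifnot(!is.null(expression_b))
      a <- med_split(expression, keep)
      b <- med_split(expression_b[samples], keep)
      ifelse(is.na(a) | is.na(b), NA,
             paste0("A_", a, ".B_", b))
    },
    genotype_within_stratum = {
      stopifnot(!is.null(genotype))
      strat <- med_split(expression, keep)
      gt <- genotype[samples]
      lab <- rep(NA_character_, length(samples))
      inside <- !is.na(strat) & strat == stratum & !is.na(gt)
      if (genotype_mode == "TT_vs_CC") inside <- inside & gt %in% c("TT", "CC")
      lab[inside] <- ifelse(gt[inside] == "TT", "TT", "TC_CC")
      if (genotype_mode == "TT_vs_CC")
        lab[inside] <- ifelse(gt[inside] == "TT", "TT", "CC")
      if (sum(!is.na(lab)) == 0) flag <- "empty stratum"
      lab
    },
    gleason_subgroup = {
      ifelse(!keep | is.na(gleason), NA,
             ifelse(gleason <= 6, "<=6", ifelse(gleason == 7, "7", ">=8")))
    })
  names(labels) <- samples
  attr(labels, "flag") <- flag %||% "none"
  labels
}
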