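#' Percent change from baseline
#'
#' @param baseline,post Numeric vectors (baseline strictly positive).
#' @return `100 * (post - baseline) / baseline`.
#' @examples
#' percent_change(10, 8)  # -20
#' @export
percent_change <- function(baseline, post) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop_data("baseline values must be positive")
  100 * (post - baseline) / baseline
}

#' Hemodynamic diagnostic rule for precapillary PAH
#'
#' A baseline record is diagnostic when mean pulmonary arterial pressure is
#' at least 25 mm Hg, pulmonary artery wedge pressure no greater than
#' 15 mm Hg, and pulmonary vascular resistance strictly greater than 3 Wood
#' units.
#'
#' @param record A list or single-row data frame with fields `mPAP`,
#'   `PAWP`, `PVR` (further fields ignored).
#' @return Logical.
#' @examples
#' validate_pah_diagnosis(list(mPAP = 55, PAWP = 7.7, PVR = 14.2))
#' @export
validate_pah_diagnosis <- function(record) {
  need <- c("mPAP", "PAWP", "PVR")
  vals <- lapply(need, function(f) record[[f]])
  missing <- need[vapply(vals, function(v)
    is.null(v) || length(v) != 1L || is.na(v), logical(1))]
  if (length(missing))
    stop_data("hemodynamic record is missing: ",
              paste(missing, collapse = ", "))
  record$mPAP >= 25 && record$PAWP <= 15 && record$PVR > 3
}

#' Age- and sex-matched control selection
#'
#' Greedy nearest-age matching within sex, without replacement: carriers are
#' processed in subject-id order and each receives its `ratio` same-sex pool
#' members with the smallest absolute age difference (ties broken by
#' smallest subject id).
#'
#' @param carriers,pool Data frames with columns `subject_id`, `age`, `sex`.
#' @param ratio Matched controls per carrier (default 3).
#' @return The selected pool rows, with a `matched_to` column naming the
#'   carrier each row was matched to.
#' @export
match_controls <- function(carriers, pool, ratio = 3L) {
  ratio <- check_count(ratio, "ratio", positive = TRUE)
  need_by_sex <- ratio * table(carriers$sex)
  have_by_sex <- table(pool$sex)
  deficit <- vapply(names(need_by_sex), function(s)
    max(0L, need_by_sex[[s]] -
          (if (s %in% names(have_by_sex)) have_by_sex[[s]] else 0L)),
    numeric(1))
  if (any(deficit > 0))
    stop_data("matching pool too small; deficit per sex: ",
              paste(names(deficit)[deficit > 0], deficit[deficit > 0],
                    sep = "=", collapse = ", "))
  pool <- pool[order(pool$subject_id), , drop = FALSE]
  taken <- rep(FALSE, nrow(pool))
  out <- vector("list", nrow(carriers))
  carriers <- carriers[order(carriers$subject_id), , drop = FALSE]
  for (i in seq_len(nrow(carriers))) {
    cand <- which(!taken & pool$sex == carriers$sex[i])
    ord <- cand[order(abs(pool$age[cand] - carriers$age[i]),
                      pool$subject_id[cand])]
    pick <- ord[seq_len(ratio)]
    taken[pick] <- TRUE
    sel <- pool[pick, , drop = FALSE]
    sel$matched_to <- carriers$subject_id[i]
    out[[i]] <- sel
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Baseline-adjusted genotype comparison of vasodilator response (ANCOVA)
#'
#' Ordinary least squares of the percent change on an intercept, the
#' genotype indicator, and the baseline measurement. The genotype
#' coefficient is the least-squares-mean difference (carrier minus
#' non-carrier) — identical to the difference of model-adjusted group means
#' at the common mean baseline for this two-group additive model. The
#' confidence interval uses t critical values at the residual degrees of
#' freedom.
#'
#' @param percent_changes Numeric outcome vector (percent change from
#'   baseline), one per subject.
#' @param genotype Logical or 0/1 vector: carrier status.
#' @param baselines Numeric vector of baseline measurements.
#' @param outcome_label Label carried into the result.
#' @param adjust_baseline Set `FALSE` to drop the baseline term (the
#'   coefficient then equals the raw group-mean difference exactly).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `"response_model_result"`: `outcome`,
#'   `ls_mean_difference`, `ci_low`, `ci_high`, `p_value`, `n_carriers`,
#'   `n_noncarriers`, and the underlying `fit`.
#' @export
genotype_response_model <- function(percent_changes, genotype, baselines,
                                    outcome_label = "outcome",
                                    adjust_baseline = TRUE,
                                    conf_level = 0.95) {
  genotype <- as.logical(genotype)
  n <- length(percent_changes)
  if (length(genotype) != n ||
      (adjust_baseline && length(baselines) != n))
    stop_data("percent_changes, genotype and baselines must align")
  keep <- is.finite(percent_changes) & !is.na(genotype)
  if (adjust_baseline) keep <- keep & is.finite(baselines)
  y <- percent_changes[keep]; g <- genotype[keep]
  n_car <- sum(g); n_non <- sum(!g)
  if (n_car < 2L || n_non < 2L)
    stop_data("each genotype group needs at least 2 subjects (",
              n_car, " carriers, ", n_non, " non-carriers)")
  if (adjust_baseline) {
    b <- baselines[keep]
    fit <- lm(y ~ g + b)
  } else {
    fit <- lm(y ~ g)
  }
  if (fit$rank < length(coef(fit)) || anyNA(coef(fit)))
    stop_data("design is collinear; cannot separate genotype from baseline")
  est <- coef(fit)[["gTRUE"]]
  se <- sqrt(vcov(fit)["gTRUE", "gTRUE"])
  dfres <- fit$df.residual
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, dfres)
  structure(list(outcome = outcome_label,
                 ls_mean_difference = est,
                 ci_low = est - tcrit * se, ci_high = est + tcrit * se,
                 p_value = 2 * pt(-abs(est / se), dfres),
                 n_carriers = n_car, n_noncarriers = n_non,
                 fit = fit),
            class = "response_model_result")
}

#' @export
print.response_model_result <- function(x, ...) {
  cat(sprintf(
    "%s: LS-mean difference %+.1f%% (95%% CI %.1f to %.1f), p = %.3g; n = %d vs %d\n",
    x$outcome, x$ls_mean_difference, x$ci_low, x$ci_high, x$p_value,
    x$n_carriers, x$n_noncarriers))
  invisible(x)
}

#' Genotype-stratified vasoreactivity analysis of a cohort
#'
#' End-to-end acute-response comparison: identifies carriers of qualifying
#' variants in `gene` among case subjects with paired hemodynamics, draws an
#' age- and sex-matched non-carrier comparison group ([match_controls()]),
#' computes per-subject percent changes, and fits the baseline-adjusted
#' model ([genotype_response_model()]) for PVR and cardiac index.
#'
#' @param cohort A cohort object.
#' @param gene Gene defining carrier status.
#' @param criteria [filter_criteria()] defining qualifying variants.
#' @param ratio Matched non-carriers per carrier (default 3).
#' @param outcomes Hemodynamic variables to model.
#' @return List with `models` (one `"response_model_result"` per outcome)
#'   and `subjects` (the analysed subject table with carrier flags).
#' @export
vasoresponse_analysis <- function(cohort, gene, criteria = filter_criteria(),
                                  ratio = 3L,
                                  outcomes = c("PVR", "cardiac_index")) {
  hd <- cohort$hemodynamics
  base <- hd[hd$phase == "baseline", , drop = FALSE]
  post <- hd[hd$phase == "post_iloprost", , drop = FALSE]
  paired <- intersect(base$subject_id, post$subject_id)
  cases <- cohort$subjects[cohort$subjects$group == "case" &
                             cohort$subjects$subject_id %in% paired, ,
                           drop = FALSE]
  v <- cohort$variants
  sites <- v$site_id[v$gene == gene & qualify_variants(v, criteria)]
  G <- cohort$genotypes[cases$subject_id, sites, drop = FALSE]
  carrier <- rowSums(!is.na(G) & G == 1L) > 0L
  carriers <- cases[carrier, , drop = FALSE]
  pool <- cases[!carrier, , drop = FALSE]
  matched <- match_controls(carriers, pool, ratio = ratio)
  ids <- c(carriers$subject_id, matched$subject_id)
  flag <- c(rep(TRUE, nrow(carriers)), rep(FALSE, nrow(matched)))
  b <- base[match(ids, base$subject_id), , drop = FALSE]
  p <- post[match(ids, post$subject_id), , drop = FALSE]
  models <- lapply(outcomes, function(vname) {
    genotype_response_model(percent_change(b[[vname]], p[[vname]]),
                            flag, b[[vname]], outcome_label = vname)
  })
  names(models) <- outcomes
  subj <- cohort$subjects[match(ids, cohort$subjects$subject_id), ,
                          drop = FALSE]
  subj$carrier <- flag
  rownames(subj) <- NULL
  list(models = models, subjects = subj)
}
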