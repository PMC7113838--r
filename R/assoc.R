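#' 2x2 contingency table of carriers by group
#'
#' Cell layout follows the case-control convention: `a` exposed (carrier)
#' cases, `b` unexposed cases, `c` exposed controls, `d` unexposed controls.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param groups Optional length-2 character vector naming the two groups
#'   (rows); defaults to case/control.
#' @param exposure Optional label for the exposure (e.g. a variant id).
#' @return An object of class `"contingency_table"`.
#' @examples
#' contingency_table(14, 216, 8, 960)
#' @export
contingency_table <- function(a, b, c, d, groups = c("case", "control"),
                              exposure = "carrier") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!vapply(cells, is_count, logical(1))))
    stop_data("contingency table cells must be non-negative integers")
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), groups = groups, exposure = exposure),
            class = "contingency_table")
}

as_matrix_ct <- function(tab) {
  matrix(c(tab$a, tab$c, tab$b, tab$d), nrow = 2,
         dimnames = list(tab$groups, c("exposed", "unexposed")))
}

#' @export
print.contingency_table <- function(x, ...) {
  print(as_matrix_ct(x))
  invisible(x)
}

#' Tabulate gene or variant carriers against a binary grouping
#'
#' A subject is a carrier when heterozygous for at least one qualifying
#' variant of the gene (or at the single site), counted once per subject
#' however many qualifying variants it holds — participants are counted,
#' not alleles.
#'
#' @param cohort A cohort object.
#' @param gene Gene symbol to tabulate (mutually exclusive with `site`).
#' @param site Single site id to tabulate.
#' @param groups Named character vector of binary labels per subject id;
#'   default the cohort's case/control labels. The first level encountered
#'   in `level_order` (or sorted order) forms the `a`/`b` row.
#' @param level_order Optional length-2 vector fixing which group is the
#'   first row.
#' @param criteria [filter_criteria()] defining "qualifying"; site-level
#'   tabulation uses heterozygosity only.
#' @return A [contingency_table()].
#' @export
carrier_table <- function(cohort, gene = NULL, site = NULL, groups = NULL,
                          level_order = NULL,
                          criteria = filter_criteria()) {
  if (is.null(gene) == is.null(site))
    stop_config("supply exactly one of gene or site")
  v <- cohort$variants
  if (!is.null(gene)) {
    if (!gene %in% v$gene) stop_data("unknown gene: ", gene)
    sites <- v$site_id[v$gene == gene & qualify_variants(v, criteria)]
  } else {
    if (!site %in% v$site_id) stop_data("unknown site: ", site)
    sites <- site
  }
  if (is.null(groups)) {
    groups <- setNames(cohort$subjects$group, cohort$subjects$subject_id)
  }
  ids <- names(groups)
  if (!all(ids %in% rownames(cohort$genotypes)))
    stop_data("group labels name subjects absent from the genotype matrix")
  lev <- level_order %||% sort(unique(as.character(groups)))
  if (length(lev) != 2L) stop_data("grouping must have exactly two levels")
  G <- cohort$genotypes[ids, sites, drop = FALSE]
  carrier <- rowSums(!is.na(G) & G == 1L) > 0L
  g1 <- groups == lev[1]
  contingency_table(sum(carrier & g1), sum(!carrier & g1),
                    sum(carrier & !g1), sum(!carrier & !g1),
                    groups = lev,
                    exposure = if (!is.null(gene)) gene else site)
}

z975 <- 1.959964  # fixed normal quantile used for all Wald intervals

#' Wald odds ratio for a 2x2 table
#'
#' Point estimate `ad/bc`; confidence interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`; two-sided p from the
#' Wald z statistic. Any zero cell makes the odds ratio not estimable
#' (reported `NE`), unless the Haldane-Anscombe +0.5 correction is enabled.
#'
#' @param tab A [contingency_table()].
#' @param alpha Two-sided error rate (default 0.05).
#' @param haldane Add 0.5 to every cell when a zero cell is present.
#' @return An object of class `"assoc_result"`: `or_estimate`, `ci_low`,
#'   `ci_high`, `p_value`, `method`, `estimable`.
#' @examples
#' odds_ratio_wald(contingency_table(14, 216, 8, 960))
#' @export
odds_ratio_wald <- function(tab, alpha = 0.05, haldane = FALSE) {
  stopifnot(inherits(tab, "contingency_table"))
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  if (any(cells == 0) && !haldane) {
    return(structure(list(or_estimate = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p_value = NA_real_,
                          method = "Wald odds ratio (NE: zero cell)",
                          estimable = FALSE, exposure = tab$exposure),
                     class = "assoc_result"))
  }
  if (any(cells == 0)) cells <- cells + 0.5
  z <- if (alpha == 0.05) z975 else qnorm(1 - alpha / 2)
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * z * se)
  p <- 2 * pnorm(-abs(log(or) / se))
  structure(list(or_estimate = or, ci_low = ci[1], ci_high = ci[2],
                 p_value = p,
                 method = if (any(c(tab$a, tab$b, tab$c, tab$d) == 0))
                   "Wald odds ratio (Haldane-Anscombe corrected)"
                 else "Wald odds ratio",
                 estimable = TRUE, exposure = tab$exposure),
            class = "assoc_result")
}

#' Single-predictor logistic regression on a 2x2 table
#'
#' Maximum-likelihood logistic fit of group membership on the binary
#' exposure; the exponentiated slope equals the cross-product odds ratio on
#' a saturated 2x2 table, with Wald confidence interval and p-value. A zero
#' cell implies separation and a not-estimable result, mirroring the `NE`
#' policy of [odds_ratio_wald()].
#'
#' @inheritParams odds_ratio_wald
#' @return An `"assoc_result"`.
#' @export
logistic_single_predictor <- function(tab, alpha = 0.05) {
  stopifnot(inherits(tab, "contingency_table"))
  if (any(c(tab$a, tab$b, tab$c, tab$d) == 0)) {
    return(structure(list(or_estimate = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p_value = NA_real_,
                          method = "logistic regression (NE: separation)",
                          estimable = FALSE, exposure = tab$exposure),
                     class = "assoc_result"))
  }
  df <- data.frame(exposed = c(1, 0),
                   n_case = c(tab$a, tab$b),
                   n_control = c(tab$c, tab$d))
  fit <- glm(cbind(n_case, n_control) ~ exposed, family = binomial(),
             data = df)
  beta <- coef(fit)[["exposed"]]
  se <- sqrt(vcov(fit)["exposed", "exposed"])
  z <- if (alpha == 0.05) z975 else qnorm(1 - alpha / 2)
  structure(list(or_estimate = exp(beta),
                 ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
                 p_value = 2 * pnorm(-abs(beta / se)),
                 method = "logistic regression (Wald)",
                 estimable = TRUE, exposure = tab$exposure),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("%s [%s]: OR NE\n", x$exposure %||% "exposure", x$method))
  } else {
    cat(sprintf("%s [%s]: OR %.1f (95%% CI %.1f-%.1f), p = %.3g\n",
                x$exposure %||% "exposure", x$method, x$or_estimate,
                x$ci_low, x$ci_high, x$p_value))
  }
  invisible(x)
}

#' Continuity-adjusted (Yates) chi-square test for a 2x2 table
#'
#' Statistic `sum(max(|O - E| - 0.5, 0)^2 / E)` with the correction
#' truncated at zero — when every `|O - E|` is below 0.5 the statistic is
#' exactly 0 and p is 1 — and p-value from the upper tail of the 1-df
#' chi-square distribution.
#'
#' @param tab A [contingency_table()].
#' @return List with `statistic` and `p_value`.
#' @examples
#' yates_chi2(contingency_table(2, 40, 6, 182, groups = c("discovery",
#'                                                        "replication")))
#' @export
yates_chi2 <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  O <- as_matrix_ct(tab)
  if (any(rowSums(O) == 0) || any(colSums(O) == 0))
    stop_data("chi-square expected counts undefined: zero margin")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum(pmax(abs(O - E) - 0.5, 0)^2 / E)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p by enumeration of the conditional (hypergeometric)
#' distribution with fixed margins, summing the probabilities of all tables
#' no more probable than the observed one (with the conventional
#' `1 + 1e-7` floating-point tie guard).
#'
#' @param tab A [contingency_table()].
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(contingency_table(14, 216, 8, 960))
#' @export
fisher_exact <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  m <- tab$a + tab$c        # exposed margin
  n <- tab$b + tab$d        # unexposed margin
  k <- tab$a + tab$b        # first-group margin
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab$a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Carrier percentage at reported precision
#'
#' @param k Carrier count.
#' @param n Group size (must be positive).
#' @param digits Decimal places in the report (default 1).
#' @return `100 * k / n` rounded to `digits` decimals.
#' @examples
#' carrier_percent(14, 230)  # 6.1
#' @export
carrier_percent <- function(k, n, digits = 1) {
  if (any(n <= 0)) stop_data("denominator must be positive")
  round(100 * k / n, digits)
}

#' Per-group carrier percentages of a 2x2 table
#'
#' @param tab A [contingency_table()].
#' @param digits Decimal places (default 1).
#' @return Named numeric vector of the two group percentages.
#' @export
frequency_report <- function(tab, digits = 1) {
  stopifnot(inherits(tab, "contingency_table"))
  setNames(c(carrier_percent(tab$a, tab$a + tab$b, digits),
             carrier_percent(tab$c, tab$c + tab$d, digits)),
           tab$groups)
}
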