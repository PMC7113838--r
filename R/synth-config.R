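#' Simulation configuration for a synthetic IPAH case-control cohort
#'
#' Bundles every parameter of the synthetic cohort generator. Defaults
#' reproduce the study conditions of a two-stage IPAH rare-variant design:
#' 42 discovery cases sequenced genome-wide, 188 replication cases and 968
#' controls genotyped at the candidate gene only, a causal gene carried
#' heterozygously by ~6.1% of cases and ~0.8% of controls, a
#' singleton-dominated background of rare candidate variants in the discovery
#' genomes, common biallelic SNPs in Hardy-Weinberg equilibrium for kinship
#' QC, and genotype-dependent acute vasodilator responses (PVR percent-change
#' difference -21.7 points, cardiac-index difference +18.3 points).
#'
#' @param seed Integer seed; fully determines the generated cohort.
#' @param n_discovery_cases,n_replication_cases,n_controls Arm sizes.
#' @param causal_gene Symbol of the planted causal gene.
#' @param n_causal_sites Number of distinct rare sites in the causal gene
#'   (one splice-donor site plus `n_causal_sites - 1` missense sites).
#' @param case_carrier_freq,control_carrier_freq Probability that a case
#'   (resp. control) carries one heterozygous causal-gene variant.
#' @param n_background_genes Size of the background gene pool.
#' @param background_hit_rate Expected number of filter-passing background
#'   rare variants per discovery-case genome.
#' @param background_reject_rate Expected number of background variants per
#'   discovery-case genome that fail the candidate filter (too common,
#'   present in the Chinese reference panel, or not consensus-deleterious);
#'   these give the filter true negatives.
#' @param lung_expressed_fraction Fraction of background genes labelled as
#'   abundantly expressed in lung; the causal gene is always lung-expressed.
#' @param n_common_snps Number of common biallelic SNPs used for kinship.
#' @param common_maf_range Length-2 MAF interval for the common SNPs.
#' @param n_related_pairs Named integer vector `c(duplicate=, first=,
#'   second=)`: number of cross-arm (case, control) relative pairs planted by
#'   gamete construction at the common SNPs.
#' @param pvr_effect True carrier-vs-non-carrier difference, in percentage
#'   points, of the post-vasodilator percent change in pulmonary vascular
#'   resistance.
#' @param ci_effect Same for cardiac index.
#' @param baseline_means_sds Named list of `c(mean, sd)` pairs for baseline
#'   hemodynamics (`mPAP`, `PAWP`, `PVR`, `cardiac_index`, `RAP`, `SvO2`).
#' @param noise_sd Residual SD of the simulated percent changes
#'   (percentage points).
#' @param panels Names of the four reference frequency panels.
#' @param predictors Names of the deleteriousness predictor columns.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @examples
#' cfg <- simulation_config(seed = 1)
#' cfg$n_controls
#' @export
simulation_config <- function(seed = 1L,
                              n_discovery_cases = 42L,
                              n_replication_cases = 188L,
                              n_controls = 968L,
                              causal_gene = "PTGIS",
                              n_causal_sites = 3L,
                              case_carrier_freq = 0.061,
                              control_carrier_freq = 0.008,
                              n_background_genes = 7600L,
                              background_hit_rate = 47.3,
                              background_reject_rate = 40,
                              lung_expressed_fraction = 0.2,
                              n_common_snps = 10000L,
                              common_maf_range = c(0.05, 0.5),
                              n_related_pairs = c(duplicate = 0L, first = 0L,
                                                  second = 0L),
                              pvr_effect = -21.7,
                              ci_effect = 18.3,
                              baseline_means_sds = NULL,
                              noise_sd = 15,
                              panels = c("panel_a", "panel_b", "panel_c",
                                         "panel_d"),
                              predictors = c("pred_1", "pred_2", "pred_3",
                                             "pred_4")) {
  if (!is_count(abs(seed))) stop_config("seed must be a single integer")
  cfg <- list(
    seed = as.integer(seed),
    n_discovery_cases = check_count(n_discovery_cases, "n_discovery_cases"),
    n_replication_cases = check_count(n_replication_cases,
                                      "n_replication_cases"),
    n_controls = check_count(n_controls, "n_controls"),
    causal_gene = as.character(causal_gene),
    n_causal_sites = check_count(n_causal_sites, "n_causal_sites",
                                 positive = TRUE),
    case_carrier_freq = check_fraction(case_carrier_freq, "case_carrier_freq"),
    control_carrier_freq = check_fraction(control_carrier_freq,
                                          "control_carrier_freq"),
    n_background_genes = check_count(n_background_genes, "n_background_genes",
                                     positive = TRUE),
    background_hit_rate = background_hit_rate,
    background_reject_rate = background_reject_rate,
    lung_expressed_fraction = check_fraction(lung_expressed_fraction,
                                             "lung_expressed_fraction"),
    n_common_snps = check_count(n_common_snps, "n_common_snps"),
    common_maf_range = as.numeric(common_maf_range),
    n_related_pairs = n_related_pairs,
    pvr_effect = as.numeric(pvr_effect),
    ci_effect = as.numeric(ci_effect),
    baseline_means_sds = baseline_means_sds %||% default_baselines(),
    noise_sd = as.numeric(noise_sd),
    panels = as.character(panels),
    predictors = as.character(predictors)
  )
  if (cfg$background_hit_rate < 0 || cfg$background_reject_rate < 0)
    stop_config("background rates must be non-negative")
  if (cfg$noise_sd < 0) stop_config("noise_sd must be non-negative")
  if (length(cfg$common_maf_range) != 2L ||
      any(cfg$common_maf_range <= 0) || any(cfg$common_maf_range > 0.5) ||
      diff(cfg$common_maf_range) < 0)
    stop_config("common_maf_range must be an increasing interval in (0, 0.5]")
  req <- c("duplicate", "first", "second")
  if (!all(req %in% names(cfg$n_related_pairs)))
    stop_config("n_related_pairs must be named duplicate/first/second")
  cfg$n_related_pairs <-
    vapply(cfg$n_related_pairs[req], check_count, integer(1),
           name = "n_related_pairs")
  n_subjects <- cfg$n_discovery_cases + cfg$n_replication_cases +
    cfg$n_controls
  if (n_subjects == 0L) stop_config("cohort has zero subjects")
  if (cfg$n_causal_sites + cfg$n_common_snps == 0L)
    stop_config("cohort has zero sites")
  n_pairs <- sum(cfg$n_related_pairs)
  if (n_pairs > min(cfg$n_discovery_cases + cfg$n_replication_cases,
                    cfg$n_controls))
    stop_config("more related pairs requested than available case/control ",
                "subjects")
  if (length(cfg$panels) < 1L) stop_config("at least one panel is required")
  bm <- cfg$baseline_means_sds
  need <- c("mPAP", "PAWP", "PVR", "cardiac_index", "RAP", "SvO2")
  if (!all(need %in% names(bm)))
    stop_config("baseline_means_sds must name: ", paste(need, collapse = ", "))
  structure(cfg, class = "sim_config")
}

# Baseline hemodynamic means/SDs pooled across the two case arms.
default_baselines <- function() {
  list(mPAP = c(61, 17), PAWP = c(8.4, 4.2), PVR = c(15.3, 8.5),
       cardiac_index = c(2.6, 1.1), RAP = c(7.6, 5.9), SvO2 = c(63, 13))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic IPAH cohort configuration\n")
  cat(sprintf("  seed: %d\n", x$seed))
  cat(sprintf("  cases: %d discovery + %d replication; controls: %d\n",
              x$n_discovery_cases, x$n_replication_cases, x$n_controls))
  cat(sprintf("  causal gene %s: carrier freq %.3f (cases) / %.3f (controls)\n",
              x$causal_gene, x$case_carrier_freq, x$control_carrier_freq))
  cat(sprintf("  background: %g qualifying + %g rejected hits/genome over %d genes\n",
              x$background_hit_rate, x$background_reject_rate,
              x$n_background_genes))
  cat(sprintf("  kinship SNPs: %d (MAF %.2f-%.2f); related pairs: %s\n",
              x$n_common_snps, x$common_maf_range[1], x$common_maf_range[2],
              paste(names(x$n_related_pairs), x$n_related_pairs,
                    sep = "=", collapse = " ")))
  cat(sprintf("  vasoresponse effects: PVR %+.1f, cardiac index %+.1f (noise SD %.1f)\n",
              x$pvr_effect, x$ci_effect, x$noise_sd))
  invisible(x)
}
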