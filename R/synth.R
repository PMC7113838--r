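#' Generate a synthetic two-stage IPAH case-control cohort
#'
#' Produces a complete, seeded set of study inputs with the statistical
#' structure the downstream analysis assumes:
#'
#' * a subject table (discovery cases, replication cases, controls, with age
#'   and sex);
#' * an annotated variant table and a subjects-by-sites genotype matrix
#'   (0/1/2 dosages). Causal-gene carriers are planted heterozygous at
#'   exactly one causal-gene site, at the configured case/control carrier
#'   frequencies. Background rare variants are Poisson-scattered over the
#'   discovery-arm genomes only (the replication and control arms are
#'   genotyped at the candidate gene alone, as in a Sanger-validation
#'   design), so most background-hit genes are singletons. A configurable
#'   number of background variants fail the candidate filter (common in a
#'   panel, present in the Chinese reference subset, or not consensus
#'   deleterious), giving the filter true negatives;
#' * common biallelic SNPs in Hardy-Weinberg equilibrium at drawn MAFs for
#'   kinship QC, with optional related (case, control) pairs constructed by
#'   gamete sharing (expected kinship 0.5 / 0.25 / 0.125 for
#'   duplicate / first / second degree);
#' * a gene-to-tissue expression table (the causal gene is always
#'   lung-expressed);
#' * paired pre/post vasodilator hemodynamic records for all cases, with
#'   genotype-dependent percent changes (see [simulate_hemodynamics()]);
#' * a `truth` component: the planted carrier roster, planted relative
#'   pairs, and the true response effects.
#'
#' @param config A [simulation_config()] object.
#' @return An object of class `"synthetic_cohort"`: a list with elements
#'   `subjects`, `variants`, `genotypes`, `expression`, `hemodynamics`,
#'   `truth`, `config`.
#' @examples
#' cohort <- generate_cohort(simulation_config(seed = 1, n_common_snps = 100))
#' table(cohort$subjects$group)
#' @seealso [write_cohort()], [read_cohort()], [discover_candidates()]
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_config("config must be created by simulation_config()")
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n_cases <- cfg$n_discovery_cases + cfg$n_replication_cases
  n_subj <- n_cases + cfg$n_controls

  ## ---- subjects -----------------------------------------------------------
  case_ids <- sprintf("P%04d", seq_len(n_cases))
  ctrl_ids <- sprintf("C%04d", seq_len(cfg$n_controls))
  subject_id <- c(case_ids, ctrl_ids)
  cohort_lab <- c(rep("discovery", cfg$n_discovery_cases),
                  rep("replication", cfg$n_replication_cases),
                  rep("control", cfg$n_controls))
  age <- numeric(n_subj)
  idx_disc <- which(cohort_lab == "discovery")
  idx_repl <- which(cohort_lab == "replication")
  idx_ctrl <- which(cohort_lab == "control")
  age[idx_disc] <- pmin(pmax(round(rnorm(length(idx_disc), 23, 10)), 2), 75)
  age[idx_repl] <- pmin(pmax(round(rnorm(length(idx_repl), 37, 18)), 2), 75)
  age[idx_ctrl] <- pmin(pmax(round(rnorm(length(idx_ctrl), 40, 13)), 18), 75)
  sex <- character(n_subj)
  sex[seq_len(n_cases)] <- ifelse(rbinom(n_cases, 1, 0.71) == 1, "F", "M")
  sex[idx_ctrl] <- ifelse(rbinom(cfg$n_controls, 1, 0.5) == 1, "F", "M")
  subjects <- data.frame(
    subject_id = subject_id,
    group = c(rep("case", n_cases), rep("control", cfg$n_controls)),
    cohort = cohort_lab,
    age = as.integer(age),
    sex = sex,
    stringsAsFactors = FALSE
  )

  ## ---- causal-gene sites --------------------------------------------------
  n_cs <- cfg$n_causal_sites
  causal_sites <- data.frame(
    site_id = sprintf("%s_rv%d", cfg$causal_gene, seq_len(n_cs)),
    gene = cfg$causal_gene,
    chrom = "20",
    consequence = c("splice", rep("missense", n_cs - 1L)),
    stringsAsFactors = FALSE
  )
  causal_freqs <- matrix(10^runif(n_cs * length(cfg$panels), -6, -3.5),
                         nrow = n_cs)
  causal_freqs[1L, ] <- 0  # the splice variant is novel in every panel
  causal_tab <- build_variant_rows(causal_sites, causal_freqs,
                                   in_chinese = rep(FALSE, n_cs),
                                   flags = matrix(TRUE, n_cs,
                                                  length(cfg$predictors)),
                                   class = "candidate", cfg = cfg)

  ## ---- causal carriers ----------------------------------------------------
  case_carrier <- rbinom(n_cases, 1, cfg$case_carrier_freq) == 1
  ctrl_carrier <- rbinom(cfg$n_controls, 1, cfg$control_carrier_freq) == 1
  # Recurrent missense sites dominate; splice-site carriers are rare and
  # absent from controls (splicing variants are typically case-private).
  site_w <- if (n_cs > 1L) c(1, rep(6.5, n_cs - 1L)) else 1
  case_site <- if (any(case_carrier))
    sample.int(n_cs, sum(case_carrier), replace = TRUE, prob = site_w)
  else integer(0)
  ctrl_site <- if (any(ctrl_carrier)) {
    if (n_cs > 1L)
      1L + sample.int(n_cs - 1L, sum(ctrl_carrier), replace = TRUE)
    else rep(1L, sum(ctrl_carrier))
  } else integer(0)

  ## ---- background rare variation (discovery genomes only) -----------------
  n_hits <- rpois(cfg$n_discovery_cases, cfg$background_hit_rate)
  hit_case_row <- rep(idx_disc, n_hits)
  K <- length(hit_case_row)
  hit_gene <- sprintf("BG%05d",
                      sample.int(cfg$n_background_genes, K, replace = TRUE))
  bg_sites <- data.frame(
    site_id = sprintf("bg_q%05d", seq_len(K)),
    gene = hit_gene,
    chrom = as.character(sample.int(22L, K, replace = TRUE)),
    consequence = rep("missense", K),
    stringsAsFactors = FALSE
  )
  bg_freqs <- matrix(10^runif(K * length(cfg$panels), -6, log10(0.0045)),
                     nrow = K, ncol = length(cfg$panels))
  bg_tab <- build_variant_rows(bg_sites, bg_freqs,
                               in_chinese = rep(FALSE, K),
                               flags = matrix(TRUE, K,
                                              length(cfg$predictors)),
                               class = "candidate", cfg = cfg)

  n_rej <- rpois(cfg$n_discovery_cases, cfg$background_reject_rate)
  rej_case_row <- rep(idx_disc, n_rej)
  K2 <- length(rej_case_row)
  rej <- build_rejected_sites(K2, cfg)

  ## ---- common SNPs for kinship -------------------------------------------
  mafs <- runif(cfg$n_common_snps, cfg$common_maf_range[1],
                cfg$common_maf_range[2])
  common_sites <- data.frame(
    site_id = sprintf("snp%05d", seq_len(cfg$n_common_snps)),
    gene = rep("", cfg$n_common_snps),
    chrom = as.character(sample.int(22L, cfg$n_common_snps, replace = TRUE)),
    consequence = rep("other", cfg$n_common_snps),
    stringsAsFactors = FALSE
  )
  common_tab <- build_variant_rows(
    common_sites, matrix(rep(mafs, length(cfg$panels)),
                         nrow = cfg$n_common_snps, ncol = length(cfg$panels)),
    in_chinese = rep(TRUE, cfg$n_common_snps),
    flags = matrix(FALSE, cfg$n_common_snps, length(cfg$predictors)),
    class = "common", cfg = cfg)

  variants <- rbind(causal_tab, bg_tab, rej$table, common_tab)
  variants$pos <- 10000L + seq_len(nrow(variants)) * 137L
  refalt <- draw_ref_alt(nrow(variants))
  variants$ref <- refalt$ref
  variants$alt <- refalt$alt
  variants <- variants[, c("site_id", "gene", "chrom", "pos", "ref", "alt",
                           "class", "consequence",
                           paste0("freq_", cfg$panels), "in_chinese_1kg",
                           paste0("del_", cfg$predictors))]

  ## ---- genotype matrix ----------------------------------------------------
  n_sites <- nrow(variants)
  G <- matrix(0L, n_subj, n_sites,
              dimnames = list(subject_id, variants$site_id))
  col_of <- setNames(seq_len(n_sites), variants$site_id)

  carrier_rows <- c(which(case_carrier), n_cases + which(ctrl_carrier))
  carrier_sites <- causal_tab$site_id[c(case_site, ctrl_site)]
  if (length(carrier_rows))
    G[cbind(carrier_rows, col_of[carrier_sites])] <- 1L
  if (K) G[cbind(hit_case_row, col_of[bg_sites$site_id])] <- 1L
  if (K2) G[cbind(rej_case_row, col_of[rej$table$site_id])] <- 1L
  if (cfg$n_common_snps > 0L) {
    common_cols <- col_of[common_tab$site_id]
    G[, common_cols] <- matrix(
      rbinom(n_subj * cfg$n_common_snps, 2L, rep(mafs, each = n_subj)),
      nrow = n_subj)
  }

  ## ---- planted relative pairs (case x control, common SNPs) --------------
  related <- data.frame(case_id = character(0), control_id = character(0),
                        degree = character(0), expected_phi = numeric(0),
                        stringsAsFactors = FALSE)
  if (sum(cfg$n_related_pairs) > 0L && cfg$n_common_snps > 0L) {
    common_cols <- col_of[common_tab$site_id]
    pair_i <- 0L
    for (deg in c("duplicate", "first", "second")) {
      for (k in seq_len(cfg$n_related_pairs[[deg]])) {
        pair_i <- pair_i + 1L
        case_row <- pair_i
        ctrl_row <- n_cases + pair_i
        g_case <- G[case_row, common_cols]
        G[ctrl_row, common_cols] <- switch(
          deg,
          duplicate = g_case,
          first = gamete_child(g_case, mafs),
          second = gamete_child(gamete_child(g_case, mafs), mafs))
        related <- rbind(related, data.frame(
          case_id = subject_id[case_row], control_id = subject_id[ctrl_row],
          degree = deg,
          expected_phi = c(duplicate = 0.5, first = 0.25, second = 0.125)[[deg]],
          stringsAsFactors = FALSE))
      }
    }
  }

  ## ---- expression labels --------------------------------------------------
  expression <- build_expression(cfg)

  ## ---- hemodynamics -------------------------------------------------------
  hemodynamics <- simulate_hemodynamics(case_ids, case_carrier, cfg)

  ## ---- truth --------------------------------------------------------------
  truth_carriers <- data.frame(
    subject_id = subject_id[carrier_rows],
    group = subjects$group[carrier_rows],
    gene = rep(cfg$causal_gene, length(carrier_rows)),
    site_id = carrier_sites,
    stringsAsFactors = FALSE
  )
  truth_carriers <- truth_carriers[order(truth_carriers$subject_id), ,
                                   drop = FALSE]
  rownames(truth_carriers) <- NULL

  structure(list(
    subjects = subjects,
    variants = variants,
    genotypes = G,
    expression = expression,
    hemodynamics = hemodynamics,
    truth = list(carriers = truth_carriers, related_pairs = related,
                 effects = list(pvr_effect = cfg$pvr_effect,
                                ci_effect = cfg$ci_effect)),
    config = cfg
  ), class = "synthetic_cohort")
}

# One random transmitted gamete plus one population allele: expected kinship
# between g and the returned vector is half the kinship of g with itself.
gamete_child <- function(g, mafs) {
  rbinom(length(g), 1L, g / 2) + rbinom(length(g), 1L, mafs)
}

draw_ref_alt <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- bases[sample.int(4L, n, replace = TRUE)]
  alt <- bases[1L + (match(ref, bases) - 1L + sample.int(3L, n, replace = TRUE)) %% 4L]
  list(ref = ref, alt = alt)
}

build_variant_rows <- function(sites, freqs, in_chinese, flags, class, cfg) {
  out <- sites
  colnames(freqs) <- paste0("freq_", cfg$panels)
  out <- cbind(out, as.data.frame(freqs))
  out$in_chinese_1kg <- in_chinese
  colnames(flags) <- paste0("del_", cfg$predictors)
  out <- cbind(out, as.data.frame(flags))
  out$class <- rep(class, nrow(out))
  out
}

# Background variants that must fail the candidate filter: one of
#  - "common":   at least one panel frequency in [0.5%, 5%)
#  - "chinese":  rare everywhere but present in the Chinese reference subset
#  - "benign":   rare and absent, but not consensus-deleterious
build_rejected_sites <- function(K2, cfg) {
  np <- length(cfg$panels)
  sites <- data.frame(
    site_id = sprintf("bg_r%05d", seq_len(K2)),
    gene = sprintf("BG%05d",
                   sample.int(cfg$n_background_genes, K2, replace = TRUE)),
    chrom = as.character(sample.int(22L, K2, replace = TRUE)),
    consequence = sample(c("missense", "other"), K2, replace = TRUE,
                         prob = c(0.7, 0.3)),
    stringsAsFactors = FALSE
  )
  if (K2 == 0L) {
    tab <- build_variant_rows(sites, matrix(numeric(0), 0, np),
                              logical(0), matrix(logical(0), 0,
                                                 length(cfg$predictors)),
                              class = "candidate", cfg = cfg)
    return(list(table = tab))
  }
  type <- sample(c("common", "chinese", "benign"), K2, replace = TRUE)
  freqs <- matrix(10^runif(K2 * np, -6, log10(0.0045)), nrow = K2, ncol = np)
  is_common <- type == "common"
  if (any(is_common)) {
    hot_panel <- sample.int(np, sum(is_common), replace = TRUE)
    freqs[cbind(which(is_common), hot_panel)] <-
      10^runif(sum(is_common), log10(0.005), log10(0.05))
  }
  flags <- matrix(TRUE, K2, length(cfg$predictors))
  is_benign <- type == "benign"
  if (any(is_benign)) {
    fl <- matrix(rbinom(sum(is_benign) * length(cfg$predictors), 1, 0.5) == 1,
                 nrow = sum(is_benign))
    fl[cbind(seq_len(nrow(fl)),
             sample.int(ncol(fl), nrow(fl), replace = TRUE))] <- FALSE
    flags[is_benign, ] <- fl
  }
  list(table = build_variant_rows(sites, freqs,
                                  in_chinese = type == "chinese",
                                  flags = flags, class = "candidate",
                                  cfg = cfg))
}

build_expression <- function(cfg) {
  genes <- c(cfg$causal_gene,
             sprintf("BG%05d", seq_len(cfg$n_background_genes)))
  n <- length(genes)
  lung <- c(TRUE, runif(n - 1L) < cfg$lung_expressed_fraction)
  others <- c("heart", "liver", "kidney", "brain", "muscle")
  t1 <- others[sample.int(5L, n, replace = TRUE)]
  t2 <- others[sample.int(5L, n, replace = TRUE)]
  tissues <- ifelse(lung, paste("lung", t1, sep = ";"),
                    ifelse(t1 == t2, t1, paste(t1, t2, sep = ";")))
  data.frame(gene = genes, tissues = tissues, stringsAsFactors = FALSE)
}

#' Simulate paired pre/post vasodilator hemodynamics
#'
#' Draws baseline hemodynamics from the configured means/SDs (truncated to
#' physiologically admissible precapillary-PH ranges) and post-vasodilator
#' values via percent changes of the form
#' `group mean + genotype effect + baseline-linked term + Gaussian noise`,
#' the generative model matched to the baseline-adjusted linear analysis in
#' [genotype_response_model()]. Only pulmonary vascular resistance (true
#' carrier effect `config$pvr_effect`, baseline slope -0.4 points per Wood
#' unit around the configured mean) and cardiac index (true effect
#' `config$ci_effect`, baseline slope -6 points per L/min/m\eqn{^2}) carry
#' genotype effects; the remaining variables change by genotype-independent
#' amounts.
#'
#' @param subject_ids Character vector of subject identifiers.
#' @param carrier Logical vector, one per subject: causal-gene carrier?
#' @param config A [simulation_config()] object (effect sizes, baseline
#'   means/SDs, noise SD).
#' @param seed Optional seed; omit when calling from already-seeded code.
#' @return A long-format data frame with columns `subject_id`,
#'   `phase` (`"baseline"` / `"post_iloprost"`), `mPAP`, `PAWP`, `PVR`,
#'   `cardiac_index`, `RAP`, `SvO2`.
#' @examples
#' cfg <- simulation_config(seed = 5)
#' hd <- simulate_hemodynamics(c("a", "b", "c"), c(TRUE, FALSE, FALSE),
#'                             cfg, seed = 5)
#' @export
simulate_hemodynamics <- function(subject_ids, carrier, config, seed = NULL) {
  stopifnot(length(subject_ids) == length(carrier))
  if (!is.null(seed)) return(with_seed(seed, simulate_hemodynamics(
    subject_ids, carrier, config)))
  n <- length(subject_ids)
  bm <- config$baseline_means_sds
  draw <- function(v, lo, hi) pmin(pmax(rnorm(n, bm[[v]][1], bm[[v]][2]), lo), hi)
  base <- data.frame(
    mPAP = draw("mPAP", 26, 120),
    PAWP = draw("PAWP", 1, 15),
    PVR = draw("PVR", 3.2, 60),
    cardiac_index = draw("cardiac_index", 0.8, 8),
    RAP = draw("RAP", 0.5, 30),
    SvO2 = draw("SvO2", 20, 90)
  )
  carrier <- as.numeric(carrier)
  clamp <- function(p) pmax(p, -95)
  pct <- data.frame(
    mPAP = clamp(-12 + rnorm(n, 0, 8)),
    PAWP = clamp(rnorm(n, 0, 10)),
    PVR = clamp(-15 + config$pvr_effect * carrier -
                  0.4 * (base$PVR - bm$PVR[1]) + rnorm(n, 0, config$noise_sd)),
    cardiac_index = clamp(10 + config$ci_effect * carrier -
                            6 * (base$cardiac_index - bm$cardiac_index[1]) +
                            rnorm(n, 0, config$noise_sd)),
    RAP = clamp(rnorm(n, 0, 10)),
    SvO2 = clamp(4 + rnorm(n, 0, 5))
  )
  post <- base * (1 + pct / 100)
  out <- rbind(
    cbind(data.frame(subject_id = subject_ids, phase = "baseline",
                     stringsAsFactors = FALSE), base),
    cbind(data.frame(subject_id = subject_ids, phase = "post_iloprost",
                     stringsAsFactors = FALSE), post)
  )
  rownames(out) <- NULL
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- table(x$subjects$group)
  cat("Synthetic IPAH cohort (seed ", x$config$seed, ")\n", sep = "")
  cat(sprintf("  subjects: %d cases (%d discovery / %d replication), %d controls\n",
              n[["case"]], sum(x$subjects$cohort == "discovery"),
              sum(x$subjects$cohort == "replication"), n[["control"]]))
  cat(sprintf("  sites: %d (%d candidate, %d common)\n", nrow(x$variants),
              sum(x$variants$class == "candidate"),
              sum(x$variants$class == "common")))
  cat(sprintf("  planted %s carriers: %d cases, %d controls\n",
              x$config$causal_gene,
              sum(x$truth$carriers$group == "case"),
              sum(x$truth$carriers$group == "control")))
  if (nrow(x$truth$related_pairs))
    cat(sprintf("  planted related pairs: %d\n", nrow(x$truth$related_pairs)))
  invisible(x)
}
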