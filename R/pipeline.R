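#' Run the full two-stage study pipeline
#'
#' Orchestrates the analysis end to end on either a synthetic cohort
#' (generated from `config`) or a cohort directory:
#'
#' 1. known-PAH-gene exclusion screen on all cases (flagged subjects are
#'    excluded from later stages, mirroring an idiopathic-cohort design);
#' 2. kinship QC: KING-robust between-group summary on the common SNPs,
#'    aborting (unless `qc_override`) when any case-control pair reaches
#'    `kinship_threshold`;
#' 3. discovery-stage candidate filtering and gene prioritization on the
#'    discovery arm only;
#' 4. pooled case-control association for the validation gene (per-site and
#'    combined carrier tables, Wald odds ratios, logistic p-values);
#' 5. discovery-vs-replication consistency and pediatric-vs-adult subgroup
#'    comparisons (continuity-adjusted chi-square);
#' 6. genotype-stratified vasoreactivity analysis (baseline-adjusted
#'    LS-mean differences for PVR and cardiac index).
#'
#' The discovery stage uses the discovery arm alone; association pools both
#' case arms against controls, as a replication design requires.
#'
#' @param config A [simulation_config()] (ignored when `input_dir` is
#'   given).
#' @param input_dir Optional cohort directory from [write_cohort()];
#'   exactly one input source is used.
#' @param output_dir Optional directory: every table is written as a
#'   seed-stamped TSV plus a JSON bundle.
#' @param criteria A [filter_criteria()].
#' @param kinship_threshold QC threshold on between-group kinship
#'   (default 0.0884).
#' @param qc_override Continue past a kinship QC failure (default `FALSE`).
#' @param validation_gene Gene taken forward to association; default the
#'   top expressed gene of the discovery priority list.
#' @param match_ratio Matched non-carriers per carrier in the
#'   vasoreactivity stage (default 3).
#' @param pediatric_age_max Upper age (exclusive) of the pediatric subgroup
#'   (default 18).
#' @param verbose Log stage-by-stage counts (default `TRUE`).
#' @return An object of class `"study_report"`: list with `seed`, `tables`
#'   (named list: `known_gene_screen`, `kinship`, `gene_priority`,
#'   `association`, `consistency`, `subgroup`, `vasoresponse`), `funnel`
#'   (filter count trail), `validation_gene`, `qc`, `cohort`.
#' @examples
#' \donttest{
#' rep <- run_study(simulation_config(seed = 1, n_common_snps = 500),
#'                  verbose = FALSE)
#' rep$tables$association
#' }
#' @export
run_study <- function(config = simulation_config(),
                      input_dir = NULL,
                      output_dir = NULL,
                      criteria = filter_criteria(),
                      kinship_threshold = 0.0884,
                      qc_override = FALSE,
                      validation_gene = NULL,
                      match_ratio = 3L,
                      pediatric_age_max = 18,
                      verbose = TRUE) {
  log_msg <- function(...) if (verbose) message("[pahburden] ", ...)

  cohort <- if (!is.null(input_dir)) {
    log_msg("reading cohort from ", input_dir)
    read_cohort(input_dir)
  } else {
    log_msg("generating synthetic cohort (seed ", config$seed, ")")
    generate_cohort(config)
  }
  seed <- cohort$config$seed
  tables <- list()

  ## stage 1: known-gene exclusion screen -----------------------------------
  screen <- screen_known_pah_genes(cohort, criteria = criteria)
  tables$known_gene_screen <- screen
  excluded <- unique(screen$subject_id)
  log_msg("known-gene screen: ", length(excluded), " case(s) flagged")
  subjects <- cohort$subjects
  keep_cases <- subjects$group == "case" &
    !subjects$subject_id %in% excluded

  ## stage 2: kinship QC ------------------------------------------------------
  common_sites <- cohort$variants$site_id[cohort$variants$class == "common"]
  qc <- NULL
  if (length(common_sites) >= 2L) {
    grp <- setNames(subjects$group, subjects$subject_id)
    qc <- cohort_relatedness_summary(
      cohort$genotypes[, common_sites, drop = FALSE], grp,
      threshold = kinship_threshold)
    tables$kinship <- data.frame(
      n_pairs = qc$n_pairs, fraction_below = qc$fraction_below,
      threshold = qc$threshold, max_phi = qc$max_phi,
      max_pair_i = qc$max_pair[1], max_pair_j = qc$max_pair[2],
      stringsAsFactors = FALSE)
    log_msg(sprintf("kinship QC: %.4f%% of %d pairs below %.4f (max phi %.4f)",
                    100 * qc$fraction_below, qc$n_pairs, qc$threshold,
                    qc$max_phi))
    if (nrow(qc$offending) && !qc_override) {
      if (!is.null(output_dir))
        write_report_tables(tables, seed, output_dir)
      stop(errorCondition(
        paste0("kinship QC failed: ", nrow(qc$offending),
               " between-group pair(s) at phi >= ", kinship_threshold,
               " (max ", signif(qc$max_phi, 3),
               "); partial report written. Use qc_override = TRUE to proceed."),
        class = c("pahburden_qc_error", "error")))
    }
  } else log_msg("kinship QC skipped: no common SNPs in cohort")

  ## stage 3: discovery-arm gene prioritization -----------------------------
  disc_ids <- subjects$subject_id[keep_cases &
                                    subjects$cohort == "discovery"]
  map <- discover_candidates(cohort, criteria, subjects = disc_ids)
  pri <- prioritize_genes(map, criteria, cohort$expression)
  tables$gene_priority <- pri
  funnel <- data.frame(
    stage = c("qualifying_variant_hits", "candidate_genes",
              "singleton_genes", "shared_genes", "shared_expressed_genes"),
    count = c(nrow(map$pairs), length(map$carrier_counts),
              sum(map$carrier_counts == 1L), nrow(pri),
              sum(pri$expressed)),
    stringsAsFactors = FALSE)
  log_msg("discovery funnel: ",
          paste(funnel$stage, funnel$count, sep = "=", collapse = ", "))

  ## stage 4: pooled association ---------------------------------------------
  gene <- validation_gene %||%
    (if (any(pri$expressed)) pri$gene[pri$expressed][1] else NA_character_)
  tables$association <- data.frame()
  tables$consistency <- data.frame()
  tables$subgroup <- data.frame()
  tables$vasoresponse <- data.frame()
  vaso <- NULL
  if (is.na(gene)) {
    log_msg("no expressed shared gene to validate; association skipped")
  } else {
    log_msg("validation gene: ", gene)
    grp <- setNames(subjects$group, subjects$subject_id)
    grp <- grp[keep_cases | subjects$group == "control"]
    v <- cohort$variants
    gene_sites <- v$site_id[v$gene == gene & qualify_variants(v, criteria)]
    site_rows <- lapply(gene_sites, function(s)
      association_row(cohort, site = s, groups = grp, criteria = criteria))
    comb <- association_row(cohort, gene = gene, groups = grp,
                            criteria = criteria)
    comb$variant <- "combined"
    assoc_tab <- rbind(do.call(rbind, site_rows), comb)
    assoc_tab <- assoc_tab[assoc_tab$cases_carriers > 0 |
                             assoc_tab$variant == "combined", , drop = FALSE]
    rownames(assoc_tab) <- NULL
    tables$association <- assoc_tab

    ## stage 5: consistency and subgroup comparisons ------------------------
    case_tab <- subjects[keep_cases, , drop = FALSE]
    carrier <- gene_carrier_flags(cohort, gene, case_tab$subject_id, criteria)
    disc <- case_tab$cohort == "discovery"
    ct <- contingency_table(sum(carrier & disc), sum(!carrier & disc),
                            sum(carrier & !disc), sum(!carrier & !disc),
                            groups = c("discovery", "replication"),
                            exposure = gene)
    cons <- try_yates(ct)
    tables$consistency <- data.frame(
      comparison = "discovery_vs_replication",
      carriers_1 = ct$a, n_1 = ct$a + ct$b,
      carriers_2 = ct$c, n_2 = ct$c + ct$d,
      chi2 = cons$statistic, p_value = cons$p_value,
      stringsAsFactors = FALSE)

    ped <- case_tab$age < pediatric_age_max
    st <- contingency_table(sum(carrier & ped), sum(!carrier & ped),
                            sum(carrier & !ped), sum(!carrier & !ped),
                            groups = c("pediatric", "adult"),
                            exposure = gene)
    sub <- try_yates(st)
    tables$subgroup <- data.frame(
      comparison = "pediatric_vs_adult",
      carriers_1 = st$a, n_1 = st$a + st$b,
      carriers_2 = st$c, n_2 = st$c + st$d,
      chi2 = sub$statistic, p_value = sub$p_value,
      stringsAsFactors = FALSE)

    ## stage 6: vasoreactivity ----------------------------------------------
    vaso <- tryCatch(
      vasoresponse_analysis(cohort, gene, criteria, ratio = match_ratio),
      error = function(e) {
        log_msg("vasoreactivity stage skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(vaso)) {
      tables$vasoresponse <- do.call(rbind, lapply(vaso$models, function(m)
        data.frame(outcome = m$outcome,
                   ls_mean_difference = m$ls_mean_difference,
                   ci_low = m$ci_low, ci_high = m$ci_high,
                   p_value = m$p_value, n_carriers = m$n_carriers,
                   n_noncarriers = m$n_noncarriers,
                   stringsAsFactors = FALSE)))
      rownames(tables$vasoresponse) <- NULL
    }
  }

  report <- structure(list(seed = seed, tables = tables, funnel = funnel,
                           validation_gene = gene, qc = qc,
                           vasoresponse = vaso, cohort = cohort),
                      class = "study_report")
  if (!is.null(output_dir)) {
    write_report_tables(tables, seed, output_dir, funnel = funnel,
                        config = cohort$config)
    log_msg("report written to ", output_dir)
  }
  report
}

# Yates chi-square that degrades to NA instead of erroring on a zero margin
# (e.g. a validation gene with no carriers in one subgroup).
try_yates <- function(ct) {
  tryCatch(yates_chi2(ct),
           error = function(e) list(statistic = NA_real_,
                                    p_value = NA_real_))
}

gene_carrier_flags <- function(cohort, gene, ids, criteria) {
  v <- cohort$variants
  sites <- v$site_id[v$gene == gene & qualify_variants(v, criteria)]
  G <- cohort$genotypes[ids, sites, drop = FALSE]
  rowSums(!is.na(G) & G == 1L) > 0L
}

association_row <- function(cohort, gene = NULL, site = NULL, groups,
                            criteria) {
  tab <- carrier_table(cohort, gene = gene, site = site, groups = groups,
                       level_order = c("case", "control"),
                       criteria = criteria)
  or <- odds_ratio_wald(tab)
  lg <- logistic_single_predictor(tab)
  pc <- frequency_report(tab)
  data.frame(variant = if (!is.null(site)) site else gene,
             cases_carriers = tab$a, cases_n = tab$a + tab$b,
             cases_pct = pc[[1]],
             controls_carriers = tab$c, controls_n = tab$c + tab$d,
             controls_pct = pc[[2]],
             or = or$or_estimate, ci_low = or$ci_low, ci_high = or$ci_high,
             p_logistic = lg$p_value,
             estimable = or$estimable,
             stringsAsFactors = FALSE)
}

write_report_tables <- function(tables, seed, dir, funnel = NULL,
                                config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  emit <- function(df, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(c("# pahburden study report",
                 paste0("# seed: ", seed),
                 paste0("# table: ", name)), con)
    if (is.data.frame(df) && nrow(df))
      write.table(format_doubles(df), con, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    else writeLines("# (empty)", con)
    close(con)
  }
  for (nm in names(tables)) emit(tables[[nm]], nm)
  if (!is.null(funnel)) emit(funnel, "funnel")
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$n_related_pairs <- as.list(cfg$n_related_pairs)
    yaml::write_yaml(cfg, file.path(dir, "config_echo.yaml"), precision = 17L)
  }
  json <- lapply(tables, function(df)
    if (is.data.frame(df)) df else as.data.frame(df))
  jsonlite::write_json(c(list(seed = seed), json),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("pahburden study report (seed ", x$seed, ")\n", sep = "")
  cat("  funnel: ", paste(x$funnel$stage, x$funnel$count, sep = "=",
                          collapse = ", "), "\n", sep = "")
  if (!is.na(x$validation_gene)) {
    cat("  validation gene: ", x$validation_gene, "\n", sep = "")
    if (nrow(x$tables$association)) {
      comb <- x$tables$association[x$tables$association$variant == "combined", ]
      if (nrow(comb) && comb$estimable)
        cat(sprintf("  combined burden: %d/%d cases vs %d/%d controls, OR %.1f (%.1f-%.1f)\n",
                    comb$cases_carriers, comb$cases_n, comb$controls_carriers,
                    comb$controls_n, comb$or, comb$ci_low, comb$ci_high))
    }
    if (nrow(x$tables$vasoresponse)) {
      for (i in seq_len(nrow(x$tables$vasoresponse))) {
        r <- x$tables$vasoresponse[i, ]
        cat(sprintf("  vasoresponse %s: LS-mean diff %+.1f (%.1f to %.1f)\n",
                    r$outcome, r$ls_mean_difference, r$ci_low, r$ci_high))
      }
    }
  }
  invisible(x)
}
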