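# Shared fixtures: all cohorts are generated in code, scaled down where the
# property under test does not depend on problem size.

small_config <- function(seed = 11, ...) {
  args <- list(seed = seed,
               n_discovery_cases = 10L, n_replication_cases = 15L,
               n_controls = 25L,
               background_hit_rate = 5, background_reject_rate = 4,
               n_common_snps = 50L, n_background_genes = 200L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

# Independent brute-force re-implementation of the discovery filter:
# explicit double loop over subject x site, re-deriving each rule from the
# variant table columns.
brute_force_candidates <- function(cohort, criteria, subjects) {
  v <- cohort$variants
  G <- cohort$genotypes
  freq_cols <- grep("^freq_", names(v), value = TRUE)
  del_cols <- grep("^del_", names(v), value = TRUE)
  out <- list()
  for (s in subjects) {
    for (k in seq_len(nrow(v))) {
      row <- v[k, ]
      if (row$gene == "") next
      g <- G[s, row$site_id]
      if (is.na(g) || g != 1L) next
      freqs <- as.numeric(row[freq_cols])
      freqs[is.na(freqs)] <- 0
      if (!all(freqs < criteria$maf_max)) next
      if (criteria$require_absent_chinese_panel && isTRUE(row$in_chinese_1kg))
        next
      flags <- as.logical(row[del_cols])
      ndel <- sum(flags, na.rm = TRUE)
      ok <- switch(criteria$deleterious_rule,
                   all = ndel == length(flags),
                   majority = ndel > length(flags) / 2,
                   any = ndel >= 1)
      if (!ok && row$consequence != "splice") next
      out[[length(out) + 1L]] <- data.frame(subject_id = s,
                                            site_id = row$site_id,
                                            gene = row$gene,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(subject_id = character(0), site_id = character(0),
                      gene = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$gene, res$subject_id, res$site_id), , drop = FALSE]
}

# A tiny hand-built cohort for targeted filter/association tests.
manual_cohort <- function(variants, genotypes, subjects = NULL,
                          expression = NULL) {
  if (is.null(subjects)) {
    subjects <- data.frame(
      subject_id = rownames(genotypes),
      group = ifelse(grepl("^P", rownames(genotypes)), "case", "control"),
      cohort = ifelse(grepl("^P", rownames(genotypes)), "discovery",
                      "control"),
      age = 30L, sex = "F", stringsAsFactors = FALSE)
  }
  structure(list(subjects = subjects, variants = variants,
                 genotypes = genotypes,
                 expression = expression %||%
                   data.frame(gene = unique(variants$gene),
                              tissues = "lung", stringsAsFactors = FALSE),
                 hemodynamics = data.frame(), truth = NULL,
                 config = simulation_config(seed = 1)),
            class = "synthetic_cohort")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Variant-table row builder with sensible defaults (rare, absent, damaging).
vrow <- function(site_id, gene, freqs = rep(0.0001, 4), chinese = FALSE,
                 flags = rep(TRUE, 4), consequence = "missense",
                 class = "candidate") {
  df <- data.frame(site_id = site_id, gene = gene, chrom = "1",
                   pos = 1000L, ref = "A", alt = "G", class = class,
                   consequence = consequence, stringsAsFactors = FALSE)
  for (i in 1:4) df[[paste0("freq_panel_", letters[i])]] <- freqs[i]
  df$in_chinese_1kg <- chinese
  for (i in 1:4) df[[paste0("del_pred_", i)]] <- flags[i]
  df
}
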