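#' Candidate-variant filter criteria
#'
#' The discovery-stage filter retains heterozygous variants that are rare in
#' every reference frequency panel (strictly below `maf_max`), absent from
#' the Chinese 1000 Genomes subset (when required), and predicted
#' deleterious. Deleteriousness is a consensus over boolean predictor
#' columns (`deleterious_rule`), except that splice-class variants are
#' deleterious by consequence regardless of the predictors — a canonical
#' donor-site change needs no missense predictor support. The dominant-model
#' zygosity rule (heterozygous carriers only) is fixed.
#'
#' @param maf_max Strict upper bound on every panel frequency
#'   (default 0.005, i.e. "less than 0.5\%").
#' @param require_absent_chinese_panel Require absence from the Chinese
#'   reference subset (default `TRUE`).
#' @param deleterious_rule One of `"all"`, `"majority"`, `"any"`: how many
#'   predictor flags must call the variant deleterious (default `"all"`,
#'   the strictest reading).
#' @param min_shared_carriers Minimum number of distinct carriers for a gene
#'   to be prioritized (default 3).
#' @param expression_tissue Tissue label used by the expression filter
#'   (default `"lung"`).
#' @return An object of class `"filter_criteria"`.
#' @export
filter_criteria <- function(maf_max = 0.005,
                            require_absent_chinese_panel = TRUE,
                            deleterious_rule = c("all", "majority", "any"),
                            min_shared_carriers = 3L,
                            expression_tissue = "lung") {
  if (!is.numeric(maf_max) || length(maf_max) != 1L || is.na(maf_max) ||
      maf_max < 0 || maf_max >= 1)
    stop_config("maf_max must be a fraction in [0, 1)")
  if (is.character(deleterious_rule) && length(deleterious_rule) >= 1L &&
      !all(deleterious_rule %in% c("all", "majority", "any")))
    stop_config("unknown deleterious_rule: ",
                paste(setdiff(deleterious_rule,
                              c("all", "majority", "any")), collapse = ", "))
  deleterious_rule <- match.arg(deleterious_rule)
  min_shared_carriers <- check_count(min_shared_carriers,
                                     "min_shared_carriers", positive = TRUE)
  structure(list(maf_max = maf_max,
                 require_absent_chinese_panel =
                   isTRUE(require_absent_chinese_panel),
                 deleterious_rule = deleterious_rule,
                 min_shared_carriers = min_shared_carriers,
                 expression_tissue = as.character(expression_tissue)),
            class = "filter_criteria")
}

#' Apply the candidate filter to a variant table
#'
#' Vectorised filter over the rows of a variant table. A variant qualifies
#' iff every panel frequency is strictly below `maf_max`, it is absent from
#' the Chinese reference subset when required, and the deleteriousness
#' consensus holds (splice-class variants are deleterious by consequence).
#' A missing (`NA`) panel frequency is treated as 0 — absence from a panel
#' is itself evidence of rarity — with a warning.
#'
#' @param variants Variant table with `freq_*` panel columns,
#'   `in_chinese_1kg`, `del_*` predictor columns and `consequence`.
#' @param criteria A [filter_criteria()] object.
#' @return Logical vector, one element per variant row.
#' @export
qualify_variants <- function(variants, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  freq_cols <- grep("^freq_", names(variants), value = TRUE)
  if (!length(freq_cols)) stop_data("variant table has no freq_* panel columns")
  fr <- as.matrix(variants[, freq_cols, drop = FALSE])
  if (anyNA(fr)) {
    warning("missing panel frequencies treated as 0 (absent from panel)",
            call. = FALSE)
    fr[is.na(fr)] <- 0
  }
  rare <- rowSums(fr < criteria$maf_max) == ncol(fr)
  absent <- if (criteria$require_absent_chinese_panel)
    !variants$in_chinese_1kg else TRUE
  del_cols <- grep("^del_", names(variants), value = TRUE)
  fl <- as.matrix(variants[, del_cols, drop = FALSE])
  n_del <- rowSums(fl, na.rm = TRUE)
  deleterious <- switch(criteria$deleterious_rule,
                        all = n_del == ncol(fl),
                        majority = n_del > ncol(fl) / 2,
                        any = n_del >= 1)
  deleterious <- deleterious | variants$consequence == "splice"
  rare & absent & deleterious
}

#' @rdname qualify_variants
#' @param site A single-row variant table (one site).
#' @export
qualify_variant <- function(site, criteria = filter_criteria()) {
  stopifnot(nrow(site) == 1L)
  qualify_variants(site, criteria)
}

#' Discover candidate (subject, site) pairs and their gene map
#'
#' Applies the candidate filter to the variant table, then collects every
#' (subject, site) pair where the subject is heterozygous (dosage exactly 1;
#' homozygous-alternate genotypes are excluded under the dominant model) at
#' a qualifying site, and groups the pairs by gene. Per-gene carrier counts
#' count each subject once, however many qualifying variants of that gene
#' it carries.
#'
#' @param cohort A cohort object (genotypes + aligned variant table).
#' @param criteria A [filter_criteria()] object.
#' @param subjects Character vector of subject ids to scan; default all
#'   case-labelled subjects.
#' @return An object of class `"gene_carrier_map"`: list with `pairs`
#'   (data frame `subject_id`, `site_id`, `gene`) and `carrier_counts`
#'   (named integer vector, distinct subjects per gene).
#' @export
discover_candidates <- function(cohort, criteria = filter_criteria(),
                                subjects = NULL) {
  G <- cohort$genotypes
  v <- cohort$variants
  if (!all(colnames(G) %in% v$site_id))
    stop_data("genotype matrix contains sites absent from the variant table: ",
              paste(head(setdiff(colnames(G), v$site_id)), collapse = ", "))
  v <- v[match(colnames(G), v$site_id), , drop = FALSE]
  if (is.null(subjects))
    subjects <- cohort$subjects$subject_id[cohort$subjects$group == "case"]
  if (!all(subjects %in% rownames(G)))
    stop_data("unknown subject ids requested")
  qual <- qualify_variants(v, criteria)
  qual[v$gene == ""] <- FALSE  # intergenic markers cannot form gene hits
  Gs <- G[subjects, qual, drop = FALSE]
  hit <- which(!is.na(Gs) & Gs == 1L, arr.ind = TRUE)
  pairs <- data.frame(
    subject_id = rownames(Gs)[hit[, 1L]],
    site_id = colnames(Gs)[hit[, 2L]],
    stringsAsFactors = FALSE
  )
  pairs$gene <- v$gene[match(pairs$site_id, v$site_id)]
  pairs <- pairs[order(pairs$gene, pairs$subject_id, pairs$site_id), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  counts <- if (nrow(pairs)) {
    cnt <- tapply(pairs$subject_id, pairs$gene,
                  function(s) length(unique(s)))
    setNames(as.integer(cnt), names(cnt))
  } else setNames(integer(0), character(0))
  structure(list(pairs = pairs, carrier_counts = counts,
                 n_subjects_scanned = length(subjects)),
            class = "gene_carrier_map")
}

#' @export
print.gene_carrier_map <- function(x, ...) {
  cat("Gene carrier map: ", nrow(x$pairs), " qualifying (subject, site) pairs",
      " in ", length(x$carrier_counts), " genes over ",
      x$n_subjects_scanned, " subjects\n", sep = "")
  if (length(x$carrier_counts)) {
    tab <- table(x$carrier_counts)
    cat("  genes by carrier count: ",
        paste(names(tab), tab, sep = "x", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Prioritize genes by shared carriers and tissue expression
#'
#' Keeps genes whose distinct-carrier count meets `min_shared_carriers`,
#' flags those expressed in `expression_tissue`, and orders by carrier count
#' (descending) with ties broken alphabetically. Genes missing from the
#' expression table are treated as not expressed, with a warning.
#'
#' @param map A [discover_candidates()] result.
#' @param criteria A [filter_criteria()] object.
#' @param expression Data frame with columns `gene` and `tissues`
#'   (`;`-separated labels).
#' @return Data frame with columns `gene`, `n_carriers`, `expressed`,
#'   ordered as above. Filtering `expressed` gives the final candidate list.
#' @export
prioritize_genes <- function(map, criteria = filter_criteria(), expression) {
  stopifnot(inherits(map, "gene_carrier_map"))
  counts <- map$carrier_counts
  if (!length(counts))
    return(data.frame(gene = character(0), n_carriers = integer(0),
                      expressed = logical(0)))
  keep <- counts[counts >= criteria$min_shared_carriers]
  if (!length(keep))
    return(data.frame(gene = character(0), n_carriers = integer(0),
                      expressed = logical(0)))
  genes <- names(keep)
  unknown <- setdiff(genes, expression$gene)
  if (length(unknown))
    warning("genes missing from expression table treated as not expressed: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  tissues <- strsplit(expression$tissues[match(genes, expression$gene)], ";",
                      fixed = TRUE)
  expressed <- vapply(tissues, function(t)
    !is.null(t) && !all(is.na(t)) && criteria$expression_tissue %in% t,
    logical(1))
  out <- data.frame(gene = genes, n_carriers = as.integer(keep),
                    expressed = expressed, stringsAsFactors = FALSE)
  out <- out[order(-out$n_carriers, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The 17 genes with established PAH associations
#'
#' @return Character vector of gene symbols used as the default exclusion
#'   screen in [screen_known_pah_genes()].
#' @export
pah_gene_panel <- function() {
  c("BMPR2", "EIF2AK4", "TBX4", "ATP13A3", "GDF2", "SOX17", "AQP1", "ACVRL1",
    "SMAD9", "ENG", "KCNK3", "CAV1", "SMAD4", "SMAD1", "KLF2", "BMPR1B",
    "KCNA5")
}

#' Screen subjects for qualifying variants in known PAH genes
#'
#' Reports rare deleterious heterozygous variants in the listed genes for
#' each requested subject. An empty result means the subject passes the
#' exclusion screen (carriers of known-gene variants, BMPR2 above all, are
#' excluded from an idiopathic cohort).
#'
#' @param cohort A cohort object.
#' @param subjects Subject ids to screen; default all case-labelled subjects.
#' @param gene_list Genes to screen; default [pah_gene_panel()].
#' @param criteria A [filter_criteria()] object defining "rare deleterious".
#' @return Data frame `subject_id`, `site_id`, `gene` of qualifying hits
#'   (zero rows = all subjects pass).
#' @export
screen_known_pah_genes <- function(cohort, subjects = NULL,
                                   gene_list = pah_gene_panel(),
                                   criteria = filter_criteria()) {
  if (!length(gene_list)) stop_config("gene_list must not be empty")
  map <- discover_candidates(cohort, criteria, subjects)
  hits <- map$pairs[map$pairs$gene %in% gene_list, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
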