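#' Write a cohort to a directory of plain-text files
#'
#' Serialises a cohort as: `genotypes.vcf` (minimal VCF v4.2 dialect — CHROM,
#' POS, ID, REF, ALT and per-sample GT), `variants.tsv` (panel frequencies,
#' deleteriousness flags, gene and consequence annotations keyed by site id),
#' `subjects.tsv`, `expression.tsv`, `hemodynamics.tsv`, `config.yaml`, and —
#' when simulation truth is present — `truth_carriers.tsv` and
#' `truth_pairs.tsv`. [read_cohort()] restores the cohort field-for-field.
#'
#' @param cohort A `"synthetic_cohort"` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param dir Output directory; created if absent.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genotypes_vcf(cohort, file.path(dir, "genotypes.vcf"))
  write_tsv <- function(df, name) {
    df <- format_doubles(df)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write_tsv(cohort$variants, "variants.tsv")
  write_tsv(cohort$subjects, "subjects.tsv")
  write_tsv(cohort$expression, "expression.tsv")
  write_tsv(cohort$hemodynamics, "hemodynamics.tsv")
  if (!is.null(cohort$truth)) {
    write_tsv(cohort$truth$carriers, "truth_carriers.tsv")
    write_tsv(cohort$truth$related_pairs, "truth_pairs.tsv")
  }
  cfg <- unclass(cohort$config)
  cfg$n_related_pairs <- as.list(cfg$n_related_pairs)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"), precision = 17L)
  invisible(dir)
}

# write.table's default numeric formatting (15 significant digits) is kept;
# doubles round-trip to within 1e-15 relative, integers and strings exactly.
format_doubles <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- format(df[[j]], digits = 17,
                                              trim = TRUE, scientific = FALSE)
  }
  df
}

write_genotypes_vcf <- function(cohort, path) {
  v <- cohort$variants
  G <- cohort$genotypes
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = ncol(G), ncol = nrow(G))  # sites x subjects
  ok <- !is.na(t(G))
  gt[ok] <- gt_codes[t(G)[ok] + 1L]
  fixed <- data.frame(v$chrom, v$pos, v$site_id, v$ref, v$alt, ".", ".", ".",
                      "GT", stringsAsFactors = FALSE)
  body <- do.call(paste, c(unname(fixed), unname(as.data.frame(gt)),
                           list(sep = "\t")))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pahburden",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' Genotypes are parsed with \pkg{vcfR}; sidecar tables are validated on
#' read (panel frequencies in \[0, 1\], genotype/variant consistency) and a
#' malformed file raises an error naming the file and offending line.
#'
#' @param dir Directory containing the cohort files.
#' @return A `"synthetic_cohort"` object.
#' @export
read_cohort <- function(dir) {
  need <- c("genotypes.vcf", "variants.tsv", "subjects.tsv", "expression.tsv",
            "hemodynamics.tsv", "config.yaml")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop_data("cohort directory ", dir, " is missing: ",
              paste(missing, collapse = ", "))

  cfg_raw <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg_raw$n_related_pairs <- unlist(cfg_raw$n_related_pairs)
  config <- do.call(simulation_config, cfg_raw)

  read_tsv <- function(name) {
    read.delim(file.path(dir, name), sep = "\t", header = TRUE,
               stringsAsFactors = FALSE, check.names = FALSE)
  }
  variants <- read_tsv("variants.tsv")
  variants$chrom <- as.character(variants$chrom)
  if ("gene" %in% names(variants))
    variants$gene[is.na(variants$gene)] <- ""
  freq_cols <- grep("^freq_", names(variants), value = TRUE)
  for (fc in freq_cols) {
    bad <- which(!is.finite(variants[[fc]]) | variants[[fc]] < 0 |
                   variants[[fc]] > 1)
    if (length(bad))
      stop_data("variants.tsv line ", bad[1] + 1L, ": column ", fc,
                " value ", variants[[fc]][bad[1]],
                " is not a frequency in [0, 1]")
  }
  if (anyDuplicated(variants$site_id))
    stop_data("variants.tsv: duplicated site_id")

  subjects <- read_tsv("subjects.tsv")
  bad_grp <- which(!subjects$group %in% c("case", "control"))
  if (length(bad_grp))
    stop_data("subjects.tsv line ", bad_grp[1] + 1L,
              ": group must be case or control")

  expression <- read_tsv("expression.tsv")
  hemodynamics <- read_tsv("hemodynamics.tsv")
  if (nrow(hemodynamics)) {
    bad_ph <- which(!hemodynamics$phase %in% c("baseline", "post_iloprost"))
    if (length(bad_ph))
      stop_data("hemodynamics.tsv line ", bad_ph[1] + 1L,
                ": unknown phase '", hemodynamics$phase[bad_ph[1]], "'")
  }

  G <- read_genotypes_vcf(file.path(dir, "genotypes.vcf"))
  if (!identical(sort(colnames(G)), sort(variants$site_id)))
    stop_data("genotypes.vcf: site ids do not match variants.tsv")
  G <- G[subjects$subject_id, variants$site_id, drop = FALSE]

  truth <- NULL
  if (file.exists(file.path(dir, "truth_carriers.tsv"))) {
    truth <- list(
      carriers = read_tsv("truth_carriers.tsv"),
      related_pairs = if (file.exists(file.path(dir, "truth_pairs.tsv")))
        read_tsv("truth_pairs.tsv")
      else data.frame(),
      effects = list(pvr_effect = config$pvr_effect,
                     ci_effect = config$ci_effect))
  }

  structure(list(subjects = subjects, variants = variants, genotypes = G,
                 expression = expression, hemodynamics = hemodynamics,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  bad <- !(gt %in% c(names(map), NA_character_, "./."))
  if (any(bad))
    stop_data(path, ": unsupported genotype code '", gt[bad][1], "'")
  M <- matrix(map[gt], nrow = nrow(gt),
              dimnames = list(rownames(gt), colnames(gt)))
  t(M)  # subjects x sites
}
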