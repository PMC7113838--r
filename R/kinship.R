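#' KING-robust kinship coefficient for one pair of subjects
#'
#' Computes the between-family ("robust") KING estimator on the biallelic
#' sites non-missing in both subjects:
#' \deqn{\hat\varphi = \frac{N_{het,het} - 2\,N_{opp.hom}}
#'                          {N_{het}(i) + N_{het}(j)}}
#' where \eqn{N_{het,het}} counts sites heterozygous in both,
#' \eqn{N_{opp.hom}} counts opposite-homozygote sites, and
#' \eqn{N_{het}(\cdot)} counts heterozygous sites of each subject over the
#' shared set. The estimator is robust to allele-frequency misspecification
#' and is the standard for case-control relatedness QC. Degree classes use
#' the conventional powers-of-two cutoffs: \eqn{\ge 2^{-3/2}} duplicate/MZ,
#' \eqn{[2^{-5/2}, 2^{-3/2})} 1st degree, \eqn{[2^{-7/2}, 2^{-5/2})} 2nd
#' degree (the 0.0884 threshold), \eqn{[2^{-9/2}, 2^{-7/2})} 3rd degree,
#' otherwise unrelated.
#'
#' @param genotypes_i,genotypes_j Numeric vectors of 0/1/2 dosages over the
#'   same site set; `NA` allowed (sites missing in either subject are
#'   dropped pairwise).
#' @param pair Optional length-2 character vector of subject ids.
#' @return An object of class `"kinship_result"`: list with `pair`, `phi`,
#'   `n_snps_used`, `degree_class`, `estimable`. When neither subject has a
#'   heterozygous shared site the denominator is zero and the result is
#'   flagged not estimable (`phi = NA`).
#' @examples
#' g <- c(0, 1, 2, 1, 0, 1)
#' king_robust_pair(g, g)$phi  # identical genotypes: 0.5
#' @export
king_robust_pair <- function(genotypes_i, genotypes_j, pair = c("i", "j")) {
  if (length(genotypes_i) != length(genotypes_j))
    stop_data("genotype vectors must cover the same site set")
  ok_vals <- function(g) all(is.na(g) | g %in% c(0, 1, 2))
  if (!ok_vals(genotypes_i) || !ok_vals(genotypes_j))
    stop_data("genotypes must be coded 0/1/2 with NA for missing")
  shared <- !is.na(genotypes_i) & !is.na(genotypes_j)
  gi <- genotypes_i[shared]
  gj <- genotypes_j[shared]
  het_i <- sum(gi == 1)
  het_j <- sum(gj == 1)
  n_hh <- sum(gi == 1 & gj == 1)
  n_opp <- sum((gi == 0 & gj == 2) | (gi == 2 & gj == 0))
  den <- het_i + het_j
  if (den == 0) {
    return(structure(list(pair = pair, phi = NA_real_,
                          n_snps_used = sum(shared),
                          degree_class = NA_character_, estimable = FALSE),
                     class = "kinship_result"))
  }
  phi <- (n_hh - 2 * n_opp) / den
  structure(list(pair = pair, phi = phi, n_snps_used = sum(shared),
                 degree_class = kinship_degree(phi), estimable = TRUE),
            class = "kinship_result")
}

#' Classify a kinship coefficient into a relationship degree
#'
#' @param phi Kinship coefficient(s).
#' @return Character vector: `"duplicate"`, `"1st"`, `"2nd"`, `"3rd"` or
#'   `"unrelated"`.
#' @export
kinship_degree <- function(phi) {
  ifelse(phi >= 2^(-3 / 2), "duplicate",
         ifelse(phi >= 2^(-5 / 2), "1st",
                ifelse(phi >= 2^(-7 / 2), "2nd",
                       ifelse(phi >= 2^(-9 / 2), "3rd", "unrelated"))))
}

#' @export
print.kinship_result <- function(x, ...) {
  if (x$estimable)
    cat(sprintf("kinship %s-%s: phi = %.4f (%s) over %d SNPs\n",
                x$pair[1], x$pair[2], x$phi, x$degree_class, x$n_snps_used))
  else
    cat(sprintf("kinship %s-%s: not estimable (no heterozygous shared sites, %d SNPs)\n",
                x$pair[1], x$pair[2], x$n_snps_used))
  invisible(x)
}

# Dense cross-group KING-robust computation via matrix products.
# X: subjects x sites (rows i), Y: subjects x sites (rows j). NA allowed.
# Returns list of matrices: phi, n_snps, denominator.
king_robust_cross <- function(X, Y) {
  stopifnot(ncol(X) == ncol(Y))
  M_x <- !is.na(X); M_y <- !is.na(Y)
  z <- function(A) { A[is.na(A)] <- 0L; A }
  X0 <- z(X); Y0 <- z(Y)
  H_x <- (X0 == 1) * 1; H_y <- (Y0 == 1) * 1
  A_x <- (X0 == 0 & M_x) * 1; A_y <- (Y0 == 0 & M_y) * 1
  B_x <- (X0 == 2) * 1; B_y <- (Y0 == 2) * 1
  n_hh <- H_x %*% t(H_y)
  n_opp <- A_x %*% t(B_y) + B_x %*% t(A_y)
  den <- H_x %*% t(M_y * 1) + (M_x * 1) %*% t(H_y)
  phi <- (n_hh - 2 * n_opp) / den
  phi[den == 0] <- NA_real_
  list(phi = phi, n_snps = (M_x * 1) %*% t(M_y * 1), denominator = den)
}

#' Cohort-level relatedness summary
#'
#' Computes KING-robust kinship for every between-group pair (all pairs when
#' only one group is present) and summarises against a threshold — by
#' default 0.0884 (\eqn{2^{-7/2}}), the conventional 2nd-degree cutoff: a
#' study sample is taken as unrelated when (nearly) all between-group
#' kinship values fall below it.
#'
#' @param genotypes Subjects-by-sites dosage matrix (0/1/2, `NA` allowed),
#'   typically the common-SNP columns of a cohort.
#' @param groups Named character vector or factor of group labels per
#'   subject (names = rownames of `genotypes`); with exactly two levels the
#'   summary covers between-group pairs.
#' @param threshold Kinship threshold (default 0.0884).
#' @return An object of class `"relatedness_summary"`: list with
#'   `fraction_below` (estimable between-group pairs with
#'   \eqn{\hat\varphi <} threshold), `max_phi`, `max_pair`, `n_pairs`,
#'   `offending` (data frame of pairs at or above the threshold, with degree
#'   class), `threshold`.
#' @export
cohort_relatedness_summary <- function(genotypes, groups,
                                       threshold = 0.0884) {
  if (nrow(genotypes) < 2L)
    return(structure(list(fraction_below = NA_real_, max_phi = NA_real_,
                          max_pair = c(NA_character_, NA_character_),
                          n_pairs = 0L,
                          offending = empty_offending(), threshold = threshold),
                     class = "relatedness_summary"))
  ids <- rownames(genotypes)
  groups <- groups[ids]
  lev <- unique(as.character(groups))
  if (length(lev) == 2L) {
    rows_i <- which(groups == lev[1]); rows_j <- which(groups == lev[2])
  } else {
    rows_i <- seq_len(nrow(genotypes)); rows_j <- rows_i
  }
  res <- king_robust_cross(genotypes[rows_i, , drop = FALSE],
                           genotypes[rows_j, , drop = FALSE])
  phi <- res$phi
  if (length(lev) != 2L) phi[upper.tri(phi, diag = TRUE)] <- NA_real_
  est <- !is.na(phi)
  n_pairs <- sum(est)
  if (n_pairs == 0L)
    return(structure(list(fraction_below = NA_real_, max_phi = NA_real_,
                          max_pair = c(NA_character_, NA_character_),
                          n_pairs = 0L, offending = empty_offending(),
                          threshold = threshold),
                     class = "relatedness_summary"))
  mx <- which(phi == max(phi[est]), arr.ind = TRUE)[1L, ]
  off_idx <- which(est & phi >= threshold, arr.ind = TRUE)
  offending <- if (nrow(off_idx)) {
    data.frame(subject_i = ids[rows_i][off_idx[, 1L]],
               subject_j = ids[rows_j][off_idx[, 2L]],
               phi = phi[off_idx],
               degree_class = kinship_degree(phi[off_idx]),
               stringsAsFactors = FALSE)
  } else empty_offending()
  structure(list(
    fraction_below = sum(phi[est] < threshold) / n_pairs,
    max_phi = max(phi[est]),
    max_pair = c(ids[rows_i][mx[1L]], ids[rows_j][mx[2L]]),
    n_pairs = n_pairs,
    offending = offending,
    threshold = threshold
  ), class = "relatedness_summary")
}

empty_offending <- function() {
  data.frame(subject_i = character(0), subject_j = character(0),
             phi = numeric(0), degree_class = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.relatedness_summary <- function(x, ...) {
  if (x$n_pairs == 0L) {
    cat("Relatedness summary: no estimable pairs\n")
    return(invisible(x))
  }
  cat(sprintf("Relatedness summary over %d between-group pairs\n", x$n_pairs))
  cat(sprintf("  %.4f%% of kinship values below %.4f; maximum phi %.4f (%s-%s)\n",
              100 * x$fraction_below, x$threshold, x$max_phi,
              x$max_pair[1], x$max_pair[2]))
  if (nrow(x$offending))
    cat(sprintf("  %d pair(s) at or above threshold\n", nrow(x$offending)))
  invisible(x)
}
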