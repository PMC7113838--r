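#' Transcript model for splice-consequence arithmetic
#'
#' A minimal coding-transcript description: ordered exon lengths (their CDS
#' contribution, in nucleotides), the offset of the CDS start within exon 1,
#' the spliced CDS sequence, and intron sequences keyed by intron index
#' (intron `i` follows exon `i`).
#'
#' @param exon_lengths Positive integer vector of per-exon CDS lengths.
#' @param cds_seq Spliced CDS sequence (A/C/G/T), length divisible by 3,
#'   beginning with ATG and ending with a stop codon.
#' @param introns Named list of intron sequences (names `"1"`, `"2"`, ...).
#' @param cds_offset Nucleotides of exon 1 upstream of the CDS (default 0).
#' @return An object of class `"transcript_model"`.
#' @export
transcript_model <- function(exon_lengths, cds_seq, introns = list(),
                             cds_offset = 0L) {
  exon_lengths <- as.integer(exon_lengths)
  if (any(exon_lengths <= 0)) stop_config("exon lengths must be positive")
  cds_offset <- check_count(cds_offset, "cds_offset")
  cds_seq <- toupper(cds_seq)
  n <- nchar(cds_seq)
  if (n %% 3 != 0) stop_config("CDS length must be divisible by 3")
  if (sum(exon_lengths) - cds_offset != n)
    stop_config("exon lengths minus cds_offset must sum to the CDS length")
  if (substr(cds_seq, 1, 3) != "ATG")
    stop_config("CDS must begin with the ATG start codon")
  if (!translate_cds(cds_seq)$terminal_stop)
    stop_config("CDS must end with a stop codon")
  structure(list(exon_lengths = exon_lengths, cds_seq = cds_seq,
                 introns = introns, cds_offset = cds_offset),
            class = "transcript_model")
}

# Cumulative CDS end coordinate of each exon (1-based, offset-adjusted).
exon_cds_ends <- function(model) {
  cumsum(model$exon_lengths) - model$cds_offset
}

# Translate a CDS string; returns the protein up to (not including) the
# first stop, the index of the first stop codon, and whether the final
# codon is a stop.
translate_cds <- function(cds) {
  usable <- 3L * (nchar(cds) %/% 3L)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, usable)),
    no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  first_stop <- if (stop_at > 0) as.integer(stop_at) else NA_integer_
  protein <- if (stop_at > 0) substr(aa, 1L, stop_at - 1L) else aa
  list(protein = protein, first_stop_codon = first_stop,
       terminal_stop = identical(first_stop, nchar(aa)))
}

#' Consequence of skipping an internal exon
#'
#' Removes the exon's CDS contribution from the spliced transcript and
#' classifies the outcome: the skip is frame-preserving iff the exon length
#' is a multiple of 3. For a frame-preserving skip of a codon-aligned exon
#' the deleted residues are exactly the exon's codon interval; for a
#' frame-preserving skip across a codon boundary the affected residue
#' interval is derived by comparing the mutant and reference proteins.
#' Frameshifting skips almost always introduce a premature termination
#' codon, which is located by scanning the shifted reading frame.
#'
#' @param model A [transcript_model()].
#' @param exon_index Index of an internal exon (not first or last).
#' @return An object of class `"splice_outcome"`: `event`,
#'   `frame_preserving`, `deleted_nt`, `deleted_residues` (inclusive
#'   `c(start, end)` residue interval, `NULL` when frameshifting),
#'   `introduces_ptc`, `ptc_codon_index`, plus the reference and mutant
#'   protein sequences.
#' @examples
#' m <- ptgis_transcript_model()
#' exon_skip(m, 4)
#' @export
exon_skip <- function(model, exon_index) {
  stopifnot(inherits(model, "transcript_model"))
  n_ex <- length(model$exon_lengths)
  if (exon_index <= 1L || exon_index >= n_ex)
    stop_config("unsupported event: only internal exons can be skipped")
  ends <- exon_cds_ends(model)
  s <- ends[exon_index - 1L] + 1L
  e <- ends[exon_index]
  deleted_nt <- e - s + 1L
  mutant_cds <- paste0(substr(model$cds_seq, 1L, s - 1L),
                       substr(model$cds_seq, e + 1L, nchar(model$cds_seq)))
  frame <- deleted_nt %% 3L == 0L
  ref <- translate_cds(model$cds_seq)
  mut <- translate_cds(mutant_cds)
  deleted_residues <- NULL
  if (frame) {
    if (s %% 3L == 1L) {          # codon-aligned: pure arithmetic
      deleted_residues <- c((s - 1L) %/% 3L + 1L, e %/% 3L)
    } else {
      deleted_residues <- protein_deletion_interval(ref$protein, mut$protein)
    }
  }
  ptc <- !is.na(mut$first_stop_codon) &&
    mut$first_stop_codon < nchar(mutant_cds) %/% 3L
  structure(list(event = "exon_skip", frame_preserving = frame,
                 deleted_nt = deleted_nt,
                 deleted_residues = deleted_residues,
                 introduces_ptc = ptc,
                 ptc_codon_index = if (ptc) mut$first_stop_codon else NA_integer_,
                 protein = ref$protein, mutant_protein = mut$protein,
                 mutant_cds = mutant_cds),
            class = "splice_outcome")
}

# Locate the residue interval deleted from `ref` to give `mut`
# (frame-preserving case): longest common prefix/suffix bracketing.
protein_deletion_interval <- function(ref, mut) {
  nr <- nchar(ref); nm <- nchar(mut)
  r <- strsplit(ref, "")[[1]]; m <- strsplit(mut, "")[[1]]
  pre <- 0L
  while (pre < nm && r[pre + 1L] == m[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < nm - pre && r[nr - suf] == m[nm - suf]) suf <- suf + 1L
  c(pre + 1L, nr - suf)
}

#' Consequence of a cryptic-donor activation retaining intronic sequence
#'
#' Models a cryptic splice donor `offset_nt` bases into the intron: the
#' first `offset_nt` intronic bases are retained in the mature transcript
#' after the upstream exon. The resulting reading frame is scanned for the
#' first stop codon; a premature termination codon is reported when
#' translation stops earlier than it would in the correspondingly lengthened
#' normal transcript.
#'
#' @param model A [transcript_model()].
#' @param intron_index Intron whose donor is displaced (intron `i` follows
#'   exon `i`); its sequence must be present in the model.
#' @param offset_nt Retained intron length (0 reproduces normal splicing).
#' @return A `"splice_outcome"` with `event = "cryptic_donor"`.
#' @examples
#' m <- ptgis_transcript_model()
#' cryptic_donor(m, 4, 371)
#' @export
cryptic_donor <- function(model, intron_index, offset_nt) {
  stopifnot(inherits(model, "transcript_model"))
  intron <- model$introns[[as.character(intron_index)]]
  if (is.null(intron))
    stop_data("no sequence for intron ", intron_index, " in the model")
  offset_nt <- check_count(offset_nt, "offset_nt")
  if (offset_nt > nchar(intron))
    stop_data("offset_nt exceeds the intron length (", nchar(intron), ")")
  ends <- exon_cds_ends(model)
  if (intron_index < 1L || intron_index >= length(model$exon_lengths))
    stop_data("intron_index must reference an internal intron")
  e <- ends[intron_index]
  mutant_cds <- paste0(substr(model$cds_seq, 1L, e),
                       substr(toupper(intron), 1L, offset_nt),
                       substr(model$cds_seq, e + 1L, nchar(model$cds_seq)))
  ref <- translate_cds(model$cds_seq)
  mut <- translate_cds(mutant_cds)
  # Without a premature stop, translation would run for at least the
  # reference protein plus the complete retained codons.
  expected_min <- nchar(ref$protein) + offset_nt %/% 3L
  ptc <- nchar(mut$protein) < expected_min
  structure(list(event = "cryptic_donor", frame_preserving = offset_nt %% 3L == 0L,
                 deleted_nt = 0L, retained_nt = offset_nt,
                 deleted_residues = NULL,
                 introduces_ptc = ptc,
                 ptc_codon_index = if (ptc) mut$first_stop_codon else NA_integer_,
                 protein = ref$protein, mutant_protein = mut$protein,
                 mutant_cds = mutant_cds),
            class = "splice_outcome")
}

#' HGVS-style protein deletion label for a frame-preserving outcome
#'
#' Builds `p.<Aaa><start>_<Bbb><end>del` (or the single-position form
#' `p.<Aaa><pos>del`) from the outcome's residue interval, reading the
#' three-letter codes off the reference protein.
#'
#' @param outcome A frame-preserving `"splice_outcome"` with a residue
#'   interval (e.g. from [exon_skip()]).
#' @return Character label, e.g. `"p.Thr127_Arg174del"`.
#' @export
protein_interval_name <- function(outcome) {
  stopifnot(inherits(outcome, "splice_outcome"))
  if (!outcome$frame_preserving || is.null(outcome$deleted_residues))
    stop_data("deletion naming applies only to frame-preserving outcomes ",
              "with a residue interval")
  iv <- outcome$deleted_residues
  aa3 <- function(pos) {
    one <- substr(outcome$protein, pos, pos)
    code <- Biostrings::AMINO_ACID_CODE[[one]]
    if (is.null(code)) stop_data("no residue at position ", pos)
    code
  }
  if (iv[1] == iv[2])
    sprintf("p.%s%ddel", aa3(iv[1]), iv[1])
  else
    sprintf("p.%s%d_%s%ddel", aa3(iv[1]), iv[1], aa3(iv[2]), iv[2])
}

#' @export
print.splice_outcome <- function(x, ...) {
  cat(sprintf("Splice outcome: %s (%s)\n", x$event,
              if (x$frame_preserving) "frame-preserving" else "frameshift"))
  if (x$event == "exon_skip")
    cat(sprintf("  deleted: %d nt", x$deleted_nt),
        if (!is.null(x$deleted_residues))
          sprintf(" = residues %d-%d (%s)", x$deleted_residues[1],
                  x$deleted_residues[2], protein_interval_name(x)), "\n")
  if (x$event == "cryptic_donor")
    cat(sprintf("  retained intron: %d nt\n", x$retained_nt))
  if (x$introduces_ptc)
    cat(sprintf("  premature termination codon at codon %d\n",
                x$ptc_codon_index))
  invisible(x)
}

#' Synthetic prostacyclin-synthase-like transcript fixture
#'
#' A deterministic, synthetic transcript model shaped like the PTGIS coding
#' transcript for the purposes of splice arithmetic: five exons contributing
#' 180, 120, 78, 144 and 981 CDS nucleotides (501 codons, a 500-residue
#' protein), with the internal 144-nt exon 4 codon-aligned at codons
#' 127-174, threonine at residue 127 and arginine at residue 174, and an
#' intron 4 whose retention introduces a stop codon immediately after the
#' exon-4-derived product. It is a constructed fixture satisfying those
#' published coordinates, not the reference PTGIS sequence.
#'
#' @return A [transcript_model()].
#' @examples
#' m <- ptgis_transcript_model()
#' nchar(m$cds_seq) / 3 - 1  # protein length
#' @export
ptgis_transcript_model <- function() {
  pool <- c("GCT", "GAA", "CTG", "AAA", "GGC", "TTC", "CCA", "GAT", "ATC",
            "GTG", "AGC", "TAC")  # sense codons only
  codons <- rep(pool, length.out = 501L)
  codons[1L] <- "ATG"
  codons[127L] <- "ACC"  # Thr127
  codons[174L] <- "CGT"  # Arg174
  codons[501L] <- "TAA"
  cds <- paste(codons, collapse = "")
  intron_body <- function(n) {
    paste0("GT", strrep("CTTC", ceiling((n - 4) / 4)))
  }
  introns <- list(
    "1" = paste0(substr(intron_body(122), 1, 122), "AG"),
    "2" = paste0(substr(intron_body(98), 1, 98), "AG"),
    "3" = paste0(substr(intron_body(150), 1, 150), "AG"),
    # GTA TAA ...: the first retained codon is Val, the second a stop, so a
    # cryptic donor within this intron yields a PTC immediately after the
    # upstream exon product.
    "4" = paste0("GTATAA", substr(strrep("CTTC", 149), 1, 592), "AG")
  )
  transcript_model(exon_lengths = c(180L, 120L, 78L, 144L, 981L),
                   cds_seq = cds, introns = introns)
}
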