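# User-facing prediction: score peptide C-termini against their source
# proteins, and scan whole proteins for cleavage propensity.

#' Score peptide C-termini against their source proteins
#'
#' For each (peptide, accession) pair the positive-style training window is
#' rebuilt — the peptide's last four residues plus the three protein
#' residues after its C-terminus — and scored with the model. Pairs that
#' cannot be resolved (accession missing, peptide not found, insufficient
#' flank, non-standard residues) yield skip rows with a reason rather than a
#' failure.
#'
#' @param model A `cleavage_model`.
#' @param pairs `data.frame` with columns `peptide` and `protein_accession`.
#' @param proteins Named character vector, accession -> protein sequence.
#' @return `data.frame` with columns `peptide`, `protein_accession`,
#'   `cut_index`, `window`, `score`, `status` in input order; skipped rows
#'   have `NA` score/window and the skip reason in `status`.
#' @export
score_peptides <- function(model, pairs, proteins) {
  if (!all(c("peptide", "protein_accession") %in% names(pairs))) {
    stop("pairs must have 'peptide' and 'protein_accession' columns")
  }
  out <- data.frame(peptide = toupper(pairs$peptide),
                    protein_accession = pairs$protein_accession,
                    cut_index = NA_integer_,
                    window = NA_character_,
                    score = NA_real_,
                    status = NA_character_,
                    stringsAsFactors = FALSE)
  # row-at-a-time keeps a strict positional mapping between input and output
  for (i in seq_len(nrow(out))) {
    one <- build_positive_windows(out[i, , drop = FALSE], proteins)
    if (nrow(one) == 1L) {
      out$cut_index[i] <- one$cut_index
      out$window[i] <- one$window
      out$status[i] <- "ok"
    } else {
      out$status[i] <- attr(one, "skipped")$reason[1L]
    }
  }
  ok <- out$status == "ok"
  if (any(ok)) {
    out$score[ok] <- predict_scores(model, out$window[ok])$score
  }
  if (!any(ok)) {
    warning("no (peptide, protein) pair could be resolved; all rows skipped")
  }
  out
}

#' Scan a protein for cleavage propensity
#'
#' Slides the 7-residue window over every admissible cut position
#' (`cut_index` in `[4, L - 3]`, 0-based index of the first residue after
#' the cut) and scores each window. Windows containing non-standard residues
#' are reported with a skip status; proteins shorter than 7 residues give an
#' empty result with a warning.
#'
#' @param model A `cleavage_model`.
#' @param sequence Protein sequence string.
#' @param accession Label used in the output (default "protein").
#' @return `data.frame` with columns `protein_accession`, `cut_index`,
#'   `window`, `score`, `status`, ordered by position; `L - 6` rows for a
#'   clean length-`L` protein.
#' @export
scan_protein <- function(model, sequence, accession = "protein") {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < WINDOW_SIZE) {
    warning("protein shorter than ", WINDOW_SIZE,
            " residues; nothing to scan")
    return(data.frame(protein_accession = character(0L),
                      cut_index = integer(0L), window = character(0L),
                      score = numeric(0L), status = character(0L),
                      stringsAsFactors = FALSE))
  }
  cuts <- seq.int(N_FLANK, L - C_FLANK)
  windows <- vapply(cuts, function(ci) window_at_cut(sequence, ci),
                    character(1L))
  scored <- predict_scores(model, windows)
  data.frame(protein_accession = accession,
             cut_index = cuts,
             window = scored$window,
             score = scored$score,
             status = ifelse(scored$status == "ok", "ok",
                             paste("skipped:", scored$status)),
             stringsAsFactors = FALSE)
}

#' Write scored sites to CSV
#'
#' Scores are rounded to 6 decimals for stable textual output.
#'
#' @param sites `data.frame` from [score_peptides()] or [scan_protein()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scored_sites <- function(sites, path) {
  sites$score <- round(sites$score, 6L)
  write.csv(sites, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
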