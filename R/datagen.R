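# Training-data generation: eluted-ligand parsing, flank retrieval,
# positive/decoy window construction, immunogenicity benchmark curation.

#' Default column mapping for eluted-ligand CSV exports
#'
#' Maps the internal record fields to the column headers of the input CSV.
#' Override individual entries to read exports with different headers, e.g.
#' `default_column_map(peptide = "Epitope.Description")`.
#'
#' @param ... Named overrides, `field = "CSV column name"`.
#' @return Named character vector over the fields `peptide`,
#'   `protein_accession`, `host`, `mhc_class`, `allele`, `technique`,
#'   `cell_type`.
#' @export
default_column_map <- function(...) {
  map <- c(peptide = "peptide",
           protein_accession = "protein_accession",
           host = "host",
           mhc_class = "mhc_class",
           allele = "allele",
           technique = "technique",
           cell_type = "cell_type")
  overrides <- c(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(map))
    if (length(unknown)) {
      stop("unknown record field(s) in column map: ",
           paste(unknown, collapse = ", "))
    }
    map[names(overrides)] <- overrides
  }
  map
}

#' Parse an eluted-ligand CSV export
#'
#' Reads a CSV of MS-eluted MHC ligand records, applies per-field filters,
#' normalizes peptide sequences to uppercase, drops peptides containing
#' non-standard residues, and deduplicates to unique
#' (peptide, protein_accession) pairs.
#'
#' @param path CSV file path.
#' @param filters Named list, `field = allowed values`. Fields must be names
#'   of `column_map`. A record survives only if every filtered field's value
#'   is among the allowed values. Empty list keeps everything.
#' @param column_map Mapping from record fields to CSV headers; see
#'   [default_column_map()].
#' @return `data.frame` with the seven record columns, one row per unique
#'   (peptide, accession) pair. Attributes: `n_raw` (rows read),
#'   `n_nonstandard` (peptides dropped for non-standard residues).
#' @export
parse_ligand_export <- function(path, filters = list(),
                                column_map = default_column_map()) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols)) {
    stop("ligand CSV is missing mapped column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- stats::setNames(raw[, unname(column_map), drop = FALSE],
                        names(column_map))
  if (length(filters)) {
    bad <- setdiff(names(filters), names(column_map))
    if (length(bad)) {
      stop("filter refers to unknown field(s): ",
           paste(bad, collapse = ", "),
           " (known: ", paste(names(column_map), collapse = ", "), ")")
    }
    for (field in names(filters)) {
      df <- df[df[[field]] %in% filters[[field]], , drop = FALSE]
    }
  }
  df$peptide <- toupper(trimws(df$peptide))
  df$protein_accession <- trimws(df$protein_accession)
  df <- df[nzchar(df$peptide) & nzchar(df$protein_accession), , drop = FALSE]
  standard <- vapply(strsplit(df$peptide, ""),
                     function(ch) all(ch %in% STANDARD_RESIDUES), logical(1L))
  n_nonstandard <- sum(!standard)
  if (n_nonstandard) {
    message(n_nonstandard,
            " peptide(s) with non-standard residues dropped")
  }
  df <- df[standard, , drop = FALSE]
  df <- df[!duplicated(df[, c("peptide", "protein_accession")]), ,
           drop = FALSE]
  rownames(df) <- NULL
  if (!nrow(df)) {
    warning("no ligand records remain after filtering")
  }
  attr(df, "n_raw") <- nrow(raw)
  attr(df, "n_nonstandard") <- n_nonstandard
  df
}

#' Read a protein FASTA into a named sequence vector
#'
#' Accessions are taken from the first whitespace-delimited header token;
#' UniProt-style `db|ACC|NAME` tokens are reduced to `ACC` when
#' `uniprot_headers = TRUE` and the token matches that layout.
#'
#' @param path FASTA file path.
#' @param uniprot_headers Extract the accession from `db|ACC|NAME` tokens.
#' @return Named character vector, accession -> uppercase sequence.
#' @export
read_protein_fasta <- function(path, uniprot_headers = TRUE) {
  seqs <- Biostrings::readAAStringSet(path)
  acc <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1L), 1L)
  if (uniprot_headers) {
    piped <- grepl("^[^|]+\\|[^|]+\\|", acc)
    acc[piped] <- vapply(strsplit(acc[piped], "|", fixed = TRUE),
                         `[[`, character(1L), 2L)
  }
  if (anyDuplicated(acc)) {
    stop("duplicated accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  stats::setNames(toupper(as.character(seqs)), acc)
}

#' Write a named sequence vector to FASTA
#'
#' @param proteins Named character vector, accession -> sequence.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), path)
  invisible(path)
}

empty_window_frame <- function() {
  data.frame(window = character(0L), label = integer(0L),
              protein_accession = character(0L), cut_index = integer(0L),
              stringsAsFactors = FALSE)
}

empty_skip_frame <- function() {
  data.frame(peptide = character(0L), protein_accession = character(0L),
             reason = character(0L), stringsAsFactors = FALSE)
}

# 7-residue window around the 0-based cut index ci (first residue after the
# cut): residues ci-4 .. ci+2 (0-based), i.e. substring(ci-3, ci+3) 1-based.
window_at_cut <- function(sequence, cut_index) {
  substring(sequence, cut_index - N_FLANK + 1L, cut_index + C_FLANK)
}

#' Build positive cleavage windows from ligand records
#'
#' For each (peptide, accession) record the peptide is located in its source
#' protein by exact substring search (first occurrence wins; further
#' occurrences are logged as ambiguous). The window is the peptide's last
#' four residues followed by the three protein residues after its C-terminus;
#' `cut_index` is the 0-based index of the first residue after the cut.
#'
#' Records are skipped (with a logged reason, never a hard failure) when the
#' accession is absent from `proteins`, the peptide is shorter than four
#' residues or not found, fewer than three residues follow the peptide, or
#' the window contains a non-standard residue.
#'
#' @param records `data.frame` with columns `peptide` and
#'   `protein_accession` (e.g. from [parse_ligand_export()]).
#' @param proteins Named character vector, accession -> protein sequence.
#' @return `data.frame` with columns `window`, `label` (all 1),
#'   `protein_accession`, `cut_index`. Attributes: `skipped` (data.frame of
#'   skipped records with reasons), `ambiguous` (count of peptides with
#'   multiple occurrences).
#' @examples
#' prot <- c(SYN1 = "MKTAYIAKQRQISFVK")
#' build_positive_windows(
#'   data.frame(peptide = "TAYIAKQR", protein_accession = "SYN1"), prot)
#' @export
build_positive_windows <- function(records, proteins) {
  n <- nrow(records)
  windows <- character(n); cuts <- integer(n)
  keep <- logical(n); reasons <- character(n)
  for (i in seq_len(n)) {
    pep <- toupper(records$peptide[[i]])
    acc <- records$protein_accession[[i]]
    if (!(acc %in% names(proteins))) {
      reasons[i] <- "accession not found"; next
    }
    if (nchar(pep) < N_FLANK) {
      reasons[i] <- "peptide shorter than 4 residues"; next
    }
    seqstr <- proteins[[acc]]
    hits <- gregexpr(pep, seqstr, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) {
      reasons[i] <- "peptide not found in protein"; next
    }
    if (length(hits) > 1L) {
      reasons[i] <- "multiple occurrences; first used"
    }
    start1 <- hits[1L]                       # 1-based start
    ci <- start1 - 1L + nchar(pep)           # 0-based cut index
    if (ci > nchar(seqstr) - C_FLANK) {
      keep[i] <- FALSE
      reasons[i] <- "insufficient C-terminal flank"; next
    }
    w <- window_at_cut(seqstr, ci)
    if (!is.null(validate_window_string(w))) {
      reasons[i] <- "non-standard residue in window"; next
    }
    windows[i] <- w; cuts[i] <- ci; keep[i] <- TRUE
  }
  out <- data.frame(window = windows[keep], label = rep(1L, sum(keep)),
                    protein_accession = records$protein_accession[keep],
                    cut_index = cuts[keep], stringsAsFactors = FALSE)
  skipped_idx <- which(!keep)
  skipped <- data.frame(peptide = records$peptide[skipped_idx],
                        protein_accession =
                          records$protein_accession[skipped_idx],
                        reason = reasons[skipped_idx],
                        stringsAsFactors = FALSE)
  ambiguous <- sum(keep & reasons == "multiple occurrences; first used")
  attr(out, "skipped") <- skipped
  attr(out, "ambiguous") <- ambiguous
  out
}

#' Generate decoy windows adjacent to positive cleavage sites
#'
#' For every positive window, two candidate decoys are built by shifting the
#' cut one residue upstream (between P2 and P1) and one downstream (between
#' P1' and P2'), using the same 4+3 window rule with label 0. A candidate is
#' dropped (and counted) if the shifted window would run past either protein
#' end or contains a non-standard residue.
#'
#' @param positives `data.frame` as returned by [build_positive_windows()].
#' @param proteins Named character vector, accession -> protein sequence.
#' @return `data.frame` with columns `window`, `label` (all 0),
#'   `protein_accession`, `cut_index`. Attribute `n_dropped` counts
#'   candidates lost to protein boundaries or non-standard residues.
#' @export
generate_decoys <- function(positives, proteins) {
  accs <- character(0L); cuts <- integer(0L)
  n_dropped <- 0L
  for (i in seq_len(nrow(positives))) {
    acc <- positives$protein_accession[[i]]
    if (!(acc %in% names(proteins))) {
      n_dropped <- n_dropped + 2L
      next
    }
    L <- nchar(proteins[[acc]])
    for (shift in c(-1L, 1L)) {
      ci <- positives$cut_index[[i]] + shift
      if (ci < N_FLANK || ci > L - C_FLANK) {
        n_dropped <- n_dropped + 1L
      } else {
        accs <- c(accs, acc); cuts <- c(cuts, ci)
      }
    }
  }
  windows <- character(length(accs)); ok <- logical(length(accs))
  for (j in seq_along(accs)) {
    w <- window_at_cut(proteins[[accs[j]]], cuts[j])
    if (is.null(validate_window_string(w))) {
      windows[j] <- w; ok[j] <- TRUE
    } else {
      n_dropped <- n_dropped + 1L
    }
  }
  out <- data.frame(window = windows[ok], label = rep(0L, sum(ok)),
                    protein_accession = accs[ok], cut_index = cuts[ok],
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Assemble the labeled training dataset
#'
#' Combines positive and decoy windows, deduplicates by window string, and
#' resolves label conflicts: a window string observed as a positive always
#' keeps label 1 and its decoy copies are dropped (an MS observation outranks
#' a presumptive negative). Output rows are sorted by window string (radix
#' order, locale-independent) for deterministic reruns.
#'
#' @param positives,decoys Window data frames with columns `window`, `label`,
#'   `protein_accession`, `cut_index`.
#' @return Deduplicated, sorted `data.frame` of the same shape. Attribute
#'   `n_conflicts` counts decoy strings that collided with positives.
#' @export
assemble_dataset <- function(positives, decoys) {
  if (!nrow(positives)) {
    stop("cannot assemble a dataset without positive windows")
  }
  pos <- positives[!duplicated(positives$window), , drop = FALSE]
  dec <- decoys[!duplicated(decoys$window), , drop = FALSE]
  conflict <- dec$window %in% pos$window
  n_conflicts <- sum(conflict)
  if (n_conflicts) {
    message(n_conflicts,
            " decoy window(s) collided with positives; positives kept")
  }
  dec <- dec[!conflict, , drop = FALSE]
  out <- rbind(pos, dec)
  out <- out[order(out$window, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_conflicts") <- n_conflicts
  out
}

#' Build a training dataset from ligand CSV and protein FASTA
#'
#' Convenience wrapper chaining [parse_ligand_export()],
#' [build_positive_windows()], [generate_decoys()] and [assemble_dataset()].
#'
#' @inheritParams parse_ligand_export
#' @param fasta_path Protein FASTA path.
#' @return Labeled window `data.frame`; see [assemble_dataset()].
#' @export
build_training_dataset <- function(path, fasta_path, filters = list(),
                                   column_map = default_column_map()) {
  records <- parse_ligand_export(path, filters = filters,
                                 column_map = column_map)
  proteins <- read_protein_fasta(fasta_path)
  positives <- build_positive_windows(records, proteins)
  decoys <- generate_decoys(positives, proteins)
  assemble_dataset(positives, decoys)
}

IMMUNOGENICITY_LABELS <- c("Negative", "Positive", "Positive-Low",
                           "Positive-Intermediate", "Positive-High")

#' Curate qualitative immunogenicity calls into binary labels
#'
#' Restricts records to a single assay technique (ELISPOT by default, the
#' dominant assay in the benchmark datasets), collapses the five-level
#' qualitative vocabulary to binary — any `Positive*` call is positive
#' regardless of strength — and, per (peptide, allele), discards peptides
#' with conflicting negative and positive calls.
#'
#' @param records `data.frame` with columns `peptide`, `allele`,
#'   `qualitative` (one call per row) and `technique`.
#' @param technique Keep only records with this technique label; `NULL`
#'   keeps all.
#' @return `data.frame` with columns `peptide`, `allele`, `label` (0/1), one
#'   row per retained (peptide, allele). Attribute `discarded` holds the
#'   conflicting (peptide, allele) pairs.
#' @export
curate_immunogenicity <- function(records, technique = "ELISPOT") {
  required <- c("peptide", "allele", "qualitative", "technique")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("immunogenicity records are missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(unique(records$qualitative), IMMUNOGENICITY_LABELS)
  if (length(unknown)) {
    stop("unknown qualitative immunogenicity label(s): ",
         paste(unknown, collapse = ", "),
         " (allowed: ", paste(IMMUNOGENICITY_LABELS, collapse = ", "), ")")
  }
  if (!is.null(technique)) {
    records <- records[records$technique %in% technique, , drop = FALSE]
  }
  if (!nrow(records)) {
    warning("no immunogenicity records remain after technique filtering")
    out <- data.frame(peptide = character(0L), allele = character(0L),
                      label = integer(0L), stringsAsFactors = FALSE)
    attr(out, "discarded") <- out[, c("peptide", "allele")]
    return(out)
  }
  records$binary <- as.integer(records$qualitative != "Negative")
  key <- paste(records$peptide, records$allele, sep = "\r")
  agg_min <- tapply(records$binary, key, min)
  agg_max <- tapply(records$binary, key, max)
  keys <- names(agg_min)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(peptide = vapply(parts, `[[`, character(1L), 1L),
                    allele = vapply(parts, `[[`, character(1L), 2L),
                    label = as.integer(agg_max),
                    stringsAsFactors = FALSE)
  conflict <- agg_min != agg_max
  discarded <- out[conflict, c("peptide", "allele"), drop = FALSE]
  out <- out[!conflict, , drop = FALSE]
  out <- out[order(out$peptide, out$allele, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  rownames(discarded) <- NULL
  attr(out, "discarded") <- discarded
  out
}

#' Write a labeled window table to CSV
#'
#' @param dataset Window `data.frame` from [assemble_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_training_table <- function(dataset, path) {
  write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labeled window table written by [write_training_table()]
#'
#' @param path CSV path with columns `window`, `label`,
#'   `protein_accession`, `cut_index`.
#' @return Window `data.frame`.
#' @export
read_training_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("window", "label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("training table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df
}
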