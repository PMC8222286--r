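# Deterministic synthetic fixtures: random proteomes with a planted P1
# cleavage motif, ligand CSVs in the eluted-ligand export layout, and
# immunogenicity-style label files. Every downstream stage is testable
# offline against the generator's own ground truth.

#' Configuration of the synthetic-data generator
#'
#' The default world plants a single-position "chymotrypsin-like" signal:
#' candidate cut sites are accepted with high probability when the P1
#' residue (the residue immediately before the cut) is F, L or Y, and with a
#' low background probability otherwise. Residue usage is uniform over the
#' 20 standard amino acids, so the planted motif is the only learnable
#' signal. Defaults (60 proteins of 200-300 residues, acceptance 0.9 after
#' F/L/Y, background 0.01) yield roughly 2,000 positive windows and 4,000
#' decoys — large enough for the network to separate the motif cleanly.
#'
#' @param n_proteins Number of proteins to simulate.
#' @param protein_length_range Integer min/max protein length.
#' @param peptide_length_range Integer min/max emitted peptide length
#'   (default 8-11, typical class-I ligand lengths).
#' @param motif Named probability vector over P1 residues; residues absent
#'   from the vector fall back to `background_cleavage_prob`.
#' @param background_cleavage_prob Acceptance probability for non-motif P1
#'   residues.
#' @param conflict_rate Fraction of benchmark peptides given deliberately
#'   conflicting immunogenicity calls (exercises the curation discard path).
#' @param allele,host,mhc_class,technique,cell_type Constant metadata
#'   written to the ligand CSV.
#' @param seed Mandatory integer seed (< 2^31 - 16; derived sub-seeds stay
#'   below 2^31).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 60L,
                             protein_length_range = c(200L, 300L),
                             peptide_length_range = c(8L, 11L),
                             motif = c(F = 0.9, L = 0.9, Y = 0.9),
                             background_cleavage_prob = 0.01,
                             conflict_rate = 0.1,
                             allele = "HLA-A*02:01",
                             host = "Homo sapiens",
                             mhc_class = "I",
                             technique = "cellular MHC/mass spectrometry",
                             cell_type = "B cell",
                             seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed < 0 || seed > 2^31 - 16) {
    stop("seed must be an integer in [0, 2^31 - 16]")
  }
  seed <- as.integer(seed)
  stopifnot(n_proteins >= 1L,
            length(protein_length_range) == 2L,
            protein_length_range[1L] <= protein_length_range[2L],
            length(peptide_length_range) == 2L,
            peptide_length_range[1L] <= peptide_length_range[2L],
            peptide_length_range[1L] >= 4L,
            all(motif >= 0 & motif <= 1),
            background_cleavage_prob >= 0, background_cleavage_prob <= 1,
            conflict_rate >= 0, conflict_rate <= 1)
  unknown <- setdiff(names(motif), STANDARD_RESIDUES)
  if (length(unknown)) {
    stop("motif names residue(s) outside the standard alphabet: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 protein_length_range = as.integer(protein_length_range),
                 peptide_length_range = as.integer(peptide_length_range),
                 motif = motif,
                 background_cleavage_prob = background_cleavage_prob,
                 conflict_rate = conflict_rate,
                 allele = allele, host = host, mhc_class = mhc_class,
                 technique = technique, cell_type = cell_type,
                 seed = seed),
            class = "synthetic_config")
}

#' Generate a random proteome
#'
#' Uniform-random sequences over the 20 standard residues, lengths uniform
#' in the configured range, accessions `SYN0001`, `SYN0002`, ...
#' Deterministic under the configuration seed.
#'
#' @param config A [synthetic_config()].
#' @return Named character vector, accession -> sequence.
#' @export
generate_proteome <- function(config) {
  withr::with_seed(config$seed, {
    lengths <- sample(seq.int(config$protein_length_range[1L],
                              config$protein_length_range[2L]),
                      config$n_proteins, replace = TRUE)
    seqs <- vapply(lengths, function(L) {
      paste(sample(STANDARD_RESIDUES, L, replace = TRUE), collapse = "")
    }, character(1L))
  })
  stats::setNames(seqs, sprintf("SYN%04d", seq_len(config$n_proteins)))
}

#' Generate eluted-ligand records with a planted cleavage motif
#'
#' Walks every admissible cut site of every protein (0-based `cut_index` in
#' `[max(4, min peptide length), L - 3]`; sites too close to either terminus
#' are never sampled) and accepts it with probability `motif[P1]`, falling
#' back to `background_cleavage_prob` for non-motif P1 residues. Each
#' accepted site emits one peptide ending at the cut, with length drawn
#' uniformly from the configured range (truncated so the peptide fits the
#' protein N-terminus), plus the constant metadata columns.
#'
#' @param proteome Named sequence vector from [generate_proteome()].
#' @param config A [synthetic_config()].
#' @return `data.frame` of ligand records (the eluted-ligand CSV layout).
#'   Attribute `ground_truth`: data.frame of the planted sites with columns
#'   `protein_accession`, `cut_index`, `window`, `p1`.
#' @export
generate_ligands <- function(proteome, config) {
  min_len <- config$peptide_length_range[1L]
  max_len <- config$peptide_length_range[2L]
  rows <- list(); truth <- list()
  withr::with_seed(config$seed + 1L, {
    for (acc in names(proteome)) {
      seqstr <- proteome[[acc]]
      L <- nchar(seqstr)
      lo <- max(N_FLANK, min_len)
      hi <- L - C_FLANK
      if (lo > hi) next
      cuts <- seq.int(lo, hi)
      p1 <- substring(seqstr, cuts, cuts)  # P1 residue (0-based ci = 1-based pos)
      prob <- unname(config$motif[p1])
      prob[is.na(prob)] <- config$background_cleavage_prob
      accepted <- cuts[runif(length(cuts)) < prob]
      if (!length(accepted)) next
      lens <- vapply(accepted, function(ci) {
        choices <- seq.int(min_len, min(max_len, ci))
        if (length(choices) == 1L) choices else sample(choices, 1L)
      }, integer(1L))
      peptides <- substring(seqstr, accepted - lens + 1L, accepted)
      rows[[acc]] <- data.frame(peptide = peptides,
                                protein_accession = acc,
                                stringsAsFactors = FALSE)
      truth[[acc]] <- data.frame(
        protein_accession = acc,
        cut_index = accepted,
        window = vapply(accepted, function(ci) window_at_cut(seqstr, ci),
                        character(1L)),
        p1 = substring(seqstr, accepted, accepted),
        stringsAsFactors = FALSE)
    }
  })
  if (!length(rows)) {
    warning("no cleavage sites accepted; raise the motif or background ",
            "probabilities or simulate more proteins")
    out <- data.frame(peptide = character(0L),
                      protein_accession = character(0L),
                      host = character(0L), mhc_class = character(0L),
                      allele = character(0L), technique = character(0L),
                      cell_type = character(0L), stringsAsFactors = FALSE)
    attr(out, "ground_truth") <-
      data.frame(protein_accession = character(0L), cut_index = integer(0L),
                 window = character(0L), p1 = character(0L),
                 stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, unname(rows))
  out$host <- config$host
  out$mhc_class <- config$mhc_class
  out$allele <- config$allele
  out$technique <- config$technique
  out$cell_type <- config$cell_type
  rownames(out) <- NULL
  gt <- do.call(rbind, unname(truth))
  rownames(gt) <- NULL
  attr(out, "ground_truth") <- gt
  out
}

#' Generate an immunogenicity benchmark file from ligand records
#'
#' Each unique peptide receives qualitative calls from the five-level
#' vocabulary (`Negative`, `Positive`, `Positive-Low`,
#' `Positive-Intermediate`, `Positive-High`) under the ELISPOT technique
#' label. A fraction `conflict_rate` of peptides gets both a negative and a
#' positive call so the curation discard path is exercised; the rest get
#' one or two homogeneous calls (positive with probability 1/2, the
#' strength level drawn uniformly). A small fraction of extra rows carries
#' a different technique label to exercise technique filtering.
#'
#' @param ligands Ligand `data.frame` from [generate_ligands()].
#' @param config A [synthetic_config()].
#' @return `data.frame` with columns `peptide`, `allele`, `qualitative`,
#'   `technique`. Attribute `truth`: per-peptide intended binary label
#'   (`NA` for deliberately conflicting peptides).
#' @export
generate_immunogenicity <- function(ligands, config) {
  peptides <- unique(ligands$peptide)
  if (!length(peptides)) stop("ligand set is empty")
  positive_levels <- c("Positive", "Positive-Low", "Positive-Intermediate",
                       "Positive-High")
  rows <- vector("list", length(peptides))
  truth <- integer(length(peptides))
  withr::with_seed(config$seed + 2L, {
    conflicted <- runif(length(peptides)) < config$conflict_rate
    for (i in seq_along(peptides)) {
      pep <- peptides[[i]]
      if (conflicted[i]) {
        calls <- c("Negative", sample(positive_levels, 1L))
        truth[i] <- NA_integer_
      } else if (runif(1L) < 0.5) {
        calls <- sample(positive_levels, sample(1:2, 1L), replace = TRUE)
        truth[i] <- 1L
      } else {
        calls <- rep("Negative", sample(1:2, 1L))
        truth[i] <- 0L
      }
      rows[[i]] <- data.frame(peptide = pep, allele = config$allele,
                              qualitative = calls, technique = "ELISPOT",
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    # off-technique duplicates; curation must ignore these
    extra <- out[runif(nrow(out)) < 0.05, , drop = FALSE]
    if (nrow(extra)) {
      extra$technique <- "ICS"
      out <- rbind(out, extra)
    }
  })
  rownames(out) <- NULL
  attr(out, "truth") <- stats::setNames(truth, peptides)
  out
}

#' Write a complete synthetic dataset to disk
#'
#' Produces `proteome.fasta`, `ligands.csv`, `immunogenicity.csv` and
#' `ground_truth_sites.csv` under `dir`.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (the four file paths) and the
#'   in-memory objects (`proteome`, `ligands`, `ground_truth`,
#'   `immunogenicity`).
#' @export
write_synthetic_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  proteome <- generate_proteome(config)
  ligands <- generate_ligands(proteome, config)
  immuno <- generate_immunogenicity(ligands, config)
  gt <- attr(ligands, "ground_truth")
  paths <- list(proteome = file.path(dir, "proteome.fasta"),
                ligands = file.path(dir, "ligands.csv"),
                immunogenicity = file.path(dir, "immunogenicity.csv"),
                ground_truth = file.path(dir, "ground_truth_sites.csv"))
  write_protein_fasta(proteome, paths$proteome)
  write.csv(ligands, paths$ligands, row.names = FALSE)
  write.csv(immuno, paths$immunogenicity, row.names = FALSE)
  write.csv(gt, paths$ground_truth, row.names = FALSE)
  invisible(list(paths = paths, proteome = proteome, ligands = ligands,
                 ground_truth = gt, immunogenicity = immuno))
}
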