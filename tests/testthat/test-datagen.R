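# Ligand parsing, window construction, decoys, dataset assembly,
# immunogenicity curation.

toy_ligand_df <- function() {
  data.frame(
    peptide = c("TAYIAKQR", "TAYIAKQR", "QRQISFVK", "AKQRQISF",
                "TAYIAKQR", "QRQISFVK"),
    protein_accession = c("P1", "P1", "P1", "P2", "P2", "P2"),
    host = c("Homo sapiens", "Homo sapiens", "Mus musculus", "Homo sapiens",
             "Homo sapiens", "Mus musculus"),
    mhc_class = "I", allele = "HLA-A*02:01",
    technique = "cellular MHC/mass spectrometry", cell_type = "B cell",
    stringsAsFactors = FALSE)
}

test_that("parse_ligand_export filters and deduplicates", {
  path <- write_ligand_csv(toy_ligand_df())
  # 4 human rows, one duplicated (peptide, accession) pair -> 3 records
  recs <- parse_ligand_export(path, filters = list(host = "Homo sapiens"))
  expect_equal(nrow(recs), 3L)
  expect_equal(anyDuplicated(recs[, c("peptide", "protein_accession")]), 0)

  # empty filter map keeps all unique pairs (5 of 6 rows)
  all_recs <- parse_ligand_export(path)
  expect_equal(nrow(all_recs), 5L)

  expect_error(parse_ligand_export(path, filters = list(foo = "x")), "foo")
  expect_error(
    parse_ligand_export(path, column_map = default_column_map(peptide = "pep")),
    "pep")
  expect_warning(
    parse_ligand_export(path, filters = list(host = "Gallus gallus")),
    "no ligand records")
})

test_that("nonstandard-residue peptides are dropped with a message", {
  df <- toy_ligand_df()
  df$peptide[1L] <- "TAYIXKQR"
  path <- write_ligand_csv(df)
  expect_message(recs <- parse_ligand_export(path), "non-standard")
  expect_false("TAYIXKQR" %in% recs$peptide)
})

test_that("positive windows follow the 4+3 rule around the C-terminus", {
  proteins <- c(P1 = "MKTAYIAKQRQISFVK")
  built <- build_positive_windows(
    data.frame(peptide = "TAYIAKQR", protein_accession = "P1"), proteins)
  expect_equal(built$window, "AKQRQIS")
  expect_equal(built$cut_index, 10L)
  expect_equal(built$label, 1L)

  # window reconstructible from protein + cut_index
  expect_equal(substring(proteins[["P1"]], built$cut_index - 3L,
                         built$cut_index + 3L), built$window)
})

test_that("unresolvable records are skipped with logged reasons", {
  proteins <- c(P1 = "MKTAYIAKQR", P2 = "MKTAYIAKQRQISFVK",
                P3 = "MKTAYIAKQRQXSFVK")  # X inside the C-terminal flank
  recs <- data.frame(
    peptide = c("TAYIAKQR", "TAYIAKQR", "GGG", "NOTHERE", "TAYIAKQR"),
    protein_accession = c("P1", "MISSING", "P2", "P2", "P3"),
    stringsAsFactors = FALSE)
  built <- build_positive_windows(recs, proteins)
  expect_equal(nrow(built), 0L)
  skipped <- attr(built, "skipped")
  expect_equal(skipped$reason,
               c("insufficient C-terminal flank", "accession not found",
                 "peptide shorter than 4 residues",
                 "peptide not found in protein",
                 "non-standard residue in window"))
})

test_that("repeated peptide occurrences use the first and log ambiguity", {
  proteins <- c(P1 = "AAKQRAAKQRAAKQRGGG")
  built <- build_positive_windows(
    data.frame(peptide = "AAKQR", protein_accession = "P1"), proteins)
  # brute-force scan finds occurrences at 1-based starts 1, 6, 11;
  # first wins: cut after position 5 -> cut_index 5
  expect_equal(built$cut_index, 5L)
  expect_equal(built$window, "AKQRAAK")
  expect_equal(attr(built, "ambiguous"), 1L)
})

test_that("decoys shift the cut one residue each way", {
  proteins <- c(P1 = "MKTAYIAKQRQISFVK")
  pos <- data.frame(window = "AKQRQIS", label = 1L,
                    protein_accession = "P1", cut_index = 10L,
                    stringsAsFactors = FALSE)
  dec <- generate_decoys(pos, proteins)
  expect_equal(dec$window, c("IAKQRQI", "KQRQISF"))
  expect_equal(dec$cut_index, c(9L, 11L))
  expect_equal(dec$label, c(0L, 0L))
})

test_that("decoys at protein boundaries are dropped", {
  proteins <- c(P1 = "MKTAYIAKQRQIS")  # length 13
  # positive at cut_index 10: downstream decoy needs cut 11 > 13-3 -> dropped
  pos_end <- data.frame(window = "AKQRQIS", label = 1L,
                        protein_accession = "P1", cut_index = 10L,
                        stringsAsFactors = FALSE)
  dec <- generate_decoys(pos_end, proteins)
  expect_equal(dec$cut_index, 9L)
  expect_equal(attr(dec, "n_dropped"), 1L)

  # positive at cut_index 4: upstream shift would cut at 3 (< 4 residues
  # before the cut) -> only downstream decoy survives
  pos_start <- data.frame(window = substring(proteins[["P1"]], 1L, 7L),
                          label = 1L, protein_accession = "P1",
                          cut_index = 4L, stringsAsFactors = FALSE)
  dec2 <- generate_decoys(pos_start, proteins)
  expect_equal(dec2$cut_index, 5L)
})

test_that("assemble_dataset deduplicates and resolves label conflicts", {
  pos <- data.frame(window = c("AAAAAAA", "CCCCCCC", "DDDDDDD"), label = 1L,
                    protein_accession = "P1", cut_index = 10L,
                    stringsAsFactors = FALSE)
  dec <- data.frame(window = c("EEEEEEE", "FFFFFFF", "GGGGGGG", "HHHHHHH",
                               "IIIIIII", "AAAAAAA"),
                    label = 0L, protein_accession = "P1", cut_index = 11L,
                    stringsAsFactors = FALSE)
  expect_message(ds <- assemble_dataset(pos, dec), "1 decoy")
  expect_equal(sum(ds$label == 1L), 3L)
  expect_equal(sum(ds$label == 0L), 5L)
  expect_equal(attr(ds, "n_conflicts"), 1L)
  expect_equal(anyDuplicated(ds$window), 0)
  expect_equal(ds$window, sort(ds$window, method = "radix"))

  # duplicate decoy strings from different proteins: one retained
  dec2 <- rbind(dec[1:2, ], transform(dec[1L, ], protein_accession = "P2"))
  ds2 <- assemble_dataset(pos, dec2)
  expect_equal(sum(ds2$label == 0L), 2L)

  # disjoint sets preserved
  ds3 <- assemble_dataset(pos, dec[1:5, ])
  expect_equal(nrow(ds3), 8L)

  expect_error(assemble_dataset(pos[0L, ], dec), "positive")
})

test_that("positive windows re-validate against peptide and protein", {
  cfg <- synthetic_config(n_proteins = 6L, seed = 33L)
  proteome <- generate_proteome(cfg)
  ligands <- generate_ligands(proteome, cfg)
  built <- build_positive_windows(ligands, proteome)
  expect_gt(nrow(built), 0L)
  for (i in seq_len(nrow(built))) {
    w <- built$window[i]; ci <- built$cut_index[i]
    seqstr <- proteome[[built$protein_accession[i]]]
    # first 4 residues are a peptide suffix ending at the cut; last 3 follow it
    expect_equal(substring(seqstr, ci - 3L, ci), substring(w, 1L, 4L))
    expect_equal(substring(seqstr, ci + 1L, ci + 3L), substring(w, 5L, 7L))
  }
  dec <- generate_decoys(built, proteome)
  expect_lte(nrow(dec), 2L * nrow(built))
})

test_that("curate_immunogenicity collapses calls and discards conflicts", {
  recs <- data.frame(
    peptide = c("AAA", "AAA", "BBB", "BBB", "CCC", "CCC", "DDD"),
    allele = "H2-Kb",
    qualitative = c("Positive-Low", "Positive-High",   # -> positive
                    "Negative", "Positive",            # conflict -> discard
                    "Negative", "Negative",            # -> negative
                    "Positive-Intermediate"),
    technique = "ELISPOT", stringsAsFactors = FALSE)
  cur <- curate_immunogenicity(recs)
  expect_equal(cur$label[cur$peptide == "AAA"], 1L)
  expect_equal(cur$label[cur$peptide == "CCC"], 0L)
  expect_equal(cur$label[cur$peptide == "DDD"], 1L)
  expect_false("BBB" %in% cur$peptide)
  expect_equal(attr(cur, "discarded")$peptide, "BBB")

  # same peptide under different alleles is curated independently
  recs2 <- data.frame(peptide = "AAA", allele = c("H2-Kb", "H2-Db"),
                      qualitative = c("Positive", "Negative"),
                      technique = "ELISPOT", stringsAsFactors = FALSE)
  cur2 <- curate_immunogenicity(recs2)
  expect_equal(nrow(cur2), 2L)

  # technique filtering removes off-assay records before conflict detection
  recs3 <- rbind(recs,
                 data.frame(peptide = "CCC", allele = "H2-Kb",
                            qualitative = "Positive", technique = "ICS",
                            stringsAsFactors = FALSE))
  cur3 <- curate_immunogenicity(recs3, technique = "ELISPOT")
  expect_equal(cur3$label[cur3$peptide == "CCC"], 0L)

  expect_error(
    curate_immunogenicity(transform(recs, qualitative = "Maybe")),
    "Positive-High")
})

test_that("dataset construction is a pure function of its file inputs", {
  cfg <- synthetic_config(n_proteins = 5L, seed = 44L)
  dir <- tempfile("pure")
  d <- write_synthetic_dataset(cfg, dir)
  ds1 <- build_training_dataset(d$paths$ligands, d$paths$proteome)
  ds2 <- build_training_dataset(d$paths$ligands, d$paths$proteome)
  expect_identical(ds1, ds2)
})
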