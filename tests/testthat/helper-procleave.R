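# Shared fixture builders. Everything is generated in code under fixed
# seeds; no files ship with the tests.

AA <- procleave::STANDARD_RESIDUES

random_window <- function(p1 = NULL) {
  chars <- sample(AA, 7L, replace = TRUE)
  if (!is.null(p1)) chars[4L] <- p1  # position 4 = P1 (last residue before cut)
  paste(chars, collapse = "")
}

# Small linearly separable window set: positives have P1 in {F, L, Y},
# negatives do not. Much faster than the full synthetic pipeline for
# network unit tests.
make_separable_dataset <- function(n = 400L, seed = 11L) {
  withr::with_seed(seed, {
    n_pos <- n %/% 2L
    pos <- vapply(seq_len(n_pos),
                  function(i) random_window(sample(c("F", "L", "Y"), 1L)),
                  character(1L))
    neg <- vapply(seq_len(n - n_pos),
                  function(i) random_window(sample(setdiff(AA, c("F", "L", "Y")), 1L)),
                  character(1L))
  })
  data.frame(window = c(pos, neg),
             label = rep(c(1L, 0L), c(length(pos), length(neg))),
             protein_accession = "FIX", cut_index = NA_integer_,
             stringsAsFactors = FALSE)
}

# quick small trained model shared across scoring/metric tests
fast_config <- function(seed = 5L, max_epochs = 25L) {
  model_config(max_epochs = max_epochs, patience = 5L, seed = seed)
}

make_toy_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- train_cleavage_model(make_separable_dataset(400L, seed = 11L),
                                     config = fast_config())
    }
    cache
  }
})

# writes a ligand CSV with the default column layout; returns path
write_ligand_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
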