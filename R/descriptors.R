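# Amino-acid descriptor table, window encoding and feature standardization.

DESCRIPTOR_CATEGORIES <- c("hydrophobic", "steric", "electronic")
# 16 hydrophobic + 17 steric + 15 electronic descriptors per residue, so a
# 7-residue window encodes to 7 x 48 = 336 features and the hidden layer of
# the network is 336 / 3 = 112 units.
N_DESCRIPTORS <- 48L
N_FEATURES <- N_DESCRIPTORS * 7L  # 336

#' Load an amino-acid descriptor table
#'
#' Reads a 20 x 48 table of real-valued physicochemical descriptors, one row
#' per standard residue: 16 hydrophobic, 17 steric and 15 electronic
#' features, so a 7-residue cleavage window encodes to 7 x 48 = 336
#' features. The expected file layout is CSV with two header lines: the
#' first names the columns (`residue` followed by 48 descriptor names), the
#' second assigns each descriptor a category among `hydrophobic`, `steric`
#' and `electronic`.
#'
#' The packaged default (`path = NULL`) is a synthetic stand-in built from
#' well-known property scales (hydropathy, residue mass and volume, charge,
#' isoelectric point, polarity, accessible surface area, polarizability)
#' plus seeded surrogate columns; see the package vignette. Any conforming
#' user table can be supplied instead.
#'
#' @param path Path to a descriptor CSV, or `NULL` for the packaged default.
#' @return An object of class `aa_descriptor_table`: a list with `values`
#'   (20 x 48 numeric matrix, rownames the residue letters), `categories`
#'   (length-48 character vector) and `source`.
#' @examples
#' tab <- load_descriptor_table()
#' dim(tab$values)
#' descriptor_category_counts(tab)
#' @export
load_descriptor_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_descriptors_48_synthetic.csv",
                        package = "procleave", mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop("descriptor table file not found: ", path)
  }
  lines <- readLines(path)
  if (length(lines) < 3L) {
    stop("descriptor table '", path, "' is too short to hold header, ",
         "category row and residue rows")
  }
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  cats   <- strsplit(lines[[2L]], ",", fixed = TRUE)[[1L]]
  if (tolower(cats[[1L]]) != "category") {
    stop("descriptor table '", path, "' lacks the category header row ",
         "(second line must start with 'category')")
  }
  body <- read.csv(text = paste(lines[-2L], collapse = "\n"),
                   stringsAsFactors = FALSE, check.names = FALSE)
  values <- as.matrix(body[, -1L, drop = FALSE])
  rownames(values) <- toupper(trimws(body[[1L]]))
  # coercion failures surface as NA and are reported by the validator
  suppressWarnings(storage.mode(values) <- "double")
  tab <- structure(
    list(values = values,
         categories = cats[-1L],
         source = path),
    class = "aa_descriptor_table")
  validate_descriptor_table(tab)
  tab
}

# validate shape, residue set, category semantics; descriptive errors
validate_descriptor_table <- function(tab) {
  values <- tab$values
  residues <- rownames(values)
  missing <- setdiff(STANDARD_RESIDUES, residues)
  if (length(missing)) {
    stop("descriptor table is missing residue(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(residues, STANDARD_RESIDUES)
  if (length(extra)) {
    stop("descriptor table has non-standard residue row(s): ",
         paste(extra, collapse = ", "))
  }
  if (anyDuplicated(residues)) {
    stop("descriptor table has duplicated residue rows")
  }
  if (ncol(values) != N_DESCRIPTORS) {
    stop("descriptor table must have exactly ", N_DESCRIPTORS,
         " descriptor columns, found ", ncol(values))
  }
  if (anyNA(values) || !is.numeric(values)) {
    stop("descriptor table contains missing or non-numeric cells")
  }
  if (length(tab$categories) != N_DESCRIPTORS) {
    stop("expected ", N_DESCRIPTORS, " category labels, found ",
         length(tab$categories))
  }
  memb <- strsplit(tab$categories, "|", fixed = TRUE)
  unknown <- setdiff(unlist(memb), DESCRIPTOR_CATEGORIES)
  if (length(unknown)) {
    stop("unknown descriptor category label(s): ",
         paste(unique(unknown), collapse = ", "),
         " (allowed: ", paste(DESCRIPTOR_CATEGORIES, collapse = ", "), ")")
  }
  counts <- descriptor_category_counts(tab)
  expected <- c(hydrophobic = 16L, steric = 17L, electronic = 15L)
  if (!identical(counts[names(expected)], expected)) {
    stop("descriptor category membership counts must be 16 hydrophobic, ",
         "17 steric, 15 electronic; found ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  invisible(tab)
}

#' Count descriptor category memberships
#'
#' @param tab An `aa_descriptor_table`.
#' @return Named integer vector of membership counts over the categories
#'   `hydrophobic`, `steric`, `electronic` (16/17/15 for a valid table).
#' @export
descriptor_category_counts <- function(tab) {
  memb <- strsplit(tab$categories, "|", fixed = TRUE)
  vapply(stats::setNames(nm = DESCRIPTOR_CATEGORIES),
         function(cat) sum(vapply(memb, function(m) cat %in% m, logical(1L))),
         integer(1L))
}

#' @export
print.aa_descriptor_table <- function(x, ...) {
  counts <- descriptor_category_counts(x)
  cat("Amino-acid descriptor table:", nrow(x$values), "residues x",
      ncol(x$values), "descriptors\n")
  cat("Category membership:",
      paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  cat("Source:", x$source, "\n")
  invisible(x)
}

# cached default table; loading the CSV once per session is enough
default_descriptor_table <- function() {
  if (is.null(.procleave_env$descriptor_table)) {
    .procleave_env$descriptor_table <- load_descriptor_table()
  }
  .procleave_env$descriptor_table
}

# uppercases and returns NULL if valid, else a reason string
validate_window_string <- function(window) {
  if (!is.character(window) || length(window) != 1L || is.na(window)) {
    return("window must be a single character string")
  }
  w <- toupper(window)
  if (nchar(w) != WINDOW_SIZE) {
    return(sprintf("window must have exactly %d residues, got %d",
                   WINDOW_SIZE, nchar(w)))
  }
  chars <- strsplit(w, "")[[1L]]
  bad <- which(!(chars %in% STANDARD_RESIDUES))
  if (length(bad)) {
    return(sprintf("non-standard residue '%s' at position %d",
                   chars[bad[1L]], bad[1L]))
  }
  NULL
}

#' Encode a 7-residue cleavage window as a 336-long feature vector
#'
#' Each window position contributes a contiguous block of 48 descriptors in
#' table column order; blocks are laid out position-major from P4 to P3'.
#'
#' @param window A 7-residue string over the 20 standard one-letter codes
#'   (lowercase accepted and normalized).
#' @param table An `aa_descriptor_table`; defaults to the packaged table.
#' @return Named numeric vector of length 336 with attribute `window` (the
#'   normalized window string). Names are `<position>.<descriptor>`.
#' @examples
#' v <- encode_window("AKQRQIS")
#' length(v)
#' @export
encode_window <- function(window, table = default_descriptor_table()) {
  reason <- validate_window_string(window)
  if (!is.null(reason)) stop("cannot encode window: ", reason)
  w <- toupper(window)
  chars <- strsplit(w, "")[[1L]]
  vec <- as.vector(t(table$values[chars, , drop = FALSE]))
  names(vec) <- paste(rep(WINDOW_POSITIONS, each = N_DESCRIPTORS),
                      rep(colnames(table$values), times = WINDOW_SIZE),
                      sep = ".")
  attr(vec, "window") <- w
  vec
}

#' Encode many windows into a feature matrix
#'
#' Vectorized form of [encode_window()]. All windows must be valid; use
#' [predict_scores()] for per-row tolerance of invalid windows.
#'
#' @param windows Character vector of 7-residue windows.
#' @inheritParams encode_window
#' @return Numeric matrix, one row per window, 336 columns.
#' @export
encode_windows <- function(windows, table = default_descriptor_table()) {
  if (!length(windows)) {
    stop("no windows supplied for encoding")
  }
  windows <- toupper(windows)
  for (i in seq_along(windows)) {
    reason <- validate_window_string(windows[[i]])
    if (!is.null(reason)) {
      stop(sprintf("cannot encode window %d ('%s'): %s",
                   i, windows[[i]], reason))
    }
  }
  chars <- matrix(unlist(strsplit(windows, ""), use.names = FALSE),
                  nrow = length(windows), byrow = TRUE)
  blocks <- lapply(seq_len(WINDOW_SIZE), function(k) {
    table$values[chars[, k], , drop = FALSE]
  })
  mat <- do.call(cbind, blocks)
  dimnames(mat) <- list(
    windows,
    paste(rep(WINDOW_POSITIONS, each = N_DESCRIPTORS),
          rep(colnames(table$values), times = WINDOW_SIZE), sep = "."))
  mat
}

#' Fit a feature standardizer
#'
#' Computes per-feature means and population standard deviations over a
#' feature matrix (rows = samples). Zero-variance features get scale 1 so
#' that standardizing maps them to exactly 0. In the training pipeline the
#' standardizer is fitted on the training partition only and stored with the
#' model.
#'
#' @param x Numeric matrix of encoded windows (rows = samples).
#' @return Object of class `standardizer` with fields `means`, `scales`
#'   (strictly positive) and `fitted_on` (number of samples).
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    stop("standardizer needs at least 2 samples, got ", nrow(x))
  }
  means <- unname(colMeans(x))
  centered <- sweep(x, 2L, means)
  scales <- sqrt(unname(colMeans(centered^2)))  # population sd
  scales[scales == 0] <- 1
  structure(list(means = means, scales = scales, fitted_on = nrow(x)),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param object A `standardizer`.
#' @param x Feature matrix (or single feature vector) to transform.
#' @param ... Unused.
#' @return Matrix of standardized features, same shape as `x`.
#' @export
predict.standardizer <- function(object, x, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(object$means)) {
    stop("standardizer was fitted on ", length(object$means),
         " features but input has ", ncol(x))
  }
  sweep(sweep(x, 2L, object$means), 2L, object$scales, "/")
}

#' Invert a standardization
#'
#' @param object A `standardizer`.
#' @param z Standardized feature matrix.
#' @return Matrix on the original feature scale.
#' @export
invert_standardizer <- function(object, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  sweep(sweep(as.matrix(z), 2L, object$scales, "*"), 2L, object$means, "+")
}

#' @export
print.standardizer <- function(x, ...) {
  cat("Feature standardizer:", length(x$means), "features, fitted on",
      x$fitted_on, "samples\n")
  invisible(x)
}
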