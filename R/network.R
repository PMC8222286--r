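# One-hidden-layer feed-forward classifier: tanh hidden layer sized to one
# third of the input, inverted dropout, sigmoid output, plain SGD on binary
# cross entropy. Implemented directly on base matrices so training is fully
# deterministic under a seed and independent of external ML backends.

#' Model configuration
#'
#' Collects the architecture and optimization settings of the cleavage
#' classifier. Defaults follow the reference architecture: 336 inputs (7
#' positions x 48 descriptors), hidden layer one third of the input (112
#' units), tanh activations, dropout 0.5 on the hidden layer, a single
#' sigmoid output, SGD with learning rate 1e-2 and no momentum, binary
#' cross-entropy loss, Glorot-normal initialization. Epoch count, batch size
#' and early-stopping patience are not pinned by the reference description
#' and are exposed here with conservative defaults.
#'
#' @param input_size Number of input features.
#' @param hidden_fraction Hidden size as a fraction of `input_size`; the
#'   hidden layer has `floor(input_size * hidden_fraction)` units.
#' @param dropout_rate Probability a hidden unit is zeroed during training
#'   (inverted dropout: survivors are scaled by `1/(1-rate)` so inference
#'   needs no rescaling).
#' @param learning_rate SGD step size.
#' @param momentum SGD momentum (0 = plain SGD).
#' @param max_epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param patience Epochs without validation-loss improvement before early
#'   stop; best-validation weights are restored.
#' @param seed Integer seed controlling initialization, epoch shuffling and
#'   dropout masks.
#' @return Object of class `model_config`.
#' @export
model_config <- function(input_size = 336L, hidden_fraction = 1 / 3,
                         dropout_rate = 0.5, learning_rate = 1e-2,
                         momentum = 0, max_epochs = 200L, batch_size = 64L,
                         patience = 10L, seed = 42L) {
  # tiny epsilon so 336 * (1/3) survives serialization round-trips of the
  # fraction without dropping below the integer boundary
  hidden_size <- as.integer(floor(input_size * hidden_fraction + 1e-9))
  if (hidden_size < 1L) {
    stop("hidden layer must have at least 1 unit; input_size ", input_size,
         " with hidden_fraction ", hidden_fraction, " gives ", hidden_size)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)")
  }
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (max_epochs < 1L || batch_size < 1L || patience < 1L) {
    stop("max_epochs, batch_size and patience must be >= 1")
  }
  structure(list(input_size = as.integer(input_size),
                 hidden_fraction = hidden_fraction,
                 hidden_size = hidden_size,
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 momentum = momentum,
                 loss = "binary_cross_entropy",
                 activation = "tanh",
                 output_activation = "sigmoid",
                 init = "glorot_normal",
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("Network config: %d -> %d (tanh, dropout %.2f) -> 1 (sigmoid)\n",
              x$input_size, x$hidden_size, x$dropout_rate))
  cat(sprintf("SGD lr=%g momentum=%g, BCE loss, max %d epochs, batch %d, patience %d, seed %d\n",
              x$learning_rate, x$momentum, x$max_epochs, x$batch_size,
              x$patience, x$seed))
  invisible(x)
}

#' Split a labeled dataset into train / validation / test partitions
#'
#' Rows are shuffled with the given seed and partitioned with sizes
#' `floor(n * fraction)`; leftover rows are assigned one at a time starting
#' with the training partition. Default fractions are 60/30/10.
#'
#' @param dataset `data.frame` of labeled windows (any row-wise data).
#' @param fractions Length-3 positive numeric summing to 1:
#'   (train, validation, test).
#' @param seed Shuffle seed.
#' @return Named list of three data frames `train`, `validation`, `test`
#'   (attribute `indices` holds the row indices of each partition).
#' @export
split_data <- function(dataset, fractions = c(0.6, 0.3, 0.1), seed = 42L) {
  n <- nrow(dataset)
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three positive values summing to 1")
  }
  sizes <- floor(n * fractions)
  if (n < 10L || sizes[3L] < 1L) {
    stop("too few samples (", n, ") for a non-empty test partition")
  }
  remainder <- n - sum(sizes)
  k <- 0L
  while (remainder > 0L) {            # leftovers go train-first
    k <- k %% 3L + 1L
    sizes[k] <- sizes[k] + 1L
    remainder <- remainder - 1L
  }
  perm <- withr::with_seed(seed, sample.int(n))
  idx <- list(train = perm[seq_len(sizes[1L])],
              validation = perm[sizes[1L] + seq_len(sizes[2L])],
              test = perm[sizes[1L] + sizes[2L] + seq_len(sizes[3L])])
  out <- lapply(idx, function(i) {
    d <- dataset[i, , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  attr(out, "indices") <- idx
  out
}

#' Initialize network weights
#'
#' Glorot-normal initialization: each weight matrix is drawn from
#' `N(0, 2 / (fan_in + fan_out))`; biases start at zero.
#'
#' @param config A [model_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return List of class `nn_weights`: `W1` (input x hidden), `b1` (hidden),
#'   `w2` (hidden), `b2` (scalar).
#' @export
init_network <- function(config, seed = config$seed) {
  d <- config$input_size; h <- config$hidden_size
  draw <- function() {
    list(W1 = matrix(rnorm(d * h, sd = sqrt(2 / (d + h))), nrow = d, ncol = h),
         w2 = rnorm(h, sd = sqrt(2 / (h + 1))))
  }
  # seed = NULL draws from the active RNG stream (used inside training)
  drawn <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(list(W1 = drawn$W1, b1 = numeric(h), w2 = drawn$w2, b2 = 0),
            class = "nn_weights")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# numerically safe mean binary cross entropy
bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log1p(-p))
}

#' Forward pass of the classifier
#'
#' Computes `sigmoid(tanh(X W1 + b1) w2 + b2)`. With `training = TRUE` and a
#' positive dropout rate, hidden activations are zeroed independently with
#' probability `dropout_rate` and survivors scaled by `1/(1-rate)` (inverted
#' dropout); masks are drawn from the current RNG stream. At inference no
#' dropout is applied and the pass is a pure function of the weights.
#'
#' @param weights `nn_weights` list (`W1`, `b1`, `w2`, `b2`).
#' @param x Numeric matrix of standardized features (rows = samples), or a
#'   single feature vector.
#' @param training Apply dropout?
#' @param dropout_rate Dropout probability (ignored unless `training`).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
nn_forward <- function(weights, x, training = FALSE, dropout_rate = 0) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != nrow(weights$W1)) {
    stop("input has ", ncol(x), " features but the network expects ",
         nrow(weights$W1))
  }
  h <- tanh(sweep(x %*% weights$W1, 2L, weights$b1, "+"))
  if (training && dropout_rate > 0) {
    mask <- matrix(rbinom(length(h), 1L, 1 - dropout_rate),
                   nrow = nrow(h)) / (1 - dropout_rate)
    h <- h * mask
  }
  as.vector(sigmoid(h %*% weights$w2 + weights$b2))
}

# Loss and analytic gradients for one minibatch. `mask` is the (already
# scaled) dropout mask matrix or NULL. Shared by training and the
# finite-difference gradient check.
nn_loss_grads <- function(weights, x, y, mask = NULL) {
  ht <- tanh(sweep(x %*% weights$W1, 2L, weights$b1, "+"))
  h <- if (is.null(mask)) ht else ht * mask
  p <- as.vector(sigmoid(h %*% weights$w2 + weights$b2))
  n <- length(y)
  dz2 <- (p - y) / n                       # d loss / d output pre-activation
  gw2 <- as.vector(crossprod(h, dz2))
  gb2 <- sum(dz2)
  dh <- tcrossprod(dz2, weights$w2)
  if (!is.null(mask)) dh <- dh * mask
  dz1 <- dh * (1 - ht^2)
  gW1 <- unname(crossprod(x, dz1))   # keep weight arrays free of dimnames
  gb1 <- unname(colSums(dz1))
  list(loss = bce_loss(p, y),
       grads = list(W1 = gW1, b1 = gb1, w2 = gw2, b2 = gb2))
}

#' Train the cleavage classifier
#'
#' Encodes the labeled windows, splits them 60/30/10 into train, validation
#' and test partitions, fits the feature standardizer on the training
#' partition only, and runs minibatch SGD on binary cross entropy. Training
#' stops early when the validation loss has not improved for
#' `config$patience` epochs; the best-validation weights are restored. All
#' randomness (weight init, epoch shuffles, dropout masks) derives from
#' `config$seed`; the data shuffle of the split uses `split_seed`. Identical
#' seeds and data reproduce the run exactly.
#'
#' @param dataset `data.frame` with columns `window` (7-residue strings) and
#'   `label` (0/1), e.g. from [assemble_dataset()].
#' @param config A [model_config()].
#' @param table Descriptor table used for encoding.
#' @param fractions Train/validation/test fractions, see [split_data()].
#' @param split_seed Seed of the partition shuffle.
#' @param verbose Print per-epoch losses.
#' @return Object of class `cleavage_model`: weights, standardizer, config,
#'   per-epoch `history` (train/validation loss), `best_epoch`, the
#'   descriptor table, and the held-out `splits` (window/label frames).
#' @export
train_cleavage_model <- function(dataset, config = model_config(),
                                 table = default_descriptor_table(),
                                 fractions = c(0.6, 0.3, 0.1),
                                 split_seed = config$seed + 1L,
                                 verbose = FALSE) {
  if (!all(c("window", "label") %in% names(dataset))) {
    stop("dataset must have 'window' and 'label' columns")
  }
  labels <- as.integer(dataset$label)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L) {
    stop("training requires both classes; dataset is single-class")
  }
  splits <- split_data(dataset, fractions = fractions, seed = split_seed)

  enc <- lapply(splits, function(s) encode_windows(s$window, table = table))
  std <- fit_standardizer(enc$train)
  X <- lapply(enc, function(m) predict(std, m))
  y <- lapply(splits, function(s) as.integer(s$label))
  if (length(unique(y$train)) < 2L) {
    stop("training partition is single-class; use a different split seed")
  }

  cfg <- config
  n_train <- nrow(X$train)
  history <- data.frame(epoch = integer(0L), train_loss = numeric(0L),
                        val_loss = numeric(0L))
  best <- list(val = Inf, weights = NULL, epoch = 0L)

  withr::with_seed(cfg$seed, {
    w <- init_network(cfg, seed = NULL)  # draws from the active stream
    vel <- list(W1 = w$W1 * 0, b1 = w$b1 * 0, w2 = w$w2 * 0, b2 = 0)
    wait <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n_train)
      batch_losses <- numeric(0L)
      for (start in seq(1L, n_train, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, n_train)]
        xb <- X$train[idx, , drop = FALSE]
        yb <- y$train[idx]
        mask <- NULL
        if (cfg$dropout_rate > 0) {
          mask <- matrix(rbinom(length(idx) * cfg$hidden_size, 1L,
                                1 - cfg$dropout_rate),
                         nrow = length(idx)) / (1 - cfg$dropout_rate)
        }
        lg <- nn_loss_grads(w, xb, yb, mask = mask)
        if (!is.finite(lg$loss)) {
          stop("non-finite training loss at epoch ", epoch,
               "; reduce the learning rate or inspect the features")
        }
        batch_losses <- c(batch_losses, lg$loss)
        for (nm in names(vel)) {
          vel[[nm]] <- cfg$momentum * vel[[nm]] -
            cfg$learning_rate * lg$grads[[nm]]
          w[[nm]] <- w[[nm]] + vel[[nm]]
        }
      }
      val_p <- nn_forward(w, X$validation)
      val_loss <- bce_loss(val_p, y$validation)
      history[epoch, ] <- list(epoch, mean(batch_losses), val_loss)
      if (verbose) {
        cat(sprintf("epoch %3d  train %.4f  val %.4f\n",
                    epoch, mean(batch_losses), val_loss))
      }
      if (val_loss < best$val - 1e-12) {
        best <- list(val = val_loss, weights = w, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })

  class_balance <- vapply(y, mean, numeric(1L))
  structure(list(weights = best$weights,
                 standardizer = std,
                 config = cfg,
                 history = history,
                 best_epoch = best$epoch,
                 class_balance = class_balance,
                 descriptor_table = table,
                 splits = lapply(splits, function(s) {
                   s[, c("window", "label"), drop = FALSE]
                 }),
                 format_version = 1L),
            class = "cleavage_model")
}

#' @export
print.cleavage_model <- function(x, ...) {
  cat("Cleavage-site classifier\n")
  print(x$config)
  cat(sprintf("Trained %d epoch(s); best validation loss %.4f at epoch %d\n",
              nrow(x$history), min(x$history$val_loss), x$best_epoch))
  cat("Split positive fractions:",
      paste(names(x$class_balance),
            sprintf("%.3f", x$class_balance), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Score cleavage windows with a trained model
#'
#' Windows are validated, encoded, standardized with the model's stored
#' standardizer and passed through the network at inference (no dropout).
#' Invalid windows yield a per-row status instead of a global failure.
#'
#' @param model A `cleavage_model`.
#' @param windows Character vector of 7-residue windows.
#' @return `data.frame` with columns `window`, `score` (NA when invalid) and
#'   `status` ("ok" or the validation failure reason), in input order.
#' @export
predict_scores <- function(model, windows) {
  windows <- toupper(as.character(windows))
  status <- vapply(windows, function(w) {
    r <- validate_window_string(w)
    if (is.null(r)) "ok" else r
  }, character(1L), USE.NAMES = FALSE)
  score <- rep(NA_real_, length(windows))
  ok <- status == "ok"
  if (any(ok)) {
    X <- encode_windows(windows[ok], table = model$descriptor_table)
    score[ok] <- nn_forward(model$weights, predict(model$standardizer, X))
  }
  data.frame(window = windows, score = score, status = status,
             stringsAsFactors = FALSE)
}

# matrix <-> portable list helpers for JSON serialization
pack_matrix <- function(m) list(dim = dim(m), data = as.vector(m))
unpack_matrix <- function(p) matrix(p$data, nrow = p$dim[[1L]],
                                    ncol = p$dim[[2L]])

#' Save a trained model to a versioned JSON file
#'
#' The file holds the weight arrays, the standardizer, the configuration,
#' the training history, the descriptor table and the data split, all at
#' full double precision, so a reloaded model reproduces scores to well
#' under 1e-9.
#'
#' @param model A `cleavage_model`.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  payload <- list(
    format = "procleave-model",
    format_version = 1L,
    config = unclass(model$config),
    standardizer = unclass(model$standardizer),
    weights = list(W1 = pack_matrix(model$weights$W1),
                   b1 = model$weights$b1,
                   w2 = model$weights$w2,
                   b2 = model$weights$b2),
    history = model$history,
    best_epoch = model$best_epoch,
    class_balance = as.list(model$class_balance),
    descriptor_table = list(values = pack_matrix(model$descriptor_table$values),
                            residues = rownames(model$descriptor_table$values),
                            descriptors = colnames(model$descriptor_table$values),
                            categories = model$descriptor_table$categories,
                            source = model$descriptor_table$source),
    splits = model$splits)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Model JSON path.
#' @return A `cleavage_model`.
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop("cannot read model file '", path,
                             "': corrupted or not a model archive (",
                             conditionMessage(e), ")")
                      })
  if (!identical(payload$format, "procleave-model")) {
    stop("file '", path, "' is not a procleave model archive")
  }
  if (!identical(as.integer(payload$format_version), 1L)) {
    stop("unsupported model format version: ", payload$format_version)
  }
  cfg <- payload$config
  config <- model_config(input_size = cfg$input_size,
                         hidden_fraction = cfg$hidden_fraction,
                         dropout_rate = cfg$dropout_rate,
                         learning_rate = cfg$learning_rate,
                         momentum = cfg$momentum,
                         max_epochs = cfg$max_epochs,
                         batch_size = cfg$batch_size,
                         patience = cfg$patience,
                         seed = cfg$seed)
  weights <- structure(list(W1 = unpack_matrix(payload$weights$W1),
                            b1 = as.numeric(payload$weights$b1),
                            w2 = as.numeric(payload$weights$w2),
                            b2 = as.numeric(payload$weights$b2)),
                       class = "nn_weights")
  std <- structure(list(means = as.numeric(payload$standardizer$means),
                        scales = as.numeric(payload$standardizer$scales),
                        fitted_on = payload$standardizer$fitted_on),
                   class = "standardizer")
  values <- unpack_matrix(payload$descriptor_table$values)
  dimnames(values) <- list(payload$descriptor_table$residues,
                           payload$descriptor_table$descriptors)
  table <- structure(list(values = values,
                          categories = payload$descriptor_table$categories,
                          source = payload$descriptor_table$source),
                     class = "aa_descriptor_table")
  validate_descriptor_table(table)
  structure(list(weights = weights,
                 standardizer = std,
                 config = config,
                 history = as.data.frame(payload$history),
                 best_epoch = payload$best_epoch,
                 class_balance = unlist(payload$class_balance),
                 descriptor_table = table,
                 splits = lapply(payload$splits, as.data.frame),
                 format_version = 1L),
            class = "cleavage_model")
}
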