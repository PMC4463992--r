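# Fitting the nine combination weights from labelled pairs. The published
# combination rule is an intercept-free linear form, so the default model is
# a single linear output unit without bias trained by full-batch gradient
# descent on squared error (classic delta-rule back-propagation). A
# one-hidden-layer network is available as a non-default alternative.

#' Training configuration
#'
#' @param learning_rate Step size of full-batch gradient descent; must be
#'   positive. Default 0.3, stable for features on the `[-0.5, 1]` scale.
#' @param epochs Maximum number of full-batch passes (>= 1).
#' @param seed Integer seed; only consumed by the randomly initialised
#'   one-hidden-layer architecture (the linear model starts from zeros and
#'   is deterministic regardless).
#' @param architecture `"linear"` (default, intercept-free single unit) or
#'   `"one_hidden"` (sigmoid hidden layer, linear output).
#' @param tol Stop early once the squared-error loss changes by less than
#'   this between epochs.
#' @param hidden_units Hidden-layer width for `"one_hidden"`.
#' @return List of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.3, epochs = 20000L, seed = 1L,
                            architecture = c("linear", "one_hidden"),
                            tol = 1e-15, hidden_units = 5L) {
  architecture <- match.arg(architecture)
  if (!is.numeric(learning_rate) || learning_rate <= 0) stop("learning_rate must be > 0")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), architecture = architecture,
                 tol = tol, hidden_units = as.integer(hidden_units)),
            class = "training_config")
}

# Accepts a 10-column data.frame (S1..S9, S) or list(features, labels) and
# returns a design matrix X (n x 9) and response y.
.as_training_matrix <- function(pairs) {
  if (is.data.frame(pairs)) {
    nm <- toupper(names(pairs))
    feat_cols <- match(paste0("S", 1:9), nm)
    lab_col <- match("S", nm)
    if (any(is.na(feat_cols)) || is.na(lab_col)) {
      stop("a training table needs the ten columns S1..S9 and S")
    }
    X <- as.matrix(pairs[, feat_cols, drop = FALSE])
    y <- as.numeric(pairs[[lab_col]])
  } else if (is.list(pairs) && !is.null(pairs$features) && !is.null(pairs$labels)) {
    X <- as.matrix(pairs$features)
    y <- as.numeric(pairs$labels)
  } else {
    stop("pairs must be a 10-column training table or list(features, labels)")
  }
  if (ncol(X) != 9L) stop("training features must have nine columns")
  if (nrow(X) != length(y)) stop("features and labels disagree in length")
  if (any(!is.finite(X)) || any(!is.finite(y))) stop("training data must be finite")
  storage.mode(X) <- "double"
  list(X = X, y = y)
}

#' Fit the nine combination weights by gradient descent
#'
#' Trains the intercept-free linear model `S ~ q1*S1 + ... + q9*S9` by
#' full-batch gradient descent on the mean squared error. The problem is
#' convex, so with the default configuration the fit converges to the
#' least-squares solution; no non-negativity or sum-to-one constraint is
#' imposed (the published weights sum to 1.0007). Results are deterministic
#' given the data and configuration, and invariant to row order because
#' every epoch uses the full batch.
#'
#' @param pairs Training data: a 10-column `data.frame` (S1..S9 features, S
#'   label) or `list(features, labels)`.
#' @param cfg A [training_config()].
#' @return List with `weights` (named `q1` ... `q9`; `NULL` for the
#'   one-hidden-layer model, whose parameters are in `model`), `model`
#'   (architecture-specific parameters and a `predict` closure), and
#'   `diagnostics` (`final_loss`, `epochs_run`, `converged`).
#' @export
train_weights <- function(pairs, cfg = training_config()) {
  stopifnot(inherits(cfg, "training_config"))
  d <- .as_training_matrix(pairs)
  X <- d$X
  y <- d$y
  n <- nrow(X)
  if (n < 1L) stop("the training set is empty")
  if (cfg$architecture == "linear" && n < 9L) {
    stop("the linear model needs at least nine training pairs")
  }
  if (cfg$architecture == "linear") .train_linear(X, y, cfg) else .train_one_hidden(X, y, cfg)
}

.train_linear <- function(X, y, cfg) {
  n <- nrow(X)
  w <- rep(0, 9L)
  prev_loss <- Inf
  epochs_run <- 0L
  converged <- FALSE
  for (t in seq_len(cfg$epochs)) {
    resid <- y - drop(X %*% w)
    loss <- mean(resid^2)
    if (!is.finite(loss)) {
      stop(sprintf("training diverged (non-finite loss) at epoch %d; lower the learning rate", t))
    }
    epochs_run <- t
    if (abs(prev_loss - loss) < cfg$tol) { converged <- TRUE; break }
    prev_loss <- loss
    grad <- -2 * drop(crossprod(X, resid)) / n
    w <- w - cfg$learning_rate * grad
  }
  final_loss <- mean((y - drop(X %*% w))^2)
  weights <- stats::setNames(w, paste0("q", 1:9))
  list(
    weights = weights,
    model = list(architecture = "linear",
                 predict = function(Xnew) drop(as.matrix(Xnew) %*% w)),
    diagnostics = list(final_loss = final_loss, epochs_run = epochs_run,
                       converged = converged)
  )
}

.train_one_hidden <- function(X, y, cfg) {
  n <- nrow(X)
  h <- cfg$hidden_units
  set.seed(cfg$seed)
  W1 <- matrix(stats::rnorm(9L * h, sd = 0.3), 9L, h)
  b1 <- rep(0, h)
  w2 <- stats::rnorm(h, sd = 0.3)
  b2 <- 0
  sigm <- function(z) 1 / (1 + exp(-z))
  prev_loss <- Inf
  epochs_run <- 0L
  converged <- FALSE
  for (t in seq_len(cfg$epochs)) {
    Z <- sweep(X %*% W1, 2L, b1, "+")
    H <- sigm(Z)
    pred <- drop(H %*% w2) + b2
    resid <- y - pred
    loss <- mean(resid^2)
    if (!is.finite(loss)) {
      stop(sprintf("training diverged (non-finite loss) at epoch %d; lower the learning rate", t))
    }
    epochs_run <- t
    if (abs(prev_loss - loss) < cfg$tol) { converged <- TRUE; break }
    prev_loss <- loss
    dout <- -2 * resid / n
    gw2 <- drop(crossprod(H, dout))
    gb2 <- sum(dout)
    dH <- outer(dout, w2) * H * (1 - H)
    gW1 <- crossprod(X, dH)
    gb1 <- colSums(dH)
    w2 <- w2 - cfg$learning_rate * gw2
    b2 <- b2 - cfg$learning_rate * gb2
    W1 <- W1 - cfg$learning_rate * gW1
    b1 <- b1 - cfg$learning_rate * gb1
  }
  predict_fn <- function(Xnew) {
    H <- sigm(sweep(as.matrix(Xnew) %*% W1, 2L, b1, "+"))
    drop(H %*% w2) + b2
  }
  final_loss <- mean((y - predict_fn(X))^2)
  list(
    weights = NULL,
    model = list(architecture = "one_hidden", W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                 predict = predict_fn),
    diagnostics = list(final_loss = final_loss, epochs_run = epochs_run,
                       converged = converged)
  )
}

#' Root-mean-squared prediction error of a weight vector
#'
#' Evaluates the dot-product model with weights `w` on labelled pairs.
#'
#' @param w Named or plain numeric vector of nine weights.
#' @param pairs Training data as for [train_weights()].
#' @return Single non-negative RMSE.
#' @export
evaluate_weights <- function(w, pairs) {
  w <- as.numeric(w)
  if (length(w) != 9L) stop("w must have nine components")
  d <- .as_training_matrix(pairs)
  if (nrow(d$X) < 1L) stop("no pairs to evaluate")
  sqrt(mean((d$y - drop(d$X %*% w))^2))
}

#' Read and write training tables and weight files
#'
#' Training tables are tab-delimited with a required header of ten columns
#' `S1` ... `S9`, `S`. Weight files are two-column tab-delimited
#' (`parameter`, `weight`) as consumed by the similarity stage.
#'
#' @param path File path.
#' @return `read_training_table`: a 10-column `data.frame`;
#'   `read_weights`: named numeric `q1` ... `q9`.
#' @export
read_training_table <- function(path) {
  if (!file.exists(path)) stop("training table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  nm <- toupper(names(tab))
  want <- c(paste0("S", 1:9), "S")
  if (!all(want %in% nm)) {
    stop("malformed training table ", path, " (header line 1): expected columns ",
         paste(want, collapse = ", "))
  }
  bad <- which(!stats::complete.cases(tab))
  if (length(bad) > 0L) {
    stop(sprintf("malformed training table %s: missing value in data line %d",
                 path, bad[1L] + 1L))
  }
  tab
}

#' @rdname read_training_table
#' @param tab Training table to write.
#' @export
write_training_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_training_table
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("parameter", "weight") %in% names(tab))) {
    stop("malformed weights file ", path, ": expected columns parameter, weight")
  }
  w <- stats::setNames(tab$weight, tab$parameter)
  want <- paste0("q", 1:9)
  if (!all(want %in% names(w))) stop("weights file ", path, " must define q1..q9")
  w[want]
}

#' @rdname read_training_table
#' @param w Named nine-weight vector to write.
#' @export
write_weights <- function(w, path) {
  w <- stats::setNames(as.numeric(w), paste0("q", 1:9))
  utils::write.table(data.frame(parameter = names(w), weight = unname(w)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
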