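#' Confusion matrix in output x target orientation
#'
#' Rows are the predicted (output) class, columns the true (target)
#' class, so column sums equal the per-class test counts.
#'
#' @param predicted,truth class labels (coerced to factors over `levels`)
#' @param levels class levels; defaults to the union of observed labels
#' @return integer k x k matrix with dimnames `output` / `target`
#' @export
confusion_matrix <- function(predicted, truth, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(as.character(predicted),
                                               as.character(truth))))
  tab <- table(factor(predicted, levels = levels),
               factor(truth, levels = levels))
  m <- matrix(as.integer(tab), nrow = length(levels),
              dimnames = list(output = levels, target = levels))
  m
}

round_half_up <- function(x) floor(x + 0.5)

#' Per-class and overall success rates of a confusion matrix
#'
#' Per-class rate = 100 * diagonal / column sum (the fraction of each
#' target class identified correctly); overall = 100 * trace / total.
#' Classes with no test spectra get `NA` and are flagged.
#'
#' @param cm confusion matrix in output x target orientation
#' @return list with `per_class`, `overall` (exact percentages),
#'   `per_class_rounded`, `overall_rounded` (integer percent,
#'   half-up), `undefined_classes`
#' @export
success_rates <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  cs <- colSums(cm)
  per <- ifelse(cs > 0, 100 * diag(cm) / cs, NA_real_)
  names(per) <- colnames(cm)
  overall <- 100 * sum(diag(cm)) / sum(cm)
  list(per_class = per, overall = overall,
       per_class_rounded = round_half_up(per),
       overall_rounded = round_half_up(overall),
       undefined_classes = colnames(cm)[cs == 0])
}

one_hot <- function(y) {
  y <- as.factor(y)
  Y <- matrix(0, length(y), nlevels(y),
              dimnames = list(NULL, levels(y)))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

#' Fit a PLS-DA model
#'
#' PLS2 regression (NIPALS) of the one-hot class indicator matrix on the
#' mean-centred spectra; prediction is the argmax of the fitted class
#' scores. Deflation makes the component sequence nested, so a model
#' fitted with `n_lv` latent variables can predict with any smaller
#' number.
#'
#' @param X numeric matrix, spectra in rows
#' @param y class labels (>= 2 classes, none empty)
#' @param n_lv number of latent variables, `<= min(n - 1, ncol(X))`
#' @return a `plsda_model`
#' @export
plsda_fit <- function(X, y, n_lv) {
  X <- as.matrix(X)
  y <- as.factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) == 0)) stop("degenerate class with 0 samples")
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n_lv >= 1, n_lv <= min(n - 1, p))
  x_mean <- colMeans(X)
  Y <- one_hot(y)
  y_mean <- colMeans(Y)
  E <- sweep(X, 2, x_mean)
  F <- sweep(Y, 2, y_mean)
  q <- ncol(Y)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Q <- matrix(0, q, n_lv)
  for (a in seq_len(n_lv)) {
    # the NIPALS inner loop converges to w = dominant eigenvector of
    # E'FF'E; with q classes this is obtained exactly from the q x q
    # eigensystem of (F'E)(F'E)', avoiding the power iteration
    M <- crossprod(F, E)                  # q x p
    v <- eigen(tcrossprod(M), symmetric = TRUE)$vectors[, 1]
    w <- as.vector(crossprod(M, v))
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w   # fix the sign convention
    tt <- E %*% w
    qq <- crossprod(F, tt) / sum(tt^2)
    pp <- crossprod(E, tt) / sum(tt^2)
    E <- E - tcrossprod(tt, pp)
    F <- F - tcrossprod(tt, qq)
    W[, a] <- w; P[, a] <- pp; Q[, a] <- qq
  }
  structure(list(W = W, P = P, Q = Q, x_mean = x_mean, y_mean = y_mean,
                 n_lv = as.integer(n_lv), levels = levels(y)),
            class = "plsda_model")
}

plsda_coefficients <- function(model, ncomp = model$n_lv) {
  stopifnot(ncomp >= 1, ncomp <= model$n_lv)
  idx <- seq_len(ncomp)
  W <- model$W[, idx, drop = FALSE]
  P <- model$P[, idx, drop = FALSE]
  Q <- model$Q[, idx, drop = FALSE]
  W %*% solve(crossprod(P, W), t(Q))
}

#' Predict classes from a PLS-DA model
#'
#' @param object a `plsda_model`
#' @param newdata matrix of spectra in rows
#' @param ncomp number of latent variables to use (default: all fitted)
#' @param ... unused
#' @return list with `class` (factor) and `scores` (fitted one-hot
#'   responses)
#' @export
predict.plsda_model <- function(object, newdata, ncomp = object$n_lv, ...) {
  newdata <- as.matrix(newdata)
  B <- plsda_coefficients(object, ncomp)
  scores <- sweep(newdata, 2, object$x_mean) %*% B
  scores <- sweep(scores, 2, object$y_mean, `+`)
  cls <- factor(object$levels[max.col(scores, ties.method = "first")],
                levels = object$levels)
  list(class = cls, scores = scores)
}

stratified_folds <- function(y, folds, seed) {
  y <- as.factor(y)
  assignment <- integer(length(y))
  with_seed(seed, {
    for (lev in levels(y)) {
      idx <- which(y == lev)
      assignment[idx] <- sample(rep(seq_len(folds),
                                    length.out = length(idx)))
    }
  })
  assignment
}

#' Choose the number of PLS-DA latent variables by cross-validation
#'
#' Stratified k-fold cross-validation accuracy for every candidate;
#' returns the argmax, smallest candidate on ties.
#'
#' @param X spectra matrix
#' @param y class labels
#' @param candidates candidate latent-variable counts
#' @param folds number of folds (default 10)
#' @param seed fold-assignment seed
#' @return list with `n_lv` (chosen), `cv_accuracy` (per candidate),
#'   `candidates`
#' @export
optimize_n_lv <- function(X, y, candidates = 1:15, folds = 10L, seed = 1L) {
  stopifnot(length(candidates) >= 1)
  X <- as.matrix(X); y <- as.factor(y)
  candidates <- sort(unique(as.integer(candidates)))
  fold_id <- stratified_folds(y, folds, seed)
  correct <- numeric(length(candidates))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    if (nlevels(droplevels(y[tr])) < nlevels(y)) {
      stop("a training fold lost an entire class; use fewer folds")
    }
    fit <- plsda_fit(X[tr, , drop = FALSE], y[tr], max(candidates))
    for (ci in seq_along(candidates)) {
      pred <- predict(fit, X[!tr, , drop = FALSE],
                      ncomp = candidates[ci])$class
      correct[ci] <- correct[ci] + sum(pred == y[!tr])
    }
  }
  acc <- correct / length(y)
  list(n_lv = candidates[which.max(acc)], cv_accuracy = acc,
       candidates = candidates)
}

#' Leave-one-out cross-validated PLS-DA confusion matrix
#'
#' Refits the model n times, each time predicting the single held-out
#' spectrum ("full CV").
#'
#' @param X spectra matrix
#' @param y class labels
#' @param n_lv latent variables per fit
#' @return confusion matrix (output x target) over all n predictions
#' @export
full_loo_cv <- function(X, y, n_lv) {
  X <- as.matrix(X); y <- as.factor(y)
  n <- nrow(X)
  stopifnot(n >= 2 * nlevels(y))
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- plsda_fit(X[-i, , drop = FALSE], y[-i], n_lv)
    pred[i] <- as.character(predict(fit, X[i, , drop = FALSE])$class)
  }
  confusion_matrix(pred, y, levels = levels(y))
}

#' Neural-network classifier configuration
#'
#' One hidden tanh layer and a softmax output, trained full-batch with
#' Adam and early stopping on a validation split. The default 50 hidden
#' units on 519 inputs and the 0.70/0.25/0.05 train/validation/internal
#' test split follow the single-grain study design; training algorithm,
#' learning rate and patience are this package's own choices.
#'
#' @param hidden hidden-layer width
#' @param split train/validation/internal-test fractions, summing to 1
#' @param max_epochs training epoch cap
#' @param patience early-stopping patience (epochs without validation
#'   improvement)
#' @param learning_rate Adam step size
#' @param seed initialisation and split seed
#' @return an `ann_config` list
#' @export
ann_config <- function(hidden = 50L, split = c(0.70, 0.25, 0.05),
                       max_epochs = 300L, patience = 20L,
                       learning_rate = 0.01, seed = 1L) {
  stopifnot(abs(sum(split) - 1) < 1e-8, length(split) == 3, hidden >= 1)
  structure(list(hidden = as.integer(hidden), split = split,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "ann_config")
}

# stratified 3-way split of indices by class; rounding by largest
# remainder within each class, training set absorbs the slack
split_indices <- function(y, split) {
  y <- as.factor(y)
  out <- list(train = integer(), val = integer(), test = integer())
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    n <- length(idx)
    n_val <- round(split[2] * n)
    n_test <- round(split[3] * n)
    n_train <- n - n_val - n_test
    out$train <- c(out$train, idx[seq_len(n_train)])
    out$val <- c(out$val, idx[n_train + seq_len(n_val)])
    out$test <- c(out$test, idx[n_train + n_val + seq_len(n_test)])
  }
  out
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

cross_entropy <- function(Pr, Y) -mean(rowSums(Y * log(pmax(Pr, 1e-12))))

#' Train a feed-forward neural network and predict a test set
#'
#' Architecture input-hidden-softmax (by default 519-50-5). The training
#' spectra are split 70/25/5 into training, validation and internal test
#' parts; full-batch Adam minimises cross-entropy and training stops when
#' the validation loss fails to improve for `patience` epochs, restoring
#' the best weights. Deterministic given `config$seed`.
#'
#' @param train_X,train_y training spectra and labels
#' @param test_X spectra to classify
#' @param config an [ann_config()]
#' @return list with `class` (predicted factor for `test_X`),
#'   `internal_test_accuracy`, `epochs_run`, `split_sizes`
#' @export
ann_train_predict <- function(train_X, train_y, test_X,
                              config = ann_config()) {
  train_X <- as.matrix(train_X); test_X <- as.matrix(test_X)
  train_y <- as.factor(train_y)
  stopifnot(ncol(test_X) == ncol(train_X))
  p <- ncol(train_X); h <- config$hidden; q <- nlevels(train_y)
  x_mean <- colMeans(train_X)
  x_scale <- stats::sd(as.vector(sweep(train_X, 2, x_mean)))
  if (x_scale == 0) x_scale <- 1
  std <- function(X) sweep(X, 2, x_mean) / x_scale
  with_seed(config$seed, {
    parts <- split_indices(train_y, config$split)
    Xtr <- std(train_X[parts$train, , drop = FALSE])
    Ytr <- one_hot(train_y)[parts$train, , drop = FALSE]
    Xval <- std(train_X[parts$val, , drop = FALSE])
    Yval <- one_hot(train_y)[parts$val, , drop = FALSE]
    W1 <- matrix(stats::rnorm(p * h, 0, 1 / sqrt(p)), p, h)
    b1 <- numeric(h)
    W2 <- matrix(stats::rnorm(h * q, 0, 1 / sqrt(h)), h, q)
    b2 <- numeric(q)
  })
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  mom <- lapply(params, function(x) x * 0)
  vel <- lapply(params, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  best <- params; best_val <- Inf; wait <- 0; epochs <- 0
  n_tr <- nrow(Xtr)
  for (epoch in seq_len(config$max_epochs)) {
    epochs <- epoch
    A1 <- tanh(sweep(Xtr %*% params$W1, 2, params$b1, `+`))
    Pr <- softmax_rows(sweep(A1 %*% params$W2, 2, params$b2, `+`))
    dZ2 <- (Pr - Ytr) / n_tr
    grads <- list(
      W1 = crossprod(Xtr, (dZ2 %*% t(params$W2)) * (1 - A1^2)),
      b1 = colSums((dZ2 %*% t(params$W2)) * (1 - A1^2)),
      W2 = crossprod(A1, dZ2),
      b2 = colSums(dZ2))
    for (nm in names(params)) {
      mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grads[[nm]]
      vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grads[[nm]]^2
      m_hat <- mom[[nm]] / (1 - beta1^epoch)
      v_hat <- vel[[nm]] / (1 - beta2^epoch)
      params[[nm]] <- params[[nm]] - lr * m_hat / (sqrt(v_hat) + eps)
    }
    A1v <- tanh(sweep(Xval %*% params$W1, 2, params$b1, `+`))
    val_loss <- cross_entropy(
      softmax_rows(sweep(A1v %*% params$W2, 2, params$b2, `+`)), Yval)
    if (!is.finite(val_loss)) stop("non-finite validation loss at epoch ",
                                   epoch)
    if (val_loss < best_val - 1e-6) {
      best_val <- val_loss; best <- params; wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience) break
    }
  }
  fwd <- function(X) {
    A1 <- tanh(sweep(X %*% best$W1, 2, best$b1, `+`))
    softmax_rows(sweep(A1 %*% best$W2, 2, best$b2, `+`))
  }
  internal <- if (length(parts$test)) {
    pr <- fwd(std(train_X[parts$test, , drop = FALSE]))
    mean(levels(train_y)[max.col(pr)] ==
           as.character(train_y[parts$test]))
  } else NA_real_
  pr_test <- fwd(std(test_X))
  list(class = factor(levels(train_y)[max.col(pr_test, ties.method = "first")],
                      levels = levels(train_y)),
       internal_test_accuracy = internal, epochs_run = epochs,
       split_sizes = vapply(parts, length, integer(1)))
}

#' Random-forest classifier configuration
#'
#' @param n_trees number of trees (default 300)
#' @param seed RNG seed
#' @return an `rf_config` list
#' @export
rf_config <- function(n_trees = 300L, seed = 1L) {
  stopifnot(n_trees >= 1)
  structure(list(n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "rf_config")
}

#' Train a random forest and predict a test set
#'
#' Bagged decision trees with majority vote and the square-root
#' feature-subsampling heuristic; deterministic given `config$seed`.
#'
#' @param train_X,train_y training spectra and labels
#' @param test_X spectra to classify
#' @param config an [rf_config()]
#' @return list with `class` (predicted factor) and `fit`
#' @export
rf_train_predict <- function(train_X, train_y, test_X,
                             config = rf_config()) {
  train_y <- as.factor(train_y)
  train_X <- as.matrix(train_X)
  colnames(train_X) <- paste0("v", seq_len(ncol(train_X)))
  test_X <- as.matrix(test_X)
  colnames(test_X) <- colnames(train_X)
  fit <- with_seed(config$seed,
                   randomForest::randomForest(x = train_X, y = train_y,
                                              ntree = config$n_trees))
  list(class = stats::predict(fit, test_X), fit = fit)
}

#' Evaluate a classifier on an independent-population split
#'
#' Trains on one population per species and tests once on the other.
#' Raises an error if any (species, population) pair appears in both
#' sets, which would leak test-population information into training.
#' Preprocessing statistics must already have been computed on the
#' training side only (see [run_pipeline()], which enforces this).
#'
#' @param train,test [spectra_set]s with species and population metadata
#' @param classifier `"plsda"`, `"ann"` or `"rf"`
#' @param n_lv latent variables for PLS-DA
#' @param ann,rf configurations for the other classifiers
#' @return list with `confusion`, `rates` ([success_rates()]),
#'   `predictions`, `classifier`
#' @export
population_split_eval <- function(train, test,
                                  classifier = c("plsda", "ann", "rf"),
                                  n_lv = 9L, ann = ann_config(),
                                  rf = rf_config()) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(train, "spectra_set"), inherits(test, "spectra_set"))
  key <- function(s) unique(paste(s$meta$species, s$meta$population))
  leak <- intersect(key(train), key(test))
  if (length(leak)) {
    stop("population leakage: (species, population) in both sets: ",
         paste(leak, collapse = "; "))
  }
  levels <- sort(unique(train$meta$species))
  y_train <- factor(train$meta$species, levels = levels)
  pred <- switch(classifier,
    plsda = {
      fit <- plsda_fit(train$spectra, y_train, n_lv)
      predict(fit, test$spectra)$class
    },
    ann = ann_train_predict(train$spectra, y_train, test$spectra,
                            ann)$class,
    rf = rf_train_predict(train$spectra, y_train, test$spectra, rf)$class)
  cm <- confusion_matrix(pred, factor(test$meta$species, levels = levels),
                         levels = levels)
  list(confusion = cm, rates = success_rates(cm), predictions = pred,
       classifier = classifier)
}
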