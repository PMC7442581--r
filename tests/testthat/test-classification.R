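test_that("success rates follow their defining identities", {
  cm <- matrix(c(5, 0, 1,
                 0, 4, 0,
                 0, 2, 3), 3, byrow = TRUE,
               dimnames = list(output = letters[1:3],
                               target = letters[1:3]))
  r <- success_rates(cm)
  expect_equal(unname(r$per_class), 100 * c(5 / 5, 4 / 6, 3 / 4))
  expect_equal(r$overall, 100 * 12 / 15)
  # overall is the column-sum-weighted mean of per-class rates
  expect_equal(r$overall,
               sum(r$per_class * colSums(cm)) / sum(cm))
  expect_equal(unname(success_rates(diag(4))$per_class), rep(100, 4))
  # zero column flagged
  cm0 <- cm; cm0[, 2] <- 0
  expect_equal(success_rates(cm0)$undefined_classes, "b")
})

test_that("confusion matrices conserve test counts and permute with labels", {
  set.seed(20)
  truth <- sample(letters[1:4], 60, replace = TRUE)
  pred <- sample(letters[1:4], 60, replace = TRUE)
  cm <- confusion_matrix(pred, truth, levels = letters[1:4])
  expect_equal(unname(colSums(cm)), unname(as.vector(table(
    factor(truth, levels = letters[1:4])))))
  # permuting the class label alphabet permutes rows and columns together
  perm <- c(3, 1, 4, 2)
  cm2 <- confusion_matrix(pred, truth, levels = letters[1:4][perm])
  expect_equal(unname(cm2), unname(cm[perm, perm]))
})

test_that("PLS-DA separates two well-separated classes perfectly", {
  d <- separable_classes()
  fit <- plsda_fit(d$X, d$y, 2)
  expect_equal(mean(predict(fit, d$X)$class == d$y), 1)
  cm <- full_loo_cv(d$X, d$y, 2)
  expect_equal(sum(diag(cm)), sum(cm))
})

test_that("PLS-DA LOO equals a brute-force exclusion loop on a toy set", {
  set.seed(21)
  X <- matrix(rnorm(10 * 6), 10, 6)
  y <- factor(rep(c("a", "b"), 5))
  cm <- full_loo_cv(X, y, 2)
  pred <- character(10)
  for (i in 1:10) {
    fit <- plsda_fit(X[-i, ], y[-i], 2)
    pred[i] <- as.character(predict(fit, X[i, , drop = FALSE])$class)
  }
  expect_equal(cm, confusion_matrix(pred, y, levels(y)))
  expect_equal(unname(colSums(cm)), unname(as.vector(table(y))))
})

test_that("PLS-DA predictions are invariant to uniform spectrum scaling", {
  d <- separable_classes(n_per = 10)
  fit1 <- plsda_fit(d$X, d$y, 3)
  fit2 <- plsda_fit(d$X * 37, d$y, 3)
  Xnew <- d$X + 0.1
  expect_identical(predict(fit1, Xnew)$class,
                   predict(fit2, Xnew * 37)$class)
})

test_that("one latent variable on rank-1 data reduces to least squares on the score", {
  set.seed(22)
  n <- 30
  t_true <- rnorm(n)
  X <- outer(t_true, runif(8))          # rank-1 design
  y <- factor(ifelse(t_true > 0, "a", "b"))
  fit <- plsda_fit(X, y, 1)
  score <- sweep(X, 2, fit$x_mean) %*% fit$W[, 1]
  Y <- cbind(as.integer(y == "a"), as.integer(y == "b"))
  ols <- lm.fit(cbind(1, score), Y)
  yhat_ols <- cbind(1, score) %*% ols$coefficients
  pred_ols <- factor(c("a", "b")[max.col(yhat_ols)], levels = c("a", "b"))
  expect_identical(predict(fit, X)$class, pred_ols)
})

test_that("PLS-DA agrees with an independent PLS-DA implementation", {
  d <- separable_classes(n_per = 12, p = 15, gap = 4)
  colnames(d$X) <- paste0("v", seq_len(ncol(d$X)))
  fit <- plsda_fit(d$X, d$y, 3)
  mo <- mixOmics::plsda(d$X, d$y, ncomp = 3, scale = FALSE)
  pred_mo <- predict(mo, d$X)$class$max.dist[, 3]
  expect_equal(as.character(predict(fit, d$X)$class),
               unname(pred_mo))
})

test_that("latent-variable optimisation picks sensible values deterministically", {
  d <- separable_classes(n_per = 25, p = 12)
  res <- optimize_n_lv(d$X, d$y, candidates = c(1, 2, 3), folds = 5,
                       seed = 2)
  expect_true(res$n_lv %in% c(1, 2, 3))
  expect_gt(max(res$cv_accuracy), 0.95)
  res2 <- optimize_n_lv(d$X, d$y, candidates = c(1, 2, 3), folds = 5,
                        seed = 2)
  expect_identical(res$cv_accuracy, res2$cv_accuracy)
  # single candidate is returned as-is
  expect_equal(optimize_n_lv(d$X, d$y, candidates = 2, folds = 5,
                             seed = 1)$n_lv, 2)
})

test_that("pure-noise 5-class data cross-validates at chance level", {
  set.seed(23)
  n <- 500
  X <- matrix(rnorm(n * 40), n, 40)
  y <- factor(rep(letters[1:5], each = n / 5))
  res <- optimize_n_lv(X, y, candidates = c(2, 5), folds = 10, seed = 3)
  se <- sqrt(0.2 * 0.8 / n)
  expect_true(all(abs(res$cv_accuracy - 0.2) < 3 * se + 0.02))
})

test_that("the neural network learns a separable problem and is reproducible", {
  d <- separable_classes(n_per = 30, p = 20)
  cfg <- ann_config(hidden = 8, seed = 4, max_epochs = 200)
  r1 <- ann_train_predict(d$X, d$y, d$X + 0.01, cfg)
  expect_equal(mean(r1$class == d$y), 1)
  r2 <- ann_train_predict(d$X, d$y, d$X + 0.01, cfg)
  expect_identical(r1$class, r2$class)
  expect_identical(r1$epochs_run, r2$epochs_run)
})

test_that("the ANN internal split of 502 spectra is about 351/126/25", {
  set.seed(24)
  n <- 502
  y <- factor(rep(letters[1:5], length.out = n))
  X <- matrix(rnorm(n * 10), n, 10)
  cfg <- ann_config(hidden = 2, seed = 5, max_epochs = 2)
  r <- ann_train_predict(X, y, X[1:5, ], cfg)
  expect_equal(sum(r$split_sizes), n)
  expect_lte(abs(r$split_sizes[["train"]] - 351), 3)
  expect_lte(abs(r$split_sizes[["val"]] - 126), 3)
  expect_lte(abs(r$split_sizes[["test"]] - 25), 3)
})

test_that("the random forest is accurate on signal and reproducible", {
  d <- separable_classes(n_per = 25, p = 10)
  cfg <- rf_config(n_trees = 100, seed = 6)
  r1 <- rf_train_predict(d$X, d$y, d$X + 0.01, cfg)
  expect_equal(mean(r1$class == d$y), 1)
  r2 <- rf_train_predict(d$X, d$y, d$X + 0.01, cfg)
  expect_identical(r1$class, r2$class)
})

test_that("doubling the trees changes the success rate only marginally", {
  cfg <- synthetic_config(grains_per_plant = 10, n_paraffin_spectra = 30,
                          grains_per_unembedded_plant = 1, seed = 25)
  d <- generate_dataset(cfg)
  proc <- apply_approach("emsc_paraffin", d$embedded, d$paraffin)
  set <- proc$set
  mask <- set$meta$population == 1
  train <- subset_spectra(set, mask); test <- subset_spectra(set, !mask)
  y_tr <- factor(train$meta$species); y_te <- factor(test$meta$species)
  sr <- sapply(c(300, 600), function(nt) {
    pred <- rf_train_predict(train$spectra, y_tr, test$spectra,
                             rf_config(n_trees = nt, seed = 7))$class
    success_rates(confusion_matrix(pred, y_te))$overall
  })
  expect_lt(abs(sr[1] - sr[2]), 3)
})

test_that("population-split evaluation detects leakage and reports rates", {
  cfg <- small_config(seed = 26)
  d <- generate_dataset(cfg)
  set <- vector_normalize_set(asls_correct(d$embedded))
  mask <- set$meta$population == 1
  train <- subset_spectra(set, mask)
  test <- subset_spectra(set, !mask)
  ev <- population_split_eval(train, test, "plsda", n_lv = 5)
  expect_equal(sum(ev$confusion), n_spectra(test))
  expect_equal(unname(colSums(ev$confusion)),
               unname(as.vector(table(test$meta$species))))
  expect_error(population_split_eval(train, train, "plsda"),
               "leakage")
})
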