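test_that("PCA satisfies its algebraic identities", {
  s <- toy_set(10, toy_axis(40))
  res <- spectra_pca(s, n_pc = 9)
  # orthonormal loadings
  G <- res$loadings %*% t(res$loadings)
  expect_equal(G, diag(nrow(res$loadings)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # centred scores
  expect_equal(unname(colMeans(res$scores)), rep(0, ncol(res$scores)),
               tolerance = 1e-10)
  # non-increasing variance shares summing to <= 100
  expect_true(all(diff(res$explained_variance_pct) <= 1e-10))
  expect_lte(sum(res$explained_variance_pct), 100 + 1e-8)
  # full-rank reconstruction
  rec <- res$scores %*% res$loadings +
    matrix(res$mean_spectrum, 10, 40, byrow = TRUE)
  expect_equal(rec, s$spectra, tolerance = 1e-8, ignore_attr = TRUE)
  # scores equal brute-force projection of centred data onto loadings
  Xc <- sweep(s$spectra, 2, res$mean_spectrum)
  expect_equal(res$scores, Xc %*% t(res$loadings), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("collinear data put 100 percent of variance on PC1", {
  ax <- toy_axis(30)
  base <- sin(seq(0, 3, length.out = 30))
  amat <- outer(seq(-2, 2, length.out = 6), base)
  res <- spectra_pca(spectra_set(amat + 5, ax), n_pc = 1)
  expect_equal(res$explained_variance_pct[1], 100, tolerance = 1e-8)
})

test_that("explained variance is invariant to spectrum reordering and n_pc is truncated at rank", {
  s <- toy_set(6, toy_axis(25))
  r1 <- spectra_pca(s, 5)
  r2 <- spectra_pca(subset_spectra(s, 6:1), 5)
  expect_equal(r1$explained_variance_pct, r2$explained_variance_pct,
               tolerance = 1e-9)
  expect_warning(res <- spectra_pca(s, 20), "rank")
  expect_lte(nrow(res$loadings), 5)
})

test_that("Ward clustering separates well-separated species and has monotone heights", {
  lib <- default_band_library()[c("A_odoratum", "B_inermis")]
  cfg <- synthetic_config(species = lib, plants_per_population = 5,
                          grains_per_plant = 3,
                          population_shift_sd = 0.02,
                          plant_shift_sd = 0.02, seed = 17,
                          n_paraffin_spectra = 2,
                          grains_per_unembedded_plant = 1)
  d <- generate_dataset(cfg)
  avg <- average_by_plant(d$embedded)
  h <- hca_ward(avg)
  expect_true(all(diff(h$hclust$height) >= -1e-10))
  top2 <- stats::cutree(h$hclust, 2)
  split_species <- table(avg$meta$species, top2)
  expect_true(all(apply(split_species, 1, function(r) sum(r > 0)) == 1))
})

test_that("duplicate spectra merge first at height zero", {
  ax <- toy_axis(20)
  set.seed(3)
  a <- runif(20); b <- runif(20) + 2
  s <- spectra_set(rbind(a, a, b), ax,
                   data.frame(spectrum_id = c("a1", "a2", "b")))
  h <- hca_ward(s)
  expect_equal(h$hclust$height[1], 0, tolerance = 1e-12)
  expect_setequal(abs(h$hclust$merge[1, ]), c(1, 2))
})

test_that("Newick export roundtrips through an independent parser", {
  cfg <- small_config(seed = 18)
  d <- generate_dataset(cfg)
  avg <- average_by_plant(subset_spectra(d$embedded,
                                         d$embedded$meta$population == 1))
  h <- hca_ward(avg)
  path <- withr::local_tempfile(fileext = ".nwk")
  export_newick(h, path)
  phy <- ape::read.tree(path)
  expect_equal(length(phy$tip.label), n_spectra(avg))
  expect_setequal(phy$tip.label, h$labels)
  # topology oracle: cophenetic tree distances rank plant pairs like the
  # dendrogram merge structure for the first merged pair
  first_pair <- h$hclust$merge[1, ]
  expect_true(all(first_pair < 0))
  labs <- h$labels[-first_pair]
  cd <- ape::cophenetic.phylo(phy)
  expect_equal(unname(cd[labs[1], labs[2]]), min(cd[cd > 0]),
               tolerance = 1e-9)
})

test_that("two-leaf trees have the (A:h,B:h); shape", {
  ax <- toy_axis(10)
  s <- spectra_set(rbind(runif(10), runif(10) + 1), ax,
                   data.frame(species = c("A", "B"),
                              plant_id = c("p1", "p2")))
  h <- hca_ward(s)
  path <- withr::local_tempfile(fileext = ".nwk")
  export_newick(h, path)
  txt <- readLines(path)
  expect_match(txt, "^\\(A_p1:.+,B_p2:.+\\);$")
})

test_that("cluster purity has its closed-form values", {
  ax <- toy_axis(15)
  set.seed(4)
  amat <- rbind(matrix(rnorm(45, 0), 3), matrix(rnorm(45, 20), 3))
  s <- spectra_set(amat, ax,
                   data.frame(species = rep(c("x", "y"), each = 3),
                              plant_id = sprintf("p%d", 1:6)))
  h <- hca_ward(s)
  perfect <- cluster_purity(h, 2)
  expect_equal(perfect$mean_purity, 1)
  single <- cluster_purity(h, 1)
  expect_equal(single$mean_purity, 0.5)   # largest class share
})

test_that("random labels over 5 balanced classes give chance-level purity", {
  # labels are independent of the data, so the weighted mean purity is
  # the mean majority-count share of a random label assignment over the
  # observed cluster sizes; simulate that directly as the oracle
  ax <- toy_axis(12)
  set.seed(5)
  n <- 50
  reps <- 100
  sim <- replicate(reps, {
    amat <- matrix(rnorm(n * 12), n)
    s <- spectra_set(amat, ax,
                     data.frame(species = sample(rep(letters[1:5], n / 5)),
                                plant_id = sprintf("p%d", seq_len(n))))
    res <- cluster_purity(hca_ward(s), 5)
    oracle <- mean(replicate(20, {
      labs <- sample(rep(1:5, n / 5))
      splits <- split(labs, rep(seq_len(nrow(res$per_cluster)),
                                times = res$per_cluster$size))
      sum(vapply(splits, function(v) max(table(v)), 0)) / n
    }))
    c(purity = res$mean_purity, oracle = oracle)
  })
  se <- sd(sim["purity", ]) / sqrt(reps)
  expect_lt(abs(mean(sim["purity", ]) - mean(sim["oracle", ])),
            3 * se + 0.02)
  expect_gt(mean(sim["purity", ]), 0.2)
  expect_lt(mean(sim["purity", ]), 0.45)
})
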