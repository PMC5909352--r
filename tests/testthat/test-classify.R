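tree_toy <- tibble::tibble(
  depth = c(1, 2, 8, 9),
  label = c("benign", "benign", "malignant", "malignant")
)

test_that("decision tree finds the separating split with Laplace leaves", {
  tr <- train_tree(tree_toy)
  expect_identical(tr$root$type, "split")
  expect_gt(tr$root$threshold, 2)
  expect_lt(tr$root$threshold, 8)
  # pure leaves of size 2: Laplace (2+1)/(2+2)
  expect_equal(tr$root$left$p_malignant, 0.25)
  expect_equal(tr$root$right$p_malignant, 0.75)

  p <- predict_proba(tr, tibble::tibble(depth = 1.5))
  expect_equal(p$p_malignant, 0.25)
  expect_equal(p$p_malignant + p$p_benign, 1)

  expect_error(predict_proba(tr, tibble::tibble(width = 1)), "missing")
  expect_error(train_tree(tibble::tibble(x = 1:3, label = rep("benign", 3))),
               ">= 2 instances")
})

test_that("a pure leaf of size 10 carries the Laplace probability 11/12", {
  tab <- tibble::tibble(
    x = c(1:10, 21:30),
    label = rep(c("benign", "malignant"), each = 10))
  tr <- train_tree(tab)
  p <- predict_proba(tr, tibble::tibble(x = 25))
  expect_equal(p$p_malignant, 11 / 12)
})

test_that("constant features are never selected for splitting", {
  tab <- tibble::tibble(
    useful = c(1, 2, 8, 9), stuck = rep(3, 4),
    label = c("benign", "benign", "malignant", "malignant"))
  tr <- train_tree(tab)
  nodes <- tidy(tr)
  expect_false("stuck" %in% nodes$feature[nodes$type == "split"])
})

test_that("unpruned trees reach 100% training accuracy on consistent data", {
  tab <- withr::with_seed(21, tibble::tibble(
    a = rnorm(30), b = rnorm(30),
    label = sample(c("benign", "malignant"), 30, replace = TRUE,
                   prob = c(0.5, 0.5))))
  # ensure both classes present
  tab$label[1:2] <- c("benign", "malignant")
  tr <- train_tree(tab)
  p <- predict_proba(tr, tab)
  pred <- ifelse(p$p_malignant >= p$p_benign, "malignant", "benign")
  expect_identical(pred, tab$label)
})

test_that("pessimistic pruning collapses noise splits but keeps real ones", {
  tab <- withr::with_seed(8, tibble::tibble(
    signal = c(rnorm(40, 0), rnorm(40, 6)),
    noise = rnorm(80),
    label = rep(c("benign", "malignant"), each = 40)))
  tab$label[c(3, 47)] <- c("malignant", "benign")  # a little label noise
  unpruned <- train_tree(tab)
  pruned <- train_tree(tab, pruned = TRUE)
  expect_lte(glance(pruned)$n_leaves, glance(unpruned)$n_leaves)
  p <- predict_proba(pruned, tibble::tibble(signal = 6, noise = 0))
  expect_gt(p$p_malignant, 0.5)
})

test_that("Gaussian naive Bayes reproduces closed-form posteriors", {
  tab <- tibble::tibble(
    x = c(-1, 0, 1, 9, 10, 11),
    label = rep(c("benign", "malignant"), each = 3))
  nb <- train_nb(tab)
  expect_gt(predict_proba(nb, tibble::tibble(x = 0))$p_benign, 0.999)
  # exact midpoint of symmetric equal-variance classes, equal priors
  mid <- predict_proba(nb, tibble::tibble(x = 5))
  expect_equal(mid$p_malignant, 0.5, tolerance = 1e-9)

  # identical likelihoods: posterior equals the priors
  prior_tab <- tibble::tibble(
    x = rep(5, 10), label = c(rep("benign", 9), "malignant"))
  p <- predict_proba(train_nb(prior_tab), tibble::tibble(x = 5))
  expect_equal(p$p_benign, 0.9, tolerance = 1e-9)

  expect_error(train_nb(tab, kernel_estimator = TRUE), "kernel")
})

test_that("naive Bayes agrees with the e1071 reference implementation", {
  skip_if_not_installed("e1071")
  tab <- withr::with_seed(31, tibble::tibble(
    f1 = c(rnorm(25, 0, 1), rnorm(35, 2, 1.5)),
    f2 = c(rnorm(25, 5, 2), rnorm(35, 3, 1)),
    label = rep(c("benign", "malignant"), c(25, 35))))
  nb <- train_nb(tab)
  query <- tibble::tibble(f1 = c(-1, 0.5, 2, 4), f2 = c(6, 4, 3, 2))
  mine <- predict_proba(nb, query)
  ref <- e1071::naiveBayes(factor(label) ~ f1 + f2, data = tab)
  theirs <- predict(ref, as.data.frame(query), type = "raw")
  expect_equal(mine$p_malignant, unname(theirs[, "malignant"]),
               tolerance = 1e-6)
})

test_that("NB posteriors are invariant to affine feature rescaling", {
  tab <- withr::with_seed(13, tibble::tibble(
    f1 = rnorm(40, rep(c(0, 2), each = 20)),
    f2 = rnorm(40),
    label = rep(c("benign", "malignant"), each = 20)))
  q <- tibble::tibble(f1 = 1.2, f2 = 0.1)
  p1 <- predict_proba(train_nb(tab), q)
  tab2 <- dplyr::mutate(tab, f1 = 100 * f1 - 7)
  q2 <- dplyr::mutate(q, f1 = 100 * f1 - 7)
  p2 <- predict_proba(train_nb(tab2), q2)
  expect_equal(p1$p_malignant, p2$p_malignant, tolerance = 1e-9)
})

test_that("voxel votes produce D_m = n_m / N with D_m + D_b = 1", {
  # NB trained so the vote of each voxel is known by construction
  train <- tibble::tibble(
    re = c(rep(-1, 20), rep(1, 20)),
    label = rep(c("benign", "malignant"), each = 20))
  nb <- train_nb(train, features = "re")
  dyn <- tibble::tibble(re = c(rep(1, 7), rep(-1, 3)))
  d <- voxel_dynamic_probabilities(dyn, nb)
  expect_equal(d$D_m, 0.7)
  expect_equal(d$D_b, 0.3)
  all_m <- voxel_dynamic_probabilities(tibble::tibble(re = rep(1, 5)), nb)
  expect_equal(c(all_m$D_m, all_m$D_b), c(1, 0))

  # property: the pair always sums to 1
  for (i in 1:25) {
    dyn_i <- withr::with_seed(400 + i,
                              tibble::tibble(re = rnorm(sample(1:50, 1))))
    d_i <- voxel_dynamic_probabilities(dyn_i, nb)
    expect_equal(d_i$D_m + d_i$D_b, 1)
  }
  expect_error(voxel_dynamic_probabilities(tibble::tibble(re = numeric(0)), nb),
               "no voxels")
})

test_that("stratified cross-validation behaves at the two extremes", {
  sep <- tibble::tibble(
    x = c(rnorm(30, 0, 0.3), rnorm(30, 10, 0.3)),
    label = rep(c("benign", "malignant"), each = 30))
  cv <- cross_validate(sep, kind = "nb", folds = 10, seed = 3)
  expect_equal(cv$accuracy, 1)

  chance <- withr::with_seed(17, tibble::tibble(
    x = rnorm(100),
    label = sample(rep(c("benign", "malignant"), 50))))
  cv2 <- cross_validate(chance, kind = "nb", folds = 10, seed = 3)
  expect_gte(cv2$accuracy, 0.3)
  expect_lte(cv2$accuracy, 0.7)

  cv3 <- cross_validate(chance, kind = "nb", folds = 10, seed = 3)
  expect_identical(cv2, cv3)
  expect_error(cross_validate(sep[1:5, ], kind = "nb", folds = 10), "folds")
})

test_that("model summaries expose the fitted structure", {
  tr <- train_tree(tree_toy)
  expect_identical(glance(tr)$n_leaves, 2L)
  nb <- train_nb(tibble::tibble(x = c(-1, 0, 1, 9, 10, 11),
                                label = rep(c("benign", "malignant"), each = 3)))
  td <- tidy(nb)
  expect_identical(nrow(td), 2L)
  expect_equal(td$mean[td$class == "malignant"], 10)
  expect_equal(glance(nb)$prior_malignant, 0.5)
})
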