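test_that("gini impurity matches hand values", {
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(24, 40)), 0.46875)
  expect_error(gini_impurity(c(0, 0)), "counts")
})

test_that("growing splits at midpoints and stops on purity", {
  X <- data.frame(x = c(1, 2, 4, 5))
  y <- c(0, 0, 1, 1)
  t1 <- grow_tree(X, y, cart_params(min_split = 2, min_leaf = 1))
  expect_equal(t1$root$split$var, "x")
  expect_equal(t1$root$split$threshold, 3.0)
  expect_equal(t1$root$improvement, 4 * 0.5)   # n * gini(2,2) down to purity
  # pure response: a single leaf
  t2 <- grow_tree(data.frame(x = 1:10), rep(1, 10))
  expect_null(t2$root$split)
  # constant features: a single leaf, not an error
  t3 <- grow_tree(data.frame(x = rep(2, 20)), rep(c(0, 1), 10))
  expect_null(t3$root$split)
  expect_error(grow_tree(data.frame(x = 1:4), c(0, 1, 2, 1)), "binary")
})

test_that("XOR needs exactly depth two and zero training error", {
  # cell counts are unbalanced so the first split has positive Gini gain
  # (perfectly balanced XOR leaves every single split gainless and greedy
  # Gini partitioning honestly refuses to split it)
  g <- expand.grid(a = c(0, 1), b = c(0, 1))
  X <- g[rep(1:4, times = c(7, 5, 4, 6)), ]
  y <- as.integer(xor(X$a, X$b))
  p <- cart_params(min_split = 4, min_leaf = 2)
  tr <- grow_tree(X, y, p)
  expect_equal(sort(unique(c(split_variables(tr)))), c("a", "b"))
  expect_equal(sum(predict(tr, X) != y), 0)
  ref <- grow_tree_reference(X, y, p)
  expect_equal(tr$root, ref$root, tolerance = 1e-9)
})

test_that("vectorised grower equals the exhaustive reference on random data", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(12:30, 1)
    X <- data.frame(a = runif(n), b = rnorm(n),
                    g = factor(sample(c("u", "v", "w"), n, TRUE)))
    y <- as.integer(runif(n) < plogis(2 * X$a + (X$g == "v") - 1))
    p <- cart_params(min_split = 5, min_leaf = 2)
    expect_equal(grow_tree(X, y, p)$root,
                 grow_tree_reference(X, y, p)$root, tolerance = 1e-9)
  }
})

test_that("weakest-link pruning collapses a clean depth-1 tree at alpha 1", {
  # 6 absent / 4 present, perfectly separated: root risk 4, leaf risk 0
  X <- data.frame(x = c(1:6, 11:14))
  y <- c(rep(0, 6), rep(1, 4))
  tr <- grow_tree(X, y, cart_params(min_split = 2, min_leaf = 1))
  path <- prune_path(tr)
  s <- attr(path, "summary")
  expect_equal(s$alpha, c(0, 1))
  expect_equal(s$n_leaves, c(2L, 1L))
  expect_equal(s$rel_error, c(0, 1))
  # single-leaf tree: path of length one at alpha 0
  leafy <- grow_tree(data.frame(x = 1:10), rep(0, 10))
  expect_equal(nrow(attr(prune_path(leafy), "summary")), 1)
})

collect_splits <- function(node) {
  if (is.null(node$split)) return(character())
  c(paste(node$split$var, node$split$threshold,
          paste(node$split$left_set, collapse = "|")),
    collect_splits(node$left), collect_splits(node$right))
}

test_that("pruning paths are nested with increasing alpha on random trees", {
  set.seed(4)
  for (i in 1:10) {
    n <- 150
    X <- data.frame(a = runif(n), b = runif(n), c = runif(n))
    y <- as.integer(runif(n) < plogis(4 * (X$a - 0.5)))
    tr <- grow_tree(X, y, cart_params(min_split = 10, min_leaf = 4))
    path <- prune_path(tr)
    s <- attr(path, "summary")
    expect_true(all(diff(s$alpha) > 0))
    expect_true(all(diff(s$n_leaves) < 0))
    expect_true(all(diff(s$rel_error) >= -1e-12))
    expect_equal(s$rel_error[nrow(s)], 1)      # root scores 1 by definition
    expect_null(path[[length(path)]]$tree$split)
    # nested: every split of entry k appears in entry k-1
    for (k in 2:length(path))
      expect_true(all(collect_splits(path[[k]]$tree) %in%
                        collect_splits(path[[k - 1]]$tree)))
  }
})

test_that("cross-validation is seeded, reproducible, and scaled to the root", {
  # a clean margin around the planted cut leaves no generalisation error
  set.seed(21)
  d <- list(X = data.frame(a = c(runif(120, 0, 0.5), runif(80, 0.7, 1)),
                           b = runif(200)))
  d$y <- as.integer(d$X$a > 0.6)
  cv <- cross_validate(d$X, d$y, seed = 5)
  expect_s3_class(cv, "cv_result")
  expect_equal(cv$rel_error[nrow(cv)], 1)
  expect_equal(min(cv$xerror), 0)              # noiseless signal generalises
  expect_identical(as.data.frame(cv),
                   as.data.frame(cross_validate(d$X, d$y, seed = 5)))
  # with noisy labels, different fold seeds give different error estimates
  dn <- signal_dataset(200, seed = 21, noise = 0.15)
  expect_false(identical(cross_validate(dn$X, dn$y, seed = 5)$xerror,
                         cross_validate(dn$X, dn$y, seed = 6)$xerror))
  expect_error(cross_validate(d$X[1:5, ], d$y[1:5], k = 10), "k must not")
})

test_that("pure-noise labels show no spurious cross-validated skill", {
  set.seed(11)
  mins <- numeric(20)
  for (s in 1:20) {
    n <- 200
    X <- data.frame(a = runif(n), b = runif(n), c = runif(n))
    y <- rbinom(n, 1, 0.5)
    mins[s] <- min(cross_validate(X, y, seed = s)$xerror)
  }
  expect_gte(mean(mins), 0.9)
})

test_that("the 1-SE rule picks the smallest size within one SE", {
  cv <- data.frame(size = c(1, 2, 3, 5),
                   alpha = c(0.5, 0.2, 0.1, 0),
                   rel_error = c(1, 0.5, 0.4, 0.35),
                   xerror = c(1.0, 0.50, 0.42, 0.40),
                   xstd = c(0.1, 0.07, 0.065, 0.06))
  class(cv) <- c("cv_result", "data.frame")
  expect_equal(select_1se(cv)$size, 3)          # 0.42 <= 0.40 + 0.06
  cv$xstd <- rep(2, 4)                          # huge SE: root wins
  expect_equal(select_1se(cv)$size, 1)
  cv$xerror <- rep(0.8, 4)                      # flat: smallest
  cv$xstd <- rep(0.05, 4)
  expect_equal(select_1se(cv)$size, 1)
  # selected size never exceeds the xerror-minimising size
  set.seed(31)
  for (s in 1:5) {
    d <- signal_dataset(150, seed = s)
    cvr <- cross_validate(d$X, d$y, seed = s)
    best <- cvr$size[which.min(cvr$xerror)]
    expect_lte(select_1se(cvr)$size, best)
  }
})

test_that("the modal tree takes the most frequent 1-SE size", {
  d <- signal_dataset(200, seed = 2, noise = 0)
  mt <- modal_optimal_tree(d$X, d$y, n_repeats = 10, base_seed = 1)
  expect_equal(attr(mt, "modal_size"), 2)
  expect_equal(split_variables(mt), "a")
  expect_equal(sum(names(attr(mt, "size_votes")) == "2"), 1)
  # learned threshold sits inside the data gap around the planted cut
  thr <- mt$root$split$threshold
  lo <- max(d$X$a[d$X$a < d$tau]); hi <- min(d$X$a[d$X$a >= d$tau])
  expect_gt(thr, lo); expect_lte(thr, hi)
})

test_that("prediction routes by split rules and rejects unseen categories", {
  d <- signal_dataset(100, seed = 8, noise = 0)
  tr <- grow_tree(d$X, d$y, cart_params(min_split = 10, min_leaf = 4))
  expect_equal(predict(tr, d$X), d$y)           # error-0 tree on its own data
  leaf <- grow_tree(d$X, rep(c(0, 0, 0, 1), 25), cart_params(max_depth = 0))
  expect_equal(unique(predict(leaf, d$X)), 0L)
  # monotone transform of a numeric feature leaves predictions unchanged
  Xt <- d$X; Xt$a <- exp(3 * Xt$a)
  trt <- grow_tree(Xt, d$y, cart_params(min_split = 10, min_leaf = 4))
  expect_equal(predict(trt, Xt), predict(tr, d$X))
  # unseen factor level at a categorical split errors
  Xc <- data.frame(g = factor(rep(c("u", "v"), each = 20)))
  yc <- rep(c(0, 1), each = 20)
  trc <- grow_tree(Xc, yc, cart_params(min_split = 4, min_leaf = 2))
  bad <- data.frame(g = factor("z"))
  expect_error(predict(trc, bad), "unseen")
})

test_that("evaluation reports the confusion-derived rates", {
  ev <- evaluate_classification(rep(1, 64), c(rep(1, 40), rep(0, 24)))
  expect_equal(ev$misclassification, 0.375)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 0)
  perfect <- evaluate_classification(c(0, 1, 1), c(0, 1, 1))
  expect_equal(perfect$misclassification_pct, 0)
  # TP 37 FN 3 TN 16 FP 8 -> 17% / 0.93 / 0.67 after display rounding
  y <- c(rep(1, 40), rep(0, 24))
  pred <- c(rep(1, 37), rep(0, 3), rep(0, 16), rep(1, 8))
  ev2 <- evaluate_classification(pred, y)
  expect_equal(unname(ev2$confusion), c(37, 3, 16, 8))
  expect_equal(ev2$misclassification_pct, 17)
  expect_equal(pondsight:::round_half_up(ev2$sensitivity, 2), 0.93)
  expect_equal(pondsight:::round_half_up(ev2$specificity, 2), 0.67)
  expect_error(evaluate_classification(integer(), integer()), "non-empty")
})

test_that("tree structure agrees with rpart on a well-separated fixture", {
  skip_if_not_installed("rpart")
  d <- signal_dataset(120, seed = 77, noise = 0.05)
  tr <- grow_tree(d$X, d$y)
  rp <- rpart::rpart(y ~ a + b + g, data = cbind(d$X, y = d$y),
                     method = "class",
                     control = rpart::rpart.control(minsplit = 20,
                                                    minbucket = 7, cp = 0,
                                                    xval = 0))
  expect_equal(tr$root$split$var,
               as.character(rp$frame$var[1]))
  expect_equal(tr$root$split$threshold, unname(rp$splits[1, "index"]),
               tolerance = 1e-9)
})
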