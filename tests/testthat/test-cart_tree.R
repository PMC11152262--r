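test_that("best split finds the obvious breakpoint", {
  X <- data.frame(x = c(1, 2, 3, 4))
  y <- c(0, 0, 10, 10)
  s <- best_split(X, y)
  expect_equal(s$variable, "x")
  expect_equal(s$threshold, 2.5)
  expect_equal(s$gain, 100)        # total SSE 100, post-split 0
  expect_equal(c(s$n_left, s$n_right), c(2, 2))
})

test_that("constant outcomes yield no split", {
  expect_null(best_split(data.frame(x = 1:5), rep(3, 5)))
  expect_null(best_split(data.frame(x = rep(1, 5)), c(1, 2, 3, 4, 5)))
})

test_that("a perfectly separating predictor dominates", {
  X <- data.frame(noise = c(5, 1, 4, 2, 3, 6),
                  clean = c(0, 0, 0, 1, 1, 1))
  y <- c(1, 1.1, 0.9, 5, 5.2, 4.9)
  s <- best_split(X, y)
  expect_equal(s$variable, "clean")
})

test_that("splits match an exhaustive-partition oracle", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(8:30, 1)
    X <- data.frame(num = round(runif(n, 0, 5), 1),
                    bin = rbinom(n, 1, 0.5),
                    cat = sample(letters[1:4], n, TRUE))
    y <- runif(n)
    s <- best_split(X, y)
    oracle <- brute_force_best_gain(X, y)
    if (is.null(s)) {
      expect_lt(oracle, 1e-12)
    } else {
      expect_equal(s$gain, oracle, tolerance = 1e-10)
    }
  }
})

test_that("nodes under the minimum size are never split", {
  set.seed(2)
  X <- data.frame(x = runif(19))
  y <- X$x + rnorm(19)              # plenty of signal
  tree <- grow_tree(X, y, min_node = 20)
  expect_null(tree$split)
  expect_equal(tree$n, 19)
  expect_equal(tree$proportion, 1)
})

test_that("root statistics and leaf conservation hold", {
  set.seed(3)
  X <- data.frame(a = runif(150), b = sample(c("u", "v", "w"), 150, TRUE))
  y <- as.numeric(X$b == "v") + X$a + rnorm(150, sd = 0.3)
  tree <- grow_tree(X, y)
  expect_equal(tree$mean, mean(y))
  expect_equal(tree$proportion, 1)
  leaves <- tree_leaves(tree)
  expect_gt(length(leaves), 1)
  ns <- vapply(leaves, `[[`, 0, "n")
  ms <- vapply(leaves, `[[`, 0, "mean")
  expect_equal(sum(ns), length(y))
  expect_equal(sum(ns * ms) / sum(ns), mean(y), tolerance = 1e-12)
  # every leaf mean is the arithmetic mean of its members
  preds <- predict(tree, X)
  for (lf in leaves) {
    members <- abs(preds - lf$mean) < 1e-12
    expect_equal(mean(y[members]), lf$mean, tolerance = 1e-12)
  }
})

test_that("constant outcome gives a single leaf with that mean", {
  tree <- grow_tree(data.frame(x = 1:40), rep(0.6, 40))
  expect_null(tree$split)
  expect_equal(tree$mean, 0.6)
  expect_error(grow_tree(data.frame(x = numeric(0)), numeric(0)), "empty")
})

test_that("raising the minimum node size never deepens the tree", {
  set.seed(9)
  X <- data.frame(a = runif(200), b = rbinom(200, 1, 0.4))
  y <- X$a * 2 + X$b + rnorm(200, sd = 0.4)
  depths <- vapply(c(10, 20, 40, 80), function(mn)
    tree_depth(grow_tree(X, y, min_node = mn)), 0L)
  expect_true(all(diff(depths) <= 0))
})

test_that("identical inputs grow identical trees", {
  set.seed(13)
  X <- data.frame(a = runif(100), b = sample(letters[1:3], 100, TRUE))
  y <- runif(100)
  expect_identical(grow_tree(X, y), grow_tree(X, y))
})

test_that("rendering follows the mean / proportion label convention", {
  leaf <- grow_tree(data.frame(x = 1:10), rep(0.5, 10))
  expect_equal(render_tree(leaf), "0.50 / 100%")
  set.seed(4)
  X <- data.frame(x = c(rep(0, 30), rep(1, 30)))
  y <- c(rnorm(30, 0.3, 0.01), rnorm(30, 0.7, 0.01))
  lines <- render_tree(grow_tree(X, y))
  expect_length(lines, 3)
  props <- as.numeric(sub(".*/ (\\d+)%$", "\\1", lines[2:3]))
  expect_equal(sum(props), 100)
})

test_that("the wellbeing tree wrapper drops incomplete rows and labels the root", {
  tab <- make_fixture("paper_like_300")
  scores <- score_table(tab)
  coded <- collapse_levels(tab, scores)
  tree <- wellbeing_tree(coded, scores, "quality")
  expect_equal(attr(tree, "n_used") + attr(tree, "n_dropped"), 300)
  expect_equal(attr(tree, "n_dropped"), 8)   # missing learn_elderly
  first <- render_tree(tree)[1]
  expect_match(first, "^\\d\\.\\d\\d / 100%$")
})
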