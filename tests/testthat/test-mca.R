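coded_fixture <- function(n = 120, seed = 99) {
  gen <- generate_survey(generator_config(n = n, seed = seed,
                                          missing_learn = min(8, n %/% 10)))
  collapse_levels(gen$table, score_table(gen$table))
}

test_that("one-hot expansion satisfies the indicator identities", {
  df <- data.frame(respondent_id = as.character(1:6),
                   a = c("x", "y", "x", "y", "x", "y"),
                   b = c("u", "v", "w", "u", "v", "w"))
  ind <- one_hot(df, c("a", "b"))
  expect_equal(ind$J, 5)           # 2 + 3 levels
  expect_equal(ind$Q, 2)
  expect_true(all(rowSums(ind$Z) == 2))
  expect_equal(colSums(ind$Z)[["a_x"]], 3)
  expect_equal(unname(ind$var_of_column),
               c("a", "a", "b", "b", "b"))
})

test_that("rows with missing active categories are dropped and counted", {
  df <- data.frame(respondent_id = as.character(1:5),
                   a = c("x", "y", NA, "y", "x"),
                   b = c("u", "v", "u", NA, "v"))
  ind <- one_hot(df, c("a", "b"))
  expect_equal(ind$n_dropped, 2)
  expect_equal(nrow(ind$Z), 3)
  expect_equal(ind$row_id, c("1", "2", "5"))
  df$c <- "only_level"
  expect_error(one_hot(df, c("a", "c")), "single observed level")
})

test_that("two identical binary variables give principal inertias (1, 0)", {
  df <- data.frame(respondent_id = as.character(1:10),
                   a = rep(c("x", "y"), 5))
  df$b <- df$a
  m <- fit_mca(one_hot(df, c("a", "b")), n_dims = 2)
  expect_equal(m$inertias[1], 1, tolerance = 1e-10)
  expect_equal(sum(m$inertias[-1]), 0, tolerance = 1e-10)
  # first dimension separates the two aligned category pairs
  cc <- m$category_coords[, 1]
  expect_equal(sign(cc[["a_x"]]), sign(cc[["b_x"]]))
  expect_true(sign(cc[["a_x"]]) != sign(cc[["a_y"]]))
})

test_that("two binary variables have inertias (1 +/- phi)/2", {
  set.seed(12)
  a <- rbinom(200, 1, 0.5)
  b <- ifelse(runif(200) < 0.7, a, rbinom(200, 1, 0.5))
  phi <- abs(cor(a, b))
  df <- data.frame(respondent_id = as.character(1:200),
                   a = c("n", "y")[a + 1], b = c("n", "y")[b + 1])
  m <- fit_mca(one_hot(df, c("a", "b")), n_dims = 2)
  expect_equal(sort(m$inertias, decreasing = TRUE),
               sort(c((1 + phi) / 2, (1 - phi) / 2), decreasing = TRUE),
               tolerance = 1e-10)
})

test_that("total inertia is (J - Q)/Q, matching a brute-force trace", {
  set.seed(21)
  for (rep in 1:5) {
    nvar <- sample(2:4, 1)
    df <- data.frame(respondent_id = as.character(1:50))
    for (v in seq_len(nvar))
      df[[paste0("v", v)]] <- sample(letters[1:sample(2:4, 1)], 50, TRUE)
    ind <- one_hot(df, paste0("v", seq_len(nvar)))
    m <- fit_mca(ind, n_dims = 3)
    expect_equal(m$total_inertia, (ind$J - ind$Q) / ind$Q,
                 tolerance = 1e-10)
    # brute force: trace of S'S by explicit summation
    P <- unname(ind$Z) / sum(ind$Z)
    r <- rowSums(P); cc <- colSums(P)
    tr <- 0
    for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
      tr <- tr + (P[i, j] - r[i] * cc[j])^2 / (r[i] * cc[j])
    }
    expect_equal(m$total_inertia, tr, tolerance = 1e-10)
    expect_true(all(diff(m$inertias) <= 1e-12))   # non-increasing
    expect_equal(sum(m$explained), 1, tolerance = 1e-12)
  }
})

test_that("individual coordinates are mass-orthogonal across dimensions", {
  coded <- coded_fixture(120)
  m <- fit_mca(one_hot(coded), n_dims = 4)
  F_ <- m$individual_coords
  for (s in 1:3) for (t in (s + 1):4) {
    expect_lt(abs(sum(m$row_mass * F_[, s] * F_[, t])), 1e-10)
  }
})

test_that("transition formulas recover individual from category coordinates", {
  coded <- coded_fixture(100, seed = 55)
  ind <- one_hot(coded)
  m <- fit_mca(ind, n_dims = 3)
  P <- ind$Z / sum(ind$Z)
  sv <- m$singular_values[1:3]
  F_rec <- sweep(P %*% sweep(m$category_coords, 2, sv, "/"),
                 1, m$row_mass, "/")
  expect_equal(unname(F_rec), unname(m$individual_coords),
               tolerance = 1e-8)
})

test_that("inertias and coordinates match an independent CA implementation", {
  skip_if_not_installed("vegan")
  coded <- coded_fixture(80, seed = 3)
  ind <- one_hot(coded)
  m <- fit_mca(ind, n_dims = 3)
  ref <- vegan::cca(ind$Z)
  k <- min(length(ref$CA$eig), length(m$inertias))
  expect_equal(unname(m$inertias[1:k]), unname(ref$CA$eig[1:k]),
               tolerance = 1e-6)
  sp <- vegan::scores(ref, display = "species", scaling = "species",
                      choices = 1:3)
  expect_equal(unname(sign_align(m$category_coords, unname(sp))),
               unname(m$category_coords), tolerance = 1e-6)
})

test_that("MASS squared singular values agree with the principal inertias", {
  skip_if_not_installed("MASS")
  coded <- coded_fixture(80, seed = 4)
  vars <- c("health_good", "family_good", "learn_elderly", "children_band")
  sub <- coded[stats::complete.cases(coded[vars]), ]
  df <- data.frame(lapply(sub[vars], factor))
  m <- fit_mca(one_hot(sub, vars), n_dims = 3)
  ref <- MASS::mca(df, nf = 3)
  expect_equal(unname(m$inertias[1:3]), unname(ref$d^2), tolerance = 1e-6)
})

test_that("factor tables list every category once with group tags", {
  coded <- coded_fixture(90, seed = 6)
  m <- fit_mca(one_hot(coded), n_dims = 3)
  ft <- factor_table(m, c(1, 2), coded)
  cats <- ft[ft$type == "category", ]
  expect_equal(sort(cats$label), sort(rownames(m$category_coords)))
  expect_setequal(unique(cats$group),
                  c("wellbeing", "learning", "demographic"))
  inds <- ft[ft$type == "individual", ]
  expect_equal(nrow(inds), m$n)
  expect_true(all(inds$group %in% c("learn_yes", "learn_no", "unknown")))
  expect_error(factor_table(m, c(1, 9)), "out of range")
})
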