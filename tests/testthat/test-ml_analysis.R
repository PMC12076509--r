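toy_dataset <- function(n = 30, seed = 1) {
  set.seed(seed)
  ids <- paste0("sub", 1:12)
  tibble::tibble(
    id = seq_len(n),
    sub_ids = lapply(seq_len(n), function(i) sample(ids, 2)),
    x1 = rnorm(n), x2 = rnorm(n),
    y = rnorm(n))
}

test_that("the unseen-substituent predicate holds exhaustively on a toy set", {
  d <- toy_dataset(30, seed = 8)
  sp <- split_unseen_substituent(d, fraction = 0.2, seed = 3)
  train_ids <- unique(unlist(sp$train$sub_ids))
  for (k in seq_len(nrow(sp$test))) {
    expect_true(any(!sp$test$sub_ids[[k]] %in% train_ids))
  }
  expect_true(sp$verified)
  # deterministic for a fixed seed
  sp2 <- split_unseen_substituent(d, fraction = 0.2, seed = 3)
  expect_identical(sp$test$id, sp2$test$id)
})

test_that("an all-shared substituent set is infeasible", {
  d <- toy_dataset(10)
  d$sub_ids <- rep(list(c("common")), 10)
  expect_error(split_unseen_substituent(d, 0.1, seed = 1), "infeasible")
})

test_that("LASSO shrinks a null signal to the constant model", {
  d <- toy_dataset(40, seed = 2)
  d$y <- 3.5
  m <- fit_lasso_cv(d, "y", c("x1", "x2"), seed = 1)
  expect_equal(unname(m$coef), c(0, 0))
  expect_equal(m$intercept, 3.5, tolerance = 1e-9)
})

test_that("LASSO recovers a planted sparse signal, agreeing with OLS", {
  set.seed(11)
  n <- 400
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                      x4 = rnorm(n))
  d$y <- 2 * d$x1 - 1 * d$x2 + rnorm(n, sd = 0.05)
  m <- fit_lasso_cv(d, "y", paste0("x", 1:4), seed = 7)
  ols <- stats::lm(y ~ x1 + x2 + x3 + x4, data = d)
  expect_gt(m$coef["x1"], 0)
  expect_lt(m$coef["x2"], 0)
  expect_lt(max(abs(m$coef[c("x3", "x4")])), 0.02)
  # standardized-scale coefficients match OLS slopes times feature sd
  expect_equal(unname(m$coef["x1"]), unname(coef(ols)["x1"] * sd(d$x1)),
               tolerance = 0.05)
  # prediction consistency
  expect_lt(mean(abs(predict(m, d) - d$y)), 0.1)
})

test_that("duplicated feature columns split the coefficient mass", {
  set.seed(12)
  n <- 300
  d <- tibble::tibble(x1 = rnorm(n))
  d$x1b <- d$x1
  d$y <- 1.5 * d$x1 + rnorm(n, sd = 0.05)
  m_single <- fit_lasso_cv(d, "y", "x1", seed = 3)
  m_dup <- fit_lasso_cv(d, "y", c("x1", "x1b"), seed = 3)
  expect_equal(sum(m_dup$coef), unname(m_single$coef["x1"]), tolerance = 0.02)
})

test_that("coefficients are invariant to raw-feature rescaling", {
  set.seed(13)
  n <- 200
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- d$x1 - 0.5 * d$x2 + rnorm(n, sd = 0.1)
  m1 <- fit_lasso_cv(d, "y", c("x1", "x2"), seed = 5)
  d2 <- d; d2$x1 <- d2$x1 * 1000
  m2 <- fit_lasso_cv(d2, "y", c("x1", "x2"), seed = 5)
  expect_equal(unname(m1$coef), unname(m2$coef), tolerance = 1e-8)
})

test_that("constant feature columns are dropped with a warning", {
  d <- toy_dataset(30, seed = 4)
  d$flat <- 1
  expect_warning(m <- fit_lasso_cv(d, "y", c("x1", "flat"), seed = 1),
                 "constant")
  expect_identical(m$features, "x1")
})

test_that("random forests rank a planted single-feature signal first", {
  set.seed(21)
  n <- 250
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- sin(2 * d$x2) * 2 + rnorm(n, sd = 0.1)
  m <- fit_rf(d, "y", paste0("x", 1:3), seed = 5)
  expect_identical(names(which.max(m$importance)), "x2")
  # determinism
  m2 <- fit_rf(d, "y", paste0("x", 1:3), seed = 5)
  expect_identical(predict(m, d), predict(m2, d))
  # pure noise: importances stay near zero
  d$y <- rnorm(n)
  m3 <- fit_rf(d, "y", paste0("x", 1:3), seed = 5)
  expect_lt(max(m3$importance), 0.2)
})

test_that("RF and LASSO agree on the top feature of single-signal data", {
  set.seed(31)
  n <- 300
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- 3 * d$x3 + rnorm(n, sd = 0.3)
  ml <- fit_lasso_cv(d, "y", paste0("x", 1:3), seed = 2)
  mr <- fit_rf(d, "y", paste0("x", 1:3), seed = 2)
  expect_identical(names(which.max(abs(ml$coef))), "x3")
  expect_identical(names(which.max(mr$importance)), "x3")
})

test_that("bootstrap evaluation reports noiseless linear data as near-exact", {
  set.seed(41)
  n <- 120
  d <- tibble::tibble(
    id = 1:n,
    sub_ids = lapply(1:n, function(i) paste0("s", sample(1:12, 2))),
    x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 2 + d$x1 - d$x2
  rep <- bootstrap_evaluate(d, "y", c("x1", "x2"), models = "lasso",
                            B = 5, seed = 2, fraction = 0.15)
  expect_lt(rep$mae$mean, 0.02)
  expect_lt(rep$mae$hi - rep$mae$lo, 0.05)
  expect_identical(rep$meta$B, 5)
  expect_identical(rep$meta$ci, 0.95)
})

test_that("test MAE under Gaussian noise matches the analytic value", {
  # MAE of a Gaussian residual is sigma * sqrt(2/pi)
  set.seed(51)
  n <- 500; sigma <- 0.4
  d <- tibble::tibble(
    id = 1:n,
    sub_ids = lapply(1:n, function(i) paste0("s", sample(1:20, 2))),
    x1 = rnorm(n), x2 = rnorm(n))
  d$y <- d$x1 + 0.5 * d$x2 + rnorm(n, sd = sigma)
  rep <- bootstrap_evaluate(d, "y", c("x1", "x2"), models = "lasso",
                            B = 8, seed = 3, fraction = 0.1)
  expect_equal(rep$mae$mean, sigma * sqrt(2 / pi), tolerance = 0.25)
})

test_that("the coefficient table has the documented shape and HOMA policy", {
  set.seed(61)
  n <- 80
  mk <- function(variant) {
    d <- tibble::tibble(
      id = 1:n,
      sub_ids = lapply(1:n, function(i) paste0("s", sample(1:10, 2))),
      f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n), f4 = rnorm(n),
      f5 = rnorm(n))
    for (tg in c("total_oop", "sad", "ruf", "homa_inner")) {
      d[[tg]] <- rnorm(n)
    }
    bootstrap_evaluate(d, c("total_oop", "sad", "ruf", "homa_inner"),
                       paste0("f", 1:5), models = "lasso", B = 2,
                       seed = 4, fraction = 0.2, variant = variant)
  }
  reps <- list(mk("cone_angles"), mk("distances"))
  tab <- coefficient_table(reps)
  expect_equal(nrow(tab), 3 * 5 * 2)       # targets x features x variants
  expect_false(any(grepl("^homa", tab$target)))
  tab2 <- coefficient_table(reps, include_homa = TRUE)
  expect_true(any(grepl("^homa", tab2$target)))
})
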