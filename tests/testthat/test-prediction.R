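test_that("breed allele frequencies are plain counting with missing excluded", {
  g <- rbind(c(0, 2), c(1, 2), c(1, 2), c(2, NA),
             c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  ds <- tiny_dataset(g, rep(c("p", "q"), each = 4))
  f <- breed_allele_frequencies(ds, c("s001", "s002"))
  expect_equal(f["p", "s001"], 0.5)        # dosages 0,1,1,2
  expect_equal(f["p", "s002"], 1.0)        # fixed, one missing excluded
  expect_equal(f["q", "s001"], 0)
  expect_error(breed_allele_frequencies(ds, "nope"), "nope")
  # complement identity under allele flip
  ds2 <- ds
  ds2$genotypes <- 2 - ds2$genotypes
  f2 <- breed_allele_frequencies(ds2, c("s001", "s002"))
  expect_equal(unname(f2), unname(1 - f))
})

test_that("a noiseless planted signal is recovered exactly", {
  set.seed(33)
  X <- matrix(runif(12 * 5, 0.05, 0.95), 12, 5,
              dimnames = list(NULL, paste0("m", 1:5)))
  y <- 2 * X[, 1]
  mod <- stepwise_fit(X, y, alpha = 0.05)
  expect_equal(mod$selected, "m1")
  expect_equal(unname(mod$coefficients), 2, tolerance = 1e-10)
  expect_false(mod$empty)
})

test_that("stepwise selection matches the independent lm()-based oracle", {
  set.seed(55)
  agree <- 0
  for (rep in 1:40) {
    nb <- sample(10:16, 1)
    X <- matrix(runif(nb * 7, 0, 1), nb, 7,
                dimnames = list(NULL, paste0("m", 1:7)))
    beta <- numeric(7)
    k <- sample(0:3, 1)
    if (k > 0) beta[sample(7, k)] <- runif(k, 0.5, 2)
    y <- drop(X %*% beta) + rnorm(nb, sd = 0.2)
    mod <- stepwise_fit(X, y, alpha = 0.05)
    orc <- stepwise_oracle(X, y, alpha = 0.05)
    expect_equal(mod$selected, orc$selected)
    expect_equal(unname(mod$coefficients), unname(orc$coefficients),
                 tolerance = 1e-8)
    agree <- agree + identical(mod$selected, orc$selected)
  }
  expect_equal(agree, 40L)
})

test_that("pure-noise responses mostly select nothing and fall back", {
  set.seed(91)
  empties <- 0
  for (rep in 1:30) {
    X <- matrix(runif(12 * 5, 0, 1), 12, 5,
                dimnames = list(NULL, paste0("m", 1:5)))
    y <- rnorm(12)
    mod <- stepwise_fit(X, y, alpha = 0.05)
    empties <- empties + mod$empty
    if (mod$empty) {
      p <- predict_breeds(mod, X)
      expect_true(isTRUE(attr(p, "fallback")))
      expect_equal(as.numeric(p), rep(mean(y), 12))
    }
  }
  expect_gt(empties, 15)
})

test_that("constant candidate columns are excluded with a warning", {
  X <- cbind(m1 = runif(10), m2 = rep(0.4, 10))
  y <- 2 * X[, 1]
  expect_warning(mod <- stepwise_fit(X, y), "m2")
  expect_equal(mod$selected, "m1")
})

test_that("predictions are linear with no intercept", {
  mod <- structure(list(selected = c("m1", "m2"),
                        coefficients = c(m1 = 1, m2 = -1),
                        train_mean = 0.5, empty = FALSE),
                   class = "PredictionModel")
  X <- rbind(a = c(m1 = 0.5, m2 = 0.5), b = c(m1 = 1, m2 = 0))
  p <- predict_breeds(mod, X)
  expect_equal(unname(p), c(0, 1))
  expect_error(predict_breeds(mod, X[, 1, drop = FALSE]), "m2")
  # affine in each frequency column (finite differences are constant)
  X2 <- X; X2[, "m1"] <- X2[, "m1"] + 0.1
  X3 <- X; X3[, "m1"] <- X3[, "m1"] + 0.2
  d1 <- predict_breeds(mod, X2) - predict_breeds(mod, X)
  d2 <- predict_breeds(mod, X3) - predict_breeds(mod, X2)
  expect_equal(unname(d1), unname(d2), tolerance = 1e-12)
})

test_that("success matrices count cells and totals coherently", {
  obs <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8), 4, 2,
                dimnames = list(letters[1:4], c("t1", "t2")))
  sm <- success_matrix(obs, obs)
  expect_equal(sm$success_rate, 1)
  expect_equal(sum(sm$row_totals), sum(sm$col_totals))
  # zero tolerance: any discrepancy fails the cell
  pred <- obs; pred[1, 1] <- pred[1, 1] + 1e-9
  sm0 <- success_matrix(pred, obs, tolerance = 0)
  expect_false(sm0$success[1, 1])
  expect_true(all(sm0$success[-1, 1]))
  expect_error(success_matrix(obs[1:2, ], obs), "shape")
  # invariance under simultaneous breed permutation
  set.seed(10)
  pred2 <- obs + rnorm(8, sd = 0.5)
  perm <- sample(4)
  expect_equal(success_matrix(pred2, obs)$success_rate,
               success_matrix(pred2[perm, ], obs[perm, ])$success_rate)
})

test_that("permutation chance behaves analytically for rank criteria", {
  set.seed(77)
  k <- 6
  obs <- matrix(rnorm(k * 3), k, 3,
                dimnames = list(letters[1:k], c("t1", "t2", "t3")))
  pred <- matrix(rnorm(k * 3), k, 3, dimnames = dimnames(obs))
  pc <- permutation_chance(pred, obs, criterion = "rank_window",
                           window = 0L, n_perm = 2000, seed = 4)
  # exact-rank criterion admits 1 of k equally likely outcomes per cell
  expect_lt(abs(pc$chance_rate - 1 / k), 0.015)
  # a criterion that always succeeds has chance 1 and p 1
  pc1 <- permutation_chance(pred, obs,
                            criterion = function(p, o) p == p,
                            n_perm = 200, seed = 1)
  expect_equal(pc1$chance_rate, 1)
  expect_equal(pc1$p_value, 1)
  # fixed seed reproduces the null distribution
  pc2 <- permutation_chance(pred, obs, criterion = "rank_window",
                            window = 0L, n_perm = 500, seed = 9)
  pc3 <- permutation_chance(pred, obs, criterion = "rank_window",
                            window = 0L, n_perm = 500, seed = 9)
  expect_identical(pc2$null_rates, pc3$null_rates)
})

test_that("held-out prediction on the fixture beats its permutation chance", {
  fx <- make_prediction_fixture(11)
  X <- breed_allele_frequencies(fx$dataset, fx$markers)
  obs <- fx$stereotypes$values
  traits <- fx$stereotypes$traits
  pred <- matrix(NA_real_, length(fx$test_breeds), length(traits),
                 dimnames = list(fx$test_breeds, traits))
  for (tr in traits) {
    m <- stepwise_fit(X[fx$train_breeds, ], obs[fx$train_breeds, tr],
                      trait = tr)
    pred[, tr] <- predict_breeds(m, X[fx$test_breeds, ])
  }
  pc <- permutation_chance(pred, obs[fx$test_breeds, ], n_perm = 500,
                           seed = 11)
  expect_lt(pc$p_value, 0.05)
  expect_gt(pc$achieved, pc$chance_rate)
})
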