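test_that("design matrices follow the group definitions and canonical order", {
  rec <- tiny_records(30)
  dm1 <- build_design_matrix(rec, design_spec(1))
  expect_equal(colnames(dm1$X),
               c("(Intercept)", "urinary", "bowel", "sexual", "hormonal"))
  expect_equal(nrow(dm1$X), 30)

  # the 6i specification reproduces the printed 26-term regressor list
  spec6i <- design_spec(6, score_powers = 1, age_powers = 1:3,
                        interactions = "zubrod:score", label = "6i")
  expect_equal(
    spec_regressors(spec6i),
    c("uf", "ub", "uirr", "uinc", "bf", "bb", "sf", "sb", "hf", "hb",
      "age", "age^2", "age^3", "race_other", "zubrod",
      "uf:zubrod", "ub:zubrod", "uirr:zubrod", "uinc:zubrod", "bf:zubrod",
      "bb:zubrod", "sf:zubrod", "sb:zubrod", "hf:zubrod", "hb:zubrod",
      "psa_ge4")
  )
  dm6 <- build_design_matrix(rec, spec6i)
  expect_equal(ncol(dm6$X), 27)
  # polynomial and product columns are literal powers / elementwise products
  expect_equal(dm6$X[, "age^3"], dm6$X[, "age"]^3)
  expect_equal(dm6$X[, "uf:zubrod"], dm6$X[, "uf"] * dm6$X[, "zubrod"])
})

test_that("incomplete records are dropped and counted, empty designs error", {
  rec <- tiny_records(12)
  rec$epic_bb[c(2, 5)] <- NA
  dm <- build_design_matrix(rec, design_spec(2))
  expect_equal(dm$n_dropped, 2)
  expect_equal(dm$rows_used, setdiff(1:12, c(2, 5)))

  rec_all_bad <- tiny_records(5)
  rec_all_bad$eq5d <- NA
  expect_error(build_design_matrix(rec_all_bad, design_spec(1)),
               "no usable records")

  expect_error(design_spec(2, age_powers = 1:2), "no demographic")
  expect_error(design_spec(4, interactions = "zubrod:score"), "group 5 or 6")
})

test_that("OLS interpolates noiseless data and matches hand least squares", {
  X <- cbind(`(Intercept)` = 1, x = c(1, 2, 3, 4))
  beta <- c(0.3, 0.12)
  fit <- fit_ols(X, drop(X %*% beta))
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-12)

  # closed-form two-parameter least squares at n = 3
  x <- c(0, 1, 3); y <- c(1, 2, 2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  fit3 <- fit_ols(cbind(`(Intercept)` = 1, x = x), y)
  expect_equal(unname(fit3$coefficients), c(intercept, slope), tolerance = 1e-12)
})

test_that("OLS equals the normal-equation solution on random designs", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(15:60, 1); p <- sample(2:6, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
    y <- rnorm(n)
    fit <- fit_ols(X, y)
    ne <- solve(crossprod(X), crossprod(X, y))
    expect_equal(unname(fit$coefficients), unname(drop(ne)), tolerance = 1e-8)
  }
})

test_that("rank deficiency is reported with the collinear column named", {
  X <- cbind(`(Intercept)` = 1, a = rnorm(20))
  X <- cbind(X, a_copy = X[, "a"])
  expect_error(fit_ols(X, rnorm(20)), "a_copy")
})

test_that("adding a regressor never increases the training RSS", {
  set.seed(7)
  n <- 80
  X <- cbind(`(Intercept)` = 1, a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 0.5 + 0.3 * X[, "a"] + rnorm(n, sd = 0.4)
  rss <- function(cols) {
    f <- fit_ols(X[, c("(Intercept)", cols), drop = FALSE], y)
    n * f$scale_sigma^2
  }
  expect_true(rss("a") <= rss(character(0)) + 1e-10)
  expect_true(rss(c("a", "b")) <= rss("a") + 1e-10)
  expect_true(rss(c("a", "b", "c")) <= rss(c("a", "b")) + 1e-10)
})

test_that("Tobit on censoring-free data reduces to OLS maximum likelihood", {
  set.seed(11)
  n <- 150
  X <- cbind(`(Intercept)` = 1, x = runif(n))
  y <- 0.2 + 0.4 * X[, "x"] + rnorm(n, sd = 0.2) # all far below 1? keep below
  y <- pmin(y, 0.999) # ensure no exact-1 values
  tob <- fit_tobit(X, y)
  ols <- fit_ols(X, y)
  expect_true(tob$converged)
  expect_equal(unname(tob$coefficients), unname(ols$coefficients),
               tolerance = 1e-6)
  # sigma is the RMS residual (MLE), not the unbiased variant
  expect_equal(tob$scale_sigma, ols$scale_sigma, tolerance = 1e-6)
})

test_that("Tobit maximum likelihood beats a dense grid-search oracle", {
  # tiny dataset: n = 6, 2 censored at 1, one regressor
  X <- cbind(`(Intercept)` = 1, x = c(0.1, 0.3, 0.4, 0.6, 0.8, 0.9))
  y <- c(0.70, 0.85, 0.80, 0.95, 1.00, 1.00)
  fit <- fit_tobit(X, y)
  expect_true(fit$converged)

  # independent censored-normal log-likelihood, written from the model
  # definition rather than shared with the implementation
  oracle_ll <- function(b0, b1, s) {
    mu <- b0 + b1 * X[, "x"]
    cens <- y == 1
    sum(dnorm(y[!cens], mu[!cens], s, log = TRUE)) +
      sum(pnorm((mu[cens] - 1) / s, log.p = TRUE))
  }
  # the optimiser's solution evaluates identically under the oracle
  expect_equal(fit$loglik,
               oracle_ll(fit$coefficients[1], fit$coefficients[2], fit$scale_sigma),
               tolerance = 1e-8)
  grid <- expand.grid(b0 = seq(0, 1.4, by = 0.05),
                      b1 = seq(-0.5, 1, by = 0.05),
                      s = seq(0.02, 0.5, by = 0.02))
  best_grid <- max(mapply(oracle_ll, grid$b0, grid$b1, grid$s))
  expect_gte(fit$loglik, best_grid)
})

test_that("Tobit log-likelihood at the optimum dominates random parameter draws", {
  set.seed(5)
  truth <- generate_linear_truth(
    c(`(Intercept)` = 0.9, x = 0.3), sigma_true = 0.15, n = 200, seed = 31,
    censor = TRUE
  )
  fit <- fit_tobit(truth$X, truth$y)
  expect_true(fit$converged)
  cens <- truth$y == 1
  oracle_ll <- function(b0, b1, s) {
    mu <- b0 + b1 * truth$X[, "x"]
    sum(dnorm(truth$y[!cens], mu[!cens], s, log = TRUE)) +
      sum(pnorm((mu[cens] - 1) / s, log.p = TRUE))
  }
  draws <- matrix(c(runif(1000, 0, 2), runif(1000, -1, 1.5),
                    runif(1000, 0.02, 1)), ncol = 3)
  lls <- apply(draws, 1, function(p) oracle_ll(p[1], p[2], p[3]))
  expect_gte(fit$loglik, max(lls))
})

test_that("Tobit recovers generative parameters under heavy ceiling censoring", {
  beta_true <- c(`(Intercept)` = 0.92, x = 0.15)
  sigma_true <- 0.12
  truth <- generate_linear_truth(beta_true, sigma_true, n = 2000, seed = 2207,
                                 censor = TRUE)
  expect_gt(truth$censored_fraction, 0.35)
  expect_lt(truth$censored_fraction, 0.60)
  fit <- fit_tobit(truth$X, truth$y)
  expect_true(fit$converged)
  for (j in 1:2) {
    expect_lt(abs(fit$coefficients[j] - beta_true[j]), 3 * fit$se[j])
  }
  expect_lt(abs(fit$scale_sigma - sigma_true) / sigma_true, 0.05)
})

test_that("Tobit estimates agree with an independent censored-regression fit", {
  skip_if_not_installed("survival")
  truth <- generate_linear_truth(c(`(Intercept)` = 0.9, x = 0.2),
                                 sigma_true = 0.15, n = 500, seed = 77,
                                 censor = TRUE)
  fit <- fit_tobit(truth$X, truth$y)
  sr <- survival::survreg(
    survival::Surv(truth$y, truth$y < 1, type = "right") ~ truth$X[, "x"],
    dist = "gaussian"
  )
  expect_equal(unname(fit$coefficients), unname(coef(sr)), tolerance = 1e-4)
  expect_equal(fit$scale_sigma, sr$scale, tolerance = 1e-3)
})

test_that("fully censored data is rejected as unidentified", {
  X <- cbind(`(Intercept)` = 1, x = runif(10))
  expect_error(fit_tobit(X, rep(1, 10)), "unidentified")
  expect_error(fit_tobit(X, rep(1.2, 10)), "exceeds")
})

test_that("Tobit prediction policies behave as declared", {
  truth <- generate_linear_truth(c(`(Intercept)` = 0.9, x = 0.3),
                                 sigma_true = 0.1, n = 300, seed = 13,
                                 censor = TRUE)
  fit <- fit_tobit(truth$X, truth$y)
  Xnew <- cbind(`(Intercept)` = 1, x = c(0, 1))
  latent <- predict_tobit(fit, Xnew, "latent")
  trunc <- predict_tobit(fit, Xnew, "truncate_at_1")
  expect_equal(trunc, pmin(latent, 1))
  expect_true(all(predict_tobit(fit, truth$X) <= 1))
  expect_error(predict_tobit(fit, Xnew, "banana"))
})

test_that("the censored expectation matches a Monte-Carlo oracle", {
  # E[min(N(1, 0.1^2), 1)] by simulation at 10^6 draws
  set.seed(123)
  mc <- mean(pmin(rnorm(1e6, 1, 0.1), 1))
  fit <- structure(
    list(form = "tobit", coefficients = c(`(Intercept)` = 1), scale_sigma = 0.1,
         converged = TRUE, upper_censor = 1),
    class = "fit_result"
  )
  ce <- predict_tobit(fit, cbind(`(Intercept)` = 1), "censored_expectation")
  expect_equal(ce, mc, tolerance = 5e-4)
  # closed form at mu = U: U - sigma/sqrt(2*pi)
  expect_equal(ce, 1 - 0.1 / sqrt(2 * pi), tolerance = 1e-12)
})

test_that("two-part estimation splits, recombines, and degenerates correctly", {
  set.seed(21)
  n <- 200
  X <- cbind(`(Intercept)` = 1, x = runif(n))
  y_latent <- 0.7 + 0.2 * X[, "x"] + rnorm(n, sd = 0.1)
  y <- ifelse(y_latent > 0.95, 1, pmin(y_latent, 0.95))
  fit <- fit_two_part(X, y)
  expect_true(fit$converged)

  # combined prediction is p*ceiling + (1-p)*yhat2, verified arithmetically
  p <- plogis(drop(X %*% fit$part1$coefficients))
  yhat2 <- drop(X %*% fit$part2$coefficients)
  expect_equal(predict_two_part(fit, X), p * 1 + (1 - p) * yhat2,
               tolerance = 1e-12)
  expect_equal(unname(p[1] * 1 + (1 - p[1]) * yhat2[1]),
               unname(predict(fit, X[1, , drop = FALSE])))

  # no ceiling mass: p degenerates to 0 and combined == part-2 OLS exactly
  y_free <- pmin(y_latent, 0.95)
  fit0 <- fit_two_part(X, y_free)
  ols <- fit_ols(X, y_free)
  expect_null(fit0$part1)
  expect_equal(predict_two_part(fit0, X), drop(X %*% ols$coefficients),
               tolerance = 1e-12)
})

test_that("two-part degeneracies are flagged or rejected", {
  n <- 60
  X <- cbind(`(Intercept)` = 1, x = seq_len(n) / n)
  # perfectly separated part 1: ceiling iff x > 0.5
  y <- ifelse(X[, "x"] > 0.5, 1, 0.5 + 0.3 * X[, "x"])
  fit <- fit_two_part(X, y)
  expect_false(fit$converged)

  # a part with fewer than two distinct outcomes errors, naming the part
  expect_error(fit_two_part(X, rep(1, n)), "part 2")
  expect_error(fit_two_part(X, c(rep(1, n - 3), rep(0.8, 3))), "part 2")
})

test_that("forward stepwise keeps signal, drops noise, honours thresholds", {
  set.seed(909)
  hits_A <- 0; drops_B <- 0
  reps <- 25
  for (r in seq_len(reps)) {
    n <- 400
    X <- cbind(`(Intercept)` = 1, A = rnorm(n), B = rnorm(n))
    y <- 0.5 + 0.5 * X[, "A"] + rnorm(n, sd = 0.5)
    sel <- stepwise_forward(X, y, "ols")$selected
    if ("A" %in% sel) hits_A <- hits_A + 1
    if (!("B" %in% sel)) drops_B <- drops_B + 1
  }
  expect_equal(hits_A, reps) # the true regressor always enters
  expect_gt(drops_B / reps, 0.6) # pure noise enters at most at the sle rate

  # empty candidate pool: intercept-only model
  Xi <- cbind(`(Intercept)` = rep(1, 50))
  sw0 <- stepwise_forward(Xi, rnorm(50), "ols")
  expect_equal(sw0$selected, character(0))
  expect_equal(length(sw0$fit$coefficients), 1)

  # sle = 1: every candidate eventually enters
  X3 <- cbind(`(Intercept)` = 1, a = rnorm(50), b = rnorm(50), c = rnorm(50))
  swf <- stepwise_forward(X3, rnorm(50), "ols", sle = 1, slstay = 1)
  expect_setequal(swf$selected, c("a", "b", "c"))
})

test_that("weak hierarchy gates product terms behind their parents", {
  set.seed(404)
  n <- 500
  uf <- rnorm(n); zub <- rbinom(n, 1, 0.5)
  X <- cbind(`(Intercept)` = 1, uf = uf, zubrod = zub, `uf:zubrod` = uf * zub)
  # signal lives in the product only
  y <- 0.2 + 0.6 * uf * zub + rnorm(n, sd = 0.3)
  sw <- stepwise_forward(X, y, "ols", hierarchy = TRUE)
  if ("uf:zubrod" %in% sw$selected) {
    pos <- match(c("uf", "zubrod", "uf:zubrod"), sw$selected)
    expect_true(all(pos[1:2] < pos[3]))
  }
  sw_free <- stepwise_forward(X, y, "ols", hierarchy = FALSE)
  expect_true("uf:zubrod" %in% sw_free$selected)
  expect_equal(sw_free$selected[1], "uf:zubrod")
})

test_that("stepwise works for Tobit and two-part forms", {
  truth <- generate_linear_truth(c(`(Intercept)` = 0.9, A = 0.2, B = 0),
                                 sigma_true = 0.1, n = 400, seed = 55,
                                 censor = TRUE)
  swt <- stepwise_forward(truth$X, truth$y, "tobit")
  expect_true("A" %in% swt$selected)
  sw2 <- stepwise_forward(truth$X, truth$y, "two_part")
  expect_true("A" %in% sw2$selected)
})

test_that("fits freeze into mapping models and round-trip predictions", {
  rec <- generate_cohort(cohort_params(), n = 300, seed = 808)
  dm <- build_design_matrix(rec, design_spec(1))
  fit <- fit_ols(dm$X, dm$y)
  m <- as_mapping_model(fit, "frozen_ols", 1)
  direct <- drop(dm$X %*% fit$coefficients)
  via_model <- predict_utility(m, rec)$predicted_utility
  expect_equal(via_model, direct, tolerance = 1e-12)

  fit2p <- fit_two_part(dm$X, dm$y)
  expect_error(as_mapping_model(fit2p, "nope", 1), "two-part")
})
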