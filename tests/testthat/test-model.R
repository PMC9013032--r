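test_that("polynomial contrasts match their closed forms", {
  C3 <- orthogonal_contrasts(3)
  expect_equal(unname(C3[, 1]), c(-1, 0, 1) / sqrt(2))
  expect_equal(unname(C3[, 2]), c(1, -2, 1) / sqrt(6))
  C2 <- orthogonal_contrasts(2)
  expect_equal(unname(C2[, 1]), c(-1, 1) / sqrt(2))
  expect_error(orthogonal_contrasts(1), "k >= 2")
})

test_that("contrast columns are orthonormal and orthogonal to constants", {
  for (k in 2:5) {
    C <- orthogonal_contrasts(k)
    expect_equal(crossprod(C), diag(k - 1), ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(colSums(C), rep(0, k - 1), ignore_attr = TRUE,
                 tolerance = 1e-12)
    # independent reference: base R's polynomial contrasts
    expect_equal(unname(C), unname(stats::contr.poly(k)),
                 tolerance = 1e-12)
  }
})

test_that("the three design specifications have the documented widths", {
  full <- design_info("full")
  com <- design_info("comorbidity")
  bs <- design_info("body_system")
  expect_equal(full$n_variables, 48)
  expect_equal(com$n_variables, 30)
  expect_equal(bs$n_variables, 18)
  expect_equal(full$n_columns, 66)
  expect_equal(com$n_columns, 30)
  expect_equal(bs$n_columns, 36)
})

zero_features <- function(n = 1) {
  structure(list(
    body = matrix(0L, n, 18, dimnames = list(NULL, sprintf("bs%02d", 1:18))),
    elix = matrix(0L, n, 30, dimnames = list(NULL, elix_registry())),
    registry = elix_registry()),
    class = "severity_features")
}

test_that("design encoding substitutes contrast rows deterministically", {
  f0 <- zero_features()
  Xb <- encode_design(f0, "body_system")
  expect_equal(ncol(Xb), 36)
  expect_equal(unname(Xb[1, seq(1, 36, 2)]), rep(-1 / sqrt(2), 18))
  expect_equal(unname(Xb[1, seq(2, 36, 2)]), rep(1 / sqrt(6), 18))
  Xf <- encode_design(f0, "full")
  expect_equal(ncol(Xf), 66)
  # absent flags encode as the level-0 two-point contrast value
  expect_equal(unname(Xf[1, 37:66]), rep(-1 / sqrt(2), 30))

  sim <- small_sim(seed = 5, n = 40)
  f <- build_features(sim$enc, sim$maps, "discharge")
  expect_identical(encode_design(f, "full"), encode_design(f, "full"))
})

test_that("intercept-only fit recovers the closed-form log odds", {
  y <- c(rep(1, 30), rep(0, 70))
  fit <- fit_logistic(matrix(numeric(0), 100, 0), y)
  expect_equal(fit$intercept, log(0.3 / 0.7), tolerance = 1e-8)
  fit2 <- fit_severity_model(matrix(numeric(0), 100, 0), y)
  expect_equal(fit2$intercept, log(0.3 / 0.7), tolerance = 1e-8)
})

test_that("IRLS matches reference fits on the same data", {
  set.seed(402)
  n <- 500
  f <- zero_features(n)
  f$body[] <- sample(0:2, n * 18, replace = TRUE,
                     prob = c(0.6, 0.25, 0.15))
  f$elix[] <- rbinom(n * 30, 1, 0.12)
  X <- encode_design(f, "body_system")
  beta_true <- rep(c(0.8, 0.1), 18)
  y <- rbinom(n, 1, plogis(-0.2 + X %*% beta_true))
  fit <- fit_severity_model(X, y, variant = "body_system")
  ref <- stats::glm.fit(cbind(1, X), y,
                        family = stats::binomial())
  expect_true(fit$converged)
  expect_equal(c(fit$intercept, unname(fit$coefficients)),
               unname(ref$coefficients), tolerance = 1e-6)

  # tiny dataset: compare against direct numerical maximization
  set.seed(403)
  Xs <- matrix(sample(c(-1, 1) / sqrt(2), 8 * 2, replace = TRUE), 8, 2)
  Xs <- Xs[rep(1:8, 5), ]
  ys <- rbinom(40, 1, plogis(0.4 + Xs %*% c(0.9, -0.6)))
  if (sum(ys) %in% c(0, 40)) ys[1:2] <- c(0, 1)
  nll <- function(b) {
    eta <- b[1] + Xs %*% b[-1]
    -sum(ys * eta - log1p(exp(eta)))
  }
  opt <- stats::optim(c(0, 0, 0), nll, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  fit2 <- fit_logistic(Xs, ys, maxit = 200)
  expect_equal(c(fit2$intercept, unname(fit2$coefficients)), opt$par,
               tolerance = 1e-5)
})

test_that("duplicating every row leaves the fit unchanged", {
  set.seed(404)
  n <- 600
  f <- zero_features(n)
  f$body[] <- sample(0:2, n * 18, replace = TRUE, prob = c(0.6, 0.25, 0.15))
  X <- encode_design(f, "body_system")
  y <- rbinom(n, 1, plogis(X %*% rep(c(0.5, 0), 18)))
  fit1 <- fit_severity_model(X, y, variant = "body_system", tol = 1e-10)
  fit2 <- fit_severity_model(X[rep(1:n, 2), ], rep(y, 2),
                             variant = "body_system", tol = 1e-10)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-7)
  expect_equal(fit1$intercept, fit2$intercept, tolerance = 1e-7)
})

test_that("degenerate inputs are rejected with useful errors", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_logistic(X, rep(1, 10)), "single class")
  # perfectly separated data diverge without ridge and fit with it
  Xs <- matrix(c(rep(-1, 25), rep(1, 25)), 50, 1)
  Xs <- cbind(Xs, 0.01 * rnorm(50))
  ys <- as.integer(Xs[, 1] > 0)
  expect_error(fit_logistic(Xs, ys, maxit = 20), "ridge")
  fitr <- fit_logistic(Xs, ys, ridge = 1e-2, maxit = 200)
  expect_true(all(is.finite(fitr$coefficients)))
})

test_that("orthogonal contrasts and one-hot dummies span the same model", {
  sim <- small_sim(seed = 31, n = 500)
  f <- build_features(sim$enc, sim$maps, "discharge")
  y <- binarize_outcome(sim$enc$encounters$discharge_soi)
  Xc <- encode_design(f, "body_system")
  fit_c <- fit_severity_model(Xc, y, variant = "body_system")
  p_c <- predict_probability(fit_c, f)
  # plain dummy encoding of the same ordinal factors, fitted with glm
  Xd <- cbind(f$body == 1, f$body == 2) * 1
  ref <- stats::glm.fit(cbind(1, Xd), y, family = stats::binomial())
  p_d <- stats::plogis(drop(cbind(1, Xd) %*% ref$coefficients))
  expect_lt(max(abs(p_c - p_d)), 1e-8)
})

test_that("predicted probabilities equal the inverse-logit dot product", {
  sim <- small_sim(seed = 13, n = 400)
  f <- build_features(sim$enc, sim$maps, "discharge")
  y <- binarize_outcome(sim$enc$encounters$discharge_soi)
  X <- encode_design(f, "full")
  fit <- fit_severity_model(X, y, variant = "full", ridge = 0.05)
  p <- predict_probability(fit, f)
  # independent row-by-row dot product
  manual <- vapply(seq_len(nrow(X)), function(i) {
    1 / (1 + exp(-(fit$intercept + sum(X[i, ] * fit$coefficients))))
  }, numeric(1))
  expect_lt(max(abs(p - manual)), 1e-12)
  expect_true(all(p > 0 & p < 1))
  # zero coefficients, zero intercept -> 0.5 everywhere
  fit0 <- fit
  fit0$intercept <- 0
  fit0$coefficients[] <- 0
  expect_equal(unique(predict_probability(fit0, f)), 0.5)
  # variant mismatch is fatal
  expect_error(predict_probability(fit, encode_design(f, "body_system")),
               "mismatch")
})

test_that("coefficients are recovered from data simulated under the model", {
  cfg <- sim_config(seed = 55, n_encounters = 6000)
  maps <- generate_reference_maps(cfg)
  enc <- generate_encounters(cfg, maps)
  f <- build_features(enc, maps, "discharge")
  X <- encode_design(f, "body_system")
  fit <- fit_severity_model(X, enc$truth$label, variant = "body_system")
  z <- abs(fit$coefficients - cfg$coefficients) / fit$se
  expect_gt(mean(z < 3), 0.9)
  expect_lt(abs(fit$intercept - cfg$intercept) / fit$se_intercept, 4)
})

test_that("models survive a JSON round trip", {
  sim <- small_sim(seed = 61, n = 400)
  f <- build_features(sim$enc, sim$maps, "discharge")
  y <- binarize_outcome(sim$enc$encounters$discharge_soi)
  fit <- fit_severity_model(encode_design(f, "body_system"), y,
                            variant = "body_system",
                            version_label = sim$maps$version_label)
  p <- file.path(withr::local_tempdir(), "model.json")
  write_model(fit, p)
  back <- read_model(p)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$variant, fit$variant)
  expect_equal(predict_probability(back, f), predict_probability(fit, f))
  expect_error(read_model(write_reference_maps(sim$maps,
                                               withr::local_tempdir())[1]),
               "not a serialized")
})
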