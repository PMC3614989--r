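test_that("spline bases have the requested dimension and reusable knots", {
  set.seed(51)
  x <- runif(40, 60, 110)
  for (df in c(2, 3, 5)) {
    b <- spline_basis(x, df)
    expect_equal(ncol(b), df)
  }
  b <- spline_basis(x, 4)
  b2 <- spline_basis(x[7], 4, knots = attr(b, "knots"),
                     boundary_knots = attr(b, "Boundary.knots"))
  expect_equal(as.numeric(b2), as.numeric(b[7, ]))
  expect_error(spline_basis(rep(1, 10), 3), "constant")
  expect_error(spline_basis(c(1, 2, 3), 5), "distinct")
})

test_that("a basis of dimension n interpolates a smooth function", {
  x <- seq(0, 2, length.out = 8)
  y <- sin(x) + 0.3 * x^2
  fit <- lm(y ~ spline_basis(x, df = 8))
  expect_lt(max(abs(stats::fitted(fit) - y)), 1e-8)
})

test_that("Gaussian fits without a random term equal closed-form OLS", {
  set.seed(52)
  n <- 120
  dat <- tibble::tibble(
    fork_length_cm = runif(n, 60, 110),
    y = 1 + 0.05 * runif(n, 60, 110) + rnorm(n))
  dat$y <- 1 + 0.04 * dat$fork_length_cm + rnorm(n, 0, 0.5)
  f <- fit_model(model_spec("y", "gaussian_identity",
                            terms = list(fork_length_cm = 3),
                            random_set = NULL), dat)
  X <- cbind(1, splines::ns(dat$fork_length_cm, df = 3))
  beta <- solve(crossprod(X), crossprod(X, dat$y))
  expect_equal(unname(f$coefficients), as.numeric(beta), tolerance = 1e-8)
})

test_that("an intercept-only binomial fit returns the logit of the proportion", {
  dat <- tibble::tibble(y = rep(c(1L, 0L), c(9, 11)))
  f <- fit_model(model_spec("y", "binomial_logit", random_set = NULL), dat)
  expect_equal(unname(f$coefficients), qlogis(0.45), tolerance = 1e-8)
  expect_error(
    fit_model(model_spec("y2", "binomial_logit", random_set = NULL),
              tibble::tibble(y2 = c(0, 2))), "0/1")
})

test_that("the random-intercept SD is recovered from clustered data", {
  cg <- simulate_clustered_gaussian(200, 10, sd_set = 1, sd_resid = 1,
                                    seed = 61)
  f <- fit_model(model_spec("y", "gaussian_identity"), cg)
  expect_lt(abs(f$random_sd - 1), 0.15)
  expect_equal(f$n, 2000)
  # k = intercept + set variance + residual variance
  expect_equal(f$k, 3)
})

test_that("AICc matches the closed form and its limits", {
  expect_equal(aicc(-100, 3, 50), 206 + 24 / 46)
  expect_equal(round(aicc(-100, 3, 50), 4), 206.5217)
  expect_lt(abs(aicc(-100, 3, 1e6) - (200 + 6)), 1e-4)
  expect_equal(aicc(-77.5, 0, 30), 155)
  expect_error(aicc(-10, 5, 6), "n > k")
})

test_that("Akaike weights follow the exp(-delta/2) normalisation", {
  mk <- function(ll, k, label) {
    structure(list(spec = model_spec("y", "gaussian_identity", label = label),
                   loglik = ll, k = k, n = 100, aicc = aicc(ll, k, 100),
                   converged = TRUE), class = "pf_fit")
  }
  # two models one AICc unit of 2 apart
  tab <- rank_models(list(mk(-50, 3, "a"), mk(-51, 3, "b")))
  expect_equal(tab$delta_aicc, c(0, 2))
  expect_equal(round(tab$akaike_weight, 3), c(0.731, 0.269))
  expect_true(all(tab$equivalent == c(TRUE, FALSE)))
  single <- rank_models(list(mk(-50, 3, "a")))
  expect_equal(single$akaike_weight, 1)
  expect_equal(single$delta_aicc, 0)
  # weights always sum to one
  set.seed(53)
  lls <- -runif(6, 40, 60)
  tab6 <- rank_models(lapply(seq_along(lls), function(i)
    mk(lls[i], 3, paste0("m", i))))
  expect_equal(sum(tab6$akaike_weight), 1)
  # shifting every log-likelihood leaves deltas and weights unchanged
  tab6b <- rank_models(lapply(seq_along(lls), function(i)
    mk(lls[i] + 7.3, 3, paste0("m", i))))
  expect_equal(tab6b$delta_aicc, tab6$delta_aicc)
  expect_equal(tab6b$akaike_weight, tab6$akaike_weight)
  bad <- list(mk(-50, 3, "a"),
              structure(list(spec = model_spec("y", "gaussian_identity"),
                             loglik = -50, k = 3, n = 99,
                             aicc = aicc(-50, 3, 99), converged = TRUE),
                        class = "pf_fit"))
  expect_error(rank_models(bad), "different observation counts")
})

test_that("nested fixed-effect models cannot lose log-likelihood", {
  set.seed(54)
  dat <- tibble::tibble(x = runif(80, 0, 10))
  dat$y <- 0.3 * dat$x + rnorm(80)
  small <- fit_model(model_spec("y", "gaussian_identity",
                                terms = list(x = "linear"),
                                random_set = NULL), dat)
  large <- fit_model(model_spec("y", "gaussian_identity",
                                terms = list(x = 4), random_set = NULL), dat)
  expect_gte(large$loglik, small$loglik - 1e-8)
})

test_that("predictions are population-level and flag extrapolation", {
  dat <- tibble::tibble(
    set_id = rep(sprintf("s%02d", 1:20), each = 10),
    y = rep(c(1L, 0L), 100))
  f <- fit_model(model_spec("y", "binomial_logit",
                            terms = list(), random_set = "set_id"), dat)
  p <- predict(f, tibble::tibble(set_id = "s01"))
  expect_equal(as.numeric(p), 0.5, tolerance = 1e-6)
  # prediction at a training covariate matches the fitted value (no random
  # term, so fitted values are fixed-effect predictions)
  dat2 <- tibble::tibble(x = runif(50, 0, 1))
  dat2$y <- dat2$x + rnorm(50, 0, 0.1)
  g <- fit_model(model_spec("y", "gaussian_identity",
                            terms = list(x = 2), random_set = NULL), dat2)
  p2 <- predict(g, dat2[3, ])
  expect_equal(as.numeric(p2), unname(stats::fitted(g$fit)[3]),
               tolerance = 1e-10)
  expect_false(attr(p2, "extrapolated"))
  p3 <- predict(g, tibble::tibble(x = 2))
  expect_true(attr(p3, "extrapolated"))
})

test_that("model selection recovers the generating model form", {
  n_sets <- 200; per <- 10
  pick_true <- 0L
  n_rep <- 50
  for (r in seq_len(n_rep)) {
    set.seed(100 + r)
    fl <- runif(n_sets * per, 60, 110)
    month <- sample(1:12, n_sets * per, TRUE)
    u <- rep(rnorm(n_sets, 0, 0.5), each = per)
    dat <- tibble::tibble(
      set_id = rep(sprintf("s%03d", 1:n_sets), each = per),
      fork_length_cm = fl, month = month,
      y = 0.03 * fl + 0.4 * cos(2 * pi * month / 12) + u + rnorm(n_sets * per))
    specs <- list(
      model_spec("y", "gaussian_identity",
                 list(fork_length_cm = 2, month = 2)),
      model_spec("y", "gaussian_identity", list(fork_length_cm = 2)),
      model_spec("y", "gaussian_identity", list(month = 2)),
      model_spec("y", "gaussian_identity"))
    tab <- rank_models(lapply(specs, fit_model, data = dat))
    if (tab$model[1] == specs[[1]]$label) pick_true <- pick_true + 1L
  }
  expect_gt(pick_true / n_rep, 0.8)
})

test_that("fitted spawning-fraction surfaces rise with length in every month", {
  truth <- modifyList(default_truth(71L), list(n_sets = 150L))
  sim <- simulate_population(truth, seed = 71L)
  d <- join_records(sim$samples, classify_histology(sim$histology))
  mat <- dplyr::filter(d, !is.na(mature) & mature,
                       latitude >= -25, latitude <= -10)
  mat$pof01 <- as.integer(mat$pof_stage %in% c("new", "lt12h", "h12_24"))
  f <- fit_model(model_spec("pof01", "binomial_logit",
                            list(fork_length_cm = "linear", month = 2)), mat)
  grid <- tidyr::expand_grid(fork_length_cm = seq(88, 106, 2), month = 1:12)
  p <- matrix(predict(f, grid), ncol = 12, byrow = TRUE)
  expect_true(all(apply(p, 2, function(col) all(diff(col) > 0))))
})
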