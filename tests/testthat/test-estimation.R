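# exact single-site decay used as an arithmetic oracle for the likelihood
decay_df <- function(times, y_obs_k16) {
  data.frame(motif_label = "K16ac", time_min = times,
             replicate = 1, y = y_obs_k16)
}

test_that("the Gaussian likelihood matches a hand-computed sum", {
  m <- kinetic_model("mass_action", net1, c(K16 = 0.1), mode = "site")
  times <- c(5, 15, 30)
  y_true <- 1 - exp(-0.1 * times)          # closed form, not the solver
  resid <- c(0.1, -0.1, 0.02)
  d <- tc_dataset(decay_df(times, y_true + resid), sites = "K16")

  sigma <- 0.05
  expected <- sum(resid^2) / (2 * sigma^2) + 3 * log(sigma) + 1.5 * log(2 * pi)
  nll <- negative_log_likelihood(m, d, likelihood_spec("fixed", sigma = sigma))
  expect_equal(as.numeric(nll), expected, tolerance = 1e-6)

  # zero residuals: NLL = N/2 log 2pi at sigma 1; doubling sigma adds N log 2
  d0 <- tc_dataset(decay_df(times, y_true), sites = "K16")
  n0 <- negative_log_likelihood(m, d0, likelihood_spec("fixed", sigma = 1))
  expect_equal(as.numeric(n0), 1.5 * log(2 * pi), tolerance = 1e-8)
  n2 <- negative_log_likelihood(m, d0, likelihood_spec("fixed", sigma = 2))
  expect_equal(as.numeric(n2) - as.numeric(n0), 3 * log(2), tolerance = 1e-8)
})

test_that("masked observations are omitted from the likelihood", {
  m <- kinetic_model("mass_action", net1, c(K16 = 0.1), mode = "site")
  times <- c(5, 15, 30)
  y_true <- 1 - exp(-0.1 * times)
  df <- decay_df(times, y_true + c(0.5, 0, 0))  # one gross outlier
  df$mask <- c(TRUE, FALSE, FALSE)
  d <- tc_dataset(df, sites = "K16")
  nll <- negative_log_likelihood(m, d, likelihood_spec("fixed", sigma = 1))
  expect_equal(as.numeric(nll), 2 * 0.5 * log(2 * pi), tolerance = 1e-8)
})

test_that("integration failure is penalized, not fatal", {
  m <- kinetic_model("mass_action", net4,
                     c(K5 = 1e300, K8 = 1, K12 = 1, K16 = 1), mode = "site")
  d <- tc_dataset(decay_df(c(5, 15), c(0.5, 0.6)), sites = h4_sites())
  expect_warning(v <- negative_log_likelihood(m, d, likelihood_spec()),
                 "integration failure")
  expect_equal(as.numeric(v), 1e10)
})

test_that("maximum likelihood recovers a noise-free single-site rate", {
  truth <- c(K16 = 0.05)
  m <- kinetic_model("mass_action", net1, truth, mode = "site")
  times <- c(0, 5, 15, 30, 60)
  tr <- simulate_model(m, times)
  df <- data.frame(motif_label = rep(rownames(tr$y), ncol(tr$y)),
                   time_min = rep(times, each = 2), replicate = 1,
                   y = as.vector(tr$y))
  d <- tc_dataset(df, sites = "K16")
  spec <- likelihood_spec("fixed", sigma = 0.01)
  f <- fit_model("mass_action", d, spec, n_starts = 5, seed = 7)
  expect_lt(abs(f$theta_hat[["kcat.K16"]] / 0.05 - 1), 0.01)

  # a start placed at the optimum converges immediately to the NLL at truth
  f1 <- fit_model("mass_action", d, spec, n_starts = 1, seed = 7,
                  theta0 = c(kcat.K16 = 0.05))
  expect_equal(-f1$logL,
               as.numeric(negative_log_likelihood(m, d, spec)),
               tolerance = 1e-6)

  # determinism: same seed, bit-identical estimate
  f2 <- fit_model("mass_action", d, spec, n_starts = 5, seed = 7)
  expect_identical(f$theta_hat, f2$theta_hat)
})

test_that("best-of-starts NLL is monotone in the number of starts", {
  b <- generate_dataset(recovery_preset(5))
  spec <- likelihood_spec("fixed", sigma = 0.01)
  lls <- vapply(c(1, 3, 6), function(ns)
    fit_model("mass_action", b$dataset, spec, n_starts = ns, seed = 31)$logL,
    numeric(1))
  expect_true(all(diff(lls) >= -1e-9))
})

test_that("AIC arithmetic and the rejection rule behave as defined", {
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(-10, 3), 26)
  expect_equal(aic(-10, 4) - aic(-10, 3), 2)

  mk <- function(fam, a, k) structure(
    list(family = fam, aic = a, n_params = k), class = "fit_result")
  cmp <- compare_models(list(mk("a", 100, 3), mk("b", 115, 4),
                             mk("c", 130, 5)), threshold = 10)
  expect_equal(cmp$family, c("a", "b", "c"))
  expect_equal(cmp$rejected, c(FALSE, TRUE, TRUE))
  expect_equal(min(cmp$delta_aic), 0)

  cmp2 <- compare_models(list(mk("a", 100, 3), mk("b", 105, 4)))
  expect_false(any(cmp2$rejected))

  # permutation invariance and the fewer-parameters tie-break
  cmp3 <- compare_models(list(mk("b", 115, 4), mk("c", 130, 5),
                              mk("a", 100, 3)))
  expect_equal(cmp3$family, cmp$family)
  tie <- compare_models(list(mk("rich", 100, 9), mk("lean", 100, 2)))
  expect_equal(tie$family[1], "lean")
})
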