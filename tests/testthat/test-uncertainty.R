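# tiny single-parameter problem: 1-site mass action, closed-form-free oracle
# by dense quadrature over the log10-scale posterior
one_site_data <- function(seed = 2, sigma = 0.02) {
  p <- structure(
    list(name = "one", family = "mass_action", mode = "site", sites = "K16",
         kcat = c(K16 = 0.08), kon = NULL, koff = NULL, k_transfer = 0,
         E_tot = 0.25, times = c(0, 5, 15, 30, 60), n_replicates = 3L,
         sigma = sigma, detection_limit = 3e-5, seed = as.integer(seed),
         version = "1"),
    class = "scenario_preset")
  generate_dataset(p)$dataset
}

test_that("a flat likelihood returns the bounded uniform prior", {
  d <- one_site_data()
  prior <- prior_spec(1e-3, 1e2)
  spec <- likelihood_spec("fixed", sigma = 1e6)  # noise floor drowns the data
  ens <- sample_posterior("mass_action", d, prior, spec,
                          n_walkers = 10, n_steps = 1000, seed = 5)
  u <- (ens$log10_samples[, 1] - log10(1e-3)) / (log10(1e2) - log10(1e-3))
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  expect_true(all(u >= 0 & u <= 1))  # samples never leave the prior box
})

test_that("the sampler agrees with dense quadrature on one parameter", {
  d <- one_site_data()
  prior <- prior_spec(1e-3, 1e2)
  spec <- likelihood_spec("fixed", sigma = 0.02)
  net <- transition_network("K16")
  grid <- seq(log10(1e-3), log10(1e2), length.out = 4001)
  lp <- vapply(grid, function(g) {
    m <- kinetic_model("mass_action", net, c(K16 = 10^g), mode = "site")
    -as.numeric(negative_log_likelihood(m, d, spec))
  }, numeric(1))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  mean_q <- sum(w * grid)
  sd_q <- sqrt(sum(w * (grid - mean_q)^2))

  ens <- sample_posterior("mass_action", d, prior, spec,
                          n_walkers = 10, n_steps = 800, seed = 9,
                          theta0 = c(kcat.K16 = 0.08))
  x <- ens$log10_samples[, 1]
  expect_lt(abs(mean(x) - mean_q), 4 * sd_q / sqrt(100))  # ~effective draws
  expect_lt(abs(stats::sd(x) / sd_q - 1), 0.25)
  expect_true(ens$acceptance_rate > 0.1 && ens$acceptance_rate < 0.9)

  # determinism: identical seed, identical sample stream
  ens2 <- sample_posterior("mass_action", d, prior, spec,
                           n_walkers = 10, n_steps = 800, seed = 9,
                           theta0 = c(kcat.K16 = 0.08))
  expect_identical(ens$samples, ens2$samples)
})

test_that("credibility intervals follow the central-quantile convention", {
  fake <- structure(
    list(samples = matrix(1:1000, ncol = 1,
                          dimnames = list(NULL, "kcat.K16")),
         credibility_level = 0.99),
    class = "posterior_ensemble")
  ci <- credibility_intervals(fake, 0.99)
  expect_equal(ci$lower, unname(stats::quantile(1:1000, 0.005)))
  expect_equal(ci$upper, unname(stats::quantile(1:1000, 0.995)))
  tiny <- credibility_intervals(fake, 1e-9)
  expect_equal(tiny$lower, tiny$median, tolerance = 1e-5)  # collapses to median
})

test_that("ensemble prediction bands are order-consistent and collapse for one draw", {
  d <- one_site_data()
  spec <- likelihood_spec("fixed", sigma = 0.02)
  ens <- sample_posterior("mass_action", d, prior_spec(1e-3, 1e2), spec,
                          n_walkers = 10, n_steps = 60, seed = 13,
                          theta0 = c(kcat.K16 = 0.08))
  band <- ensemble_predict(ens, times = c(0, 10, 30), max_draws = 40)
  expect_true(all(band$lower <= band$median + 1e-12))
  expect_true(all(band$median <= band$upper + 1e-12))
  expect_true(all(band$lower >= 0 & band$upper <= 1 + 1e-9))

  ens1 <- ens
  ens1$samples <- ens$samples[1, , drop = FALSE]
  b1 <- ensemble_predict(ens1, times = c(0, 10, 30))
  m <- kinetic_model("mass_action", transition_network("K16"),
                     c(K16 = unname(ens$samples[1, 1])), mode = "site")
  tr <- simulate_model(m, c(0, 10, 30))
  expect_equal(b1$median, as.vector(tr$y), tolerance = 1e-10)
  expect_equal(b1$lower, b1$upper, tolerance = 1e-12)
})

test_that("the K16-disabled prediction conserves total H4 on the restricted space", {
  b <- generate_dataset(preset_library()$wildtype)
  spec <- likelihood_spec("fixed", sigma = 0.01)
  f <- fit_model("processive", b$dataset, spec, n_starts = 1, seed = 3,
                 theta0 = c(kcat.K5 = 0.015, kcat.K8 = 0.03, kcat.K12 = 0.22,
                            kcat.K16 = 8, kon = 10, koff = 1))
  ens <- sample_posterior("processive", b$dataset, prior_spec(), spec,
                          n_steps = 40, seed = 17, theta0 = f$theta_hat)
  band <- ensemble_predict(ens, times = c(0, 30, 60), disable = "K16",
                           max_draws = 20)
  expect_equal(sort(unique(band$motif_label)),
               sort(enumerate_motifs(c("K5", "K8", "K12"))$label))
  med_sum <- tapply(band$median, band$time_min, sum)
  expect_true(all(abs(med_sum - 1) < 0.05))  # quantiles are not additive, so loose
})

test_that("site-preference profiles normalize per motif and flag ties", {
  net <- net2
  en <- paste0("kcat.", edge_names(net))
  # concentrated ensemble: unmod->K16 dominant
  base <- c(0.05, 1.0, 0.2, 0.3)  # unmod->K12, unmod->K16, K12ac->K16, K16ac->K12
  samp <- matrix(rep(base, each = 50), nrow = 50)
  colnames(samp) <- en
  ens <- structure(list(samples = samp, mode = "edge", sites = c("K12", "K16"),
                        par_names = colnames(samp)),
                   class = "posterior_ensemble")
  prof <- site_preference_profile(ens)
  un <- prof[prof$motif_label == "unmod", ]
  expect_equal(un$rel_probability[un$site == "K16"], 1)
  expect_equal(un$rel_probability[un$site == "K12"], 0.05)
  expect_true(un$preferred[un$site == "K16"])
  # global rescaling leaves the profile unchanged
  ens_scaled <- ens; ens_scaled$samples <- ens$samples * 37
  expect_equal(site_preference_profile(ens_scaled)$rel_probability,
               prof$rel_probability)
  # exact ties are flagged
  ens_tie <- ens; ens_tie$samples[, 1] <- ens_tie$samples[, 2]
  prof_tie <- site_preference_profile(ens_tie)
  expect_true(all(prof_tie$tied[prof_tie$motif_label == "unmod"]))

  ens_site <- ens; ens_site$mode <- "site"
  expect_error(site_preference_profile(ens_site), "per-edge")
})
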