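test_that("single-site mass action follows first-order decay", {
  m <- kinetic_model("mass_action", net1, c(K16 = 0.1), mode = "site")
  times <- c(0, 5, 15, 30, 60)
  tr <- simulate_model(m, times)
  expect_equal(tr$y["unmod", ], stats::setNames(exp(-0.1 * times), times),
               tolerance = 1e-7)
  expect_equal(colSums(tr$y), stats::setNames(rep(1, 5), times),
               tolerance = 1e-8)
})

test_that("zero rates freeze every family at its initial state", {
  zero2 <- c(K12 = 0, K16 = 0)
  models <- list(
    kinetic_model("mass_action", net2, zero2, mode = "site"),
    kinetic_model("michaelis_menten", net2, zero2, mode = "site", Km = 1),
    kinetic_model("processive", net2, zero2, mode = "site", kon = 0, koff = 0)
  )
  for (m in models) {
    expect_true(all(abs(unlist(
      if (m$family == "mass_action") rhs_mass_action(initial_state(m), m)
      else if (m$family == "michaelis_menten")
        rhs_michaelis_menten(initial_state(m), m)
      else rhs_processive(initial_state(m), m))) == 0))
    tr <- simulate_model(m, c(0, 30, 60))
    expect_true(all(tr$y["unmod", ] == 1))
  }
})

test_that("mass-action trajectories match the matrix-exponential oracle", {
  times <- c(0, 5, 15, 30, 60)
  set.seed(42)
  for (i in 1:5) {
    m <- kinetic_model("mass_action", net4, random_site_kcat(), mode = "site")
    expect_lt(max(abs(simulate_model(m, times)$y - expm_trajectory(m, times))),
              1e-6)
  }
})

test_that("Michaelis-Menten flux matches direct substitution at the start", {
  m <- kinetic_model("michaelis_menten", net1, c(K16 = 2), mode = "site",
                     Km = 0.5, E_tot = 0.25)
  d <- rhs_michaelis_menten(initial_state(m), m)
  expect_equal(d[[1]], -2 * 0.25 * 1 / (0.5 + 1))  # outflow from unmod
  m0 <- kinetic_model("michaelis_menten", net1, c(K16 = 2), mode = "site",
                      Km = 0.5, E_tot = 1e-300)
  expect_equal(max(abs(rhs_michaelis_menten(initial_state(m0), m0))), 0,
               tolerance = 1e-290)
  expect_error(kinetic_model("michaelis_menten", net1, c(K16 = 2),
                             mode = "site", Km = -1), "Km")
})

test_that("processive binding equilibrium satisfies detailed balance", {
  # no catalysis, no hand-off: a single reversible binding reaction, so at
  # steady state C_tot / (E * S_tot) = kon / koff
  m <- kinetic_model("processive", net2, c(K12 = 0, K16 = 0), mode = "site",
                     kon = 5, koff = 2, E_tot = 0.25)
  tr <- simulate_model(m, c(0, 200, 400))
  n <- nrow(m$net$motifs)
  S_tot <- sum(tr$state[seq_len(n), 3])
  C_tot <- sum(tr$state[n + seq_len(n), 3])
  E <- tr$state[2 * n + 1, 3]
  expect_equal(C_tot / (E * S_tot), 5 / 2, tolerance = 1e-6)
})

test_that("the processive analytic Jacobian matches finite differences", {
  set.seed(3)
  m <- kinetic_model("processive", net2, c(K12 = 0.3, K16 = 1.2),
                     mode = "site", kon = 8, koff = 2, k_transfer = 0.7,
                     E_tot = 0.25)
  n <- nrow(m$net$motifs)
  y <- abs(stats::rnorm(2 * n + 1, 0.1, 0.05))
  f0 <- rhs_processive(y, m)
  eps <- 1e-7
  J_num <- sapply(seq_along(y), function(j) {
    yp <- y; yp[j] <- yp[j] + eps
    (rhs_processive(yp, m) - f0) / eps
  })
  # rebuild the analytic Jacobian the solver uses
  tr <- simulate_model(m, c(0, 1))  # touches the jac path
  Acat <- h4zip:::edge_generator(m$net, h4zip:::edge_rates(m))
  S <- y[seq_len(n)]; C <- y[n + seq_len(n)]; E <- y[2 * n + 1]
  I <- diag(n); ones <- rep(1, n)
  kon <- m$kon; koff <- m$koff; kt <- m$k_transfer
  J <- rbind(
    cbind((-kon * E - kt * sum(C)) * I + kt * outer(C, ones),
          (koff + kt * sum(S)) * I - kt * outer(S, ones), -kon * S),
    cbind((kon * E + kt * sum(C)) * I - kt * outer(C, ones),
          -koff * I + Acat - kt * sum(S) * I + kt * outer(S, ones), kon * S),
    c(rep(-kon * E, n), rep(koff, n), -kon * sum(S)))
  expect_lt(max(abs(J - J_num)), 1e-5)
})

test_that("mass and enzyme are conserved and tetra-ac is monotone", {
  set.seed(11)
  times <- c(0, 15, 45, 90, 180)
  for (i in 1:3) {
    m <- kinetic_model("processive", net4, random_site_kcat(),
                       mode = "site", kon = 10^stats::runif(1, -1, 2),
                       koff = 10^stats::runif(1, -1, 2),
                       k_transfer = 10^stats::runif(1, -2, 1), E_tot = 0.25)
    tr <- simulate_model(m, times)
    n <- 16L
    tot <- colSums(tr$state[seq_len(2 * n), , drop = FALSE])
    enz <- tr$state[2 * n + 1, ] + colSums(tr$state[n + seq_len(n), ])
    expect_lt(max(abs(tot - 1)), 1e-8)
    expect_lt(max(abs(enz - 0.25)), 1e-8)
    expect_true(all(tr$state >= -1e-10))
    expect_true(all(diff(tr$y["K5acK8acK12acK16ac", ]) >= -1e-10))
  }
})

test_that("disable_site restricts the model and preserves parameters", {
  # edge mode: 32 kcat wild-type -> 12 after disabling K16
  kc <- stats::setNames(seq_len(32) / 10, edge_names(net4))
  m <- kinetic_model("processive", net4, kc, mode = "edge",
                     kon = 5, koff = 1, E_tot = 0.25)
  m16 <- disable_site(m, "K16")
  expect_equal(length(m16$kcat), 12L)
  expect_equal(nrow(m16$net$motifs), 8L)
  # surviving edges keep their values and globals are unchanged
  expect_equal(unname(m16$kcat["unmod->K5"]), unname(kc["unmod->K5"]))
  expect_equal(m16$kon, 5)
  expect_error(disable_site(m16, "K16"), "not in the model")

  mz <- kinetic_model("mass_action", net4,
                      stats::setNames(rep(0, 4), h4_sites()), mode = "site")
  trz <- simulate_model(disable_site(mz, "K16"), c(0, 30, 60))
  expect_true(all(trz$y["unmod", ] == 1))
})

test_that("simulate_model validates its time grid", {
  m <- kinetic_model("mass_action", net1, c(K16 = 0.1), mode = "site")
  expect_error(simulate_model(m, c(5, 10)), "start at 0")
  expect_error(simulate_model(m, c(0, 10, 10)), "increasing")
})
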