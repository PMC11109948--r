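#' Bounded uniform prior specification
#'
#' Uniform priors on the log10 scale within finite positive natural-scale
#' bounds, one interval per parameter.
#'
#' @param lower,upper scalar or named vectors of natural-scale bounds.
#' @export
prior_spec <- function(lower = 1e-5, upper = 1e3) {
  if (any(lower <= 0) || any(!is.finite(upper)) || any(upper <= lower))
    stop("prior bounds must be finite, positive, lower < upper", call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "prior_spec")
}

#' Sample the Bayesian posterior of a model family
#'
#' Markov chain Monte Carlo targeting `posterior ~ likelihood x uniform
#' prior` on log10-scale parameters, using an affine-invariant ensemble
#' (stretch-move) sampler: a population of walkers proposes moves along the
#' line through a randomly chosen companion walker, with the scaled step
#' `z ~ g(z) propto 1/sqrt(z)` on `[1/a, a]`. The first half of the chain is
#' discarded as burn-in. The run is deterministic given `seed`.
#'
#' Convergence is reported via the split-chain potential scale reduction
#' factor (computed per parameter over the post-burn-in walker chains, each
#' split in half); values above 1.05 set `converged = FALSE` as a warning
#' flag on the ensemble, not a hard error.
#'
#' @param family model family name.
#' @param data a [tc_dataset()].
#' @param prior a [prior_spec()].
#' @param spec a [likelihood_spec()] (the noise model of the likelihood).
#' @param mode kcat parameterization (`"site"` or `"edge"`).
#' @param E_tot total enzyme (fixed).
#' @param k_transfer_free,k_transfer_fixed as in [fit_model()].
#' @param n_walkers number of walkers (at least `2 * n_params + 2`;
#'   default chooses that minimum, rounded up to even).
#' @param n_steps ensemble steps including burn-in.
#' @param seed RNG seed.
#' @param theta0 optional natural-scale center for the initial walker cloud
#'   (e.g. an MLE); otherwise walkers start uniform in the prior.
#' @param a stretch parameter (default 2).
#' @return object of class `"posterior_ensemble"`: `samples` (matrix, one
#'   row per retained draw, columns named by parameter, natural scale),
#'   `log10_samples`, `acceptance_rate`, `rhat`, `converged`, `seed`,
#'   `credibility_level` (default 0.99), plus the model bookkeeping needed
#'   to re-simulate samples.
#' @export
sample_posterior <- function(family, data, prior = prior_spec(),
                             spec = likelihood_spec(), mode = "site",
                             E_tot = 0.25, k_transfer_free = FALSE,
                             k_transfer_fixed = 0,
                             n_walkers = NULL, n_steps = 400, seed = 1,
                             theta0 = NULL, a = 2) {
  net <- transition_network(data$sites)
  par_names <- model_param_template(family, net, mode, E_tot, k_transfer_free)
  d <- length(par_names)
  lower <- log10(expand_bounds(prior$lower, par_names))
  upper <- log10(expand_bounds(prior$upper, par_names))
  if (is.null(n_walkers)) n_walkers <- max(2 * d + 2, 10)
  if (n_walkers %% 2 == 1) n_walkers <- n_walkers + 1
  if (n_walkers < 4) stop("need at least 4 walkers", call. = FALSE)
  stopifnot(n_steps >= 2)

  log_post <- function(lp) {
    if (any(lp < lower) || any(lp > upper)) return(-Inf)
    theta <- stats::setNames(10^lp, par_names)
    m <- tryCatch(model_from_theta(theta, family, net, mode, E_tot,
                                   k_transfer_fixed),
                  error = function(e) NULL)
    if (is.null(m)) return(-Inf)
    nll <- suppressWarnings(negative_log_likelihood(m, data, spec))
    if (!is.finite(nll) || nll >= 1e10) return(-Inf)
    -as.numeric(nll)
  }

  set.seed(seed)
  # initial cloud: uniform in the prior, or a tight ball around theta0
  X <- matrix(stats::runif(n_walkers * d, min = rep(lower, each = n_walkers),
                           max = rep(upper, each = n_walkers)),
              nrow = n_walkers)
  if (!is.null(theta0)) {
    if (!all(par_names %in% names(theta0)))
      stop("theta0 must be named by the model's parameters: ",
           paste(par_names, collapse = ", "), call. = FALSE)
    ctr <- pmin(pmax(log10(theta0[par_names]), lower), upper)
    X <- matrix(rep(ctr, each = n_walkers), nrow = n_walkers) +
      matrix(stats::rnorm(n_walkers * d, sd = 0.01), nrow = n_walkers)
    X <- pmin(pmax(X, matrix(rep(lower, each = n_walkers), nrow = n_walkers)),
              matrix(rep(upper, each = n_walkers), nrow = n_walkers))
  }
  lpX <- apply(X, 1, log_post)
  # re-draw any walker starting at -Inf (up to a few tries)
  for (tries in 1:20) {
    bad <- !is.finite(lpX)
    if (!any(bad)) break
    X[bad, ] <- matrix(stats::runif(sum(bad) * d,
                                    min = rep(lower, each = sum(bad)),
                                    max = rep(upper, each = sum(bad))),
                       nrow = sum(bad))
    lpX[bad] <- apply(X[bad, , drop = FALSE], 1, log_post)
  }
  if (any(!is.finite(lpX)))
    stop("could not initialize all walkers at finite posterior density",
         call. = FALSE)

  half <- n_walkers / 2
  chain <- array(NA_real_, dim = c(n_steps, n_walkers, d))
  n_acc <- 0L
  for (step in seq_len(n_steps)) {
    for (block in 1:2) {
      idx <- if (block == 1) seq_len(half) else half + seq_len(half)
      other <- if (block == 1) half + seq_len(half) else seq_len(half)
      for (i in idx) {
        j <- other[sample.int(half, 1)]
        z <- (stats::runif(1) * (sqrt(a) - 1 / sqrt(a)) + 1 / sqrt(a))^2
        prop <- X[j, ] + z * (X[i, ] - X[j, ])
        lp_prop <- log_post(prop)
        log_ratio <- (d - 1) * log(z) + lp_prop - lpX[i]
        if (is.finite(lp_prop) && log(stats::runif(1)) < log_ratio) {
          X[i, ] <- prop
          lpX[i] <- lp_prop
          n_acc <- n_acc + 1L
        }
      }
    }
    chain[step, , ] <- X
  }

  burn <- floor(n_steps / 2)
  kept <- chain[(burn + 1):n_steps, , , drop = FALSE]
  rhat <- vapply(seq_len(d), function(p) split_rhat(kept[, , p]), numeric(1))
  flat <- matrix(aperm(kept, c(1, 2, 3)), ncol = d)
  colnames(flat) <- par_names
  structure(
    list(samples = 10^flat, log10_samples = flat,
         par_names = par_names, family = family, mode = mode,
         sites = data$sites, E_tot = E_tot,
         k_transfer_free = k_transfer_free,
         k_transfer_fixed = k_transfer_fixed,
         acceptance_rate = n_acc / (n_steps * n_walkers),
         rhat = stats::setNames(rhat, par_names),
         converged = all(rhat < 1.05),
         n_walkers = n_walkers, n_steps = n_steps, burn_in = burn,
         seed = seed, credibility_level = 0.99),
    class = "posterior_ensemble"
  )
}

# split-chain potential scale reduction over a (steps x walkers) matrix
split_rhat <- function(x) {
  ns <- nrow(x)
  if (ns < 4) return(NA_real_)
  h <- floor(ns / 2)
  chains <- cbind(x[seq_len(h), , drop = FALSE],
                  x[(ns - h + 1):ns, , drop = FALSE])
  m <- ncol(chains); n <- nrow(chains)
  mu <- colMeans(chains)
  B <- n * stats::var(mu)
  W <- mean(apply(chains, 2, stats::var))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.posterior_ensemble <- function(x, ...) {
  cat("Posterior ensemble [", x$family, "/", x$mode, "]: ",
      nrow(x$samples), " draws, ", x$n_walkers, " walkers x ", x$n_steps,
      " steps, acceptance ", round(x$acceptance_rate, 3),
      ", max split-Rhat ", round(max(x$rhat), 3),
      if (!x$converged) " (NOT converged)" else "", "\n", sep = "")
  invisible(x)
}

#' Central credibility intervals of a posterior ensemble
#'
#' Per-parameter central quantile intervals at the given level, i.e. the
#' `(1-level)/2` and `1-(1-level)/2` quantiles (linear interpolation of
#' order statistics, R quantile type 7 — stated because 99% bands on small
#' ensembles are convention-sensitive).
#'
#' @param ens a [sample_posterior()] result.
#' @param level credibility level in (0, 1); default the ensemble's level
#'   (0.99).
#' @return data.frame `parameter`, `lower`, `median`, `upper` (natural
#'   scale).
#' @export
credibility_intervals <- function(ens, level = ens$credibility_level) {
  stopifnot(inherits(ens, "posterior_ensemble"), level > 0, level < 1)
  p <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  q <- t(apply(ens$samples, 2, stats::quantile, probs = p, names = FALSE))
  data.frame(parameter = colnames(ens$samples),
             lower = q[, 1], median = q[, 2], upper = q[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

# rebuild a kinetic model from one posterior draw, applying any scenario
# surgery (disabled sites)
model_from_draw <- function(ens, theta, disable = NULL) {
  net <- transition_network(ens$sites)
  m <- model_from_theta(stats::setNames(theta, ens$par_names), ens$family,
                        net, ens$mode, ens$E_tot, ens$k_transfer_fixed)
  for (s in disable) m <- disable_site(m, s)
  m
}

#' Ensemble prediction bands
#'
#' Simulates every retained posterior draw (optionally thinned) under a
#' scenario and summarizes observed motif abundances by per-(motif, time)
#' central quantiles at the ensemble's credibility level. A scenario may
#' disable sites (`disable = "K16"` gives the K16R counterfactual on the
#' restricted motif space) and set the simulation grid. Draws whose
#' integration fails are dropped with a count; more than 10% failures is an
#' error.
#'
#' @param ens a [sample_posterior()] result.
#' @param times simulation grid (minutes, starting at 0).
#' @param disable character vector of sites to disable (default none).
#' @param level credibility level (default the ensemble's, 0.99).
#' @param max_draws cap on the number of draws simulated (evenly thinned);
#'   default 200.
#' @return data.frame of class `"prediction_band"`: `motif_label`,
#'   `time_min`, `lower`, `median`, `upper`; attribute `n_failed`.
#' @export
ensemble_predict <- function(ens, times = c(0, 5, 15, 30, 60), disable = NULL,
                             level = ens$credibility_level, max_draws = 200) {
  stopifnot(inherits(ens, "posterior_ensemble"))
  n <- nrow(ens$samples)
  take <- if (n > max_draws) round(seq(1, n, length.out = max_draws)) else seq_len(n)
  sims <- lapply(take, function(i) {
    m <- model_from_draw(ens, ens$samples[i, ], disable)
    tryCatch(simulate_model(m, times = times)$y, error = function(e) NULL)
  })
  failed <- vapply(sims, is.null, logical(1))
  if (mean(failed) > 0.1)
    stop("more than 10% of ensemble simulations failed (",
         sum(failed), "/", length(sims), ")", call. = FALSE)
  sims <- sims[!failed]
  arr <- simplify2array(sims)  # motif x time x draw
  p <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  qs <- apply(arr, c(1, 2), stats::quantile, probs = p, names = FALSE)
  labels <- rownames(sims[[1]])
  out <- expand.grid(motif_label = labels, time_min = times,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$lower <- as.vector(qs[1, , ])
  out$median <- as.vector(qs[2, , ])
  out$upper <- as.vector(qs[3, , ])
  attr(out, "n_failed") <- sum(failed)
  attr(out, "level") <- level
  class(out) <- c("prediction_band", class(out))
  out
}

#' Per-motif site-preference profile (relative acetylation probabilities)
#'
#' For an edge-parameterized ensemble, the posterior-median catalytic
#' constant of every lattice edge, normalized within each source motif by
#' that motif's maximum median. A value of 1 marks the preferred site of a
#' motif (ties broken toward the N-terminal-most site and flagged); the
#' profile is invariant under global rescaling of all rate samples. This is
#' the arrow-thickness representation of the acetylation flux map.
#'
#' @param ens a [sample_posterior()] result with `mode = "edge"`.
#' @return data.frame: `motif_label` (source), `site`, `median_kcat`,
#'   `rel_probability`, `preferred`, `tied`.
#' @export
site_preference_profile <- function(ens) {
  stopifnot(inherits(ens, "posterior_ensemble"))
  if (ens$mode != "edge")
    stop("site-preference profile requires the per-edge parameterization",
         call. = FALSE)
  net <- transition_network(ens$sites)
  en <- paste0("kcat.", edge_names(net))
  med <- apply(ens$samples[, en, drop = FALSE], 2, stats::median)
  src <- net$motifs$label[net$edges$from]
  out <- data.frame(motif_label = src, site = net$edges$site,
                    median_kcat = unname(med), stringsAsFactors = FALSE)
  out$rel_probability <- NA_real_
  out$preferred <- FALSE
  out$tied <- FALSE
  for (m in unique(src)) {
    i <- which(out$motif_label == m)
    mx <- max(out$median_kcat[i])
    out$rel_probability[i] <- out$median_kcat[i] / mx
    top <- i[out$median_kcat[i] == mx]
    out$preferred[top[1]] <- TRUE       # tie-break: first edge in site order
    if (length(top) > 1) out$tied[i] <- TRUE
  }
  out
}
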