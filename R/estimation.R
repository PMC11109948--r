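#' Time-course dataset of relative motif abundances
#'
#' Wraps a long table of replicate motif measurements into the fitting
#' container. Observations carrying `mask = TRUE` (below the detection
#' limit) are omitted from likelihoods by default.
#'
#' @param df data.frame with columns `motif_label`, `time_min`, `replicate`,
#'   `y` and optionally `mask`.
#' @param sites site labels of the motif space the data live on.
#' @return object of class `"tc_dataset"`.
#' @export
tc_dataset <- function(df, sites = h4_sites()) {
  req <- c("motif_label", "time_min", "replicate", "y")
  if (!all(req %in% names(df)))
    stop("dataset needs columns ", paste(req, collapse = ", "), call. = FALSE)
  if (any(df$y < -1e-12 | df$y > 1 + 1e-12))
    stop("relative abundances must lie in [0, 1]", call. = FALSE)
  if (!"mask" %in% names(df)) df$mask <- FALSE
  motifs <- enumerate_motifs(sites)
  if (!all(df$motif_label %in% motifs$label))
    stop("dataset contains motif labels outside the given site space",
         call. = FALSE)
  structure(list(df = df, sites = sites,
                 times = sort(unique(df$time_min)),
                 replicates = unique(df$replicate)),
            class = "tc_dataset")
}

#' @export
print.tc_dataset <- function(x, ...) {
  cat("Time-course dataset:", nrow(x$df), "observations,",
      length(x$times), "time points,", length(x$replicates), "replicates on",
      length(x$sites), "sites\n")
  invisible(x)
}

#' Likelihood specification
#'
#' Additive Gaussian noise on relative abundances. `sigma_mode = "fixed"`
#' uses the supplied `sigma`; `"estimated"` profiles a single shared sigma
#' analytically at its conditional MLE (`sigma^2 = RSS / N`), which counts as
#' one extra parameter in the AIC. Parameters are optimized on the log10
#' scale within finite positive bounds.
#'
#' @param sigma_mode `"fixed"` or `"estimated"`.
#' @param sigma noise s.d. (used when fixed; also the fallback reporting
#'   value).
#' @param lower,upper named or scalar parameter bounds on the natural scale.
#'   Defaults span 1e-5 to 1e3, the plausible per-minute range for a
#'   0-180 min experiment.
#' @param rtol,atol ODE solver tolerances used inside the likelihood. The
#'   defaults (1e-6 / 1e-9) are looser than the reporting-grade simulation
#'   defaults because the Gaussian noise floor (sigma around 0.01) makes
#'   tighter integration irrelevant to the objective.
#' @export
likelihood_spec <- function(sigma_mode = c("fixed", "estimated"), sigma = 0.01,
                            lower = 1e-5, upper = 1e3,
                            rtol = 1e-6, atol = 1e-9) {
  sigma_mode <- match.arg(sigma_mode)
  if (any(lower <= 0) || any(!is.finite(upper)))
    stop("bounds must be finite and positive on the natural scale",
         call. = FALSE)
  structure(list(sigma_mode = sigma_mode, sigma = sigma,
                 lower = lower, upper = upper, rtol = rtol, atol = atol),
            class = "likelihood_spec")
}

# observed matrix aligned to a model's motif order; list(y_obs, keep) with one
# column per (time, replicate) cell
align_observations <- function(model, data) {
  labels <- model$net$motifs$label
  df <- data$df
  idx <- match(df$motif_label, labels)
  if (anyNA(idx))
    stop("dataset motifs do not match the model's network", call. = FALSE)
  list(motif_idx = idx,
       time_idx = match(df$time_min, data$times),
       y = df$y, keep = !df$mask)
}

#' Negative log-likelihood of a model given time-course data
#'
#' Gaussian NLL over all unmasked (motif, time, replicate) observations:
#' `sum((y_obs - y_sim)^2 / (2 sigma^2) + log(sigma) + log(2 pi)/2)`. The
#' simulated observation maps motifs directly onto measured motifs (`y = S +
#' C`). Integration failures return a large-but-finite penalty (1e10) with a
#' warning so multi-start optimizers survive pathological parameter regions.
#'
#' @param model a [kinetic_model()] with its parameters set.
#' @param data a [tc_dataset()].
#' @param spec a [likelihood_spec()].
#' @param times_sim simulation grid (defaults to the data's time points).
#' @return scalar NLL; attribute `"sigma_hat"` carries the profiled sigma
#'   when `sigma_mode = "estimated"`.
#' @export
negative_log_likelihood <- function(model, data, spec = likelihood_spec(),
                                    times_sim = NULL) {
  obs <- align_observations(model, data)
  if (is.null(times_sim)) times_sim <- sort(unique(c(0, data$times)))
  tr <- tryCatch(simulate_model(model, times = times_sim,
                                rtol = spec$rtol %||% 1e-8,
                                atol = spec$atol %||% 1e-10),
                 error = function(e) e)
  if (inherits(tr, "error")) {
    warning("integration failure penalized in likelihood: ",
            conditionMessage(tr), call. = FALSE)
    return(1e10)
  }
  y_sim <- tr$y[cbind(obs$motif_idx, match(data$df$time_min, times_sim))]
  r <- (obs$y - y_sim)[obs$keep]
  N <- length(r)
  if (spec$sigma_mode == "fixed") {
    s <- spec$sigma
    nll <- sum(r^2) / (2 * s^2) + N * log(s) + N * log(2 * pi) / 2
    attr(nll, "sigma_hat") <- s
  } else {
    s2 <- max(sum(r^2) / N, 1e-30)
    nll <- N / 2 * (log(2 * pi) + log(s2) + 1)
    attr(nll, "sigma_hat") <- sqrt(s2)
  }
  nll
}

# free-parameter template of a family: names, defaults and which entries are
# kcat-like. theta is always on the natural scale here.
model_param_template <- function(family, net, mode = "site",
                                 E_tot = 0.25, k_transfer_free = FALSE) {
  kn <- if (mode == "site") net$sites else edge_names(net)
  nm <- paste0("kcat.", kn)
  if (family == "michaelis_menten") nm <- c(nm, "Km")
  if (family == "processive") {
    nm <- c(nm, "kon", "koff")
    if (k_transfer_free) nm <- c(nm, "k_transfer")
  }
  nm
}

# build a model from a natural-scale named theta
model_from_theta <- function(theta, family, net, mode = "site",
                             E_tot = 0.25, k_transfer = 0) {
  kc <- theta[startsWith(names(theta), "kcat.")]
  names(kc) <- sub("^kcat\\.", "", names(kc))
  kinetic_model(family, net, kc, mode = mode,
                Km = unname(theta["Km"]),
                kon = unname(theta["kon"]), koff = unname(theta["koff"]),
                k_transfer = if ("k_transfer" %in% names(theta))
                  unname(theta["k_transfer"]) else k_transfer,
                E_tot = E_tot)
}

expand_bounds <- function(bound, par_names) {
  if (length(bound) == 1L) stats::setNames(rep(bound, length(par_names)), par_names)
  else {
    if (!all(par_names %in% names(bound)))
      stop("named bounds must cover all parameters", call. = FALSE)
    bound[par_names]
  }
}

#' Fit a model family to time-course data by multi-start maximum likelihood
#'
#' Bounded local optimization (L-BFGS-B) of the Gaussian NLL on
#' log10-transformed parameters, from `n_starts` starting points drawn
#' uniformly (on the log10 scale) within the bounds by a seeded RNG. The best
#' converged optimum is returned; the result is deterministic given
#' `(data, spec, n_starts, seed)`.
#'
#' @param family model family name.
#' @param data a [tc_dataset()].
#' @param spec a [likelihood_spec()].
#' @param mode kcat parameterization, `"site"` (reduced) or `"edge"` (full).
#' @param E_tot total enzyme (fixed, not fitted).
#' @param k_transfer_free if `TRUE` the processive hand-off rate is a free
#'   parameter (the spatial variant); otherwise it is fixed at
#'   `k_transfer_fixed`.
#' @param k_transfer_fixed fixed hand-off rate when not free (default 0).
#' @param n_starts number of optimization starts (>= 1).
#' @param seed integer seed for the start draws.
#' @param theta0 optional named start vector (natural scale) used as the
#'   first start.
#' @return object of class `"fit_result"`: `theta_hat` (natural scale),
#'   `logL`, `n_params` (free kinetic parameters + 1 if sigma is estimated),
#'   `aic`, `sigma_hat`, `n_starts`, `n_converged`, `seed`, `family`,
#'   per-start diagnostics.
#' @export
fit_model <- function(family, data, spec = likelihood_spec(), mode = "site",
                      E_tot = 0.25, k_transfer_free = FALSE,
                      k_transfer_fixed = 0,
                      n_starts = 10, seed = 1, theta0 = NULL) {
  stopifnot(n_starts >= 1)
  net <- transition_network(data$sites)
  par_names <- model_param_template(family, net, mode, E_tot, k_transfer_free)
  lower <- log10(expand_bounds(spec$lower, par_names))
  upper <- log10(expand_bounds(spec$upper, par_names))

  objective <- function(lp) {
    theta <- stats::setNames(10^lp, par_names)
    m <- tryCatch(model_from_theta(theta, family, net, mode, E_tot,
                                   k_transfer_fixed),
                  error = function(e) NULL)
    if (is.null(m)) return(1e10)
    as.numeric(suppressWarnings(negative_log_likelihood(m, data, spec)))
  }

  set.seed(seed)
  # one RNG block per start, so the starts for n_starts = k are a prefix of
  # those for k + 1 and best-of-starts is monotone in n_starts
  starts <- do.call(rbind, lapply(seq_len(n_starts),
                                  function(i) stats::runif(length(par_names))))
  starts <- sweep(sweep(starts, 2, upper - lower, "*"), 2, lower, "+")
  # the first start is deterministic: user-supplied theta0 when given,
  # otherwise the midpoint of the log10 bounds (a well-behaved basin for
  # rate-like parameters); random starts fill the rest
  if (!is.null(theta0)) {
    if (!all(par_names %in% names(theta0)))
      stop("theta0 must be named by the model's parameters: ",
           paste(par_names, collapse = ", "), call. = FALSE)
    starts[1, ] <- pmin(pmax(log10(theta0[par_names]), lower), upper)
  } else {
    starts[1, ] <- (lower + upper) / 2
  }

  runs <- lapply(seq_len(n_starts), function(i) {
    res <- tryCatch(
      stats::optim(starts[i, ], objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 300, factr = 1e9)),
      error = function(e) list(value = Inf, convergence = 99L,
                               message = conditionMessage(e)))
    res
  })
  vals <- vapply(runs, function(r) r$value, numeric(1))
  conv <- vapply(runs, function(r) r$convergence %in% c(0L, 1L), logical(1)) &
    is.finite(vals) & vals < 1e9
  if (!any(conv))
    stop("no optimization start converged (", n_starts, " starts); ",
         "min objective = ", format(min(vals)), call. = FALSE)
  best <- which(conv)[which.min(vals[conv])]
  theta_hat <- stats::setNames(10^runs[[best]]$par, par_names)

  m_hat <- model_from_theta(theta_hat, family, net, mode, E_tot,
                            k_transfer_fixed)
  nll <- negative_log_likelihood(m_hat, data, spec)
  n_params <- length(par_names) + (spec$sigma_mode == "estimated")
  logL <- -as.numeric(nll)
  structure(
    list(family = family, mode = mode, theta_hat = theta_hat, logL = logL,
         n_params = n_params, aic = aic(logL, n_params),
         sigma_hat = attr(nll, "sigma_hat"),
         E_tot = E_tot, k_transfer_free = k_transfer_free,
         k_transfer_fixed = k_transfer_fixed,
         n_starts = n_starts, n_converged = sum(conv), seed = seed,
         start_values = vals, sites = data$sites),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit [", x$family, "/", x$mode, "]: logL = ", format(x$logL),
      ", AIC = ", format(x$aic), " (", x$n_params, " params, ",
      x$n_converged, "/", x$n_starts, " starts converged)\n", sep = "")
  invisible(x)
}

#' Akaike Information Criterion
#'
#' `AIC = 2 k - 2 logL`.
#'
#' @param logL maximized log-likelihood.
#' @param n_params number of free parameters.
#' @export
aic <- function(logL, n_params) {
  stopifnot(is.finite(logL), is.finite(n_params))
  2 * n_params - 2 * logL
}

#' Compare fitted model families by delta-AIC
#'
#' Ranks fits by AIC relative to the best; a family with `delta_aic >=
#' threshold` (default 10) is rejected. Ties in the minimum are resolved
#' toward the model with fewer parameters.
#'
#' @param fits list of [fit_model()] results (>= 2).
#' @param threshold rejection threshold on delta-AIC (> 0).
#' @return data.frame of class `"model_comparison"`: `family`, `aic`,
#'   `delta_aic`, `n_params`, `rejected`, sorted by AIC.
#' @export
compare_models <- function(fits, threshold = 10) {
  stopifnot(length(fits) >= 2, threshold > 0)
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  nps <- vapply(fits, function(f) f$n_params, numeric(1))
  fams <- vapply(fits, function(f) f$family, character(1))
  best_aic <- min(aics)
  delta <- aics - best_aic
  ord <- order(aics, nps)  # tie-break toward fewer parameters
  out <- data.frame(family = fams[ord], aic = aics[ord],
                    delta_aic = delta[ord], n_params = nps[ord],
                    rejected = delta[ord] >= threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("model_comparison", class(out))
  out
}
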