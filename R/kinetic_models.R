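#' Kinetic model of combinatorial H4 tail acetylation
#'
#' Constructs one of three competing model families over an acetylation
#' transition network:
#'
#' * `"mass_action"` — acetylation is first-order in the substrate motif
#'   (enzyme in excess, not processive): each lattice edge carries a rate
#'   constant `k` (1/min) with the enzyme concentration folded in.
#' * `"michaelis_menten"` — not processive, enzyme not in excess; all motifs
#'   compete for one enzyme pool at quasi-equilibrium, so the flux on edge
#'   `(m, i)` is `kcat * E_tot * S[m] / (Km + sum(S))`.
#' * `"processive"` — the enzyme, substrate and enzyme–substrate complex are
#'   modelled explicitly: binding `E + S[m] -> C[m]` at rate `kon*E*S[m]`,
#'   release `C[m] -> E + S[m]` at `koff*C[m]`, on-complex catalysis
#'   `C[m] -> C[m + e_i]` at `kcat*C[m]` (the enzyme stays bound between
#'   catalytic events), and an optional within-array hand-off
#'   `C[m] + S[n] -> S[m] + C[n]` at `k_transfer*C[m]*S[n]` (the spatial
#'   variant: moving to a neighbouring nucleosome without passing through the
#'   free-enzyme pool; `k_transfer = 0` disables it).
#'
#' Units: time in minutes; substrate as fraction of total H4 (so total
#' substrate is 1); enzyme in the same fractional units. The acetyl-CoA
#' cofactor is assumed saturating and is not modelled.
#'
#' Catalytic constants come in two parameterizations: `"site"` mode (one kcat
#' per site, shared across motifs — 4 parameters on the wild-type lattice,
#' cheap to fit) and `"edge"` mode (one kcat per lattice edge — 32 parameters
#' wild-type, needed for per-motif site-preference profiles).
#'
#' @param family one of `"mass_action"`, `"michaelis_menten"`, `"processive"`.
#' @param net a [transition_network()].
#' @param kcat named numeric: per-site (site mode) or per-edge (edge mode,
#'   names `"<from label>-><site>"`) catalytic constants, 1/min. For the
#'   mass-action family these are the first-order rates `k`.
#' @param mode `"site"` or `"edge"`.
#' @param Km Michaelis constant (substrate-fraction units; Michaelis-Menten
#'   family only).
#' @param kon,koff binding and dissociation rates (processive family).
#' @param k_transfer within-array hand-off rate (processive family; default 0).
#' @param E_tot total enzyme, fraction-of-H4 units. Default 0.25 reflects the
#'   assay stoichiometry (50 nM complex on 200 nM nucleosomes).
#' @return an object of class `"kinetic_model"`.
#' @export
kinetic_model <- function(family = c("mass_action", "michaelis_menten", "processive"),
                          net, kcat, mode = c("site", "edge"),
                          Km = NULL, kon = NULL, koff = NULL,
                          k_transfer = 0, E_tot = 0.25) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  stopifnot(inherits(net, "motif_network"))
  kcat <- check_kcat(kcat, net, mode)
  if (family == "michaelis_menten") {
    if (is.null(Km) || Km <= 0) stop("Km must be > 0", call. = FALSE)
    if (E_tot <= 0) stop("E_tot must be > 0", call. = FALSE)
  }
  if (family == "processive") {
    if (is.null(kon) || is.null(koff) || kon < 0 || koff < 0)
      stop("kon and koff must be supplied and non-negative", call. = FALSE)
    if (k_transfer < 0) stop("k_transfer must be >= 0", call. = FALSE)
    if (E_tot <= 0) stop("E_tot must be > 0", call. = FALSE)
  }
  structure(
    list(family = family, net = net, kcat = kcat, mode = mode,
         Km = Km, kon = kon, koff = koff, k_transfer = k_transfer,
         E_tot = E_tot),
    class = "kinetic_model"
  )
}

check_kcat <- function(kcat, net, mode) {
  if (any(kcat < 0)) stop("rate constants must be >= 0", call. = FALSE)
  if (mode == "site") {
    if (length(kcat) != length(net$sites))
      stop("site mode needs one kcat per site (", length(net$sites), ")",
           call. = FALSE)
    if (is.null(names(kcat))) names(kcat) <- net$sites
    if (!setequal(names(kcat), net$sites))
      stop("kcat names must match the network sites", call. = FALSE)
    kcat[net$sites]
  } else {
    if (length(kcat) != nrow(net$edges))
      stop("edge mode needs one kcat per edge (", nrow(net$edges), ")",
           call. = FALSE)
    en <- edge_names(net)
    if (is.null(names(kcat))) names(kcat) <- en
    if (!setequal(names(kcat), en))
      stop("kcat names must match the network edges", call. = FALSE)
    kcat[en]
  }
}

#' Canonical edge names of a transition network
#'
#' `"<source motif label>-><site>"`, in the network's edge order.
#' @param net a [transition_network()].
#' @export
edge_names <- function(net) {
  paste0(net$motifs$label[net$edges$from], "->", net$edges$site)
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("Kinetic model [", x$family, "] on ", nrow(x$net$motifs),
      " motifs, kcat mode '", x$mode, "'\n", sep = "")
  invisible(x)
}

# per-edge rate vector (expands site-mode kcat onto edges)
edge_rates <- function(model) {
  if (model$mode == "edge") unname(model$kcat)
  else unname(model$kcat[model$net$edges$site])
}

# linear generator A of the lattice: (A %*% S)[m] = inflow - outflow when each
# edge carries unit flux rate r_e * S[from]
edge_generator <- function(net, rates) {
  n <- nrow(net$motifs)
  A <- matrix(0, n, n)
  for (e in seq_len(nrow(net$edges))) {
    f <- net$edges$from[e]; t <- net$edges$to[e]
    A[t, f] <- A[t, f] + rates[e]
    A[f, f] <- A[f, f] - rates[e]
  }
  A
}

#' Default initial state: all substrate unmodified
#'
#' @param model a [kinetic_model()].
#' @return named state vector: motif substrate fractions `S` (plus bound
#'   complex `C` per motif and free enzyme `E` for the processive family).
#' @export
initial_state <- function(model) {
  n <- nrow(model$net$motifs)
  S <- numeric(n)
  S[model$net$motifs$id[model$net$motifs$bits == 0L]] <- 1
  names(S) <- paste0("S.", model$net$motifs$label)
  if (model$family == "processive") {
    C <- numeric(n); names(C) <- paste0("C.", model$net$motifs$label)
    c(S, C, E = model$E_tot)
  } else S
}

#' Time derivative of the mass-action model
#'
#' `dS[m]/dt = sum inflow k[m',i] S[m'] - sum outflow k[m,i] S[m]`; linear in
#' the state.
#'
#' @param state substrate vector `S` over motifs (canonical order).
#' @param model a mass-action [kinetic_model()].
#' @export
rhs_mass_action <- function(state, model) {
  n <- nrow(model$net$motifs)
  if (length(state) != n)
    stop("state length does not match the network", call. = FALSE)
  A <- edge_generator(model$net, edge_rates(model))
  drop(A %*% state)
}

#' Time derivative of the Michaelis-Menten model
#'
#' Competitive substrates sharing one enzyme pool at quasi-equilibrium: the
#' flux on edge `(m, i)` is `kcat[m,i] * E_tot * S[m] / (Km + sum(S))`.
#'
#' @inheritParams rhs_mass_action
#' @param model a Michaelis-Menten [kinetic_model()].
#' @export
rhs_michaelis_menten <- function(state, model) {
  n <- nrow(model$net$motifs)
  if (length(state) != n)
    stop("state length does not match the network", call. = FALSE)
  if (model$Km <= 0) stop("Km must be > 0", call. = FALSE)
  A <- edge_generator(model$net, edge_rates(model))
  scale <- model$E_tot / (model$Km + sum(state))
  scale * drop(A %*% state)
}

#' Time derivative of the processive model
#'
#' Explicit enzyme kinetics: binding, release, on-complex catalysis along the
#' lattice, and (spatial variant) direct complex-to-substrate hand-off that
#' bypasses the free-enzyme pool.
#'
#' @param state vector `c(S, C, E)` (lengths n, n, 1).
#' @param model a processive [kinetic_model()].
#' @export
rhs_processive <- function(state, model) {
  n <- nrow(model$net$motifs)
  if (length(state) != 2 * n + 1)
    stop("state length does not match the network", call. = FALSE)
  if (any(state < -1e-6))
    stop("negative concentrations in state", call. = FALSE)
  S <- state[seq_len(n)]
  C <- state[n + seq_len(n)]
  E <- state[2 * n + 1]
  Acat <- edge_generator(model$net, edge_rates(model))
  bind <- model$kon * E * S
  release <- model$koff * C
  dC_cat <- drop(Acat %*% C)
  # hand-off C_m + S_n -> S_m + C_n, rate k_transfer*C_m*S_n, summed over pairs
  kt <- model$k_transfer
  dS_tr <- kt * (C * sum(S) - sum(C) * S)
  dS <- -bind + release + dS_tr
  dC <- bind - release + dC_cat - dS_tr
  dE <- -sum(bind) + sum(release)
  c(dS, dC, dE)
}

#' Simulate a kinetic model
#'
#' Stiff-capable numerical integration (lsoda via \pkg{deSolve}) of the
#' selected family's ODEs. The observation is `y = S + C`: mass spectrometry
#' measures every H4 molecule whether or not the enzyme is bound. Tiny
#' negative round-off values are clipped to zero in the observation layer
#' only, never in the solver state.
#'
#' @param model a [kinetic_model()].
#' @param times increasing time grid in minutes, starting at 0.
#' @param init initial state (default [initial_state()]).
#' @param rtol,atol solver tolerances.
#' @return object of class `"trajectory"`: list with `times`, `y` (motif x
#'   time matrix of observed relative abundances, rows named by motif label)
#'   and `state` (full solver output).
#' @export
simulate_model <- function(model, times = c(0, 5, 15, 30, 60), init = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "kinetic_model"))
  if (is.unsorted(times, strictly = TRUE) || times[1] != 0)
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  n <- nrow(model$net$motifs)
  if (is.null(init)) init <- initial_state(model)

  if (model$family == "mass_action") {
    A <- edge_generator(model$net, edge_rates(model))
    deriv <- function(t, y, p) list(drop(A %*% y))
    jac <- function(t, y, p) A
    out <- deSolve::ode(y = init, times = times, func = deriv, parms = NULL,
                        jacfunc = jac, jactype = "fullusr",
                        method = "lsoda", rtol = rtol, atol = atol)
  } else if (model$family == "michaelis_menten") {
    A <- edge_generator(model$net, edge_rates(model))
    Km <- model$Km; E_tot <- model$E_tot
    deriv <- function(t, y, p) list(E_tot / (Km + sum(y)) * drop(A %*% y))
    out <- deSolve::ode(y = init, times = times, func = deriv, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
  } else {
    Acat <- edge_generator(model$net, edge_rates(model))
    kon <- model$kon; koff <- model$koff; kt <- model$k_transfer
    idxS <- seq_len(n); idxC <- n + seq_len(n); idxE <- 2L * n + 1L
    deriv <- function(t, y, p) {
      S <- y[idxS]; C <- y[idxC]; E <- y[idxE]
      bind <- kon * E * S
      release <- koff * C
      dS_tr <- kt * (C * sum(S) - sum(C) * S)
      dS <- -bind + release + dS_tr
      dC <- bind - release + drop(Acat %*% C) - dS_tr
      list(c(dS, dC, -sum(bind) + sum(release)))
    }
    I <- diag(n)
    ones <- rep(1, n)
    jac <- function(t, y, p) {
      S <- y[idxS]; C <- y[idxC]; E <- y[idxE]
      Ssum <- sum(S); Csum <- sum(C)
      # dS_i = -kon E S_i + koff C_i + kt (C_i Ssum - Csum S_i)
      dSdS <- (-kon * E - kt * Csum) * I + kt * outer(C, ones)
      dSdC <- (koff + kt * Ssum) * I - kt * outer(S, ones)
      # dC_i = kon E S_i - koff C_i + (Acat C)_i - kt (C_i Ssum - Csum S_i)
      dCdS <- (kon * E + kt * Csum) * I - kt * outer(C, ones)
      dCdC <- -koff * I + Acat - kt * Ssum * I + kt * outer(S, ones)
      rbind(cbind(dSdS, dSdC, -kon * S),
            cbind(dCdS, dCdC, kon * S),
            c(rep(-kon * E, n), rep(koff, n), -kon * Ssum))
    }
    out <- deSolve::ode(y = init, times = times, func = deriv, parms = NULL,
                        jacfunc = jac, jactype = "fullusr",
                        method = "lsoda", rtol = rtol, atol = atol)
  }
  di <- diagnostics_ok(out, times)
  if (!isTRUE(di))
    stop("ODE integration failed near t = ", di, " min", call. = FALSE)
  sol <- t(unname(out[, -1, drop = FALSE]))  # state x time
  y <- sol[seq_len(n), , drop = FALSE]
  if (model$family == "processive")
    y <- y + sol[n + seq_len(n), , drop = FALSE]
  y <- pmax(y, 0)
  rownames(y) <- model$net$motifs$label
  colnames(y) <- times
  structure(list(times = times, y = y, state = sol, model_family = model$family),
            class = "trajectory")
}

diagnostics_ok <- function(out, times) {
  if (nrow(out) < length(times)) return(out[nrow(out), 1])
  if (anyNA(out)) return(out[which(rowSums(is.na(out)) > 0)[1], 1])
  TRUE
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory [", x$model_family, "]: ", nrow(x$y), " motifs x ",
      length(x$times), " times (", min(x$times), "-", max(x$times),
      " min)\n", sep = "")
  invisible(x)
}

#' Disable all reactions at one site
#'
#' Returns the same model family on the site-restricted network (the
#' counterfactual used for the K16R mutant: every reaction acetylating the
#' site is removed and motifs containing it cease to exist). Rate parameters
#' for the surviving edges/sites keep their values; global parameters (kon,
#' koff, Km, E_tot, k_transfer) are unchanged.
#'
#' @param model a [kinetic_model()].
#' @param site site label to disable.
#' @export
disable_site <- function(model, site) {
  stopifnot(inherits(model, "kinetic_model"))
  if (!site %in% model$net$sites)
    stop("site '", site, "' is not in the model's network", call. = FALSE)
  net2 <- restrict_site(model$net, site)
  kcat2 <- if (model$mode == "site") {
    model$kcat[setdiff(names(model$kcat), site)]
  } else {
    old <- stats::setNames(unname(model$kcat), edge_names(model$net))
    old[edge_names(net2)]
  }
  kinetic_model(model$family, net2, kcat2, mode = model$mode,
                Km = model$Km, kon = model$kon, koff = model$koff,
                k_transfer = model$k_transfer, E_tot = model$E_tot)
}
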