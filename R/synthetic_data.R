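#' Library of synthetic scenario presets
#'
#' Named, versioned presets emulating the statistical structure of the
#' targeted-MS acetylation time-course experiments: 3 replicates, five time
#' points in 0-60 min, relative motif abundances summing to 1, and a 0.003%
#' detection limit. The kinetic parameters are implementation-tuned so that
#' simulated envelopes land where the measured ones do (K16 mono-acetylation
#' around half of all H4 by 5 min; motifs lacking K16ac at or below 1%;
#' K12 mono-acetylation reaching roughly 13% by 60 min on the K16R
#' substrate); they are not fitted values.
#'
#' * `wildtype` — processive family on the 4-site space, K16-dominant kcat.
#' * `k16r` — the 3-site (K16-less) space with reduced efficiency,
#'   emulating the K16R mutant arrays.
#' * `zip_suppressed` — wild-type rates with a much higher dissociation rate
#'   (low processivity), emulating the outcome of the RNA-containing
#'   reactions: oligo-acetylation suppressed in favor of K16 mono-ac.
#' * `k12_preferring` — a K12-dominant enzyme preset (dTIP60-like
#'   selectivity).
#'
#' @return named list of `"scenario_preset"` objects with fields `name`,
#'   `family`, `sites`, `kcat`, `kon`, `koff`, `k_transfer`, `E_tot`,
#'   `times`, `n_replicates`, `sigma`, `detection_limit`, `seed`, `version`.
#' @export
preset_library <- function() {
  base <- list(
    family = "processive", mode = "site",
    kon = 10, koff = 1, k_transfer = 0, E_tot = 0.25,
    times = c(0, 5, 15, 30, 60), n_replicates = 3L,
    sigma = 0.01, detection_limit = 3e-5, version = "1"
  )
  wt_kcat <- c(K5 = 0.015, K8 = 0.03, K12 = 0.22, K16 = 8)
  presets <- list(
    wildtype = utils::modifyList(base, list(
      name = "wildtype", sites = h4_sites(), kcat = wt_kcat, seed = 101L)),
    k16r = utils::modifyList(base, list(
      name = "k16r", sites = c("K5", "K8", "K12"),
      kcat = c(K5 = 0.003, K8 = 0.006, K12 = 0.022),
      koff = 10, seed = 102L)),
    zip_suppressed = utils::modifyList(base, list(
      name = "zip_suppressed", sites = h4_sites(), kcat = wt_kcat,
      koff = 40, seed = 103L)),
    k12_preferring = utils::modifyList(base, list(
      name = "k12_preferring", sites = h4_sites(),
      kcat = c(K5 = 0.02, K8 = 0.05, K12 = 4, K16 = 0.3), seed = 104L))
  )
  lapply(presets, function(p) structure(p, class = "scenario_preset"))
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat("Scenario preset '", x$name, "' [", x$family, "]: ",
      length(x$sites), " sites, times {",
      paste(x$times, collapse = ", "), "} min, ",
      x$n_replicates, " replicates, sigma = ", x$sigma, "\n", sep = "")
  invisible(x)
}

preset_model <- function(preset) {
  net <- transition_network(preset$sites)
  kinetic_model(preset$family, net, preset$kcat, mode = preset$mode,
                kon = preset$kon, koff = preset$koff,
                k_transfer = preset$k_transfer, E_tot = preset$E_tot)
}

#' Generate a synthetic motif time-course dataset
#'
#' Simulates the preset's model, then adds i.i.d. Gaussian measurement noise
#' (s.d. `sigma`) per (motif, time, replicate), clips observations to
#' [0, 1] and renormalizes each (time, replicate) column to sum to 1 — the
#' relative-abundance constraint of the MS readout. Deterministic given the
#' seed.
#'
#' @param preset a [preset_library()] entry.
#' @param seed RNG seed (default the preset's own, for bit-identical
#'   regeneration from metadata).
#' @return object of class `"synthetic_bundle"`: `truth` (noise-free
#'   [simulate_model()] trajectory), `dataset` (a [tc_dataset()]), `preset`,
#'   `seed`, `version`.
#' @export
generate_dataset <- function(preset, seed = preset$seed) {
  if (!inherits(preset, "scenario_preset"))
    stop("preset must come from preset_library() or carry its structure",
         call. = FALSE)
  if (any(preset$times < 0) || any(preset$times > 180))
    stop("preset times must lie in [0, 180] minutes", call. = FALSE)
  model <- preset_model(preset)
  truth <- simulate_model(model, times = preset$times)
  set.seed(seed)
  raw <- list()
  rows <- lapply(seq_len(preset$n_replicates), function(r) {
    noisy <- truth$y + matrix(stats::rnorm(length(truth$y), sd = preset$sigma),
                              nrow = nrow(truth$y))
    raw[[r]] <<- noisy   # pre-projection draws, kept for noise diagnostics
    noisy <- pmin(pmax(noisy, 0), 1)
    noisy <- sweep(noisy, 2, colSums(noisy), "/")
    data.frame(motif_label = rep(rownames(truth$y), times = ncol(noisy)),
               time_min = rep(truth$times, each = nrow(noisy)),
               replicate = r, y = as.vector(noisy),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  structure(
    list(truth = truth, dataset = tc_dataset(df, sites = preset$sites),
         raw_replicates = raw,
         preset = preset, seed = seed, version = preset$version),
    class = "synthetic_bundle"
  )
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("Synthetic bundle '", x$preset$name, "' (seed ", x$seed, ", v",
      x$version, "): ", sep = "")
  print(x$dataset)
  invisible(x)
}

#' Generate a synthetic MS1 peak table from a bundle
#'
#' Converts the bundle's noise-free trajectory into per-species MS1 areas:
#' `area = total_intensity * y_true * lognormal(meanlog 0 adjusted, cv)`,
#' with species composed via [species_for_motif()] (light enzymatic vs heavy
#' chemical acetyl bookkeeping). At `cv = 0` the round trip through
#' [relative_abundance()] recovers the truth exactly; scaling
#' `total_intensity` never changes recovered abundances.
#'
#' @param bundle a [generate_dataset()] result.
#' @param total_intensity summed MS1 intensity per (time, replicate).
#' @param cv coefficient of variation of the multiplicative area noise.
#' @param sequence_id peptide backbone (default chosen from the bundle's
#'   site count).
#' @param seed RNG seed.
#' @return data.frame in the peak-table CSV schema.
#' @export
generate_peak_table <- function(bundle, total_intensity = 1e9, cv = 0,
                                sequence_id = NULL, seed = bundle$seed + 1L) {
  stopifnot(inherits(bundle, "synthetic_bundle"),
            total_intensity > 0, cv >= 0)
  if (is.null(sequence_id))
    sequence_id <- if (length(bundle$preset$sites) == 4L) "wildtype_G4R17"
      else "k16r_G4R16"
  y <- bundle$truth$y
  times <- bundle$truth$times
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  out <- do.call(rbind, lapply(seq_len(bundle$preset$n_replicates), function(r) {
    noise <- if (cv > 0)
      matrix(stats::rlnorm(length(y), meanlog = -sdlog^2 / 2, sdlog = sdlog),
             nrow = nrow(y))
    else matrix(1, nrow(y), ncol(y))
    data.frame(sequence_id = sequence_id,
               motif_label = rep(rownames(y), times = ncol(y)),
               charge = 2L,
               time_min = rep(times, each = nrow(y)),
               replicate = r,
               ms1_area = as.vector(total_intensity * y * noise),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
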