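#' Aggregate motif abundances into report categories
#'
#' Summarizes a motif abundance table the way the experiment's bar plots do:
#' `unmod`, `K16ac` (the specific mono-acetylation), `other mono-ac` (sum of
#' K5ac, K8ac, K12ac), `di-/tri-ac` (sum of all 2- and 3-acetyl motifs) and
#' `tetra-ac`, per time point with mean and s.e.m. over replicates. The
#' categories partition the motif space, so per (time, replicate) the
#' category sums equal the total abundance.
#'
#' For 3-site (K16-less) spaces the `K16ac` category is absent and
#' `tetra-ac` means the fully acetylated motif of that space.
#'
#' @param at abundance table (long data.frame with `motif_label`,
#'   `time_min`, `replicate`, `y`).
#' @param sites site labels of the space the table lives on.
#' @return data.frame: `category`, `time_min`, `mean`, `sem`.
#' @export
aggregate_motifs <- function(at, sites = h4_sites()) {
  motifs <- enumerate_motifs(sites)
  n <- length(sites)
  cat_of <- function(label) {
    i <- match(label, motifs$label)
    nac <- motifs$n_ac[i]
    if (nac == 0) "unmod"
    else if (nac == n) "tetra-ac"
    else if (nac == 1) {
      if (label == "K16ac") "K16ac" else "other mono-ac"
    } else "di-/tri-ac"
  }
  at$category <- vapply(at$motif_label, cat_of, character(1))
  per_rep <- stats::aggregate(y ~ category + time_min + replicate, at, sum)
  agg <- stats::aggregate(y ~ category + time_min, per_rep, function(v)
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v))))
  out <- data.frame(category = agg$category, time_min = agg$time_min,
                    mean = agg$y[, "mean"], sem = agg$y[, "sem"],
                    stringsAsFactors = FALSE)
  cats <- c("unmod", "K16ac", "other mono-ac", "di-/tri-ac", "tetra-ac")
  out <- out[order(match(out$category, cats), out$time_min), ]
  rownames(out) <- NULL
  out
}

# deterministic per-stage seed fan-out from one global seed (documented
# counter scheme; keeps every derived seed a valid 32-bit integer)
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, quantify = 2L, fit = 3L, sample = 4L,
               predict = 5L)
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% 2147483647)
}

#' Default pipeline configuration
#'
#' @param preset preset name from [preset_library()].
#' @param families model families to fit.
#' @param seed global seed; per-stage seeds are derived from it by a fixed
#'   counter scheme so stages can be re-run in isolation.
#' @param n_starts optimization starts per family.
#' @param n_steps posterior ensemble steps.
#' @param sigma_mode noise handling in the likelihood.
#' @param predict_disable sites disabled in the counterfactual prediction
#'   (default `"K16"`, the K16R scenario; ignored when absent from the
#'   space).
#' @param outdir output directory for tables (`NULL` = return only).
#' @export
pipeline_config <- function(preset = "wildtype",
                            families = c("mass_action", "michaelis_menten",
                                         "processive"),
                            seed = 1, n_starts = 4, n_steps = 300,
                            sigma_mode = "estimated",
                            predict_disable = "K16", outdir = NULL) {
  list(preset = preset, families = families, seed = seed,
       n_starts = n_starts, n_steps = n_steps, sigma_mode = sigma_mode,
       predict_disable = predict_disable, outdir = outdir)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take [pipeline_config()]
#' defaults. A seed is mandatory.
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(raw$seed)) stop("config must set a seed", call. = FALSE)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline on a synthetic preset
#'
#' Executes simulate -> quantify -> fit -> compare -> sample -> predict with
#' per-stage seeds derived from the global seed, and assembles the report
#' bundle: motif-by-time abundance table (heatmap layout), aggregate table
#' (bar-plot layout), delta-AIC comparison, credibility intervals, the
#' counterfactual prediction band and a provenance block. Identical config
#' and seed reproduce the bundle exactly. When `outdir` is set every table
#' is written as CSV (provenance as JSON) as soon as its stage completes.
#'
#' @param config a [pipeline_config()].
#' @return list of class `"report_bundle"`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  presets <- preset_library()
  if (!config$preset %in% names(presets))
    stop("unknown preset '", config$preset, "'", call. = FALSE)
  preset <- presets[[config$preset]]
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(obj, name) {
    if (!is.null(outdir))
      utils::write.csv(obj, file.path(outdir, paste0(name, ".csv")),
                       row.names = FALSE)
    obj
  }

  # simulate + quantify
  bundle <- generate_dataset(preset, seed = stage_seed(config$seed, "simulate"))
  at <- apply_detection_limit(bundle$dataset$df, preset$detection_limit)
  heat <- stats::aggregate(y ~ motif_label + time_min, at, mean)
  heat <- stats::reshape(heat, idvar = "motif_label", timevar = "time_min",
                         direction = "wide")
  names(heat) <- sub("^y\\.", "t", names(heat))
  motifs <- enumerate_motifs(preset$sites)
  heat <- heat[order(match(heat$motif_label, motifs$label)), ]
  emit(heat, "abundance_heatmap")
  aggregate_tbl <- emit(aggregate_motifs(at, preset$sites), "aggregates")

  # fit + compare
  spec <- likelihood_spec(sigma_mode = config$sigma_mode,
                          sigma = preset$sigma)
  fit_seed <- stage_seed(config$seed, "fit")
  fits <- lapply(config$families, function(fam)
    fit_model(fam, bundle$dataset, spec, mode = "site",
              E_tot = preset$E_tot, n_starts = config$n_starts,
              seed = fit_seed))
  names(fits) <- config$families
  comparison <- emit(compare_models(fits), "model_comparison")

  # sample the best family's posterior
  best_family <- comparison$family[1]
  ens <- sample_posterior(best_family, bundle$dataset,
                          spec = spec, mode = "site", E_tot = preset$E_tot,
                          n_steps = config$n_steps,
                          seed = stage_seed(config$seed, "sample"),
                          theta0 = fits[[best_family]]$theta_hat)
  ci <- emit(credibility_intervals(ens), "credibility_intervals")

  # counterfactual prediction
  disable <- intersect(config$predict_disable, preset$sites)
  band <- ensemble_predict(ens, times = preset$times, disable = disable)
  emit(as.data.frame(band), "prediction_band")

  provenance <- list(
    preset = preset$name, preset_version = preset$version,
    families = config$families, global_seed = config$seed,
    stage_seeds = lapply(c("simulate", "fit", "sample"),
                         function(s) stage_seed(config$seed, s)),
    sigma_mode = config$sigma_mode, n_starts = config$n_starts,
    n_steps = config$n_steps,
    best_family = best_family,
    sampler = list(acceptance_rate = ens$acceptance_rate,
                   max_rhat = max(ens$rhat), converged = ens$converged),
    package_version = as.character(utils::packageVersion("h4zip"))
  )
  if (!is.null(outdir))
    jsonlite::write_json(provenance, file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)

  structure(list(abundance_heatmap = heat, aggregates = aggregate_tbl,
                 comparison = comparison, credibility_intervals = ci,
                 prediction_band = band, fits = fits, ensemble = ens,
                 bundle = bundle, provenance = provenance),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Report bundle — preset '", x$provenance$preset, "', best family: ",
      x$provenance$best_family, "\n", sep = "")
  print(x$comparison)
  invisible(x)
}
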