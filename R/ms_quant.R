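#' Peptides and mass constants for H4 tail acetyl quantification
#'
#' Targeted MS quantifies combinatorial H4 tail acetylation on the tryptic
#' peptide spanning G4-R17 (sequence `GKGGKGLGKGGAKR`, lysines K5/K8/K12/K16).
#' Before digestion every unmodified lysine is chemically acetylated with
#' acetic anhydride-D6, adding a heavy D3-acetyl group 3.0188 Da heavier than
#' an enzymatic (light) acetyl, so enzymatic and chemical acetylation are
#' distinguishable by mass while being chemically identical. For the K16R
#' mutant the peptide is G4-R16 (`GKGGKGLGKGGAR`, lysines K5/K8/K12): trypsin
#' cleaves after the substituted arginine.
#'
#' The N-terminal amine is treated as unmodified (derivatization precedes
#' digestion, so the peptide alpha-amine produced by trypsin is free); this
#' convention affects theoretical masses and is therefore stated here.
#'
#' `ms_constants()` returns all monoisotopic constants in one editable list,
#' including the instrument-reference m/z values kept as metadata (they are
#' not reproduced exactly by the standard monoisotopic computation; see
#' [theoretical_mz()]).
#'
#' @export
h4_peptides <- function() {
  list(
    wildtype_G4R17 = list(sequence = "GKGGKGLGKGGAKR",
                          sites = c("K5", "K8", "K12", "K16"), n_lysines = 4L),
    k16r_G4R16 = list(sequence = "GKGGKGLGKGGAR",
                      sites = c("K5", "K8", "K12"), n_lysines = 3L)
  )
}

#' @rdname h4_peptides
#' @export
ms_constants <- function() {
  list(
    residue_mass = c(G = 57.02146, A = 71.03711, L = 113.08406,
                     K = 128.09496, R = 156.10111),
    water = 18.010565,
    proton = 1.007276,
    acetyl_light = 42.010565,    # enzymatic acetyl
    acetyl_heavy = 45.029395,    # chemical D3-acetyl
    heavy_light_delta = 3.01883,
    # published instrument reference m/z (2+), kept as metadata only
    reference_mz = list(
      wildtype_G4R17 = c(mono = 724.9428, di = 723.4329, tri = 721.9221),
      k16r_G4R16 = c(mono = 637.8759, di = 636.3665, tri = 634.8571)
    )
  )
}

#' Peptide species carrying a given acetylation motif
#'
#' Converts a motif into the measured peptide species: the motif's acetylated
#' sites carry light (enzymatic) acetyls and every remaining lysine carries a
#' heavy (chemical D3) acetyl, so `n_light + n_heavy` always equals the
#' peptide's lysine count.
#'
#' @param motif motif label (or bitmask) on the sequence's site set.
#' @param sequence_id `"wildtype_G4R17"` or `"k16r_G4R16"`.
#' @param charge precursor charge state (default 2).
#' @return list of class `"peptide_species"` with fields `sequence_id`,
#'   `motif`, `n_light`, `n_heavy`, `charge`.
#' @export
species_for_motif <- function(motif, sequence_id = "wildtype_G4R17", charge = 2L) {
  pep <- h4_peptides()[[sequence_id]]
  if (is.null(pep)) stop("unknown sequence_id: ", sequence_id, call. = FALSE)
  bits <- if (is.character(motif)) parse_motif_label(motif, pep$sites) else as.integer(motif)
  if (bits < 0 || bits >= 2^length(pep$sites))
    stop("motif is not valid for the site set of ", sequence_id, call. = FALSE)
  n_light <- popcount(bits)
  structure(
    list(sequence_id = sequence_id,
         motif = motif_label(bits, pep$sites),
         n_light = n_light,
         n_heavy = pep$n_lysines - n_light,
         charge = as.integer(charge)),
    class = "peptide_species"
  )
}

#' Theoretical m/z of a peptide species
#'
#' Monoisotopic peptide mass from standard residue masses plus light/heavy
#' acetyl masses and water, converted to m/z at the species' charge:
#' `(M + z * proton) / z`. Note the published instrument m/z values differ
#' from this standard computation by about 1 Da at neutral mass for the same
#' nominal composition; the published values are therefore retained as
#' reference metadata in [ms_constants()] and are not asserted against.
#'
#' @param sp a [species_for_motif()] result.
#' @export
theoretical_mz <- function(sp) {
  stopifnot(inherits(sp, "peptide_species"))
  if (sp$charge < 1) stop("charge must be >= 1", call. = FALSE)
  pep <- h4_peptides()[[sp$sequence_id]]
  if (is.null(pep)) stop("unknown sequence_id: ", sp$sequence_id, call. = FALSE)
  cst <- ms_constants()
  aa <- strsplit(pep$sequence, "")[[1]]
  M <- sum(cst$residue_mass[aa]) + cst$water +
    sp$n_light * cst$acetyl_light + sp$n_heavy * cst$acetyl_heavy
  (M + sp$charge * cst$proton) / sp$charge
}

#' Relative motif abundances from MS1 peak areas
#'
#' Each enzymatically acetylated peptide species is expressed as the fraction
#' of the summed MS1 areas of all H4 peptide species (unmodified and
#' modified) in the same replicate and time point. Motifs absent from the
#' table contribute zero area.
#'
#' @param peak_table data.frame with columns `sequence_id`, `motif_label`,
#'   `time_min`, `replicate`, `ms1_area` (a `charge` column is allowed and
#'   summed over).
#' @return data.frame of class `"abundance_table"` with columns
#'   `motif_label`, `time_min`, `replicate`, `y`; every motif of the
#'   sequence's space appears for every (time, replicate).
#' @export
relative_abundance <- function(peak_table) {
  req <- c("sequence_id", "motif_label", "time_min", "replicate", "ms1_area")
  if (!all(req %in% names(peak_table)))
    stop("peak table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  sid <- unique(peak_table$sequence_id)
  if (length(sid) != 1L)
    stop("peak table mixes sequence_ids; normalize one peptide at a time",
         call. = FALSE)
  if (any(peak_table$ms1_area < 0))
    stop("MS1 areas must be non-negative", call. = FALSE)
  pep <- h4_peptides()[[sid]]
  if (is.null(pep)) stop("unknown sequence_id: ", sid, call. = FALSE)
  motifs <- enumerate_motifs(pep$sites)

  grid <- unique(peak_table[, c("time_min", "replicate")])
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    sel <- peak_table$time_min == grid$time_min[g] &
      peak_table$replicate == grid$replicate[g]
    areas <- stats::setNames(numeric(nrow(motifs)), motifs$label)
    agg <- tapply(peak_table$ms1_area[sel], peak_table$motif_label[sel], sum)
    bad <- setdiff(names(agg), motifs$label)
    if (length(bad))
      stop("unknown motif labels in peak table: ",
           paste(bad, collapse = ", "), call. = FALSE)
    areas[names(agg)] <- agg
    tot <- sum(areas)
    if (tot <= 0)
      stop("total MS1 area is zero for time ", grid$time_min[g],
           ", replicate ", grid$replicate[g],
           "; relative abundance undefined", call. = FALSE)
    data.frame(motif_label = motifs$label, time_min = grid$time_min[g],
               replicate = grid$replicate[g], y = unname(areas) / tot,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "sequence_id") <- sid
  class(out) <- c("abundance_table", class(out))
  out
}

#' Flag abundances below the detection limit
#'
#' Adds/updates a logical `mask` column marking observations strictly below
#' the detection limit (default 0.003%, i.e. 3e-5). Values exactly at the
#' limit are not masked ("below the detection limit" is strict). Masking is a
#' reporting flag: the `y` values are preserved, so downstream fitting can
#' choose to omit or censor masked points. Applying the limit twice is a
#' no-op.
#'
#' @param at an abundance table (any data.frame with a `y` column).
#' @param limit detection limit as a fraction, in (0, 1).
#' @export
apply_detection_limit <- function(at, limit = 3e-5) {
  if (!is.numeric(limit) || limit <= 0 || limit >= 1)
    stop("limit must be a fraction in (0, 1)", call. = FALSE)
  at$mask <- at$y < limit
  attr(at, "detection_limit") <- limit
  at
}

#' Read / write the peak-table CSV schema
#'
#' Columns: `sequence_id`, `motif_label`, `charge`, `time_min`, `replicate`,
#' `ms1_area`. Exports from spectral-processing software must be pre-mapped
#' to this schema.
#'
#' @param path file path.
#' @export
read_peak_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_peak_table
#' @param x data.frame to write.
#' @export
write_peak_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
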