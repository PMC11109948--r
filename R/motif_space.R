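#' Default acetylation sites of the histone H4 N-terminal tail
#'
#' The four lysines of the H4 tail that carry acetylation, ordered from the
#' N-terminus inward: K5 < K8 < K12 < K16. Site index 0..3 follows this order.
#'
#' @export
h4_sites <- function() c("K5", "K8", "K12", "K16")

#' Enumerate all combinatorial acetylation motifs
#'
#' A motif is one combinatorial acetylation pattern over a set of lysines,
#' encoded as a bit vector (bit i set = site i acetylated). All `2^n` motifs
#' are returned in a stable canonical order: by acetyl count ascending, then
#' lexicographically by the index tuple of acetylated sites. This is the
#' reading order of heatmap-style report tables.
#'
#' @param sites character vector of site labels (N-terminal to internal), or a
#'   single non-negative integer giving the number of (auto-labelled) sites.
#' @return data.frame with columns `id` (1-based canonical index), `bits`
#'   (integer bitmask over site indices), `n_ac` (acetyl count) and `label`
#'   (canonical motif label, see [motif_label()]).
#' @examples
#' enumerate_motifs(h4_sites())   # the 16 wild-type motifs
#' enumerate_motifs(0)            # the single empty pattern
#' @export
enumerate_motifs <- function(sites = h4_sites()) {
  if (is.numeric(sites) && length(sites) == 1L) {
    if (is.na(sites) || sites < 0 || sites != round(sites))
      stop("number of sites must be a non-negative integer", call. = FALSE)
    sites <- if (sites == 0L) character(0) else paste0("S", seq_len(sites))
  }
  sites <- as.character(sites)
  if (anyDuplicated(sites)) stop("site labels must be unique", call. = FALSE)
  n <- length(sites)
  bits <- 0:(2^n - 1L)
  n_ac <- vapply(bits, popcount, integer(1))
  # canonical order: acetyl count, then lexicographic on the acetylated-site
  # index tuple; for fixed count this equals ascending order of the reversed
  # bit pattern, implemented via an explicit key
  key <- vapply(bits, function(b) {
    idx <- which(bitwAnd(b, 2^(0:max(0, n - 1))) > 0)
    paste(sprintf("%02d", idx), collapse = "")
  }, character(1))
  ord <- order(n_ac, key)
  bits <- bits[ord]
  data.frame(
    id = seq_along(bits),
    bits = bits,
    n_ac = n_ac[ord],
    label = vapply(bits, motif_label, character(1), sites = sites),
    stringsAsFactors = FALSE
  )
}

popcount <- function(x) {
  n <- 0L
  while (x > 0L) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

#' Canonical label of a motif
#'
#' The unmodified motif is `"unmod"`; otherwise acetylated sites are
#' concatenated N-terminal to internal, e.g. `"K12acK16ac"`. The alias
#' `"tetra-ac"` is accepted on input for the fully acetylated four-site motif
#' (see [parse_motif_label()]).
#'
#' @param bits integer bitmask.
#' @param sites site labels.
#' @export
motif_label <- function(bits, sites = h4_sites()) {
  if (bits == 0L) return("unmod")
  idx <- which(bitwAnd(bits, 2^(seq_along(sites) - 1L)) > 0)
  paste0(paste0(sites[idx], "ac"), collapse = "")
}

#' Parse a motif label back to its bitmask
#'
#' Inverse of [motif_label()]; additionally accepts `"tetra-ac"` as an alias
#' for the fully acetylated motif of a four-site space.
#'
#' @inheritParams motif_label
#' @param label canonical motif label.
#' @export
parse_motif_label <- function(label, sites = h4_sites()) {
  if (label == "unmod") return(0L)
  if (label == "tetra-ac") {
    if (length(sites) != 4L)
      stop("'tetra-ac' alias is defined for four-site spaces only", call. = FALSE)
    return(15L)
  }
  parts <- strsplit(label, "ac", fixed = TRUE)[[1]]
  idx <- match(parts, sites)
  if (anyNA(idx) || length(parts) == 0L)
    stop("unknown motif label: ", label, call. = FALSE)
  as.integer(sum(2^(idx - 1)))
}

#' Acetylation transition network over a motif space
#'
#' Directed acyclic lattice whose nodes are all motifs over `sites` and whose
#' edges add exactly one acetyl group (bit 0 -> 1). There are no deacetylation
#' edges by construction: the in-vitro assay contains no deacetylase, so the
#' fully acetylated motif is the unique absorbing sink. Do not mistake the
#' lattice for a steady-state (reversible) model.
#'
#' @param sites site labels (N-terminal to internal).
#' @return an object of class `"motif_network"`: list with `sites`, `motifs`
#'   (as [enumerate_motifs()]) and `edges` (data.frame `from`, `to` — canonical
#'   motif ids — and `site` label).
#' @export
transition_network <- function(sites = h4_sites()) {
  motifs <- enumerate_motifs(sites)
  n <- length(sites)
  id_of_bits <- integer(2^max(0, n))
  id_of_bits[motifs$bits + 1L] <- motifs$id
  from <- integer(0); to <- integer(0); site <- character(0)
  for (i in seq_len(nrow(motifs))) {
    b <- motifs$bits[i]
    for (s in seq_len(n)) {
      bit <- 2L^(s - 1L)
      if (bitwAnd(b, bit) == 0L) {
        from <- c(from, motifs$id[i])
        to <- c(to, id_of_bits[bitwOr(b, bit) + 1L])
        site <- c(site, sites[s])
      }
    }
  }
  structure(
    list(sites = sites, motifs = motifs,
         edges = data.frame(from = from, to = to, site = site,
                            stringsAsFactors = FALSE)),
    class = "motif_network"
  )
}

#' @export
print.motif_network <- function(x, ...) {
  cat("Acetylation transition network:", length(x$sites), "sites (",
      paste(x$sites, collapse = ", "), "), ", nrow(x$motifs), "motifs,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Single-site acetylation transitions available from one motif
#'
#' One entry per unacetylated site; each target differs from the source at
#' exactly that site. The fully acetylated motif has none (absorbing state).
#'
#' @param bits motif bitmask.
#' @param sites site labels.
#' @return data.frame with columns `target` (bitmask), `site` (label).
#' @export
motif_transitions <- function(bits, sites = h4_sites()) {
  n <- length(sites)
  free <- which(bitwAnd(bits, 2^(seq_len(n) - 1L)) == 0L)
  data.frame(
    target = vapply(free, function(s) bitwOr(bits, 2L^(s - 1L)), integer(1)),
    site = sites[free],
    stringsAsFactors = FALSE
  )
}

#' Restrict a transition network to motifs lacking one site
#'
#' Models the counterfactual in which all reactions acetylating a given site
#' are disabled (e.g. the K16R mutant, where lysine 16 is replaced by
#' arginine). The result is the full lattice over the remaining sites: node
#' count halves, and every edge touching the removed site disappears.
#'
#' @param net a `"motif_network"`.
#' @param site site label to remove.
#' @export
restrict_site <- function(net, site) {
  stopifnot(inherits(net, "motif_network"))
  if (!site %in% net$sites)
    stop("site '", site, "' is not in the network", call. = FALSE)
  transition_network(setdiff(net$sites, site))
}

#' Motifs in which a given site is acetylated
#'
#' @param net a `"motif_network"`.
#' @param site site label.
#' @return the subset of `net$motifs` rows with that site acetylated
#'   (`2^(n-1)` motifs); empty when the network does not carry the site at
#'   all (e.g. any site on the single-motif zero-site space).
#' @export
motifs_containing <- function(net, site) {
  stopifnot(inherits(net, "motif_network"))
  s <- match(site, net$sites)
  if (is.na(s)) return(net$motifs[0L, , drop = FALSE])
  net$motifs[bitwAnd(net$motifs$bits, 2L^(s - 1L)) > 0L, , drop = FALSE]
}
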