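# Accessibility of the Ssa1/Sis1 chaperone-binding region relative to
# the ordered fibril core, and the strain-landscape coordinate table.

#' Chaperone binding site
#'
#' The Ssa1/Sis1 binding region of Sup35, residues 143-164 by default.
#' Residue identities come from the input sequence, never from the
#' package.
#'
#' @param span a [residue_span()] (default 143-164).
#' @param label text label.
#' @export
binding_site <- function(span = residue_span(143, 164), label = "Ssa1/Sis1") {
  structure(list(span = span, label = label), class = "binding_site")
}

#' Sequence distance between core and chaperone site
#'
#' Number of residues strictly between the nearest core-span boundary
#' and the site boundary; zero if (and only if) any core span overlaps
#' the site.  Symmetric in the roles of core and site.
#'
#' @param core list of [residue_span()] (the ordered core).
#' @param site a [binding_site()] or [residue_span()].
#' @return integer residue gap.
#' @export
chaperone_sequence_distance <- function(core, site) {
  core <- .as_span_list(core)
  if (length(core) == 0L) stop("empty core")
  s <- if (inherits(site, "binding_site")) site$span else site
  gaps <- vapply(core, function(cs) {
    if (cs$last >= s$first && s$last >= cs$first) return(0L)
    if (cs$last < s$first) s$first - cs$last - 1L else cs$first - s$last - 1L
  }, integer(1))
  min(gaps)
}

#' Classify exposure of the chaperone site in a model
#'
#' Whether the binding-site residues appear among the model's ordered
#' residues, and if so whether they contact the rest of the core (any
#' heavy-atom pair closer than `contact_cutoff`).
#'
#' @param model a `fibril_model`.
#' @param site a [binding_site()].
#' @param contact_cutoff Angstrom; default 5.
#' @return one of `"absent_from_model"`, `"ordered_overlapping_core"`,
#'   `"ordered_adjacent"`.
#' @export
site_exposure <- function(model, site = binding_site(),
                          contact_cutoff = 5) {
  a <- .protein_atoms(model)
  s <- site$span
  in_site <- a$resid >= s$first & a$resid <= s$last
  if (!any(in_site)) return("absent_from_model")
  if (!any(!in_site)) return("ordered_overlapping_core")
  P <- .coords(a[in_site, ])
  Q <- .coords(a[!in_site, ])
  cut2 <- contact_cutoff^2
  for (i in seq_len(nrow(P))) {
    d2 <- (Q[, 1] - P[i, 1])^2 + (Q[, 2] - P[i, 2])^2 + (Q[, 3] - P[i, 3])^2
    if (any(d2 < cut2)) return("ordered_overlapping_core")
  }
  "ordered_adjacent"
}

#' Minimum 3D distance from site to core (variant metric)
#'
#' Heavy-atom minimum distance between site residues and the rest of
#' the model; `Inf` when the site is absent.  The landscape table uses
#' sequence separation, not this.
#'
#' @inheritParams site_exposure
#' @return Angstrom.
#' @export
site_min_distance <- function(model, site = binding_site()) {
  a <- .protein_atoms(model)
  s <- site$span
  in_site <- a$resid >= s$first & a$resid <= s$last
  if (!any(in_site) || !any(!in_site)) return(Inf)
  P <- .coords(a[in_site, ])
  Q <- .coords(a[!in_site, ])
  sqrt(min(vapply(seq_len(nrow(P)), function(i)
    min((Q[, 1] - P[i, 1])^2 + (Q[, 2] - P[i, 2])^2 +
          (Q[, 3] - P[i, 3])^2), numeric(1))))
}

#' Strain record
#'
#' One polymorph's coordinates in the structure-phenotype landscape:
#' per-layer stabilization energy, sequence distance from the ordered
#' core to the chaperone-binding site, and its population fraction in
#' the preparation.
#'
#' @param polymorph polymorph name.
#' @param dg_per_chain kcal/mol/layer.
#' @param core_to_site_distance residues (see
#'   [chaperone_sequence_distance()]).
#' @param polymorph_fraction fraction of particles in `[0, 1]`.
#' @param handedness `"left"`, `"right"` or `"undefined"`.
#' @param core list of [residue_span()].
#' @param preparation name of the fibril preparation the fraction refers
#'   to (fractions within one preparation must sum to <= 1); defaults to
#'   the polymorph name.
#' @export
strain_record <- function(polymorph, dg_per_chain, core_to_site_distance,
                          polymorph_fraction = 1, handedness = "undefined",
                          core = list(), preparation = polymorph) {
  if (polymorph_fraction < 0 || polymorph_fraction > 1)
    stop("polymorph_fraction must be in [0, 1]")
  structure(list(polymorph = polymorph, dg_per_chain = dg_per_chain,
                 core_to_site_distance = core_to_site_distance,
                 polymorph_fraction = polymorph_fraction,
                 handedness = handedness, core = .as_span_list(core),
                 preparation = preparation),
            class = "strain_record")
}

#' Structure-phenotype landscape table
#'
#' Tidy table of landscape coordinates, one row per polymorph, sorted by
#' stabilization energy ascending (ties broken by name).  No phenotype
#' is predicted: the table holds coordinates only.
#'
#' @param records list of [strain_record()].
#' @return data.frame with columns `polymorph`, `dg_per_chain`,
#'   `core_to_site_distance`, `fraction`, `handedness`, `preparation`.
#' @export
strain_landscape_table <- function(records) {
  if (inherits(records, "strain_record")) records <- list(records)
  if (length(records) == 0L) stop("need at least one record")
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(polymorph = r$polymorph, dg_per_chain = r$dg_per_chain,
               core_to_site_distance = r$core_to_site_distance,
               fraction = r$polymorph_fraction,
               handedness = r$handedness,
               preparation = r$preparation,
               stringsAsFactors = FALSE)))
  sums <- tapply(df$fraction, df$preparation, sum)
  if (any(sums > 1 + 1e-9))
    stop("polymorph fractions of preparation '",
         names(sums)[which(sums > 1 + 1e-9)[1]], "' sum to more than 1")
  df <- df[order(df$dg_per_chain, df$polymorph), ]
  rownames(df) <- NULL
  df
}
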