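# Atomic-solvation-parameter stabilization free energy of fibril layers.
#
# dG_stab(chain) = sum over heavy atoms of ASP(class) * (A_fibril -
# A_reference).  Burial of apolar carbon area is stabilizing (negative
# dG); burial of charged nitrogen/oxygen area is destabilizing.  The
# reference state is the same chain either rebuilt as an extended
# monomer or taken in its deposited conformation in isolation.

#' Atomic solvation parameter set
#'
#' Eisenberg-McLachlan-class parameters in kcal/(mol Angstrom^2) by atom
#' class: apolar carbon, uncharged N/O, charged carboxylate oxygen,
#' charged amine/guanidinium nitrogen, and sulfur.  The defaults are the
#' classic transfer-free-energy values (+0.016, -0.006, -0.024, -0.050,
#' +0.021); they can be rescaled against a reference table with
#' [calibrate_solvation_params()].
#'
#' @param apolar_C,polar_NO,charged_O,charged_N,sulfur parameters in
#'   kcal/(mol A^2).
#' @param reference_state `"extended_chain"` (default: the chain rebuilt
#'   with extended backbone dihedrals, so intra-layer packing counts) or
#'   `"isolated_chain"` (deposited conformation, neighbours removed).
#' @param name label for the set.
#' @export
solvation_params <- function(apolar_C = 0.016, polar_NO = -0.006,
                             charged_O = -0.024, charged_N = -0.050,
                             sulfur = 0.021,
                             reference_state = c("extended_chain",
                                                 "isolated_chain"),
                             name = "eisenberg-mclachlan") {
  if (apolar_C <= 0)
    stop("apolar carbon parameter must be positive")
  if (charged_O >= 0 || charged_N >= 0)
    stop("charged-atom parameters must be negative")
  structure(list(asp = c(apolar_C = apolar_C, polar_NO = polar_NO,
                         charged_O = charged_O, charged_N = charged_N,
                         sulfur = sulfur),
                 reference_state = match.arg(reference_state),
                 name = name),
            class = "solvation_params")
}

#' @export
print.solvation_params <- function(x, ...) {
  cat(sprintf("solvation_params '%s' (reference: %s)\n", x$name,
              x$reference_state))
  print(x$asp)
  invisible(x)
}

#' Read/write solvation parameters as JSON
#' @param file path.
#' @rdname solvation_params_io
#' @export
read_solvation_params <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  solvation_params(j$asp[["apolar_C"]], j$asp[["polar_NO"]],
                   j$asp[["charged_O"]], j$asp[["charged_N"]],
                   j$asp[["sulfur"]],
                   reference_state = j$reference_state, name = j$name)
}

#' @param params a [solvation_params()].
#' @rdname solvation_params_io
#' @export
write_solvation_params <- function(params, file) {
  jsonlite::write_json(list(asp = as.list(params$asp),
                            reference_state = params$reference_state,
                            name = params$name),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

# atom class of each heavy atom: side-chain carboxylate oxygens and the
# C-terminal OXT are charged O; Lys NZ and Arg NE/NH* are charged N (His
# treated neutral at pH 7.4); everything else by element.
.atom_class <- function(atoms) {
  cls <- rep(NA_character_, nrow(atoms))
  cls[atoms$element == "C"] <- "apolar_C"
  cls[atoms$element %in% c("N", "O")] <- "polar_NO"
  cls[atoms$element == "S"] <- "sulfur"
  chg_o <- (atoms$resname == "ASP" & atoms$atom_name %in% c("OD1", "OD2")) |
    (atoms$resname == "GLU" & atoms$atom_name %in% c("OE1", "OE2")) |
    atoms$atom_name == "OXT"
  chg_n <- (atoms$resname == "LYS" & atoms$atom_name == "NZ") |
    (atoms$resname == "ARG" & atoms$atom_name %in% c("NE", "NH1", "NH2"))
  cls[chg_o] <- "charged_O"
  cls[chg_n] <- "charged_N"
  cls
}

# NeRF placement: position of atom D given A-B-C, bond |CD|, angle
# B-C-D (deg) and torsion A-B-C-D (deg)
.place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# orthonormal residue frame from backbone N, CA, C (origin at CA)
.bb_frame <- function(n, ca, c) {
  e1 <- .unit(n - ca)
  e2 <- .unit((c - ca) - sum((c - ca) * e1) * e1)
  cbind(e1, e2, pracma_cross(e1, e2))
}

#' Rebuild a chain in the extended reference conformation
#'
#' The unassembled reference state of the stabilization-energy model:
#' backbone N/CA/C placed by ideal geometry with extended dihedrals
#' (phi = -140, psi = 135, omega = 180 degrees; N-CA 1.458, CA-C 1.525,
#' C-N 1.329 Angstrom), all remaining atoms of each residue (O, CB, side
#' chain) carried over rigidly in the local N-CA-C frame, so the rebuilt
#' chain contains exactly the atoms of the input chain.
#'
#' @param model a `fibril_model`.
#' @param chain chain id.
#' @return a single-chain `fibril_model` with the same atom rows.
#' @export
build_extended_reference <- function(model, chain) {
  a <- .protein_atoms(model, heavy = FALSE)
  a <- a[a$chain == chain, ]
  if (nrow(a) == 0L) stop("chain not found: ", chain)
  if (!all(a$resname %in% .aa3))
    stop("unknown residue type in chain ", chain)
  resids <- sort(unique(a$resid))
  # ideal extended backbone
  bb <- vector("list", length(resids))
  for (i in seq_along(resids)) {
    if (i == 1) {
      N <- c(0, 0, 0)
      CA <- c(1.458, 0, 0)
      C <- CA + 1.525 * c(-cos(111.2 * pi / 180), sin(111.2 * pi / 180), 0)
    } else {
      p <- bb[[i - 1]]
      N <- .place_atom(p$N, p$CA, p$C, 1.329, 116.2, 135)    # psi
      CA <- .place_atom(p$CA, p$C, N, 1.458, 121.7, 180)     # omega
      C <- .place_atom(p$C, N, CA, 1.525, 111.2, -140)       # phi
    }
    bb[[i]] <- list(N = N, CA = CA, C = C)
  }
  out <- a
  for (i in seq_along(resids)) {
    ri <- which(a$resid == resids[i])
    res <- a[ri, ]
    idx <- function(nm) ri[match(nm, res$atom_name)]
    iN <- idx("N"); iCA <- idx("CA"); iC <- idx("C")
    if (anyNA(c(iN, iCA, iC)))
      stop("residue ", resids[i], " lacks a complete N/CA/C backbone")
    old <- .bb_frame(as.numeric(a[iN, c("x", "y", "z")]),
                     as.numeric(a[iCA, c("x", "y", "z")]),
                     as.numeric(a[iC, c("x", "y", "z")]))
    new <- .bb_frame(bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C)
    R <- new %*% t(old)
    ca_old <- as.numeric(a[iCA, c("x", "y", "z")])
    xyz <- sweep(.coords(res), 2, ca_old)
    xyz <- sweep(xyz %*% t(R), 2, bb[[i]]$CA, "+")
    out[ri, c("x", "y", "z")] <- xyz
    out[idx("N"), c("x", "y", "z")] <- bb[[i]]$N
    out[idx("CA"), c("x", "y", "z")] <- bb[[i]]$CA
    out[idx("C"), c("x", "y", "z")] <- bb[[i]]$C
  }
  fibril_model(out, label = paste0(model$label, "_extended"))
}

#' Reference-state SASA of a chain
#'
#' Per-atom accessible area of the chain in the unassembled reference
#' state: either the deposited conformation with all other chains
#' removed (`isolated_chain`) or the chain rebuilt with extended
#' backbone dihedrals (`extended_chain`; see
#' [build_extended_reference()]).
#'
#' @param model a `fibril_model`.
#' @param chain chain id.
#' @param params a [solvation_params()] (its `reference_state` selects
#'   the mode).
#' @inheritParams compute_sasa
#' @return a `sasa_result` whose rows match the chain's heavy atoms in
#'   model order.
#' @export
reference_sasa <- function(model, chain, params = solvation_params(),
                           probe = 1.4, n_points = 960) {
  a <- .protein_atoms(model)
  a <- a[a$chain == chain, ]
  if (nrow(a) == 0L) stop("chain not found: ", chain)
  if (!all(a$resname %in% .aa3))
    stop("unknown residue type in chain ", chain)
  ref_atoms <- if (params$reference_state == "extended_chain") {
    .protein_atoms(build_extended_reference(model, chain))
  } else a
  compute_sasa(ref_atoms, probe = probe, n_points = n_points)
}

# ensure `chain` has >= 2 neighbour layers on each side, extending the
# stack by helical symmetry when possible
.ensure_interior <- function(model, chain, min_side = 2) {
  if (is.null(model$layers)) model <- order_layers(model)
  pos <- match(chain, model$layers)
  n <- length(model$layers)
  if (!is.na(pos) && pos > min_side && pos <= n - min_side)
    return(list(model = model, chain = chain))
  hel <- model$helical
  if (is.null(hel) && n >= 2) hel <- measure_rise_twist(model)
  if (is.null(hel))
    stop("chain ", chain, " is on the stack edge and no helical ",
         "parameters are available to extend the stack")
  a <- .protein_atoms(model, heavy = FALSE)
  layer <- fibril_model(a[a$chain == chain, ], label = model$label)
  axis <- if (n >= 2) estimate_axis(model)
  else fibril_axis(colMeans(.coords(.protein_atoms(layer))), c(0, 0, 1))
  stack <- build_helical_stack(layer, hel$rise, hel$twist,
                               2 * min_side + 1, axis = axis)
  list(model = stack, chain = stack$layers[stack$central])
}

#' Stabilization free energy of a fibril layer
#'
#' The solvation stabilization energy of one chain in fibril context:
#' `dG = sum_atoms ASP(class) * (A_fibril - A_reference)` in kcal/mol
#' per chain (layer).  Negative values are stabilizing; the least stable
#' structures have positive values.  The scored chain must be interior
#' (at least two neighbour layers on each side); shorter stacks are
#' extended by helical symmetry when the model carries (or yields)
#' helical parameters, otherwise an edge-effect error is raised.
#'
#' @param model a `fibril_model`.
#' @param chain chain id; defaults to the central layer.
#' @param params a [solvation_params()].
#' @inheritParams compute_sasa
#' @return object of class `stability_profile`: `dg_per_chain`,
#'   `dg_per_residue_mean`, `per_residue` (named by residue index),
#'   `buried_area_per_atom`, `atoms`, `context_layers`.
#' @export
stabilization_energy <- function(model, chain = NULL,
                                 params = solvation_params(),
                                 probe = 1.4, n_points = 960) {
  if (is.null(model$layers)) model <- order_layers(model)
  if (is.null(chain)) chain <- model$layers[model$central]
  ctx <- .ensure_interior(model, chain)
  model <- ctx$model; chain <- ctx$chain
  a_all <- .protein_atoms(model)
  sel <- which(a_all$chain == chain)
  fib <- compute_sasa(a_all, probe = probe, n_points = n_points,
                      subset = sel)
  ref <- reference_sasa(model, chain, params, probe = probe,
                        n_points = n_points)
  at <- a_all[sel, ]
  a_fib <- fib$area[sel]
  # reference rows are the same atoms; align by (resid, atom_name)
  m <- match(paste(at$resid, at$atom_name),
             paste(ref$atoms$resid, ref$atoms$atom_name))
  if (anyNA(m)) stop("reference atoms do not match fibril chain atoms")
  a_ref <- ref$area[m]
  cls <- .atom_class(at)
  asp <- params$asp[cls]
  dg_atom <- asp * (a_fib - a_ref)
  per_res <- tapply(dg_atom, at$resid, sum)
  per_res <- setNames(as.numeric(per_res), names(per_res))
  n_res <- length(unique(at$resid))
  structure(list(dg_per_chain = sum(dg_atom),
                 dg_per_residue_mean = sum(dg_atom) / n_res,
                 per_residue = per_res,
                 buried_area_per_atom = a_ref - a_fib,
                 atoms = at[, c("chain", "resid", "resname", "atom_name")],
                 n_ordered_residues = n_res,
                 context_layers = length(model$layers),
                 params = params),
            class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat(sprintf(
    "stabilization energy: %+.2f kcal/mol/chain (%+.3f kcal/mol/residue, %d residues, %d-layer context)\n",
    x$dg_per_chain, x$dg_per_residue_mean, x$n_ordered_residues,
    x$context_layers))
  invisible(x)
}

#' Subunit decomposition of the layer energy
#'
#' Splits the per-layer stabilization energy over residue-span subunits.
#' `in_context`: per-residue terms of the full-model profile summed
#' within each span (additive: sums to the chain total).  `alone`: the
#' model is rebuilt with only that subunit's residues present in every
#' layer and rescored, measuring what the subunit would contribute
#' without its partner.
#'
#' @param model a `fibril_model`.
#' @param chain chain id.
#' @param subunits list of [residue_span()] partitioning the chain's
#'   ordered residues.
#' @param params a [solvation_params()].
#' @param mode `"in_context"` or `"alone"`.
#' @inheritParams compute_sasa
#' @return named numeric vector, kcal/mol per subunit; names from span
#'   labels or `subunit1`, `subunit2`, ...
#' @export
subunit_decomposition <- function(model, chain, subunits,
                                  params = solvation_params(),
                                  mode = c("in_context", "alone"),
                                  probe = 1.4, n_points = 960) {
  mode <- match.arg(mode)
  subunits <- .as_span_list(subunits)
  a <- .protein_atoms(model)
  res <- sort(unique(a$resid[a$chain == chain]))
  covered <- unlist(lapply(subunits, function(s) s$first:s$last))
  in_model <- intersect(covered, res)
  if (anyDuplicated(in_model) || !setequal(in_model, res))
    stop("subunit spans must partition the chain's ordered residues")
  nm <- vapply(seq_along(subunits), function(i) {
    if (nzchar(subunits[[i]]$label)) subunits[[i]]$label
    else paste0("subunit", i)
  }, character(1))
  if (mode == "in_context") {
    prof <- stabilization_energy(model, chain, params, probe, n_points)
    r <- as.integer(names(prof$per_residue))
    out <- vapply(subunits, function(s)
      sum(prof$per_residue[r >= s$first & r <= s$last]), numeric(1))
  } else {
    out <- vapply(subunits, function(s) {
      keep <- model$atoms$resid >= s$first & model$atoms$resid <= s$last
      sub <- fibril_model(model$atoms[keep, ], label = model$label,
                          helical = model$helical)
      stabilization_energy(sub, chain, params, probe,
                           n_points)$dg_per_chain
    }, numeric(1))
  }
  setNames(out, nm)
}

#' Per-residue display values for energy maps
#'
#' Clips per-residue energies to the rendering scale of stabilization
#' maps, [-2.5, +2.5] kcal/mol (red = stabilizing, blue =
#' destabilizing); monotone non-decreasing in the input.
#'
#' @param profile a `stability_profile` or a numeric vector of
#'   per-residue energies.
#' @param limit clip bound in kcal/mol.
#' @return named numeric vector of clipped values.
#' @export
energy_map_values <- function(profile, limit = 2.5) {
  v <- if (inherits(profile, "stability_profile")) profile$per_residue
  else profile
  pmin(pmax(v, -limit), limit)
}

#' Calibrate solvation parameters against reference energies
#'
#' The legacy parameterization behind published per-layer energies is
#' not public; this rescales the whole parameter set by the single
#' factor minimizing the squared difference between computed and
#' reference per-chain energies (least squares through the origin).
#'
#' @param params a [solvation_params()].
#' @param computed numeric vector of per-chain energies computed with
#'   `params`.
#' @param reference corresponding reference energies (same units).
#' @return a rescaled `solvation_params` (name gains a "+calibrated"
#'   suffix); the scale is attached as attribute `"scale"`.
#' @export
calibrate_solvation_params <- function(params, computed, reference) {
  if (length(computed) != length(reference) || length(computed) == 0)
    stop("computed and reference must be equal-length, non-empty")
  s <- sum(reference * computed) / sum(computed^2)
  if (!is.finite(s) || s <= 0)
    stop("calibration failed: non-positive scale")
  out <- params
  out$asp <- params$asp * s
  out$name <- paste0(params$name, "+calibrated")
  attr(out, "scale") <- s
  out
}
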