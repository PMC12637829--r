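# Worm-like chain elasticity and the dual-handle tether model.

.kB <- 0.0138064852  # pN nm / K

#' Worm-like chain parameters
#'
#' @param persistence_length nm.
#' @param contour_length nm.
#' @param temperature K (default 298, giving kT = 4.114 pN nm).
#' @export
wlc_params <- function(persistence_length, contour_length,
                       temperature = 298) {
  if (persistence_length <= 0 || contour_length <= 0 || temperature <= 0)
    stop("WLC parameters must be positive")
  structure(list(persistence_length = persistence_length,
                 contour_length = contour_length,
                 temperature = temperature),
            class = "wlc_params")
}

#' Worm-like chain force at a given extension
#'
#' Marko-Siggia interpolation:
#' `F = (kT/P) * (1 / (4 (1 - x/L)^2) - 1/4 + x/L)`, strictly increasing
#' in `x` on `[0, L)` and divergent at `x = L`.
#'
#' @param x extension in nm, `0 <= x < L` (vectorized).
#' @param params a [wlc_params()].
#' @return force in pN.
#' @export
wlc_force <- function(x, params) {
  L <- params$contour_length
  if (any(x < 0)) stop("extension must be non-negative")
  if (any(x >= L)) stop("extension must be below the contour length")
  kT <- .kB * params$temperature
  z <- x / L
  (kT / params$persistence_length) * (1 / (4 * (1 - z)^2) - 0.25 + z)
}

#' Worm-like chain extension at a given force
#'
#' Unique root of [wlc_force()] on `[0, L)`, bracketed bisection to
#' 1e-10 nm (relative).  Vectorized over `F`; non-positive forces give
#' zero extension.
#'
#' @param F force in pN.
#' @param params a [wlc_params()].
#' @return extension in nm.
#' @export
wlc_extension <- function(F, params) {
  L <- params$contour_length
  vapply(F, function(f) {
    if (f <= 0) return(0)
    L * .wlc_unit_extension(f, params$persistence_length,
                            .kB * params$temperature)
  }, numeric(1))
}

# fractional extension z = x/L at force f for unit contour length
.wlc_unit_extension <- function(f, P, kT) {
  g <- function(z) (kT / P) * (1 / (4 * (1 - z)^2) - 0.25 + z) - f
  upper <- 1 - 1e-12
  if (g(upper) < 0) return(upper)
  uniroot(g, c(0, upper), tol = 1e-14)$root
}

# cached spline of z(F) for a given (P, kT): fast path used by the
# simulator and rip fitting (wlc_extension itself stays exact)
.wlc_cache <- new.env(parent = emptyenv())
.wlc_unit_fun <- function(P, temperature, f_max = 80) {
  key <- sprintf("%.9g|%.9g|%.9g", P, temperature, f_max)
  if (!is.null(.wlc_cache[[key]])) return(.wlc_cache[[key]])
  kT <- .kB * temperature
  fg <- seq(0, f_max, length.out = 4001)
  zg <- vapply(fg, function(f) if (f <= 0) 0
               else .wlc_unit_extension(f, P, kT), numeric(1))
  sf <- splinefun(fg, zg, method = "hyman")
  fun <- function(f, deriv = 0) {
    f <- pmax(f, 0)
    out <- sf(pmin(f, f_max), deriv = deriv)
    out[f > f_max] <- NA_real_
    out
  }
  .wlc_cache[[key]] <- fun
  fun
}

#' Dual-handle tether model
#'
#' The series elastic model of a protein tethered between two dsDNA
#' handles: one WLC for both handles combined (default two 2,000 bp
#' handles at 0.338 nm/bp, contour 1352 nm, persistence 45 nm) plus one
#' WLC for the unfolded part of the protein (0.365 nm/residue contour,
#' 0.65 nm persistence).  `folded_offset` subtracts a fixed end-to-end
#' distance of the folded part (0 by default).
#'
#' @param handle_bp base pairs per handle.
#' @param n_handles number of handles in series.
#' @param nm_per_bp dsDNA rise per base pair, nm.
#' @param handle_persistence nm.
#' @param protein_persistence persistence length of unfolded
#'   polypeptide, nm.
#' @param nm_per_residue contour length gained per unfolded residue, nm.
#' @param folded_offset nm.
#' @param temperature K.
#' @export
tether_model <- function(handle_bp = 2000, n_handles = 2,
                         nm_per_bp = 0.338, handle_persistence = 45,
                         protein_persistence = 0.65,
                         nm_per_residue = 0.365, folded_offset = 0,
                         temperature = 298) {
  structure(list(
    handle = wlc_params(handle_persistence,
                        handle_bp * n_handles * nm_per_bp, temperature),
    protein_persistence = protein_persistence,
    nm_per_residue = nm_per_residue,
    folded_offset = folded_offset,
    temperature = temperature),
    class = "tether_model")
}

#' Tether extension at a given force
#'
#' Series-connected elements add extension at equal force: handle WLC
#' plus an unfolded-protein WLC whose contour length is
#' `n_unfolded_residues * nm_per_residue`, minus the folded offset.
#'
#' @param F force in pN (vectorized).
#' @param tether a [tether_model()].
#' @param n_unfolded_residues number of unfolded residues.
#' @return extension in nm.
#' @export
tether_extension <- function(F, tether, n_unfolded_residues = 0) {
  x <- wlc_extension(F, tether$handle)
  if (n_unfolded_residues > 0) {
    prot <- wlc_params(tether$protein_persistence,
                       n_unfolded_residues * tether$nm_per_residue,
                       tether$temperature)
    x <- x + wlc_extension(F, prot)
  }
  x - tether$folded_offset
}

# fast vectorized tether extension via cached unit-extension splines
.tether_extension_fast <- function(F, tether, n_unfolded_residues = 0) {
  zh <- .wlc_unit_fun(tether$handle$persistence_length,
                      tether$temperature)
  x <- tether$handle$contour_length * zh(F)
  if (n_unfolded_residues > 0) {
    zp <- .wlc_unit_fun(tether$protein_persistence, tether$temperature)
    x <- x + n_unfolded_residues * tether$nm_per_residue * zp(F)
  }
  x - tether$folded_offset
}

#' Convert a contour-length gain to a residue count
#'
#' `round(delta_lc / nm_per_residue)`; the default 0.365 nm/residue is
#' the crystallographic contour length per peptide unit.
#'
#' @param delta_lc contour-length gain in nm (>= 0).
#' @param nm_per_residue nm per residue.
#' @return integer residue count.
#' @export
contour_length_to_residues <- function(delta_lc, nm_per_residue = 0.365) {
  if (any(delta_lc < 0)) stop("delta_lc must be non-negative")
  as.integer(round(delta_lc / nm_per_residue))
}
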