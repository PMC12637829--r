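# Deterministic solvent-accessible surface area.
#
# Sphere-sampling (Shrake-Rupley style) with a fixed quasi-uniform
# Fibonacci point set, so results are bit-reproducible: no RNG anywhere.

#' Quasi-uniform points on the unit sphere
#'
#' Deterministic Fibonacci (golden-angle) lattice.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area
#'
#' For each heavy atom, the fraction of quasi-uniform test points on its
#' probe-expanded sphere that fall outside every other probe-expanded
#' atom sphere, times the full sphere area `4 pi (r + probe)^2`.
#' Hydrogens are excluded by default (both as targets and as occluders).
#'
#' @param model a `fibril_model`, or a data.frame of atoms with columns
#'   `x`, `y`, `z`, `vdw`.
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points points per atom sphere (>= 100); the default 960
#'   keeps quadrature error well under 0.5 percent.
#' @param subset optional logical/integer index of atoms whose area is
#'   wanted; all atoms still occlude.  Areas of atoms outside the subset
#'   are returned as NA.
#' @param include_hydrogens keep hydrogen atoms.
#' @return object of class `sasa_result`: `area` (per-atom, Angstrom^2),
#'   `total`, `probe`, `n_points`.
#' @export
compute_sasa <- function(model, probe = 1.4, n_points = 960,
                         subset = NULL, include_hydrogens = FALSE) {
  atoms <- if (inherits(model, "fibril_model")) {
    a <- model$atoms
    if (!include_hydrogens) a <- a[!a$hydrogen, ]
    a
  } else model
  if (probe <= 0) stop("probe radius must be positive")
  if (n_points < 100) stop("need at least 100 sphere points")
  xyz <- .coords(atoms)
  n <- nrow(xyz)
  if (n == 0L) stop("no atoms")
  if (anyDuplicated(round(xyz, 6)))
    stop("duplicate atom coordinates")
  rr <- atoms$vdw + probe
  want <- rep(FALSE, n)
  if (is.null(subset)) want[] <- TRUE else want[subset] <- TRUE
  pts <- sphere_points(n_points)
  area <- rep(NA_real_, n)
  for (i in which(want)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rr + rr[i])^2 & d2 > 0)
    p <- pts * rr[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
        (p[free, 3] - xyz[j, 3])^2
      free[free] <- dj >= rr[j]^2
    }
    area[i] <- mean(free) * 4 * pi * rr[i]^2
  }
  structure(list(area = area, total = sum(area, na.rm = TRUE),
                 probe = probe, n_points = n_points,
                 atoms = atoms[, intersect(c("chain", "resid", "resname",
                                             "atom_name", "element"),
                                           names(atoms))]),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("SASA: %.1f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, sum(!is.na(x$area)), x$probe, x$n_points))
  invisible(x)
}
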