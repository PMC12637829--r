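# Seeded generators for ground-truth-bearing inputs: idealized
# cross-beta fibril coordinate models and quasi-static force-extension
# curves.  All randomness flows through the seed carried in the spec.

#' Specification of an idealized cross-beta fibril
#'
#' @param sequence one-letter protein sequence; its length fixes the
#'   number of residues per layer.
#' @param path `"linear"`, `"U_bend"`, `"S_fold"`, or an n x 2 matrix of
#'   in-plane C-alpha coordinates (Angstrom).
#' @param rise,twist helical symmetry of the stack (Angstrom, degrees).
#' @param n_layers number of layers (>= 1).
#' @param warp `NULL` or `list(amplitude = , period = )`: sinusoidal
#'   out-of-plane C-alpha displacement (Angstrom; period in residues)
#'   applied to the layer before stacking.
#' @param noise_sigma isotropic Gaussian coordinate noise, Angstrom.
#' @param seed integer seed for the noise.
#' @param first_resid author residue number of the first residue.
#' @param ca_spacing C-alpha spacing along the path, Angstrom.
#' @export
ideal_fibril_spec <- function(sequence, path = "U_bend", rise = 4.8,
                              twist = -1.5, n_layers = 5, warp = NULL,
                              noise_sigma = 0, seed = 1, first_resid = 1,
                              ca_spacing = 3.8) {
  sequence <- toupper(sequence)
  if (!all(strsplit(sequence, "")[[1]] %in% .aa1))
    stop("invalid residue letters in sequence")
  if (n_layers < 1) stop("n_layers must be >= 1")
  if (!is.null(warp)) {
    if (is.null(warp$amplitude) || is.null(warp$period) ||
        warp$amplitude < 0 || warp$period <= 0)
      stop("warp must be list(amplitude >= 0, period > 0)")
  }
  structure(list(sequence = sequence, path = path, rise = rise,
                 twist = twist, n_layers = n_layers, warp = warp,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 first_resid = as.integer(first_resid),
                 ca_spacing = ca_spacing),
            class = "ideal_fibril_spec")
}

# in-plane CA trace for the named templates, sampled at fixed arc-length
# spacing; bend radius 4 A keeps arms dominant
.layer_path <- function(template, n, spacing) {
  if (is.matrix(template)) {
    if (nrow(template) != n) stop("path matrix must have one row per residue")
    return(template)
  }
  s <- (seq_len(n) - 1) * spacing
  total <- (n - 1) * spacing
  r <- 4
  if (template == "linear") {
    return(cbind(s, rep(0, n)))
  }
  if (template == "U_bend") {
    arm <- (total - pi * r) / 2
    if (arm <= 0) stop("chain too short for a U_bend path")
    t(vapply(s, function(si) {
      if (si <= arm) c(si, 0)
      else if (si <= arm + pi * r) {
        th <- (si - arm) / r
        c(arm + r * sin(th), r - r * cos(th))
      } else c(arm - (si - arm - pi * r), 2 * r)
    }, numeric(2)))
  } else if (template == "S_fold") {
    arm <- (total - 2 * pi * r) / 3
    if (arm <= 0) stop("chain too short for an S_fold path")
    t(vapply(s, function(si) {
      if (si <= arm) c(si, 0)
      else if (si <= arm + pi * r) {
        th <- (si - arm) / r
        c(arm + r * sin(th), r - r * cos(th))
      } else if (si <= 2 * arm + pi * r) {
        c(arm - (si - arm - pi * r), 2 * r)
      } else if (si <= 2 * arm + 2 * pi * r) {
        th <- (si - 2 * arm - pi * r) / r
        c(-r * sin(th), 2 * r + r - r * cos(th))
      } else c(si - 2 * arm - 2 * pi * r, 4 * r)
    }, numeric(2)))
  } else stop("unknown path template: ", template)
}

#' Generate an idealized cross-beta fibril with known ground truth
#'
#' Places C-alpha atoms on the in-plane path, adds N, C, O and C-beta by
#' idealized cross-beta local geometry (backbone hydrogen-bond donors
#' and acceptors pointing along the stacking axis, side chains
#' alternating above and below the sheet), applies the optional
#' sinusoidal out-of-plane warp, stacks `n_layers` copies with
#' [build_helical_stack()], and finally adds seeded Gaussian coordinate
#' noise.
#'
#' @param spec an [ideal_fibril_spec()].
#' @return list with `model` (a `fibril_model`) and `truth`: the exact
#'   `rise`, `twist`, per-residue warp displacement `warp_dz`, its RMS
#'   `warp_rms` (the RMS out-of-plane displacement of the warped layer),
#'   `seed` and the generating `spec`.
#' @export
make_ideal_fibril <- function(spec) {
  aa <- strsplit(spec$sequence, "")[[1]]
  n <- length(aa)
  if (n < 3) stop("need at least 3 residues")
  P <- .layer_path(spec$path, n, spec$ca_spacing)
  resname <- .aa3[match(aa, .aa1)]
  # local frames along the path
  rows <- vector("list", n)
  z <- c(0, 0, 1)
  for (i in seq_len(n)) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    t2 <- .unit(c(P[hi, ] - P[lo, ], 0))
    u <- pracma_cross(z, t2)
    alt <- if (i %% 2 == 1) 1 else -1
    ca <- c(P[i, ], 0)
    atoms <- rbind(
      N  = ca - 1.20 * t2 + 0.83 * alt * z,
      CA = ca,
      C  = ca + 1.25 * t2 - 0.87 * alt * z,
      O  = ca + 1.25 * t2 - 0.87 * alt * z - 1.23 * alt * z,
      CB = ca + 1.53 * (0.55 * alt * z + 0.835 * u))
    nm <- rownames(atoms)
    if (resname[i] == "GLY") {
      atoms <- atoms[nm != "CB", , drop = FALSE]
      nm <- nm[nm != "CB"]
    }
    rows[[i]] <- data.frame(
      chain = "A", resid = spec$first_resid + i - 1L,
      resname = resname[i], atom_name = nm,
      element = substr(nm, 1, 1),
      x = atoms[, 1], y = atoms[, 2], z = atoms[, 3],
      stringsAsFactors = FALSE)
  }
  a <- do.call(rbind, rows)
  rownames(a) <- NULL
  # out-of-plane warp, per residue, before stacking
  dz <- rep(0, n)
  if (!is.null(spec$warp))
    dz <- spec$warp$amplitude * sin(2 * pi * (seq_len(n) - 1) /
                                      spec$warp$period)
  a$z <- a$z + dz[a$resid - spec$first_resid + 1L]
  layer <- fibril_model(a, label = "synthetic")
  model <- build_helical_stack(layer, spec$rise, spec$twist,
                               spec$n_layers,
                               axis = fibril_axis(colMeans(.coords(a)),
                                                  c(0, 0, 1)))
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    m <- as.matrix(model$atoms[, c("x", "y", "z")])
    model$atoms[, c("x", "y", "z")] <-
      m + rnorm(length(m), 0, spec$noise_sigma)
  }
  truth <- list(rise = spec$rise, twist = spec$twist,
                warp_dz = dz, warp_rms = sqrt(mean((dz - mean(dz))^2)),
                seed = spec$seed, spec = spec)
  list(model = model, truth = truth)
}

#' Specification of a simulated force-extension experiment
#'
#' @param segments data.frame with columns `n_residues` and
#'   `rupture_force` (pN): the structured segments that unfold during
#'   the stretch, or `NULL` for a tether-only pull.
#' @param tether a [tether_model()].
#' @param force_window c(min, max) pN of the pull (default 2-35 pN).
#' @param samples_per_nm sampling density along the extension axis.
#' @param noise_sigma additive Gaussian force noise, pN.
#' @param seed integer seed.
#' @param pulling_speed nm/s (metadata only; pulls are quasi-static).
#' @export
fec_sim_spec <- function(segments = NULL, tether = tether_model(),
                         force_window = c(2, 35), samples_per_nm = 10,
                         noise_sigma = 0.2, seed = 1,
                         pulling_speed = 100) {
  if (is.null(segments))
    segments <- data.frame(n_residues = integer(),
                           rupture_force = numeric())
  if (nrow(segments)) {
    if (any(segments$n_residues < 1)) stop("segment sizes must be >= 1")
    if (any(segments$rupture_force <= force_window[1] |
              segments$rupture_force >= force_window[2]))
      stop("rupture forces must lie inside the force window")
  }
  structure(list(segments = segments, tether = tether,
                 force_window = force_window,
                 samples_per_nm = samples_per_nm,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 pulling_speed = pulling_speed),
            class = "fec_sim_spec")
}

#' Simulate a quasi-static dual-handle pull
#'
#' Stretch and relax branches of a tethered-protein pull.  During the
#' stretch, each structured segment unfolds (its residues join the
#' unfolded contour) when the force first exceeds its rupture force; no
#' refolding occurs on the relax branch.  Gaussian force noise is added
#' with the spec's seed; the output is deterministic given the seed.
#'
#' @param spec a [fec_sim_spec()].
#' @return list with `stretch` and `relax`
#'   ([force_extension_curve()]s) and `truth` (segment table in
#'   unfolding order with per-segment contour gain `delta_lc` and the
#'   extension `x_unfold` at which each unfolds).
#' @export
simulate_fec <- function(spec) {
  tether <- spec$tether
  seg <- spec$segments
  ord <- order(seg$rupture_force)
  seg <- seg[ord, , drop = FALSE]
  k <- nrow(seg)
  n_unf <- cumsum(c(0, seg$n_residues))  # per state 0..k
  fw <- spec$force_window
  # state transitions: extension at which branch s reaches the next
  # rupture force (cummax handles cascades)
  xt <- if (k) vapply(seq_len(k), function(s)
    .tether_extension_fast(seg$rupture_force[s], tether, n_unf[s]),
    numeric(1)) else numeric()
  xt <- cummax(xt)
  x_lo <- .tether_extension_fast(fw[1], tether, n_unf[1])
  x_hi <- .tether_extension_fast(fw[2], tether, n_unf[k + 1])
  x <- seq(x_lo, x_hi, by = 1 / spec$samples_per_nm)
  state <- findInterval(x, xt) + 1L   # 1-based index into n_unf
  fg <- seq(fw[1] * 0.5, fw[2], length.out = 4001)
  F <- numeric(length(x))
  for (s in unique(state)) {
    xs <- .tether_extension_fast(fg, tether, n_unf[s])
    sel <- state == s
    F[sel] <- approx(xs, fg, xout = x[sel], rule = 2)$y
  }
  set.seed(spec$seed)
  Fn <- F + rnorm(length(F), 0, spec$noise_sigma)
  # relax: fully unfolded, descending force, no refolding
  xr <- rev(x[x >= .tether_extension_fast(fw[1], tether, n_unf[k + 1])])
  if (length(xr) < 10) xr <- rev(x)
  xs_full <- .tether_extension_fast(fg, tether, n_unf[k + 1])
  Fr <- approx(xs_full, fg, xout = xr, rule = 2)$y +
    rnorm(length(xr), 0, spec$noise_sigma)
  truth <- cbind(seg,
                 delta_lc = seg$n_residues * tether$nm_per_residue,
                 x_unfold = if (k) xt else numeric())
  list(stretch = force_extension_curve(x, Fn, spec$pulling_speed,
                                       "stretch"),
       relax = force_extension_curve(xr, Fr, spec$pulling_speed,
                                     "relax"),
       truth = truth)
}
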