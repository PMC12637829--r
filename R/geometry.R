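# Fibril-axis estimation, helical parameters, layer-plane statistics and
# rigid superposition.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' Fibril axis
#'
#' @param anchor 3-vector, a point on the axis (Angstrom).
#' @param direction 3-vector; normalized internally.
#' @export
fibril_axis <- function(anchor, direction) {
  structure(list(anchor = as.numeric(anchor),
                 direction = .unit(as.numeric(direction))),
            class = "fibril_axis")
}

#' Estimate the fibril axis from layer centroids
#'
#' Least-squares line through the per-layer C-alpha centroids, oriented
#' from the first to the last layer.
#'
#' @param model a `fibril_model` with at least two chains.
#' @return a [fibril_axis()].
#' @export
estimate_axis <- function(model) {
  a <- .protein_atoms(model)
  chains <- if (!is.null(model$layers)) model$layers else unique(a$chain)
  if (length(chains) < 2L) stop("need >= 2 layers to estimate an axis")
  cent <- .chain_centroids(a, chains)
  mu <- colMeans(cent)
  sv <- svd(sweep(cent, 2, mu))
  dir <- sv$v[, 1]
  span <- cent[nrow(cent), ] - cent[1, ]
  if (sum(dir * span) < 0) dir <- -dir
  fibril_axis(mu, dir)
}

#' Best-fit plane through a point cloud
#'
#' Plane minimizing the sum of squared orthogonal distances (normal =
#' smallest principal direction of the centered cloud).
#'
#' @param points n x 3 matrix, n >= 3, not collinear.
#' @return list with `plane` (fields `normal`, `offset`) and `rmsd`, the
#'   root-mean-square orthogonal distance in Angstrom.
#' @export
best_fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need >= 3 points")
  mu <- colMeans(points)
  sv <- svd(sweep(points, 2, mu))
  # collinear (or coincident) clouds have no unique plane
  if (sv$d[2] < max(sv$d[1], 1) * 1e-9)
    stop("degenerate point cloud: points are collinear")
  normal <- .unit(sv$v[, 3])
  d <- sweep(points, 2, mu) %*% normal
  list(plane = list(normal = normal, offset = sum(normal * mu)),
       rmsd = sqrt(mean(d^2)))
}

.plane_rms <- function(points, normal, through) {
  d <- sweep(as.matrix(points), 2, through) %*% .unit(normal)
  sqrt(mean(d^2))
}

#' Layer warping RMSD
#'
#' The two layer-planarity statistics of a fibril polymorph: the RMS
#' orthogonal distance of core C-alpha atoms of one layer (the central
#' chain by default) (i) from the plane normal to the fibril axis through
#' their centroid, and (ii) from the least-squares best-fit plane.  By
#' construction the best-fit value is never larger than the normal-plane
#' value.
#'
#' @param model a `fibril_model`.
#' @param chain chain id; defaults to the central layer (the model is
#'   layer-ordered on the fly if needed).
#' @param axis a [fibril_axis()]; estimated when `NULL`.
#' @param core list of [residue_span()]; defaults to the chain's ordered
#'   spans.
#' @return object of class `warping_result` with `rmsd_normal_plane`,
#'   `rmsd_best_fit`, `n_calpha`, `chain`.
#' @export
warping_rmsd <- function(model, chain = NULL, axis = NULL, core = NULL) {
  if (is.null(model$layers)) model <- order_layers(model, axis)
  if (is.null(axis)) axis <- estimate_axis(model)
  if (is.null(chain)) chain <- model$layers[model$central]
  if (is.null(core)) core <- ordered_spans(model, chain)
  core <- .as_span_list(core)
  a <- .protein_atoms(model)
  a <- a[a$chain == chain & a$atom_name == "CA", ]
  keep <- rep(FALSE, nrow(a))
  for (s in core) keep <- keep | (a$resid >= s$first & a$resid <= s$last)
  want <- sum(vapply(core, function(s) s$last - s$first + 1L, integer(1)))
  if (sum(keep) < want)
    warning(sprintf("%d core residues lack a CA atom and were skipped",
                    want - sum(keep)))
  pts <- .coords(a[keep, ])
  if (nrow(pts) < 3L) stop("fewer than 3 core CA atoms in chain ", chain)
  bf <- best_fit_plane(pts)
  res <- list(rmsd_normal_plane = .plane_rms(pts, axis$direction,
                                             colMeans(pts)),
              rmsd_best_fit = bf$rmsd,
              n_calpha = nrow(pts), chain = chain)
  class(res) <- "warping_result"
  res
}

#' @export
print.warping_result <- function(x, ...) {
  cat(sprintf(
    "warping RMSD (chain %s, %d CA): normal-plane %.2f A, best-fit %.2f A\n",
    x$chain, x$n_calpha, x$rmsd_normal_plane, x$rmsd_best_fit))
  invisible(x)
}

#' Helical parameters
#'
#' Rise (Angstrom) and signed twist (degrees) per layer.  The sign
#' convention is the right-hand rule about the axis oriented from the
#' first to the last layer; positive twist is right-handed.
#'
#' @param rise Angstrom per layer, > 0.
#' @param twist degrees per layer, signed.
#' @param rise_sd,twist_sd optional spread over consecutive layer pairs.
#' @export
helical_params <- function(rise, twist, rise_sd = NA_real_,
                           twist_sd = NA_real_) {
  if (rise <= 0) stop("rise must be positive")
  structure(list(rise = rise, twist = twist,
                 handedness = handedness(twist),
                 rise_sd = rise_sd, twist_sd = twist_sd),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("helical_params: rise %.3f A, twist %.3f deg, %s-handed\n",
              x$rise, x$twist, x$handedness))
  invisible(x)
}

#' Twist handedness
#'
#' Positive twist is right-handed, negative left-handed, zero undefined
#' (right-hand-rule convention about the first-to-last layer axis).
#'
#' @param params a [helical_params()] or a bare twist in degrees.
#' @export
handedness <- function(params) {
  twist <- if (inherits(params, "helical_params")) params$twist else params
  if (twist > 0) "right" else if (twist < 0) "left" else "undefined"
}

#' Crossover length of a twisted fibril
#'
#' Length along the fibril over which the helix completes a half turn:
#' `rise * 180 / |twist|`.
#'
#' @param params a [helical_params()].
#' @return crossover distance in Angstrom.
#' @export
crossover_length <- function(params) {
  if (params$twist == 0) stop("crossover is undefined for zero twist")
  params$rise * 180 / abs(params$twist)
}

# rotation matrix for angle degrees about unit axis u (Rodrigues)
.rotation_about <- function(u, angle_deg) {
  u <- .unit(u)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.next_chain_ids <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)]
  else c(LETTERS, as.vector(outer(LETTERS, LETTERS, paste0)))[seq_len(n)]
}

#' Build a helical stack from a single layer
#'
#' Layer k is the input layer rotated by `k * twist` about the axis and
#' translated by `k * rise` along it; chain ids are generated
#' deterministically (A, B, C, ...).
#'
#' @param layer a single-chain `fibril_model`.
#' @param rise Angstrom per layer.
#' @param twist degrees per layer (signed, right-hand rule about the
#'   axis direction).
#' @param n_layers number of layers (>= 1).
#' @param axis a [fibril_axis()]; default z axis through the layer's
#'   centroid.
#' @return a layer-ordered `fibril_model` with `helical` set.
#' @export
build_helical_stack <- function(layer, rise, twist, n_layers,
                                axis = NULL) {
  if (n_layers < 1) stop("n_layers must be >= 1")
  a <- layer$atoms
  if (length(unique(a$chain[!a$het])) != 1L)
    stop("layer must contain exactly one protein chain")
  if (is.null(axis))
    axis <- fibril_axis(colMeans(.coords(.protein_atoms(layer))), c(0, 0, 1))
  ids <- .next_chain_ids(n_layers)
  xyz0 <- sweep(.coords(a), 2, axis$anchor)
  stack <- do.call(rbind, lapply(seq_len(n_layers) - 1L, function(k) {
    R <- .rotation_about(axis$direction, k * twist)
    xyz <- xyz0 %*% t(R)
    xyz <- sweep(xyz, 2, axis$anchor + k * rise * axis$direction, "+")
    ak <- a
    ak$chain <- ids[k + 1L]
    ak[, c("x", "y", "z")] <- xyz
    ak
  }))
  fibril_model(stack, label = layer$label,
               helical = helical_params(rise, twist),
               layers = ids, central = ceiling(n_layers / 2))
}

# Kabsch: proper-rotation least-squares fit of X onto Y (n x 3 each).
# Returns R, t with Y ~ X %*% t(R) + t, plus the rmsd after fitting.
.kabsch <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  mx <- colMeans(X); my <- colMeans(Y)
  H <- crossprod(sweep(X, 2, mx), sweep(Y, 2, my))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- my - as.numeric(R %*% mx)
  fit <- sweep(X %*% t(R), 2, t, "+")
  list(rotation = R, translation = t,
       rmsd = sqrt(mean(rowSums((fit - Y)^2))))
}

# screw decomposition of the transform x -> R x + t relative to a
# reference direction d: signed angle and rise along d
.screw <- function(R, t, d) {
  ang <- acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  if (ang < 1e-9)
    return(list(twist = 0, rise = sum(t * d)))
  u <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sqrt(sum(u^2)) < 1e-9) {      # angle ~ 180 deg: axis from R + I
    M <- R + diag(3)
    u <- M[, which.max(colSums(M^2))]
  }
  u <- .unit(u)
  s <- if (sum(u * d) >= 0) 1 else -1
  list(twist = s * ang, rise = s * sum(t * u))
}

#' Measure helical rise and twist of a stack
#'
#' Least-squares rigid transform (Kabsch) mapping each layer onto the
#' next, decomposed into a screw motion about the fibril axis; values
#' are averaged over consecutive layer pairs and the spread is reported.
#' Layers must have identical residue/atom composition.
#'
#' @param model a `fibril_model` with >= 2 layers.
#' @param axis optional [fibril_axis()] fixing the sign reference.
#' @return a [helical_params()].
#' @export
measure_rise_twist <- function(model, axis = NULL) {
  if (is.null(model$layers)) model <- order_layers(model, axis)
  if (length(model$layers) < 2L) stop("need >= 2 layers")
  if (is.null(axis)) axis <- estimate_axis(model)
  a <- .protein_atoms(model)
  key <- function(df) paste(df$resid, df$atom_name)
  ref <- a[a$chain == model$layers[1], ]
  ref <- ref[order(ref$resid, ref$atom_name), ]
  pairs <- lapply(seq_len(length(model$layers) - 1L), function(k) {
    A <- a[a$chain == model$layers[k], ]
    B <- a[a$chain == model$layers[k + 1L], ]
    A <- A[order(A$resid, A$atom_name), ]
    B <- B[order(B$resid, B$atom_name), ]
    if (!identical(key(A), key(B)))
      stop("layers ", k, " and ", k + 1, " have non-identical composition")
    kb <- .kabsch(.coords(A), .coords(B))
    .screw(kb$rotation, kb$translation, axis$direction)
  })
  tw <- vapply(pairs, `[[`, numeric(1), "twist")
  ri <- vapply(pairs, `[[`, numeric(1), "rise")
  helical_params(mean(ri), mean(tw),
                 rise_sd = if (length(ri) > 1) sd(ri) else NA_real_,
                 twist_sd = if (length(tw) > 1) sd(tw) else NA_real_)
}

#' Rigid superposition of two residue segments
#'
#' Optimal proper-rotation least-squares superposition (Kabsch) of the
#' shared backbone atoms (N, CA, C, O) of two equal-length residue
#' spans; residues are paired by offset within the spans.
#'
#' @param model_a,model_b `fibril_model`s.
#' @param span_a,span_b [residue_span()]s of equal length.
#' @param chain_a,chain_b chain ids.
#' @return object of class `superposition_result`: `rotation` (3x3,
#'   det +1), `translation`, `rmsd`, `n_atoms`.  The transform maps
#'   segment a onto segment b.
#' @export
segment_rmsd <- function(model_a, span_a, chain_a,
                         model_b, span_b, chain_b) {
  if ((span_a$last - span_a$first) != (span_b$last - span_b$first))
    stop("spans must cover equal numbers of residues")
  bb <- c("N", "CA", "C", "O")
  get <- function(model, span, chain) {
    a <- .protein_atoms(model)
    a[a$chain == chain & a$resid >= span$first & a$resid <= span$last &
        a$atom_name %in% bb, ]
  }
  A <- get(model_a, span_a, chain_a)
  B <- get(model_b, span_b, chain_b)
  A$off <- A$resid - span_a$first
  B$off <- B$resid - span_b$first
  ka <- paste(A$off, A$atom_name)
  kb <- paste(B$off, B$atom_name)
  shared <- intersect(ka, kb)
  if (length(shared) == 0L || length(shared) < 3L)
    stop("fewer than 3 shared backbone atoms between the segments")
  A <- A[match(shared, ka), ]
  B <- B[match(shared, kb), ]
  if (nrow(A) != nrow(B)) stop("atom-count mismatch after intersection")
  kb_ <- .kabsch(.coords(A), .coords(B))
  structure(list(rotation = kb_$rotation, translation = kb_$translation,
                 rmsd = kb_$rmsd, n_atoms = nrow(A)),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition over %d backbone atoms: rmsd %.3f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}
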