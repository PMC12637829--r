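# Independent oracles and small fixture builders used across the suite.

# atom-table builder for hand-made models
make_atoms <- function(chain, resid, atom_name, xyz, resname = "ALA",
                       element = substr(atom_name, 1, 1)) {
  data.frame(chain = chain, resid = as.integer(resid), resname = resname,
             atom_name = atom_name, element = element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

# a planar CA-only layer: n residues on a 2D arc so points are
# non-collinear
ca_layer <- function(n = 24, chain = "A", z = 0) {
  th <- seq(0, pi, length.out = n)
  xyz <- cbind(12 * cos(th), 12 * sin(th), rep(z, n))
  fibril_model(make_atoms(chain, seq_len(n), "CA", xyz))
}

rotate_model <- function(model, R, shift = c(0, 0, 0)) {
  m <- as.matrix(model$atoms[, c("x", "y", "z")])
  model$atoms[, c("x", "y", "z")] <- sweep(m %*% t(R), 2, shift, "+")
  model
}

rotation_xyz <- function(ax, ay, az) {
  cx <- cos(ax); sx <- sin(ax)
  cy <- cos(ay); sy <- sin(ay)
  cz <- cos(az); sz <- sin(az)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# brute-force best-fit plane: coarse grid over normals followed by
# Nelder-Mead refinement of the spherical angles; rmsd uses the optimal
# (mean-projection) offset for each normal
brute_force_plane_rmsd <- function(points) {
  points <- as.matrix(points)
  rms_for <- function(ang) {
    n <- c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]),
           cos(ang[1]))
    d <- points %*% n
    sqrt(mean((d - mean(d))^2))
  }
  grid <- expand.grid(th = seq(0, pi, length.out = 60),
                      ph = seq(0, pi, length.out = 60))
  vals <- apply(grid, 1, rms_for)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- optim(best, rms_for, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# Horn's quaternion method for optimal rigid superposition (independent
# of the SVD route used by the package)
quaternion_rmsd <- function(X, Y) {
  X <- sweep(as.matrix(X), 2, colMeans(X))
  Y <- sweep(as.matrix(Y), 2, colMeans(Y))
  S <- crossprod(X, Y)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[3, 1] + S[1, 3]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(X^2) + sum(Y^2) - 2 * lam) / nrow(X)
  sqrt(max(0, msd))
}

# exact accessible areas of two overlapping probe-expanded spheres
two_sphere_areas <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(c(4 * pi * R1^2, 4 * pi * R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  c(4 * pi * R1^2 - 2 * pi * R1 * h1, 4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# the synthetic single-rip cohort used for recovery properties: rip
# sizes span the 20-200 residue range seen in pulling experiments;
# small rips are paired with the higher rupture forces at which their
# force drop is instrumentally resolvable
recovery_cohort_case <- function(s) {
  set.seed(s + 1000)
  nres <- sample(20:200, 1)
  fr <- if (nres < 80) runif(1, 10, 15) else runif(1, 6, 14)
  list(n_residues = nres, rupture_force = fr)
}
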