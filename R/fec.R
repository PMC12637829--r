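# Force-extension curves, unfolding-rip detection and summaries.

#' Force-extension curve
#'
#' One stretch (or relax) trace of a dual-handle optical-tweezers pull:
#' extension in nm (monotone in trap position) and force in pN.
#'
#' @param extension numeric vector, nm.
#' @param force numeric vector, pN.
#' @param pulling_speed nm/s (metadata).
#' @param direction `"stretch"` or `"relax"`.
#' @export
force_extension_curve <- function(extension, force, pulling_speed = 100,
                                  direction = c("stretch", "relax")) {
  direction <- match.arg(direction)
  if (length(extension) != length(force) || length(force) < 10L)
    stop("extension and force must be equal-length vectors of >= 10 points")
  structure(list(extension = as.numeric(extension),
                 force = as.numeric(force),
                 pulling_speed = pulling_speed, direction = direction),
            class = "fec")
}

#' @export
print.fec <- function(x, ...) {
  cat(sprintf("force-extension curve (%s): %d points, %.1f-%.1f nm, %.1f-%.1f pN\n",
              x$direction, length(x$force), min(x$extension),
              max(x$extension), min(x$force), max(x$force)))
  invisible(x)
}

#' Read/write a force-extension curve as TSV
#'
#' Two columns: `extension_nm`, `force_pN`.
#'
#' @param path file path.
#' @param direction stretch or relax.
#' @rdname fec_io
#' @export
read_fec <- function(path, direction = "stretch") {
  d <- read.table(path, header = TRUE, sep = "\t")
  force_extension_curve(d$extension_nm, d$force_pN, direction = direction)
}

#' @param fec a [force_extension_curve()].
#' @rdname fec_io
#' @export
write_fec <- function(fec, path) {
  write.table(data.frame(extension_nm = fec$extension,
                         force_pN = fec$force),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# running mean of width w (centered; shrinking windows at the ends)
.runmean <- function(x, w) {
  n <- length(x)
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# slope-corrected step statistic: for each candidate last-pre-rip index
# j, a line is fitted to the nfit samples ending at j and the statistic
# is the mean shortfall of the next w samples below that line's
# extrapolation.  Positive values measure an abrupt force drop net of
# the local loading slope.
.step_stat <- function(F, w, nfit) {
  n <- length(F)
  out <- rep(NA_real_, n)
  if (n < nfit + w + 1) return(out)
  t0 <- seq_len(nfit) - (nfit + 1) / 2          # centered abscissa
  sxx <- sum(t0^2)
  cs <- cumsum(c(0, F))
  csw <- cumsum(c(0, F * seq_len(n)))
  for (j in nfit:(n - w)) {
    i0 <- j - nfit + 1L
    m <- (cs[j + 1] - cs[i0]) / nfit
    # slope via centered weights: sum(t0 * F[i0:j]) / sxx
    sw <- csw[j + 1] - csw[i0] - (i0 + (nfit - 1) / 2) * (cs[j + 1] - cs[i0])
    b <- sw / sxx
    pred <- m + b * ((nfit + 1) / 2 + (1:w) - 1)  # extrapolated to j+1..j+w
    out[j] <- mean(pred - F[(j + 1):(j + w)])
  }
  out
}

# protein contour length fit for one branch, in force space: extension
# is the clean trap coordinate and the noise lives in the force, so the
# least-squares residual is F_i - F_model(x_i; Lp).  One free parameter;
# deliberately unclamped at 0 (clamping would bias contour-length
# differences between branches when the true pre-rip value is 0).
.fit_branch_lp <- function(x, F, tether, f_floor = 1) {
  if (length(x) < 10) return(NA_real_)
  zh <- .wlc_unit_fun(tether$handle$persistence_length, tether$temperature)
  zp <- .wlc_unit_fun(tether$protein_persistence, tether$temperature)
  Lh <- tether$handle$contour_length
  fg <- seq(f_floor / 2, 60, length.out = 1500)
  xh <- Lh * zh(fg) - tether$folded_offset
  xp <- zp(fg)
  sse <- function(lp) {
    Fm <- approx(xh + lp * xp, fg, xout = x, rule = 2)$y
    sum((F - Fm)^2)
  }
  lp_max <- diff(range(x)) + 50
  opt <- optimize(sse, c(-20, lp_max), tol = 1e-4)
  opt$minimum
}

#' Detect unfolding rips in a stretch curve
#'
#' A rip is an abrupt force drop while the trap position keeps
#' increasing.  Drops larger than `max(4 * noise_sigma, 0.5)` pN over a
#' `window`-sample span of the smoothed trace split the curve into
#' branches; each branch is fitted with the tether model (single free
#' parameter: unfolded protein contour length), the contour-length gain
#' between consecutive branches gives the rip size, and the rupture
#' force is the fitted pre-rip branch force at the rupture point.
#' Events are returned in order of increasing rupture force (the order
#' they occur in a quasi-static pull).
#'
#' @param fec a stretch-direction [force_extension_curve()].
#' @param noise_sigma force noise s.d. in pN.
#' @param tether a [tether_model()].
#' @param window smoothing / drop-detection span in samples.
#' @return list of rip events, each with `rupture_force` (pN),
#'   `extension_change` (nm), `delta_contour_length` (nm), `n_residues`;
#'   class `rip_events`.
#' @export
detect_rips <- function(fec, noise_sigma = 0, tether = tether_model(),
                        window = 5) {
  if (fec$direction != "stretch")
    stop("rip detection expects a stretch-direction curve")
  x <- fec$extension
  F <- fec$force
  if (any(diff(x) < 0)) stop("non-monotone trap positions")
  n <- length(F)
  thr <- max(4 * noise_sigma, 0.5)
  nfit <- max(3 * window, 15)
  st <- .step_stat(F, window, nfit)
  hit <- which(!is.na(st) & st > thr)
  if (length(hit) == 0L) return(structure(list(), class = "rip_events"))
  # contiguous hits belong to one event; the rupture index is the hit
  # with the largest step (the last pre-drop sample)
  grp <- cumsum(c(TRUE, diff(hit) > window))
  i_rup <- vapply(split(hit, grp), function(ix) ix[which.max(st[ix])],
                  numeric(1))
  # branches between successive drops (trim the drop transient)
  starts <- c(1, pmin(i_rup + window + 1, n))
  ends <- c(i_rup, n)
  zp <- .wlc_unit_fun(tether$protein_persistence, tether$temperature)
  lps <- vapply(seq_along(starts), function(b) {
    sel <- starts[b]:ends[b]
    .fit_branch_lp(x[sel], F[sel], tether)
  }, numeric(1))
  events <- list()
  for (k in seq_along(i_rup)) {
    lp_pre <- lps[k]; lp_post <- lps[k + 1]
    if (is.na(lp_pre) || is.na(lp_post)) next
    dlc <- lp_post - lp_pre
    if (dlc <= 0) next
    # pre-rip branch force as a function of extension
    n_res_pre <- max(0, lp_pre) / tether$nm_per_residue
    fg <- seq(0.25, 70, length.out = 2000)
    xg <- .tether_extension_fast(fg, tether, n_res_pre)
    branch_f <- function(xq) approx(xg, fg, xout = xq, rule = 2)$y
    # refine the rupture point: the last sample around the detected
    # index whose force still tracks the pre-rip branch
    win <- max(1, i_rup[k] - window):min(n, i_rup[k] + window)
    on_branch <- abs(F[win] - branch_f(x[win])) <=
      3 * noise_sigma + 0.05
    j_rup <- if (any(on_branch)) win[max(which(on_branch))] else i_rup[k]
    f_rup <- branch_f(x[j_rup])
    events[[length(events) + 1]] <- list(
      rupture_force = f_rup,
      extension_change = dlc * zp(f_rup),
      delta_contour_length = dlc,
      n_residues = contour_length_to_residues(dlc, tether$nm_per_residue))
  }
  if (length(events))
    events <- events[order(vapply(events, `[[`, numeric(1),
                                  "rupture_force"))]
  structure(events, class = "rip_events")
}

#' @export
print.rip_events <- function(x, ...) {
  if (length(x) == 0) {
    cat("no unfolding rips detected\n")
    return(invisible(x))
  }
  cat(sprintf("%d unfolding rip(s):\n", length(x)))
  for (e in x)
    cat(sprintf("  %6.2f pN  dLc %6.2f nm  ~%d residues\n",
                e$rupture_force, e$delta_contour_length, e$n_residues))
  invisible(x)
}

#' Summarize rips over a cohort of stretches
#'
#' @param events_per_stretch list (one element per stretch) of
#'   `rip_events` (possibly empty).
#' @param bin_width histogram bin width in residues.
#' @return object of class `rip_summary`: `fraction_with_rip`,
#'   `histogram` (data.frame bin_lo, bin_hi, fraction; fractions sum to
#'   1 over all detected rips), `scatter` (data.frame stretch,
#'   rupture_force, n_residues), `n_stretches`.
#' @export
summarize_rips <- function(events_per_stretch, bin_width = 20) {
  if (length(events_per_stretch) == 0L) stop("need at least one stretch")
  n_rips <- vapply(events_per_stretch, length, integer(1))
  sc <- do.call(rbind, lapply(seq_along(events_per_stretch), function(i) {
    ev <- events_per_stretch[[i]]
    if (length(ev) == 0) return(NULL)
    data.frame(stretch = i,
               rupture_force = vapply(ev, `[[`, numeric(1),
                                      "rupture_force"),
               n_residues = vapply(ev, `[[`, numeric(1), "n_residues"))
  }))
  if (is.null(sc))
    sc <- data.frame(stretch = integer(), rupture_force = numeric(),
                     n_residues = numeric())
  hist <- if (nrow(sc)) {
    lo <- floor(min(sc$n_residues) / bin_width) * bin_width
    hi <- ceiling((max(sc$n_residues) + 1) / bin_width) * bin_width
    br <- seq(lo, hi, by = bin_width)
    cnt <- tabulate(findInterval(sc$n_residues, br,
                                 rightmost.closed = TRUE),
                    nbins = length(br) - 1)
    data.frame(bin_lo = br[-length(br)], bin_hi = br[-1],
               fraction = cnt / sum(cnt))
  } else data.frame(bin_lo = numeric(), bin_hi = numeric(),
                    fraction = numeric())
  structure(list(fraction_with_rip = mean(n_rips >= 1),
                 histogram = hist, scatter = sc,
                 n_stretches = length(events_per_stretch)),
            class = "rip_summary")
}

#' @export
print.rip_summary <- function(x, ...) {
  cat(sprintf("rip summary over %d stretches: %.0f%% with >= 1 rip, %d rips total\n",
              x$n_stretches, 100 * x$fraction_with_rip, nrow(x$scatter)))
  invisible(x)
}
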