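# Specular reflectivity of slab stacks: Abeles optical-matrix kernel with
# Nevot-Croce or erf-profile microslicing roughness treatments, Gaussian
# resolution smearing, and per-dataset scale/background.

#' Momentum transfer from incidence angle and wavelength
#'
#' \eqn{Q_z = 4\pi \sin\theta / \lambda}.
#'
#' @param theta Incidence angle in degrees, `0 < theta < 90`. Vectorised.
#' @param wavelength Neutron wavelength in Angstrom, `> 0`. Vectorised.
#' @return Momentum transfer in \eqn{\AA^{-1}}.
#' @examples
#' qz_from_angle(0.7, 16)
#' @export
qz_from_angle <- function(theta, wavelength) {
  if (any(wavelength <= 0)) stop("wavelength must be positive", call. = FALSE)
  if (any(theta < 0 | theta >= 90)) {
    stop("theta must lie in [0, 90) degrees", call. = FALSE)
  }
  4 * pi * sin(theta * pi / 180) / wavelength
}

#' Build a slab table
#'
#' A slab stack is a tibble ordered fronting to backing with columns
#' `thickness` (Angstrom; ignored for the two semi-infinite end media),
#' `sld` (\eqn{10^{-6} \AA^{-2}}) and `roughness` (Gaussian width, Angstrom,
#' of the slab's top, solution-side interface — i.e. the interface it shares
#' with the next slab in the table).
#'
#' @param thickness,sld,roughness Equal-length numeric vectors.
#' @return A slab tibble.
#' @export
slab_stack <- function(thickness, sld, roughness = 0) {
  n <- length(thickness)
  roughness <- rep_len(roughness, n)
  check_slabs(tibble(thickness = thickness, sld = sld, roughness = roughness))
}

check_slabs <- function(slabs) {
  stopifnot(is.data.frame(slabs),
            all(c("thickness", "sld", "roughness") %in% names(slabs)))
  if (nrow(slabs) < 2) {
    stop("a stack needs at least fronting and backing media", call. = FALSE)
  }
  if (any(slabs$thickness < 0) || any(slabs$roughness < 0)) {
    stop("thicknesses and roughnesses must be >= 0", call. = FALSE)
  }
  if (any(!is.finite(slabs$sld))) stop("SLDs must be finite", call. = FALSE)
  tibble::as_tibble(slabs)
}

# Discretise the erf-broadened SLD profile of a slab stack into thin
# zero-roughness sub-slabs. Interface i (between slab i and i+1) sits at the
# cumulative thickness of the internal slabs and carries slab i's roughness.
# Runs of slices within `merge_tol` (1e-6 A^-2) of a common mean are merged
# into single uniform slabs (exact on plateaus, O(tol) on gradients).
microslice_stack <- function(slabs, dz = 1, merge_tol = 0.005) {
  slabs <- check_slabs(slabs)
  ms <- microslice_vectors(slabs$thickness, slabs$sld, slabs$roughness,
                           dz, merge_tol)
  tibble(thickness = ms$thickness, sld = ms$sld, roughness = 0)
}

# Vector core of the microslicer (no data-frame overhead).
microslice_vectors <- function(th, sld, ro, dz = 1, merge_tol = 0.005) {
  n <- length(th)
  z_if <- cumsum(c(0, th[-c(1, n)]))     # n-1 interface positions, z=0 first
  sig <- pmax(ro[-n], 1e-6)              # avoid 0/0 in sharp steps
  pad <- 4 * sig + dz
  z_lo <- min(z_if - pad)
  z_hi <- max(z_if + pad)
  edges <- seq(z_lo, z_hi + dz, by = dz)
  a <- edges[-length(edges)]
  b <- edges[-1]
  # exact mean of the erf profile over each slice, via the antiderivative
  # of the normal CDF: Psi(x) = x Phi(x) + phi(x)
  psi <- function(x) x * pnorm(x) + dnorm(x)
  rho <- rep(sld[1], length(a))
  dsld <- diff(sld)
  for (i in seq_along(z_if)) {
    rho <- rho + dsld[i] * sig[i] *
      (psi((b - z_if[i]) / sig[i]) - psi((a - z_if[i]) / sig[i])) / dz
  }
  m <- merge_slices_cpp(rep(dz, length(a)), rho, merge_tol)
  list(thickness = c(0, m$thickness, 0),
       sld = c(sld[1], m$sld, sld[n]))
}

# Kernel entry on plain vectors (shared by the public API and the fitting
# hot path).
abeles_vectors <- function(q, th, sld, ro, roughness_model, dz = 1,
                           merge_tol = 0.005) {
  if (roughness_model == "microslice" && any(ro > 0)) {
    ms <- microslice_vectors(th, sld, ro, dz, merge_tol)
    th <- ms$thickness
    sld <- ms$sld
    ro <- numeric(length(th))
  }
  abeles_cpp(q, th, sld, c(ro[-length(ro)], 0))
}

#' Slab-stack reflectivity via the Abeles optical matrix formalism
#'
#' Computes \eqn{|r|^2} for each momentum transfer. Interfacial roughness is
#' treated either by Nevot-Croce damping of the Fresnel coefficients (fast;
#' valid while every roughness is small compared to the adjacent layer
#' thicknesses) or by microslicing the erf-broadened SLD profile into thin
#' zero-roughness sub-slabs (the reference path, required in the
#' large-roughness regime, e.g. strongly fluctuating floating membranes).
#'
#' @param slabs Slab tibble from [slab_stack()] (or any data frame with
#'   `thickness`, `sld`, `roughness`), ordered fronting to backing.
#' @param q Momentum transfer values, \eqn{\AA^{-1}}, positive.
#' @param roughness_model `"nevot_croce"` or `"microslice"`.
#' @param dz Sub-slab thickness (Angstrom) for microslicing.
#' @param merge_tol Microslice merging tolerance (\eqn{10^{-6} \AA^{-2}}):
#'   runs of slices within this deviation of a common mean collapse to one
#'   uniform slab. Set to 0 for strict fixed-dz slicing.
#' @return Reflectivity values in `[0, 1]` (non-absorbing media).
#' @examples
#' s <- slab_stack(c(0, 0), c(2.07, 6.36))
#' abeles_reflectivity(s, 0.01)   # below the critical edge: total reflection
#' @export
abeles_reflectivity <- function(slabs, q,
                                roughness_model = c("nevot_croce", "microslice"),
                                dz = 1, merge_tol = 0.005) {
  roughness_model <- match.arg(roughness_model)
  slabs <- check_slabs(slabs)
  if (any(q <= 0)) stop("q must be positive", call. = FALSE)
  abeles_vectors(q, slabs$thickness, slabs$sld, slabs$roughness,
                 roughness_model, dz, merge_tol)
}

# Gaussian quadrature nodes/weights for dQ/Q resolution smearing: `points`
# evenly spaced nodes over +/- `width` standard deviations, weighted by the
# normal density (normalised).
smear_quadrature <- function(points = 21, width = 3.5) {
  x <- seq(-width, width, length.out = points)
  w <- dnorm(x)
  list(x = x, w = w / sum(w))
}

#' Gaussian resolution smearing of a sampled reflectivity curve
#'
#' Convolves a reflectivity curve with a Gaussian resolution function of
#' full width at half maximum \eqn{\mathrm{FWHM} = (dQ/Q)\,Q} (time-of-flight
#' convention: dQ/Q is quoted on an FWHM basis, \eqn{\sigma = FWHM/2.355}).
#' The convolution is evaluated per point on an oversampled node set
#' (`points` quadrature nodes over \eqn{\pm}`width`\eqn{\sigma}), with the
#' curve linearly interpolated between its samples and clamped at the ends.
#'
#' For model curves prefer [reflectivity_smeared()], which evaluates the
#' optical-matrix kernel exactly at the quadrature nodes instead of
#' interpolating.
#'
#' @param reflectivity Reflectivity sampled at `q`.
#' @param q Momentum transfer grid, strictly increasing, positive.
#' @param dq_over_q Fractional resolution (FWHM basis), `>= 0`; or a vector
#'   of per-point absolute FWHM values via `dq`.
#' @param dq Optional per-point absolute resolution FWHM (same length as
#'   `q`); overrides `dq_over_q`.
#' @param points,width Quadrature settings (defaults: 21 nodes over
#'   \eqn{\pm 3.5\sigma}).
#' @return Smeared reflectivity values.
#' @export
smear_gaussian <- function(reflectivity, q, dq_over_q = 0.035, dq = NULL,
                           points = 21, width = 3.5) {
  stopifnot(length(reflectivity) == length(q))
  if (is.null(dq)) {
    if (dq_over_q < 0) stop("dq_over_q must be >= 0", call. = FALSE)
    if (dq_over_q == 0) return(reflectivity)
    dq <- dq_over_q * q
  }
  sigma <- dq / 2.355
  quad <- smear_quadrature(points, width)
  nodes <- outer(q, rep(1, points)) + outer(sigma, quad$x)
  vals <- approx(q, reflectivity, xout = pmax(nodes, min(q)), rule = 2)$y
  dim(vals) <- dim(nodes)
  as.numeric(vals %*% quad$w)
}

#' Model reflectivity with exact resolution smearing
#'
#' Evaluates the Abeles kernel at all quadrature nodes of the Gaussian
#' resolution function and reduces with the quadrature weights, avoiding the
#' interpolation step of [smear_gaussian()]. This is the forward model used
#' for fitting and simulation.
#'
#' @inheritParams abeles_reflectivity
#' @inheritParams smear_gaussian
#' @return Smeared reflectivity on `q`.
#' @export
reflectivity_smeared <- function(slabs, q, dq_over_q = 0.035, dq = NULL,
                                 roughness_model = c("nevot_croce", "microslice"),
                                 dz = 1, merge_tol = 0.005, points = 21,
                                 width = 3.5) {
  roughness_model <- match.arg(roughness_model)
  if (is.null(dq) && dq_over_q == 0) {
    return(abeles_vectors(q, slabs$thickness, slabs$sld, slabs$roughness,
                          roughness_model, dz, merge_tol))
  }
  sigma <- (if (is.null(dq)) dq_over_q * q else dq) / 2.355
  quad <- smear_quadrature(points, width)
  nodes <- outer(q, rep(1, points)) + outer(sigma, quad$x)
  nodes <- pmax(nodes, 1e-6)
  r <- abeles_vectors(as.numeric(nodes), slabs$thickness, slabs$sld,
                      slabs$roughness, roughness_model, dz, merge_tol)
  dim(r) <- dim(nodes)
  as.numeric(r %*% quad$w)
}

#' Apply instrumental scale and background
#'
#' `scale * R + background`: per-dataset nuisance map between the ideal and
#' the measured-model reflectivity.
#'
#' @param reflectivity Reflectivity values.
#' @param scale Multiplicative scale, `> 0`.
#' @param background Additive background, `>= 0`.
#' @return Adjusted reflectivity.
#' @export
apply_scale_background <- function(reflectivity, scale = 1, background = 0) {
  if (scale <= 0) stop("scale must be > 0", call. = FALSE)
  if (background < 0) stop("background must be >= 0", call. = FALSE)
  scale * reflectivity + background
}
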