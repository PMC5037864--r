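#' Preprocessing parameters
#'
#' Defaults follow the standard recipe for this analysis: the particle
#' channel is smoothed with a lateral Gaussian of 2 px, the membrane
#' channel with 30 px, no axial filtering is applied, and the membrane
#' channel is thinned by subtracting a copy axially shifted by 2 px so the
#' retained band is the apical edge. Deconvolution (Richardson-Lucy
#' against a theoretical Gaussian PSF) is optional and off by default; the
#' pipeline is validated without it.
#'
#' @param deconvolve Run Richardson-Lucy deconvolution first?
#' @param deconv_iterations Number of multiplicative updates (>= 1).
#' @param psf_sigma_um Theoretical PSF `c(lateral, axial)` sigma in um.
#' @param qd_smooth_sigma_px Lateral Gaussian sigma for the particle
#'   channel, in pixels.
#' @param membrane_smooth_sigma_px Lateral Gaussian sigma for the membrane
#'   channel, in pixels.
#' @param membrane_shift_px Axial shift (voxels, >= 1) for membrane
#'   thinning.
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(deconvolve = FALSE,
                              deconv_iterations = 40L,
                              psf_sigma_um = c(0.17, 0.55),
                              qd_smooth_sigma_px = 2,
                              membrane_smooth_sigma_px = 30,
                              membrane_shift_px = 2L) {
  stopifnot(qd_smooth_sigma_px >= 0, membrane_smooth_sigma_px >= 0,
            membrane_shift_px >= 1)
  if (deconvolve && deconv_iterations < 1)
    stop("deconv_iterations must be >= 1 when deconvolution is on")
  structure(list(deconvolve = deconvolve,
                 deconv_iterations = as.integer(deconv_iterations),
                 psf_sigma_um = psf_sigma_um,
                 qd_smooth_sigma_px = qd_smooth_sigma_px,
                 membrane_smooth_sigma_px = membrane_smooth_sigma_px,
                 membrane_shift_px = as.integer(membrane_shift_px)),
            class = "preprocess_params")
}

# Sampled, normalized 1D Gaussian kernel; radius 4 sigma. sigma = 0 gives
# the discrete delta (identity).
gaussian_kernel_1d <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_px))
  w <- stats::dnorm(seq(-r, r), sd = sigma_px)
  w / sum(w)
}

# Separable Gaussian blur with per-axis sigma in voxels (z, y, x order),
# reflective boundaries.
blur_gaussian_px <- function(arr, sigma_px_zyx) {
  d <- dim(arr)
  out <- arr
  for (axis in 1:3) {
    s <- sigma_px_zyx[axis]
    if (s > 0) out <- array(conv1d_reflect(out, d, gaussian_kernel_1d(s), axis), dim = d)
  }
  out
}

# Gaussian blur with sigma in um (lateral, axial), converted per axis.
blur_gaussian_um <- function(arr, sigma_um, spacing) {
  blur_gaussian_px(arr, c(sigma_um[2] / spacing$dz,
                          sigma_um[1] / spacing$dy,
                          sigma_um[1] / spacing$dx))
}

#' Richardson-Lucy maximum-likelihood deconvolution
#'
#' Multiplicative fixed-point iteration maximizing the Poisson likelihood
#' of the observed stack under a theoretical anisotropic Gaussian PSF.
#' Updates are `e <- e * K^T(obs / K e)` with a normalized symmetric kernel
#' and reflective boundaries, so the output stays non-negative and total
#' intensity is conserved. A PSF collapsing to the discrete delta leaves
#' the input unchanged; an all-zero stack is returned unchanged with a
#' warning.
#'
#' @param stack A [voxel_stack()] or 3D array (then `spacing` is required).
#' @param psf_sigma_um PSF `c(lateral, axial)` sigma in um.
#' @param iterations Number of updates (>= 1).
#' @param spacing Optional [voxel_spacing()] override.
#' @return Deconvolved stack, same type as the input.
#' @export
deconvolve_ml <- function(stack, psf_sigma_um = c(0.17, 0.55),
                          iterations = 40L, spacing = NULL) {
  x <- stack_data(stack)
  sp <- stack_spacing(stack, spacing)
  if (iterations < 1) stop("iterations must be >= 1")
  if (all(x == 0)) {
    warning("all-zero stack: deconvolution returns it unchanged")
    return(stack)
  }
  sig <- c(psf_sigma_um[2] / sp$dz, psf_sigma_um[1] / sp$dy, psf_sigma_um[1] / sp$dx)
  if (all(sig <= 0)) return(stack)
  d <- dim(x)
  est <- x
  eps <- .Machine$double.xmin
  for (it in seq_len(iterations)) {
    denom <- blur_gaussian_px(est, sig)
    ratio <- ifelse(denom > eps, x / denom, 0)
    est <- est * blur_gaussian_px(ratio, sig)   # Gaussian kernel is symmetric
  }
  with_data(stack, est)
}

#' Lateral Gaussian smoothing
#'
#' Gaussian filtering applied in y and x only; each z-plane is filtered
#' independently, so axial distance information is untouched (no axial
#' filtering). `sigma_px = 0` is the identity.
#'
#' @param stack A [voxel_stack()] or 3D array.
#' @param sigma_px Gaussian sigma in pixels (>= 0).
#' @return Smoothed stack, same type as the input.
#' @export
smooth_lateral <- function(stack, sigma_px) {
  if (sigma_px < 0) stop("sigma_px must be >= 0")
  x <- stack_data(stack)
  if (sigma_px == 0) return(stack)
  out <- blur_gaussian_px(x, c(0, sigma_px, sigma_px))
  with_data(stack, out)
}

#' Axial membrane thinning by shifted subtraction
#'
#' Subtracts a copy of the stack shifted by `shift_px` voxels toward the
#' basal side and clamps negatives to zero. A uniform slab of axial extent
#' `t` reduces to a band of extent `min(t, shift_px)` at its apical edge,
#' which is what makes the segmented membrane a sharp axial reference for
#' distance measurements.
#'
#' @param stack A [voxel_stack()] or 3D array.
#' @param shift_px Axial shift in voxels (>= 1 and < number of planes).
#' @return Thinned stack, same type as the input.
#' @export
thin_membrane_axially <- function(stack, shift_px = 2L) {
  x <- stack_data(stack)
  nz <- dim(x)[1]
  shift_px <- as.integer(shift_px)
  if (shift_px < 1) stop("shift_px must be >= 1")
  if (shift_px >= nz) stop("shift_px must be smaller than the number of z planes")
  # replicate-edge at the apical boundary (consistent with the reflective
  # convention of the filters): the first shift_px planes subtract the
  # first plane rather than zero, so uniform background there cancels
  # instead of surviving as a spurious apical sheet
  src <- pmax(seq_len(nz) - shift_px, 1L)
  shifted <- x[src, , , drop = FALSE]
  with_data(stack, pmax(x - shifted, 0))
}
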