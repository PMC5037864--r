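#' Segmentation parameters
#'
#' Defaults are the standard object-analyzer values for this assay: the
#' membrane channel keeps only objects of at least 1e5 voxels (the main
#' apical membrane), particle objects below 450 voxels (the minimal volume
#' of a single particle) or below 5 % of the threshold-to-maximum
#' intensity range are discarded, and agglomerates are split by a
#' watershed whose pre-smoothing Gaussian has sigma 0.1 um. Volume
#' thresholds are inclusive: objects strictly below them are discarded.
#'
#' @param membrane_min_voxels Minimum membrane object volume (voxels).
#' @param qd_min_voxels Minimum particle object volume (voxels).
#' @param qd_rel_intensity_min Fraction of the threshold-to-global-maximum
#'   range a particle object's peak intensity must reach, in (0, 1).
#' @param watershed_sigma_um Gaussian sigma (um) for the watershed
#'   pre-smoothing.
#' @param min_seed_sep_um Minimum 3D separation between watershed seeds;
#'   defaults to one lateral PSF FWHM of the particle channel so noise
#'   ripples do not oversplit.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(membrane_min_voxels = 1e5,
                                qd_min_voxels = 450,
                                qd_rel_intensity_min = 0.05,
                                watershed_sigma_um = 0.1,
                                min_seed_sep_um = 0.4) {
  stopifnot(membrane_min_voxels > 0, qd_min_voxels > 0,
            qd_rel_intensity_min > 0, qd_rel_intensity_min < 1,
            watershed_sigma_um > 0, min_seed_sep_um >= 0)
  structure(list(membrane_min_voxels = membrane_min_voxels,
                 qd_min_voxels = qd_min_voxels,
                 qd_rel_intensity_min = qd_rel_intensity_min,
                 watershed_sigma_um = watershed_sigma_um,
                 min_seed_sep_um = min_seed_sep_um),
            class = "segmentation_params")
}

#' Otsu intensity threshold
#'
#' The threshold maximizing between-class variance over a 256-bin
#' histogram of the stack's min-max intensity range (the "default Otsu" of
#' the classical object analyzers, which operate on discretized
#' intensities). The returned value is the lower edge of the first
#' foreground bin, so `x >= threshold` reproduces the optimal binary
#' split; ties are broken toward the lower threshold. Deterministic.
#'
#' @param stack A [voxel_stack()] or 3D array with at least two distinct
#'   values.
#' @param nbins Number of histogram bins (256 by default).
#' @return The threshold intensity (scalar).
#' @export
otsu_threshold <- function(stack, nbins = 256L) {
  x <- stack_data(stack)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("constant stack: no threshold exists")
  width <- (hi - lo) / nbins
  bin <- pmin(floor((x - lo) / width) + 1L, nbins)
  counts <- tabulate(bin, nbins)
  sums <- numeric(nbins)
  rs <- rowsum(as.numeric(x), as.integer(bin))
  sums[as.integer(rownames(rs))] <- rs[, 1]
  # candidate thresholds are the bin edges; class statistics use the
  # actual intensities, so the result equals exhaustive maximization of
  # between-class variance over all splits
  w0 <- cumsum(counts) / length(x)
  mu0 <- cumsum(sums) / length(x)
  muT <- mu0[nbins]
  w1 <- 1 - w0
  sb <- (muT * w0 - mu0)^2 / (w0 * w1)
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb[-nbins])   # split after bin k; both classes non-empty
  lo + k * width
}

# Build segmented_object records from a label array. Objects carry their
# voxel indices plus the stack geometry so downstream stages need no
# extra bookkeeping.
objects_from_labels <- function(labels, data, spacing) {
  d <- dim(data)
  idx <- which(labels > 0L)
  if (!length(idx)) return(list())
  lab <- labels[idx]
  val <- data[idx]
  z <- ((idx - 1L) %% d[1]) + 1L
  rest <- (idx - 1L) %/% d[1]
  y <- (rest %% d[2]) + 1L
  x <- (rest %/% d[2]) + 1L
  ids <- sort(unique(lab))
  f <- factor(lab, levels = ids)
  n <- as.integer(table(f))
  sumv <- as.numeric(rowsum(val, f))
  wz <- as.numeric(rowsum(val * z, f)); wy <- as.numeric(rowsum(val * y, f))
  wx <- as.numeric(rowsum(val * x, f))
  maxv <- as.numeric(tapply(val, f, max))
  zr <- cbind(tapply(z, f, min), tapply(z, f, max))
  yr <- cbind(tapply(y, f, min), tapply(y, f, max))
  xr <- cbind(tapply(x, f, min), tapply(x, f, max))
  vox <- split(idx, f)
  lapply(seq_along(ids), function(i) {
    s <- sumv[i]
    com_vox <- if (s > 0) c(wz[i], wy[i], wx[i]) / s
               else c(mean(z[lab == ids[i]]), mean(y[lab == ids[i]]), mean(x[lab == ids[i]]))
    structure(list(
      object_id = ids[i],
      voxel_count = n[i],
      com = c(z = (com_vox[1] - 1) * spacing$dz,
              y = (com_vox[2] - 1) * spacing$dy,
              x = (com_vox[3] - 1) * spacing$dx),
      intensity_max = maxv[i],
      intensity_mean = s / n[i],
      intensity_sum = s,
      bounding_box = rbind(z = zr[i, ], y = yr[i, ], x = xr[i, ]),
      voxels = vox[[i]],
      stack_dim = d,
      spacing = spacing), class = "segmented_object")
  })
}

#' @export
print.segmented_object <- function(x, ...) {
  cat(sprintf("segmented_object %d: %d voxels, com (z,y,x) = (%.3f, %.3f, %.3f) um, max %g\n",
              x$object_id, x$voxel_count, x$com[1], x$com[2], x$com[3], x$intensity_max))
  invisible(x)
}

#' Label supra-threshold objects
#'
#' 26-connected components of the `data >= threshold` mask, each with its
#' volume, intensity statistics and intensity-weighted centre of mass in
#' physical units.
#'
#' @param stack A [voxel_stack()] or 3D array (then `spacing` required).
#' @param threshold Intensity threshold (inclusive).
#' @param spacing Optional [voxel_spacing()] override.
#' @return List of `segmented_object` (possibly empty).
#' @export
label_objects <- function(stack, threshold, spacing = NULL) {
  x <- stack_data(stack)
  sp <- stack_spacing(stack, spacing)
  mask <- x >= threshold
  labels <- array(label3d_26(mask, dim(x)), dim = dim(x))
  objects_from_labels(labels, x, sp)
}

#' Select the apical membrane object
#'
#' Discards membrane objects below the volume threshold (inclusive: an
#' object of exactly the threshold volume survives). If several objects
#' survive, the largest is retained with a warning; if none does, the
#' error states that no membrane was found. The survivor is wrapped as a
#' membrane reference with its apical surface extracted.
#'
#' @param objects List of `segmented_object` from the membrane channel.
#' @param params A [segmentation_params()].
#' @return A `membrane_reference` (see [extract_apical_surface()]).
#' @export
filter_membrane <- function(objects, params = segmentation_params()) {
  keep <- Filter(function(o) o$voxel_count >= params$membrane_min_voxels, objects)
  if (!length(keep))
    stop("no membrane found: no object reaches ", params$membrane_min_voxels, " voxels")
  if (length(keep) > 1) {
    warning(length(keep), " membrane candidates above the volume threshold; retaining the largest")
    keep <- keep[order(vapply(keep, function(o) o$voxel_count, 1), decreasing = TRUE)]
  }
  extract_apical_surface(keep[[1]])
}

#' Filter particle objects by volume and relative intensity
#'
#' Keeps objects whose volume reaches `qd_min_voxels` (falsely segmented
#' fragments below the minimal volume of a single particle are discarded)
#' and whose peak intensity reaches `threshold + qd_rel_intensity_min *
#' (intensity_max_global - threshold)`. The intensity rule uses the
#' object's maximum — the statistic robust against volume dilution.
#'
#' @param objects List of `segmented_object` from the particle channel.
#' @param threshold The segmentation threshold used for these objects.
#' @param intensity_max_global Global intensity maximum of the channel.
#' @param params A [segmentation_params()].
#' @return Filtered list (possibly empty).
#' @export
filter_particles <- function(objects, threshold, intensity_max_global,
                             params = segmentation_params()) {
  if (intensity_max_global < threshold)
    stop("intensity_max_global must be >= threshold")
  cut <- threshold + params$qd_rel_intensity_min * (intensity_max_global - threshold)
  Filter(function(o) o$voxel_count >= params$qd_min_voxels &&
                     o$intensity_max >= cut, objects)
}

#' Split merged particle agglomerates by marker-based watershed
#'
#' Seeds are local maxima of the Gaussian-smoothed intensity inside the
#' mask (sigma given in physical units and converted to anisotropic
#' per-axis voxel sigmas), pruned so no two seeds lie closer than
#' `min_seed_sep_um` (greedy, brightest first). The watershed floods the
#' smoothed intensity downhill from the seeds with a deterministic
#' priority order, assigning every mask voxel to exactly one label, so the
#' split volumes always partition the mask.
#'
#' @param stack A [voxel_stack()] or 3D array (then `spacing` required).
#' @param mask Logical array: the particle foreground to split.
#' @param sigma_um Pre-smoothing Gaussian sigma in um.
#' @param params A [segmentation_params()] (supplies `min_seed_sep_um`).
#' @param spacing Optional [voxel_spacing()] override.
#' @return List of `segmented_object` labelled by watershed region;
#'   intensity statistics are computed on the original (unsmoothed)
#'   intensities.
#' @export
watershed_split <- function(stack, mask, sigma_um = 0.1,
                            params = segmentation_params(), spacing = NULL) {
  x <- stack_data(stack)
  sp <- stack_spacing(stack, spacing)
  d <- dim(x)
  stopifnot(identical(dim(mask), d))
  if (!any(mask)) stop("mask is empty")
  sm <- blur_gaussian_px(x, c(sigma_um / sp$dz, sigma_um / sp$dy, sigma_um / sp$dx))
  cand <- local_maxima3d(sm, mask, d)
  if (!length(cand)) cand <- which(mask)[which.max(sm[mask])]
  # greedy minimum-separation pruning, brightest candidate first
  vz <- ((cand - 1L) %% d[1]) + 1L
  rest <- (cand - 1L) %/% d[1]
  vy <- (rest %% d[2]) + 1L
  vx <- (rest %/% d[2]) + 1L
  ord <- order(-sm[cand], cand)
  pz <- (vz - 1) * sp$dz; py <- (vy - 1) * sp$dy; px <- (vx - 1) * sp$dx
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept)) { kept <- i; next }
    d2 <- (pz[kept] - pz[i])^2 + (py[kept] - py[i])^2 + (px[kept] - px[i])^2
    if (all(d2 >= params$min_seed_sep_um^2)) kept <- c(kept, i)
  }
  kept <- kept[order(cand[kept])]   # stable label order by linear index
  markers <- array(0L, dim = d)
  markers[cand[kept]] <- seq_along(kept)
  labels <- array(watershed3d(sm, markers, mask, d), dim = d)
  objects_from_labels(labels, x, sp)
}

#' Equivalent spherical diameter of a segmented object
#'
#' Diameter of the sphere with the same physical volume:
#' `d = (6 V / pi)^(1/3)` with `V = voxel_count * dx * dy * dz`.
#'
#' @param object A `segmented_object`.
#' @param spacing Optional [voxel_spacing()]; defaults to the spacing the
#'   object was segmented with.
#' @return Diameter in um.
#' @export
equivalent_diameter <- function(object, spacing = NULL) {
  sp <- if (!is.null(spacing)) {
    if (inherits(spacing, "voxel_spacing")) spacing else do.call(voxel_spacing, as.list(spacing))
  } else object$spacing
  V <- object$voxel_count * sp$dx * sp$dy * sp$dz
  (6 * V / pi)^(1 / 3)
}

#' Segment and size organelle compartments
#'
#' Default organelle segmentation: light lateral smoothing (1 px — half
#' the particle channel's, since organelles are extended objects whose
#' apparent size a heavy filter would inflate), Otsu threshold,
#' 26-connected labelling, and the equivalent spherical diameter per
#' object. Mirrors how endosome/lysosome sizes are read off such stacks.
#'
#' @param stack A [voxel_stack()] or 3D array (then `spacing` required).
#' @param smooth_sigma_px Lateral Gaussian sigma in pixels.
#' @param min_voxels Objects below this volume are treated as noise
#'   specks and dropped from the size table.
#' @param spacing Optional [voxel_spacing()] override.
#' @return Data frame with `object_id`, `voxel_count`, `diameter_um` and
#'   the centre-of-mass coordinates, one row per retained object.
#' @export
measure_organelles <- function(stack, smooth_sigma_px = 1, min_voxels = 20,
                               spacing = NULL) {
  sp <- stack_spacing(stack, spacing)
  sm <- smooth_lateral(stack, smooth_sigma_px)
  t <- otsu_threshold(sm)
  objects <- label_objects(sm, t, spacing = sp)
  objects <- Filter(function(o) o$voxel_count >= min_voxels, objects)
  if (!length(objects))
    return(data.frame(object_id = integer(0), voxel_count = numeric(0),
                      diameter_um = numeric(0), com_z_um = numeric(0),
                      com_y_um = numeric(0), com_x_um = numeric(0)))
  data.frame(
    object_id = vapply(objects, function(o) o$object_id, 1L),
    voxel_count = vapply(objects, function(o) as.numeric(o$voxel_count), 1),
    diameter_um = vapply(objects, equivalent_diameter, 1, spacing = sp),
    com_z_um = vapply(objects, function(o) unname(o$com["z"]), 1),
    com_y_um = vapply(objects, function(o) unname(o$com["y"]), 1),
    com_x_um = vapply(objects, function(o) unname(o$com["x"]), 1))
}
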