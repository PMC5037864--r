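#' Specification of a synthetic monolayer scene
#'
#' Describes a two/three-channel confocal-like stack of an epithelial
#' monolayer with exact ground truth: a bright, roughly planar apical
#' membrane sheet; sub-resolution particle spots at known signed axial
#' offsets from that sheet (negative = below the membrane, inside the
#' cell); optional spot agglomerates with bounded lateral jitter; and an
#' optional organelle channel of spherical blobs. Spots are rendered as
#' PSF-shaped point emitters: the particles this emulates (~13 nm quantum
#' dots) are far below the diffraction limit, so the PSF is the only
#' observable shape.
#'
#' Channel PSFs default to the imaging modes such data are acquired with:
#' the particle channel is two-photon with an opened pinhole (wide PSF,
#' `psf_sigma_um`), while membrane and organelle channels are confocal at
#' 1 AU, the organelle channel slightly sharper for its shorter emission
#' wavelength.
#'
#' Noise is Poisson on `poisson_scale * (signal + background)` divided back
#' by `poisson_scale`, plus additive Gaussian read noise; with
#' `poisson_scale = 0` and `gaussian_sd = 0` the render equals the
#' noiseless forward model exactly. The defaults give a signal-to-noise
#' ratio of about 10 at spot peaks. `seed` drives only the noise;
#' `geometry_seed` drives surface roughness phases and agglomerate jitter,
#' so scenes with different noise seeds share identical geometry.
#'
#' @param shape Integer `c(nz, ny, nx)` voxel counts.
#' @param spacing A [voxel_spacing()].
#' @param membrane_depth_um Axial position of the apical surface (um).
#' @param membrane_thickness_um Membrane sheet thickness (um).
#' @param membrane_roughness_um Amplitude of a smooth band-limited surface
#'   undulation (um); 0 = flat. Stands in for microvillated surfaces.
#' @param spots Data frame with columns `offset_um`, `y_um`, `x_um` and
#'   optionally `amplitude` (default 100): isolated particles.
#' @param agglomerates List of cluster specs, each a list with `n` (>= 2),
#'   `offset_um`, `y_um`, `x_um`, `jitter_um` (lateral jitter bound) and
#'   optionally `amplitude` per member spot.
#' @param organelles Data frame with columns `diameter_um`, `z_um`, `y_um`,
#'   `x_um` and optionally `amplitude`: spherical blobs for the organelle
#'   channel.
#' @param membrane_amplitude Peak membrane intensity (counts).
#' @param psf_sigma_um Particle-channel PSF `c(lateral, axial)` in um.
#' @param membrane_psf_sigma_um Membrane-channel PSF `c(lateral, axial)`.
#' @param organelle_psf_sigma_um Organelle-channel PSF `c(lateral, axial)`.
#' @param noise List with `poisson_scale`, `gaussian_sd`, `background`.
#' @param seed Integer noise seed; together with the spec it fully
#'   determines the rendered stacks.
#' @param geometry_seed Integer seed for surface roughness and jitter.
#' @return An object of class `scene_spec`.
#' @seealso [render_scene()], [spot_grid()]
#' @export
scene_spec <- function(shape = c(64L, 128L, 128L),
                       spacing = voxel_spacing(),
                       membrane_depth_um = 3,
                       membrane_thickness_um = 0.5,
                       membrane_roughness_um = 0,
                       spots = NULL,
                       agglomerates = list(),
                       organelles = NULL,
                       membrane_amplitude = 150,
                       psf_sigma_um = c(0.17, 0.55),
                       membrane_psf_sigma_um = c(0.11, 0.30),
                       organelle_psf_sigma_um = c(0.10, 0.27),
                       noise = list(poisson_scale = 1, gaussian_sd = 2,
                                    background = 10),
                       seed = 1L,
                       geometry_seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  if (!inherits(spacing, "voxel_spacing")) spacing <- do.call(voxel_spacing, as.list(spacing))
  if (!is.null(spots)) {
    spots <- as.data.frame(spots)
    stopifnot(all(c("offset_um", "y_um", "x_um") %in% names(spots)))
    if (is.null(spots$amplitude)) spots$amplitude <- 100
  }
  if (!is.null(organelles)) {
    organelles <- as.data.frame(organelles)
    stopifnot(all(c("diameter_um", "z_um", "y_um", "x_um") %in% names(organelles)))
    if (is.null(organelles$amplitude)) organelles$amplitude <- 100
  }
  noise <- utils::modifyList(list(poisson_scale = 1, gaussian_sd = 2, background = 10),
                             as.list(noise))
  spec <- structure(list(
    shape = shape, spacing = spacing,
    membrane_depth_um = membrane_depth_um,
    membrane_thickness_um = membrane_thickness_um,
    membrane_roughness_um = membrane_roughness_um,
    spots = spots, agglomerates = agglomerates, organelles = organelles,
    membrane_amplitude = membrane_amplitude,
    psf_sigma_um = psf_sigma_um,
    membrane_psf_sigma_um = membrane_psf_sigma_um,
    organelle_psf_sigma_um = organelle_psf_sigma_um,
    noise = noise, seed = as.integer(seed),
    geometry_seed = as.integer(geometry_seed)), class = "scene_spec")
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  nz <- spec$shape[1]; dz <- spec$spacing$dz
  zmin <- spec$membrane_depth_um - spec$membrane_roughness_um
  zmax <- spec$membrane_depth_um + spec$membrane_roughness_um
  if (zmin < 3 * dz || zmax > (nz - 1 - 3) * dz)
    stop("membrane surface must stay >= 3 voxels from the z boundaries")
  invisible(spec)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("scene_spec: %d x %d x %d voxels, membrane at %g um (roughness %g um)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$membrane_depth_um, x$membrane_roughness_um))
  cat(sprintf("  %d spot(s), %d agglomerate(s), %d organelle(s); noise seed %d\n",
              if (is.null(x$spots)) 0L else nrow(x$spots), length(x$agglomerates),
              if (is.null(x$organelles)) 0L else nrow(x$organelles), x$seed))
  invisible(x)
}

#' Lay out isolated spots on a lateral grid
#'
#' Convenience builder for scene specs: places `n` spots at a common signed
#' axial offset on a regular lateral grid, keeping a margin from the stack
#' edges.
#'
#' @param n Number of spots.
#' @param offset_um Signed axial offset from the membrane surface (um;
#'   negative = inside the cell).
#' @param shape,spacing Stack geometry the spots must fit into.
#' @param amplitude Peak amplitude per spot.
#' @param margin_um Lateral margin kept free at the stack edges.
#' @return Data frame usable as the `spots` argument of [scene_spec()].
#' @export
spot_grid <- function(n, offset_um, shape, spacing = voxel_spacing(),
                      amplitude = 100, margin_um = 1.5) {
  wy <- (shape[2] - 1) * spacing$dy - 2 * margin_um
  wx <- (shape[3] - 1) * spacing$dx - 2 * margin_um
  k <- ceiling(sqrt(n))
  iy <- (seq_len(n) - 1) %% k
  ix <- (seq_len(n) - 1) %/% k
  data.frame(
    offset_um = rep(offset_um, n),
    y_um = margin_um + iy * (wy / max(k - 1, 1)),
    x_um = margin_um + ix * (wx / max(k - 1, 1)),
    amplitude = rep(amplitude, n))
}

# Band-limited random surface, normalized to max |.| = 1 (before the
# roughness amplitude is applied). Smooth sum of low-frequency sinusoids
# whose phases come from the geometry seed.
roughness_surface <- function(ny, nx, geometry_seed) {
  rs <- local_rng(geometry_seed)
  on.exit(restore_rng(rs))
  u <- (0:(ny - 1)) / ny
  v <- (0:(nx - 1)) / nx
  s <- matrix(0, ny, nx)
  for (ky in 1:3) for (kx in 1:3) {
    amp <- 1 / (ky + kx)
    py <- stats::runif(1, 0, 2 * pi)
    px <- stats::runif(1, 0, 2 * pi)
    s <- s + amp * outer(sin(2 * pi * ky * u + py), sin(2 * pi * kx * v + px))
  }
  s / max(abs(s))
}

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# The ground-truth apical surface height z_s(y, x) in um.
scene_surface_um <- function(spec) {
  ny <- spec$shape[2]; nx <- spec$shape[3]
  if (spec$membrane_roughness_um > 0) {
    spec$membrane_depth_um +
      spec$membrane_roughness_um * roughness_surface(ny, nx, spec$geometry_seed)
  } else {
    matrix(spec$membrane_depth_um, ny, nx)
  }
}

# Expand agglomerate specs into individual member spots with lateral
# jitter drawn from the geometry seed; membership is recorded.
expand_agglomerates <- function(spec) {
  if (!length(spec$agglomerates)) return(NULL)
  rs <- local_rng(spec$geometry_seed + 1L)
  on.exit(restore_rng(rs))
  rows <- list()
  for (i in seq_along(spec$agglomerates)) {
    cl <- spec$agglomerates[[i]]
    if (is.null(cl$n) || cl$n < 2) stop("agglomerate ", i, " must have n >= 2 spots")
    amp <- if (is.null(cl$amplitude)) 100 else cl$amplitude
    j <- if (is.null(cl$jitter_um)) 0 else cl$jitter_um
    rows[[i]] <- data.frame(
      offset_um = rep(cl$offset_um, cl$n),
      y_um = cl$y_um + stats::runif(cl$n, -j, j),
      x_um = cl$x_um + stats::runif(cl$n, -j, j),
      amplitude = rep(amp, cl$n),
      agglomerate = rep(i, cl$n))
  }
  do.call(rbind, rows)
}

# One PSF-shaped emitter as a local patch (box out to 4.5 sigma); the
# caller adds it in place to avoid copying the full array per spot.
emitter_patch <- function(d, spec, z_um, y_um, x_um, amplitude, sigma_um) {
  sp <- spec$spacing
  sl <- sigma_um[1]; sa <- sigma_um[2]
  cz <- z_um / sp$dz + 1; cy <- y_um / sp$dy + 1; cx <- x_um / sp$dx + 1
  rz <- ceiling(4.5 * sa / sp$dz); rl <- ceiling(4.5 * sl / sp$dx)
  iz <- max(1, floor(cz - rz)):min(d[1], ceiling(cz + rz))
  iy <- max(1, floor(cy - rl)):min(d[2], ceiling(cy + rl))
  ix <- max(1, floor(cx - rl)):min(d[3], ceiling(cx + rl))
  gz <- exp(-((iz - cz) * sp$dz)^2 / (2 * sa^2))
  gy <- exp(-((iy - cy) * sp$dy)^2 / (2 * sl^2))
  gx <- exp(-((ix - cx) * sp$dx)^2 / (2 * sl^2))
  list(iz = iz, iy = iy, ix = ix, patch = amplitude * (gz %o% gy %o% gx))
}

check_spot_inside <- function(spec, z_um, y_um, x_um, idx) {
  sp <- spec$spacing; d <- spec$shape
  if (z_um < 0 || z_um > (d[1] - 1) * sp$dz ||
      y_um < 0 || y_um > (d[2] - 1) * sp$dy ||
      x_um < 0 || x_um > (d[3] - 1) * sp$dx)
    stop(sprintf("spot %d lies outside the stack (z=%.3g, y=%.3g, x=%.3g um)",
                 idx, z_um, y_um, x_um))
}

# Noiseless forward model of the particle channel for a spot table.
render_spot_table <- function(spec, spots) {
  img <- array(0, dim = spec$shape)
  if (is.null(spots) || nrow(spots) == 0) return(img)
  surf <- scene_surface_um(spec)
  sp <- spec$spacing
  for (i in seq_len(nrow(spots))) {
    iy <- pmin(pmax(round(spots$y_um[i] / sp$dy) + 1, 1), spec$shape[2])
    ix <- pmin(pmax(round(spots$x_um[i] / sp$dx) + 1, 1), spec$shape[3])
    z_um <- surf[iy, ix] - spots$offset_um[i]
    check_spot_inside(spec, z_um, spots$y_um[i], spots$x_um[i], i)
    p <- emitter_patch(dim(img), spec, z_um, spots$y_um[i], spots$x_um[i],
                       spots$amplitude[i], spec$psf_sigma_um)
    img[p$iz, p$iy, p$ix] <- img[p$iz, p$iy, p$ix] + p$patch
  }
  img
}

# Noiseless forward model of the membrane channel: an antialiased slab
# below the (possibly rough) apical surface, blurred with the membrane PSF.
render_membrane_forward <- function(spec) {
  d <- spec$shape; sp <- spec$spacing
  surf <- scene_surface_um(spec)                     # ny x nx
  zc <- (seq_len(d[1]) - 1) * sp$dz                  # voxel centre positions
  img <- array(0, dim = d)
  th <- spec$membrane_thickness_um
  # coverage of voxel [zc - dz/2, zc + dz/2] by the slab [surf, surf + th]
  for (z in seq_len(d[1])) {
    lo <- pmax(zc[z] - sp$dz / 2, surf)
    hi <- pmin(zc[z] + sp$dz / 2, surf + th)
    img[z, , ] <- spec$membrane_amplitude * pmax(hi - lo, 0) / sp$dz
  }
  blur_gaussian_um(img, spec$membrane_psf_sigma_um, sp)
}

render_organelle_forward <- function(spec) {
  d <- spec$shape; sp <- spec$spacing
  org <- spec$organelles
  img <- array(0, dim = d)
  for (i in seq_len(nrow(org))) {
    if (org$diameter_um[i] < 2 * sp$dx)
      stop(sprintf("organelle %d: diameter %.3g um is below two lateral voxels (unresolvable)",
                   i, org$diameter_um[i]))
    rz <- ceiling((org$diameter_um[i] / 2 + sp$dz) / sp$dz)
    rl <- ceiling((org$diameter_um[i] / 2 + sp$dx) / sp$dx)
    cz <- org$z_um[i] / sp$dz + 1; cy <- org$y_um[i] / sp$dy + 1; cx <- org$x_um[i] / sp$dx + 1
    iz <- max(1, floor(cz - rz)):min(d[1], ceiling(cz + rz))
    iy <- max(1, floor(cy - rl)):min(d[2], ceiling(cy + rl))
    ix <- max(1, floor(cx - rl)):min(d[3], ceiling(cx + rl))
    zz <- (iz - cz) * sp$dz; yy <- (iy - cy) * sp$dy; xx <- (ix - cx) * sp$dx
    r <- sqrt(outer(outer(zz^2, yy^2, `+`), xx^2, `+`))
    # soft edge over one lateral voxel so the half-intensity radius is exact
    cov <- pmin(pmax((org$diameter_um[i] / 2 - r) / sp$dx + 0.5, 0), 1)
    img[iz, iy, ix] <- img[iz, iy, ix] + org$amplitude[i] * cov
  }
  blur_gaussian_um(img, spec$organelle_psf_sigma_um, sp)
}

apply_noise <- function(img, noise) {
  lam <- img + noise$background
  if (noise$poisson_scale > 0) {
    lam <- stats::rpois(length(lam), lam * noise$poisson_scale) / noise$poisson_scale
    dim(lam) <- dim(img)
  }
  if (noise$gaussian_sd > 0)
    lam <- lam + stats::rnorm(length(lam), 0, noise$gaussian_sd)
  pmax(lam, 0)
}

#' Render a synthetic monolayer scene
#'
#' Renders the membrane and particle channels (and the organelle channel if
#' organelles are specified) of a [scene_spec()], applying PSF blur before
#' noise, and returns the exact ground truth alongside. The same spec and
#' seed always produce bit-identical stacks.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `scene` with elements `membrane`, `particles`,
#'   `organelles` (`NULL` if none) — each a [voxel_stack()] — and `truth`,
#'   a list with `membrane_plane_z` (mean apical surface height, um),
#'   `surface_um` (ny x nx ground-truth surface map), `spot_true_offsets`,
#'   `spot_positions` (um, columns z/y/x), `agglomerate_membership`, and
#'   `organelle_diameters_um`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  validate_scene_spec(spec)
  surf <- scene_surface_um(spec)
  agg <- expand_agglomerates(spec)
  all_spots <- spec$spots
  if (!is.null(all_spots)) all_spots$agglomerate <- NA_integer_
  all_spots <- rbind(all_spots, agg)

  mem <- render_membrane_forward(spec)
  par <- render_spot_table(spec, all_spots)
  org <- if (!is.null(spec$organelles) && nrow(spec$organelles) > 0)
    render_organelle_forward(spec) else NULL

  rs <- local_rng(spec$seed)
  on.exit(restore_rng(rs))
  mem <- apply_noise(mem, spec$noise)
  par <- apply_noise(par, spec$noise)
  if (!is.null(org)) org <- apply_noise(org, spec$noise)

  sp <- spec$spacing
  positions <- NULL
  offsets <- numeric(0)
  membership <- integer(0)
  if (!is.null(all_spots) && nrow(all_spots) > 0) {
    iy <- pmin(pmax(round(all_spots$y_um / sp$dy) + 1, 1), spec$shape[2])
    ix <- pmin(pmax(round(all_spots$x_um / sp$dx) + 1, 1), spec$shape[3])
    z_um <- surf[cbind(iy, ix)] - all_spots$offset_um
    positions <- cbind(z_um = z_um, y_um = all_spots$y_um, x_um = all_spots$x_um)
    offsets <- all_spots$offset_um
    membership <- all_spots$agglomerate
  }
  truth <- list(
    membrane_plane_z = mean(surf),
    surface_um = surf,
    spot_true_offsets = offsets,
    spot_positions = positions,
    agglomerate_membership = membership,
    organelle_diameters_um = if (is.null(spec$organelles)) numeric(0)
                             else spec$organelles$diameter_um)
  structure(list(
    membrane = voxel_stack(mem, sp, "membrane", check = FALSE),
    particles = voxel_stack(par, sp, "particles", check = FALSE),
    organelles = if (is.null(org)) NULL else voxel_stack(org, sp, "organelles", check = FALSE),
    truth = truth), class = "scene")
}

#' Render one agglomerate's particle-channel contribution
#'
#' Expands a single cluster spec into its member spots (with lateral jitter
#' bounded by `jitter_um`, drawn from the scene's geometry seed) and
#' renders their noiseless contribution to the particle channel. Used by
#' [render_scene()] internally; exposed so cluster geometry is directly
#' testable.
#'
#' @param spec A [scene_spec()].
#' @param cluster One agglomerate spec (list with `n`, `offset_um`, `y_um`,
#'   `x_um`, `jitter_um`, optionally `amplitude`).
#' @return List with `contribution` (3D array) and `spots` (member spot
#'   table including true offsets).
#' @export
render_agglomerate <- function(spec, cluster) {
  spec$agglomerates <- list(cluster)
  spots <- expand_agglomerates(spec)
  list(contribution = render_spot_table(spec, spots), spots = spots)
}

#' Render the organelle channel of a scene
#'
#' Spherical blobs of the specified diameters, PSF-blurred and noised.
#' Fails for an empty organelle list or for diameters below two lateral
#' voxels (unresolvable).
#'
#' @param spec A [scene_spec()] with a non-empty `organelles` table.
#' @return A [voxel_stack()].
#' @export
render_organelle_channel <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(spec$organelles) || nrow(spec$organelles) == 0)
    stop("scene spec has no organelles")
  img <- render_organelle_forward(spec)
  rs <- local_rng(spec$seed)
  on.exit(restore_rng(rs))
  img <- apply_noise(img, spec$noise)
  voxel_stack(img, spec$spacing, "organelles", check = FALSE)
}

#' Write a rendered scene to disk
#'
#' Writes the channels as a multi-channel TIFF plus the ground truth as
#' JSON and the spot table as CSV.
#'
#' @param scene A rendered scene from [render_scene()].
#' @param dir Output directory (created if needed).
#' @param name Base name for the files.
#' @return The stack path, invisibly.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  channels <- list(scene$membrane, scene$particles)
  if (!is.null(scene$organelles)) channels <- c(channels, list(scene$organelles))
  path <- file.path(dir, paste0(name, ".tif"))
  write_stack(channels, path)
  tr <- scene$truth
  jsonlite::write_json(
    list(membrane_plane_z = tr$membrane_plane_z,
         spot_true_offsets = tr$spot_true_offsets,
         agglomerate_membership = tr$agglomerate_membership,
         organelle_diameters_um = tr$organelle_diameters_um),
    file.path(dir, paste0(name, "_truth.json")), auto_unbox = TRUE, digits = NA)
  if (!is.null(tr$spot_positions)) {
    df <- data.frame(offset_um = tr$spot_true_offsets, tr$spot_positions,
                     agglomerate = tr$agglomerate_membership)
    utils::write.csv(df, file.path(dir, paste0(name, "_truth.csv")), row.names = FALSE)
  }
  invisible(path)
}
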