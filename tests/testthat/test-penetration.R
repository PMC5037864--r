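sp06 <- voxel_spacing(0.06, 0.06, 0.2)

slab_object <- function(zrange, dims = c(40L, 20L, 20L), tilt = 0L) {
  labels <- array(0L, dim = dims)
  data <- array(0, dim = dims)
  for (ix in seq_len(dims[3])) {
    zr <- zrange + tilt * ((ix - 1) %/% 10)
    data[zr, , ix] <- 100
    labels[zr, , ix] <- 1L
  }
  qdepth:::objects_from_labels(labels, data, sp06)[[1]]
}

test_that("the apical surface of a flat slab is its top plane everywhere", {
  obj <- slab_object(11:13)   # 0-based planes 10..12
  ref <- extract_apical_surface(obj)
  expect_true(all(ref$surface_idx[, "z"] == 11L))
  footprint <- !is.na(ref$surface_map)
  expect_equal(sum(footprint), 20L * 20L)
  expect_true(all(ref$surface_map[footprint] == (11 - 1) * 0.2))
})

test_that("a tilted slab's surface map reproduces the tilt exactly", {
  obj <- slab_object(11:13, tilt = 1L)   # one-voxel rise every 10 columns
  ref <- extract_apical_surface(obj)
  expect_equal(unname(ref$surface_map[1, 5]), (11 - 1) * 0.2)
  expect_equal(unname(ref$surface_map[1, 15]), (12 - 1) * 0.2)
})

test_that("surface voxels never have object voxels apically above them", {
  set.seed(31)
  dims <- c(30L, 16L, 16L)
  labels <- array(0L, dim = dims)
  idx <- sample(prod(dims), 2000)
  labels[idx] <- 1L
  data <- array(0, dim = dims); data[idx] <- runif(2000, 1, 10)
  obj <- qdepth:::objects_from_labels(labels, data, sp06)[[1]]
  ref <- extract_apical_surface(obj)
  occupied <- array(FALSE, dim = dims); occupied[idx] <- TRUE
  for (i in seq_len(nrow(ref$surface_idx))) {
    z <- ref$surface_idx[i, "z"]; y <- ref$surface_idx[i, "y"]; x <- ref$surface_idx[i, "x"]
    if (z > 1) expect_false(any(occupied[1:(z - 1), y, x]))
  }
})

point_object <- function(com_um, dims = c(60L, 40L, 40L)) {
  iz <- round(com_um[1] / 0.2) + 1; iy <- round(com_um[2] / 0.06) + 1
  ix <- round(com_um[3] / 0.06) + 1
  labels <- array(0L, dim = dims); data <- array(0, dim = dims)
  labels[iz, iy, ix] <- 1L; data[iz, iy, ix] <- 1
  qdepth:::objects_from_labels(labels, data, sp06)[[1]]
}

test_that("axial distances carry the penetration sign convention", {
  membrane <- slab_object(16:18, dims = c(60L, 40L, 40L))  # surface at z = 3.0 um
  ref <- extract_apical_surface(membrane)
  on_surface <- point_object(c(3.0, 1.2, 1.2))
  expect_equal(measure_distance(on_surface, ref)$axial_distance_um, 0)
  below <- point_object(c(4.2, 1.2, 1.2))
  below$com <- c(z = 4.3, y = 1.2, x = 1.2)   # com 1.3 um basal of the surface
  expect_equal(measure_distance(below, ref)$axial_distance_um, -1.3)
  above <- point_object(c(2.6, 1.2, 1.2))
  expect_equal(measure_distance(above, ref)$axial_distance_um, 0.4)
})

test_that("measure_distance equals the exhaustive surface-voxel oracle", {
  set.seed(17)
  dims <- c(50L, 30L, 30L)
  for (rep in 1:25) {
    nsurf <- sample(50:900, 1)
    vox <- sample(prod(dims), nsurf)
    z <- ((vox - 1L) %% dims[1]) + 1L
    rest <- (vox - 1L) %/% dims[1]
    y <- (rest %% dims[2]) + 1L
    x <- (rest %/% dims[2]) + 1L
    # keep only the apical-most voxel per column so the set is a valid surface
    col <- y + (x - 1L) * dims[2]
    ord <- order(col, z)
    sel <- ord[!duplicated(col[ord])]
    labels <- array(0L, dim = dims); data <- array(0, dim = dims)
    labels[vox[sel]] <- 1L; data[vox[sel]] <- 1
    obj <- qdepth:::objects_from_labels(labels, data, sp06)[[1]]
    ref <- extract_apical_surface(obj)
    com <- c(runif(1, 0, 9.8), runif(1, 0, 1.7), runif(1, 0, 1.7))
    particle <- make_object(sample(prod(dims), 1), dims, sp06)
    particle$com <- c(z = com[1], y = com[2], x = com[3])
    got <- measure_distance(particle, ref)$axial_distance_um
    expect_identical(got, distance_bruteforce(com, ref$surface_um))
  }
})

test_that("the depth Gaussian recovers known normal parameters", {
  set.seed(100)
  x <- rnorm(5000, -1.3, 0.5)
  fit <- pool_and_fit(x, bin_width_um = 0.2)
  expect_true(fit$fit_ok)
  expect_equal(fit$method, "histogram")
  expect_lt(abs(fit$x_c - (-1.3)), 3 * fit$x_c_se + 1e-12)
  expect_lt(abs(fit$x_c - (-1.3)), 0.05)
  expect_equal(fit$sigma_fit, 0.5, tolerance = 0.1)
  # the membrane-associated regime near zero resolves too
  y <- rnorm(2000, 0.03, 0.2)
  fit2 <- pool_and_fit(y, bin_width_um = 0.2)
  expect_lt(abs(fit2$x_c - 0.03), 3 * fit2$x_c_se + 5e-3)
})

test_that("degenerate and undersized distance sets are handled explicitly", {
  d <- rep(0.25, 30)
  fit <- pool_and_fit(d)
  expect_false(fit$fit_ok)
  expect_true(fit$degenerate)
  expect_equal(fit$x_c, 0.25)
  expect_equal(fit$sigma_fit, 0)
  expect_error(pool_and_fit(rnorm(10)), "at least")
})

test_that("pooling is order-invariant", {
  set.seed(55)
  recs <- data.frame(stack_id = rep(c("a", "b"), 30),
                     object_id = 1:60,
                     axial_distance_um = rnorm(60, -0.8, 0.3))
  f1 <- pool_and_fit(recs)
  f2 <- pool_and_fit(recs[sample(60), ])
  expect_equal(f1$x_c, f2$x_c)
  expect_equal(f1$counts, f2$counts)
  expect_equal(f1$n_stacks, 2L)
})

test_that("the verdict rule matches the reported regimes", {
  mk <- function(xc, se) structure(list(x_c = xc, x_c_se = se, fit_ok = TRUE),
                                   class = "depth_fit")
  expect_equal(classify_penetration(mk(-1.3, 0.1)), "penetrating")
  expect_equal(classify_penetration(mk(0.03, 0.01)), "membrane-associated")
  expect_equal(classify_penetration(mk(-0.05, 0.1)), "membrane-associated")
  expect_error(classify_penetration(structure(list(fit_ok = FALSE), class = "depth_fit")),
               "fit_ok")
})

test_that("distances are invariant under whole-scene shifts and equivariant under particle shifts", {
  spec <- small_scene(-0.5, n_spots = 4, seed = 23)
  sc <- render_scene(spec)
  cfg <- small_scene_config()
  base <- analyze_stack(sc$membrane, sc$particles, cfg, "s")$records
  # shift the whole scene axially by re-rendering two voxels deeper
  spec2 <- small_scene(-0.5, n_spots = 4, seed = 23, membrane_depth_um = 3.4)
  sc2 <- render_scene(spec2)
  shifted <- analyze_stack(sc2$membrane, sc2$particles, cfg, "s")$records
  expect_equal(sort(shifted$axial_distance_um), sort(base$axial_distance_um),
               tolerance = 0.02)
  # shift only the particle stack by k voxels: every distance moves by -k dz
  k <- 3L
  pdat <- sc$particles$data
  nz <- dim(pdat)[1]
  rolled <- pdat[c(rep(1L, k), 1:(nz - k)), , ]
  rolled[1:k, , ] <- pdat[1, , ]
  sc_shift <- voxel_stack(rolled, sc$particles$spacing, check = FALSE)
  moved <- analyze_stack(sc$membrane, sc_shift, cfg, "s")$records
  expect_equal(sort(moved$axial_distance_um),
               sort(base$axial_distance_um) - k * 0.2,
               tolerance = 1e-9)
})

test_that("the extracted surface tracks a rough membrane within the stated bound", {
  shape <- c(48L, 192L, 192L)
  spec <- scene_spec(shape = shape, membrane_depth_um = 3,
                     membrane_roughness_um = 0.5, seed = 42, geometry_seed = 5)
  sc <- render_scene(spec)
  # light smoothing only: this isolates surface extraction; the heavy
  # membrane filter deliberately flattens fine relief and is covered by
  # the end-to-end tests
  mem <- thin_membrane_axially(smooth_lateral(sc$membrane, 2), 2)
  objs <- label_objects(mem, otsu_threshold(mem))
  ref <- filter_membrane(objs, segmentation_params(membrane_min_voxels = 10000))
  truth <- sc$truth$surface_um
  common <- !is.na(ref$surface_map)
  err <- ref$surface_map[common] - truth[common]
  # one axial voxel of quantization plus the thinning shift
  expect_lt(max(abs(err)), 0.2 + 2 * 0.2)
  expect_gt(mean(common), 0.95)   # surface defined over nearly the full footprint
})
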