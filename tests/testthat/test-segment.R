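sp06 <- voxel_spacing(0.06, 0.06, 0.2)

test_that("Otsu separates a perfectly bimodal stack and rejects constants", {
  x <- array(c(rep(0, 2048), rep(200, 2048)), dim = c(16, 16, 16))
  t <- otsu_threshold(x)
  expect_true(t > 0 && t <= 200)
  expect_true(all(x[x >= t] == 200) && all(x[x < t] == 0))
  expect_error(otsu_threshold(array(5, dim = c(8, 8, 8))), "constant")
})

test_that("Otsu equals exhaustive between-class-variance maximization", {
  set.seed(42)
  for (i in 1:10) {
    x <- array(runif(4096, 0, 100), dim = c(16, 16, 16))
    expect_equal(otsu_threshold(x), otsu_bruteforce(x))
    y <- array(rpois(4096, 10) + 0.0, dim = c(16, 16, 16))
    y[1:4, 1:4, 1:4] <- y[1:4, 1:4, 1:4] + 80
    expect_equal(otsu_threshold(y), otsu_bruteforce(y))
  }
})

test_that("labelling counts disjoint objects and uses 26-connectivity", {
  a <- array(0, dim = c(12, 12, 12))
  a[1:3, 1:3, 1:3] <- 10
  a[7:9, 7:9, 7:9] <- 10
  objs <- label_objects(a, 5, spacing = sp06)
  expect_length(objs, 2L)
  expect_equal(vapply(objs, function(o) o$voxel_count, 1L), c(27L, 27L))
  # centre of mass of a symmetric object is its geometric centre
  expect_equal(unname(objs[[1]]$com), c((2 - 1) * 0.2, (2 - 1) * 0.06, (2 - 1) * 0.06))
  # diagonal contact merges
  b <- array(0, dim = c(8, 8, 8))
  b[2, 2, 2] <- 1; b[3, 3, 3] <- 1
  expect_length(label_objects(b, 0.5, spacing = sp06), 1L)
  # empty foreground gives an empty list
  expect_length(label_objects(b, 5, spacing = sp06), 0L)
})

test_that("membrane selection is inclusive at the volume threshold", {
  dims <- c(60L, 80L, 80L)
  params <- segmentation_params(membrane_min_voxels = 1000)
  big <- make_object(1:1000, dims, sp06, id = 1L)
  small <- make_object(200001:200500, dims, sp06, id = 2L)
  ref <- filter_membrane(list(big, small), params)
  expect_s3_class(ref, "membrane_reference")
  expect_equal(ref$object$voxel_count, 1000L)      # exactly at threshold: kept
  expect_error(filter_membrane(list(small), params), "no membrane found")
  big2 <- make_object(100001:101400, dims, sp06, id = 3L)
  expect_warning(ref2 <- filter_membrane(list(big, small, big2), params), "largest")
  expect_equal(ref2$object$voxel_count, 1400L)
})

test_that("particle filters enforce both the volume and the 5 % intensity rule", {
  dims <- c(40L, 60L, 60L)
  params <- segmentation_params()
  t <- 20; gmax <- 220  # range 200, 5 % rule cut at 30
  mk <- function(nvox, peak, start, id) {
    vals <- rep(peak * 0.9, nvox); vals[1] <- peak
    make_object(start + seq_len(nvox), dims, sp06, values = vals, id = id)
  }
  o449 <- mk(449, 220, 0, 1L)          # bright but one voxel short
  o450 <- mk(450, 220, 2000, 2L)       # at the volume threshold, at global max
  o600dim <- mk(600, t + 0.04 * 200, 6000, 3L)  # 4 % of the range: too dim
  o600ok <- mk(600, t + 0.05 * 200, 12000, 4L)  # exactly 5 %: kept
  kept <- filter_particles(list(o449, o450, o600dim, o600ok), t, gmax, params)
  expect_equal(vapply(kept, function(o) o$object_id, 1L), c(2L, 4L))
  expect_error(filter_particles(list(o450), 30, 10), "intensity_max_global")
})

test_that("raising the particle volume threshold never adds objects", {
  set.seed(13)
  dims <- c(30L, 40L, 40L)
  objs <- lapply(1:12, function(i)
    make_object(sample(prod(dims), sample(100:900, 1)), dims, sp06, id = i))
  prev <- Inf
  for (v in c(100, 300, 450, 700, 900)) {
    p <- segmentation_params(qd_min_voxels = v)
    n <- length(filter_particles(objs, 10, 100, p))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("watershed splits two merged spots and partitions the mask exactly", {
  shape <- c(32L, 64L, 64L)
  spec <- scene_spec(shape = shape, membrane_depth_um = 3,
                     spots = data.frame(offset_um = c(-0.5, -0.5),
                                        y_um = c(1.62, 2.22), x_um = c(1.92, 1.92)),
                     seed = 3)
  sc <- render_scene(spec)
  par <- smooth_lateral(sc$particles, 2)
  t <- otsu_threshold(par)
  mask <- par$data >= t
  comps <- label_objects(par, t)
  expect_length(comps, 1L)   # merged into one supra-threshold component
  objs <- watershed_split(par, mask, 0.1)
  expect_length(objs, 2L)
  # volumes partition the component
  expect_equal(sum(vapply(objs, function(o) o$voxel_count, 1L)),
               comps[[1]]$voxel_count)
  vox <- sort(unlist(lapply(objs, function(o) o$voxels)))
  expect_identical(vox, sort(comps[[1]]$voxels))
  # each recovered centre of mass is close to a true spot centre
  truth <- sc$truth$spot_positions
  for (o in objs) {
    err <- min(sqrt((truth[, "z_um"] - o$com["z"])^2 +
                    (truth[, "y_um"] - o$com["y"])^2 +
                    (truth[, "x_um"] - o$com["x"])^2))
    expect_lt(err, 0.12)
  }
})

test_that("an isolated spot passes the watershed unsplit", {
  shape <- c(32L, 64L, 64L)
  spec <- scene_spec(shape = shape,
                     spots = data.frame(offset_um = -0.5, y_um = 1.9, x_um = 1.9),
                     seed = 4)
  sc <- render_scene(spec)
  par <- smooth_lateral(sc$particles, 2)
  t <- otsu_threshold(par)
  mask <- par$data >= t
  comps <- label_objects(par, t)
  objs <- watershed_split(par, mask, 0.1)
  expect_length(objs, length(comps))
  expect_equal(objs[[1]]$voxel_count, comps[[1]]$voxel_count)
  expect_error(watershed_split(par, array(FALSE, dim = shape), 0.1), "empty")
})

test_that("equivalent diameter follows the closed form and the scaling law", {
  dims <- c(20L, 30L, 30L)
  o <- make_object(5000L, dims, sp06, id = 1L)
  expect_equal(equivalent_diameter(o, sp06), (6 * 0.06 * 0.06 * 0.2 / pi)^(1 / 3))
  sp2 <- voxel_spacing(0.12, 0.12, 0.4)
  expect_equal(equivalent_diameter(o, sp2), 2 * equivalent_diameter(o, sp06))
})

test_that("synthetic organelle spheres are sized close to their true diameters", {
  shape <- c(48L, 128L, 128L)
  org <- data.frame(diameter_um = rep(c(0.6, 0.9), each = 4),
                    z_um = rep(c(3.6, 4.4), 4),
                    y_um = rep(c(1.5, 3.3, 5.1, 6.6), 2),
                    x_um = rep(c(2.0, 5.5), each = 4))
  spec <- scene_spec(shape = shape, organelles = org, seed = 21)
  st <- render_organelle_channel(spec)
  sizes <- measure_organelles(st)
  expect_gte(nrow(sizes), 6L)
  # match measured objects to truth by lateral position
  err <- vapply(seq_len(nrow(sizes)), function(i) {
    j <- which.min((org$y_um - sizes$com_y_um[i])^2 + (org$x_um - sizes$com_x_um[i])^2)
    sizes$diameter_um[i] - org$diameter_um[j]
  }, 1.0)
  expect_lt(max(abs(err)), 0.25)
})

test_that("Otsu agrees with an independent library implementation", {
  skip_if_not_installed("EBImage")
  set.seed(77)
  for (i in 1:5) {
    m <- matrix(runif(64 * 64), 64)
    m[1] <- 0; m[2] <- 1   # pin the range so both binnings align
    ours <- otsu_threshold(array(m, dim = c(1L, 64L, 64L)))
    theirs <- EBImage::otsu(EBImage::Image(t(m)), range = c(0, 1), levels = 256)
    expect_lt(abs(ours - theirs), 2 / 256)   # conventions differ by <= one bin
  }
})
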