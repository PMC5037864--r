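# Independent brute-force oracles and small scene builders used across the
# suite. The oracles deliberately share no code with the implementation.

# Exhaustive Otsu: maximize between-class variance over the 255 interior
# bin-edge candidates, computing class statistics directly on the voxels.
otsu_bruteforce <- function(x, nbins = 256L) {
  lo <- min(x); hi <- max(x)
  width <- (hi - lo) / nbins
  cands <- lo + seq_len(nbins - 1L) * width
  sb <- vapply(cands, function(t) {
    a <- x[x < t]; b <- x[x >= t]
    if (!length(a) || !length(b)) return(-Inf)
    (length(a) / length(x)) * (length(b) / length(x)) * (mean(a) - mean(b))^2
  }, 1.0)
  cands[which.max(sb)]
}

# Exhaustive nearest-surface-voxel distance: scan every surface point,
# take the 3D minimizer (first minimum in storage order), project on z.
distance_bruteforce <- function(com, surface_um) {
  d2 <- (surface_um[, 1] - com[1])^2 + (surface_um[, 2] - com[2])^2 +
    (surface_um[, 3] - com[3])^2
  j <- which.min(d2)
  unname(surface_um[j, 1] - com[1])
}

# A segmented_object built by hand from a voxel index set.
make_object <- function(voxels, dims, spacing, values = NULL, id = 1L) {
  data <- array(0, dim = dims)
  data[voxels] <- if (is.null(values)) 1 else values
  labels <- array(0L, dim = dims)
  labels[voxels] <- id
  qdepth:::objects_from_labels(labels, data, spacing)[[1]]
}

# Small flat-membrane scene with isolated spots; cheap enough for unit
# tests. Membrane selection threshold is scaled to the lateral size.
small_scene_config <- function(...) {
  pipeline_config(segment = list(membrane_min_voxels = 10000),
                  penetration = list(min_records = 3), ...)
}

small_scene <- function(offset_um, n_spots = 4L, seed = 7L,
                        shape = c(48L, 96L, 96L), roughness = 0, ...) {
  scene_spec(shape = shape,
             spots = spot_grid(n_spots, offset_um, shape),
             membrane_roughness_um = roughness,
             seed = seed, ...)
}
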