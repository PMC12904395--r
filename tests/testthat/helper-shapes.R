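# rasterized test solids (voxel centres at (i - 0.5) * spacing)

digital_ball <- function(r_um, spacing = 0.5, pad = 3L) {
  n <- ceiling(2 * r_um / spacing) + pad
  co <- (seq_len(n) - (n + 1) / 2) * spacing
  d2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  array(as.numeric(d2 <= r_um^2), c(n, n, n))
}

digital_cube <- function(side_vox) array(1, rep(side_vox, 3L))

# axis-aligned or rotated ellipsoid with semi-axes in um
digital_ellipsoid <- function(axes_um, spacing = 0.5, rotation = diag(3), pad = 4L) {
  amax <- max(axes_um)
  n <- ceiling(2 * amax / spacing) + pad
  co <- (seq_len(n) - (n + 1) / 2) * spacing
  g <- as.matrix(expand.grid(x = co, y = co, z = co))
  u <- g %*% rotation
  q <- (u[, 1] / axes_um[1])^2 + (u[, 2] / axes_um[2])^2 + (u[, 3] / axes_um[3])^2
  array(as.numeric(q <= 1), c(n, n, n))
}

rotation_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0), c(0, 0, 1))
}

# wrap a mask as a single-marker voxel image (uniform foreground intensity)
mask_image <- function(mask, spacing = 0.5, value = 100) {
  zero <- array(0, dim(mask))
  voxel_image(list(cd68 = mask * value, cd163 = zero, dapi = zero),
              rep(spacing, 3L))
}

# measure the single object in a mask through the standard pipeline
measure_mask <- function(mask, spacing = 0.5, value = 100) {
  img <- mask_image(mask, spacing, value)
  lv <- segment_channel(img, "cd68", method = "fixed", threshold = value / 2,
                        min_volume_um3 = 0)
  measure_cells(lv, img)
}

# point-cloud cells for graph construction
point_cells <- function(xyz, marker = "cd68", major = 10) {
  xyz <- matrix(xyz, ncol = 3)
  tibble::tibble(cell_id = seq_len(nrow(xyz)), marker = marker,
                 x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
                 major_axis_length_um = major)
}

# small well-formed profile table for I/O and classification tests
toy_profiles <- function(n_cases = 6, labels = c("LA", "CLL"),
                         images_per_case = 2, seed = 1, effect_scale = 1) {
  presets <- lapply(labels, function(l) make_entity_preset(l, effect_scale))
  names(presets) <- labels
  simulate_profile_table(presets, n_cases = n_cases,
                         images_per_case = images_per_case, seed = seed)
}
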