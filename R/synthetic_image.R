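#' Image geometry for the voxel simulator
#'
#' Default physical extent is 171 x 171 x 20 um (a 1024 x 1024 px confocal
#' field at 0.167 um/px, with section thickness in the 18-33 um range) at
#' 0.5 um isotropic voxel spacing.
#'
#' @param size_um physical image extent (x, y, z) in um.
#' @param spacing_um voxel spacing (dx, dy, dz) in um.
#' @return List with validated geometry fields.
#' @export
image_geometry <- function(size_um = c(171, 171, 20),
                           spacing_um = c(0.5, 0.5, 0.5)) {
  size_um <- as.numeric(size_um); spacing_um <- as.numeric(spacing_um)
  stopifnot(length(size_um) == 3, length(spacing_um) == 3,
            all(size_um > 0), all(spacing_um > 0))
  list(size_um = size_um, spacing_um = spacing_um)
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_))); d[d == 0] <- 1
  R <- R %*% diag(d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Simulate one 3D two-marker fluorescence image with ground truth
#'
#' Places ellipsoidal macrophage bodies for both markers according to the
#' preset's rates, size/shape/intensity distributions and Matern-style
#' cluster process, rasterizes them into CD68/CD163 channels, adds a DAPI
#' channel (cell nuclei plus background lymphocyte nuclei) and additive
#' Gaussian background noise. Cell overlap is suppressed by rejection
#' sampling on centre distances with a retry cap; residual overlaps are
#' left in place and merge at segmentation time, as confluent staining
#' does in real data. Fully reproducible given `seed`.
#'
#' @param preset an [make_entity_preset()] object.
#' @param geometry an [image_geometry()].
#' @param seed integer seed.
#' @return List with `image` (a [voxel_image()]) and `cells` (tibble of
#'   ground-truth cells: marker, centre, semi-axes a >= b >= c, rotation,
#'   true volume, true intensities).
#' @export
simulate_image <- function(preset, geometry = image_geometry(), seed = 1L) {
  stopifnot(inherits(preset, "entity_preset"))
  size <- geometry$size_um; sp <- geometry$spacing_um
  # resolvability guard: the median smallest semi-axis must exceed spacing
  for (m in pathomic_markers()) {
    p <- preset$image_params$markers[[m]]
    q <- p$axis_ratio_mean
    c_med <- (3 * p$vol_median_um3 / (4 * pi * q^1.5))^(1/3)
    if (max(sp) > c_med) {
      stopf("voxel spacing %.2f um exceeds the typical smallest cell semi-axis %.2f um for %s: cells unresolvable",
            max(sp), c_med, m)
    }
  }
  withr::with_seed(child_seed(seed, "image", preset$entity), {
    v_img <- prod(size)
    spatial <- preset$image_params$spatial
    n_par <- max(1L, stats::rpois(1L, spatial$parent_rate_per_1e5_um3 * v_img / 1e5))
    parents <- cbind(stats::runif(n_par, 0, size[1]),
                     stats::runif(n_par, 0, size[2]),
                     stats::runif(n_par, 0, size[3]))
    cells <- list()
    centres <- matrix(numeric(0), ncol = 3)
    reqs <- numeric(0)  # equivalent-sphere radii of accepted cells
    for (m in pathomic_markers()) {
      p <- preset$image_params$markers[[m]]
      n <- stats::rpois(1L, p$rate_per_1e5_um3 * v_img / 1e5)
      if (n == 0L) next
      for (i in seq_len(n)) {
        vol <- stats::rlnorm(1L, log(p$vol_median_um3), p$vol_log_sd)
        q <- 1 + (p$axis_ratio_mean - 1) * exp(stats::rnorm(1L, 0, p$axis_ratio_log_sd))
        cax <- (3 * vol / (4 * pi * q^1.5))^(1/3)
        axes <- c(a = cax * q, b = cax * sqrt(q), c = cax)
        req <- (3 * vol / (4 * pi))^(1/3)
        centre <- NULL
        for (try in seq_len(20L)) {
          par <- parents[sample.int(n_par, 1L), ]
          r <- spatial$cluster_radius_um * stats::runif(1L)^(1/3)
          u <- stats::rnorm(3L); u <- u / sqrt(sum(u^2))
          cand <- par + r * u
          cand <- pmin(pmax(cand, axes[["c"]]), size - axes[["c"]])
          ok <- nrow(centres) == 0 ||
            all(sqrt(rowSums(sweep(centres, 2, cand)^2)) >=
                  0.95 * (reqs + req))
          if (ok) { centre <- cand; break }
        }
        if (is.null(centre)) centre <- cand  # retry cap hit: accept overlap
        centres <- rbind(centres, centre)
        reqs <- c(reqs, req)
        cells[[length(cells) + 1L]] <- tibble::tibble(
          cell_id = length(cells) + 1L, marker = m,
          x_um = centre[1], y_um = centre[2], z_um = centre[3],
          a_um = axes[["a"]], b_um = axes[["b"]], c_um = axes[["c"]],
          rotation = list(random_rotation()),
          true_volume_um3 = vol,
          marker_intensity = max(0.2 * p$marker_int_mean,
                                 stats::rnorm(1L, p$marker_int_mean, p$marker_int_sd)),
          dapi_intensity = max(0.2 * p$dapi_int_mean,
                               stats::rnorm(1L, p$dapi_int_mean, p$dapi_int_sd)))
      }
    }
    gt <- if (length(cells)) dplyr::bind_rows(cells) else empty_ground_truth()

    nv <- pmax(1L, as.integer(round(size / sp)))
    ch <- list(cd68 = array(0, nv), cd163 = array(0, nv), dapi = array(0, nv))
    if (nrow(gt)) {
      for (i in seq_len(nrow(gt))) {
        cell <- gt[i, ]
        ch[[cell$marker]] <- rasterize_ellipsoid(
          ch[[cell$marker]], sp,
          centre = c(cell$x_um, cell$y_um, cell$z_um),
          axes = c(cell$a_um, cell$b_um, cell$c_um),
          rotation = cell$rotation[[1]], value = cell$marker_intensity)
        ch$dapi <- rasterize_ellipsoid(
          ch$dapi, sp, centre = c(cell$x_um, cell$y_um, cell$z_um),
          axes = 0.55 * c(cell$a_um, cell$b_um, cell$c_um),
          rotation = cell$rotation[[1]], value = cell$dapi_intensity)
      }
    }
    # background lymphocyte nuclei in DAPI
    n_nuc <- stats::rpois(1L, 80 * v_img / 1e5)
    for (i in seq_len(n_nuc)) {
      pos <- stats::runif(3L) * size
      ch$dapi <- rasterize_ellipsoid(ch$dapi, sp, pos, rep(2.5, 3), diag(3),
                                     value = stats::runif(1L, 50, 90))
    }
    noise <- preset$image_params$noise
    for (nm in names(ch)) {
      ch[[nm]] <- pmax(ch[[nm]] + noise$background +
                         array(stats::rnorm(prod(nv), 0, noise$sd), nv), 0)
    }
    list(image = voxel_image(ch, sp), cells = gt)
  })
}

empty_ground_truth <- function() {
  tibble::tibble(cell_id = integer(0), marker = character(0),
                 x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                 a_um = numeric(0), b_um = numeric(0), c_um = numeric(0),
                 rotation = list(), true_volume_um3 = numeric(0),
                 marker_intensity = numeric(0), dapi_intensity = numeric(0))
}

# paint value into all voxels whose centre lies inside the rotated ellipsoid
rasterize_ellipsoid <- function(arr, spacing, centre, axes, rotation, value) {
  nv <- dim(arr)
  amax <- max(axes)
  lo <- pmax(1L, as.integer(floor((centre - amax) / spacing)) + 1L)
  hi <- pmin(nv, as.integer(ceiling((centre + amax) / spacing)))
  if (any(lo > hi)) return(arr)
  xs <- (lo[1]:hi[1] - 0.5) * spacing[1] - centre[1]
  ys <- (lo[2]:hi[2] - 0.5) * spacing[2] - centre[2]
  zs <- (lo[3]:hi[3] - 0.5) * spacing[3] - centre[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  u <- as.matrix(g) %*% rotation  # body-frame coordinates (R^T p)'
  qd <- (u[, 1] / axes[1])^2 + (u[, 2] / axes[2])^2 + (u[, 3] / axes[3])^2
  inside <- qd <= 1
  if (!any(inside)) return(arr)
  sub <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  sub[inside] <- pmax(sub[inside], value)
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  arr
}
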