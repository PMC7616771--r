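# Synthetic fluorescence fields and z-stacks with known ground truth:
# nuclei as disks of stated radius, a collagen channel of stated uniform
# intensity, and labeled organoid-like ROIs in projected stacks.

#' Specification for a paired nuclei/collagen fluorescence field
#'
#' @param n_cells Number of nuclei (disks) to place, >= 0.
#' @param width_px,height_px Field size in pixels.
#' @param cell_radius_px Nucleus radius in pixels (> 0).
#' @param nucleus_intensity,collagen_intensity Signal levels (16-bit scale).
#' @param background Additive background level, >= 0.
#' @param noise_sd SD of additive Gaussian noise, >= 0.
#' @param allow_touching If `FALSE` (default), nuclei are placed with centers
#'   at least `2 * cell_radius_px + min_gap_px` apart; placement fails with an
#'   error if the field cannot fit `n_cells` after bounded retries.
#' @param min_gap_px Minimum clear gap between disk edges when
#'   `allow_touching = FALSE`, default 12 px — enough that neighboring nuclei
#'   remain optically separate at typical smoothing scales (their gradient
#'   rings extend a few pixels beyond the disk edge).
#' @param seed Integer seed.
#' @return Object of class `fluor_sim_spec`.
#' @export
fluor_sim_spec <- function(n_cells = 20, width_px = 512, height_px = 512,
                           cell_radius_px = 8,
                           nucleus_intensity = 10000,
                           collagen_intensity = 2000,
                           background = 100, noise_sd = 20,
                           allow_touching = FALSE, min_gap_px = 12,
                           seed = 1L) {
  stopifnot_scalar_number(n_cells, "n_cells", min = 0, integer = TRUE)
  stopifnot_scalar_number(width_px, "width_px", min = 1, integer = TRUE)
  stopifnot_scalar_number(height_px, "height_px", min = 1, integer = TRUE)
  stopifnot_scalar_number(cell_radius_px, "cell_radius_px", min = 1e-9)
  stopifnot_scalar_number(nucleus_intensity, "nucleus_intensity", min = 1e-9)
  stopifnot_scalar_number(collagen_intensity, "collagen_intensity", min = 1e-9)
  stopifnot_scalar_number(background, "background", min = 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  stopifnot(is.logical(allow_touching), length(allow_touching) == 1L)
  stopifnot_scalar_number(min_gap_px, "min_gap_px", min = 0)
  stopifnot_scalar_number(seed, "seed", integer = TRUE)
  structure(list(n_cells = as.integer(n_cells),
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 cell_radius_px = cell_radius_px,
                 nucleus_intensity = nucleus_intensity,
                 collagen_intensity = collagen_intensity,
                 background = background, noise_sd = noise_sd,
                 allow_touching = isTRUE(allow_touching),
                 min_gap_px = min_gap_px,
                 seed = as.integer(seed)),
            class = "fluor_sim_spec")
}

# Rejection-sample n centers with minimum pairwise distance min_dist,
# margin px from the border. Errors after bounded retries.
place_centers <- function(n, H, W, radius, min_dist, max_tries = 200L) {
  margin <- ceiling(radius) + 1
  if (H - 2 * margin < 0 || W - 2 * margin < 0) {
    stop("field too small for the stated cell radius", call. = FALSE)
  }
  centers <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      y <- stats::runif(1, margin + 1, H - margin)
      x <- stats::runif(1, margin + 1, W - margin)
      if (nrow(centers) == 0L ||
          min((centers[, 1] - y)^2 + (centers[, 2] - x)^2) >= min_dist^2) {
        centers <- rbind(centers, c(y, x))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf("could not place %d non-touching nuclei in a %dx%d field",
                   n, H, W), call. = FALSE)
    }
  }
  centers
}

disk_mask <- function(H, W, cy, cx, r) {
  ys <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
  sub <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
  idx <- cbind(rep(ys, times = length(xs))[as.vector(sub)],
               rep(xs, each = length(ys))[as.vector(sub)])
  idx
}

#' Generate a paired nuclei/collagen fluorescence field
#'
#' The nuclei channel contains `n_cells` disks of `nucleus_intensity` on a
#' flat background; the collagen channel is uniform `collagen_intensity` over
#' the whole field plus background. Gaussian noise is added to both. Ground
#' truth (count, centers, designed per-cell collagen under the per-count
#' convention) is returned with the images.
#'
#' @param spec A [fluor_sim_spec()].
#' @return List with `nuclei`, `collagen` (H x W matrices), `n_cells`,
#'   `centers` (n x 2 matrix, row/col), and `true_per_cell_collagen`
#'   (designed field total / n_cells; `NA` when `n_cells = 0`).
#' @export
gen_fluor_pair <- function(spec) {
  if (!inherits(spec, "fluor_sim_spec")) {
    stop("'spec' must be a fluor_sim_spec", call. = FALSE)
  }
  H <- spec$height_px; W <- spec$width_px
  with_rng_seed(stream_seed(spec$seed, "fluor"), {
    min_dist <- if (spec$allow_touching) 0 else
      2 * spec$cell_radius_px + spec$min_gap_px
    centers <- if (spec$n_cells > 0) {
      place_centers(spec$n_cells, H, W, spec$cell_radius_px, min_dist)
    } else matrix(numeric(0), ncol = 2)

    nuclei <- matrix(spec$background, H, W)
    for (i in seq_len(nrow(centers))) {
      idx <- disk_mask(H, W, centers[i, 1], centers[i, 2], spec$cell_radius_px)
      nuclei[idx] <- spec$background + spec$nucleus_intensity
    }
    collagen <- matrix(spec$background + spec$collagen_intensity, H, W)
    if (spec$noise_sd > 0) {
      nuclei <- nuclei + matrix(stats::rnorm(H * W, sd = spec$noise_sd), H, W)
      collagen <- collagen +
        matrix(stats::rnorm(H * W, sd = spec$noise_sd), H, W)
    }
    nuclei <- pmax(nuclei, 0)
    collagen <- pmax(collagen, 0)
    true_pcc <- if (spec$n_cells > 0) {
      H * W * spec$collagen_intensity / spec$n_cells
    } else NA_real_
    list(nuclei = nuclei, collagen = collagen,
         n_cells = spec$n_cells, centers = centers,
         true_per_cell_collagen = true_pcc)
  })
}

#' Generate a fluorescence z-stack with labeled ROIs and known truth
#'
#' Builds a 2-D truth image of `roi_count` disjoint disks with designed mean
#' intensities on a flat background, then distributes it over `n_slices` so
#' that the per-pixel maximum over slices equals the truth exactly: each pixel
#' attains its truth value in one randomly chosen slice and a random fraction
#' (< 1) of it elsewhere. Noise is added per slice after that.
#'
#' @param n_slices Number of slices, >= 1.
#' @param spec A [fluor_sim_spec()]; `cell_radius_px` is the ROI radius and
#'   `background`/`noise_sd` have their usual meaning.
#' @param roi_count Number of ROIs to place, >= 1.
#' @param roi_intensities Designed ROI intensities above background; recycled
#'   to `roi_count`. Default `c(10, 20, 40)`.
#' @return List with `stack` (H x W x n_slices array), `roi_masks` (integer
#'   label matrix, 0 = background), `truth` (the noise-free 2-D truth image)
#'   and `true_roi_means` (designed per-ROI mean above background).
#' @export
gen_zstack <- function(n_slices, spec, roi_count = 3,
                       roi_intensities = c(10, 20, 40)) {
  stopifnot_scalar_number(n_slices, "n_slices", min = 1, integer = TRUE)
  stopifnot_scalar_number(roi_count, "roi_count", min = 1, integer = TRUE)
  if (!inherits(spec, "fluor_sim_spec")) {
    stop("'spec' must be a fluor_sim_spec", call. = FALSE)
  }
  H <- spec$height_px; W <- spec$width_px
  vals <- rep_len(roi_intensities, roi_count)
  with_rng_seed(stream_seed(spec$seed, "zstack"), {
    centers <- place_centers(roi_count, H, W, spec$cell_radius_px,
                             2 * spec$cell_radius_px + 2)
    labels <- matrix(0L, H, W)
    truth <- matrix(0, H, W)
    for (i in seq_len(roi_count)) {
      idx <- disk_mask(H, W, centers[i, 1], centers[i, 2], spec$cell_radius_px)
      labels[idx] <- i
      truth[idx] <- vals[i]
    }
    if (n_slices == 1L) {
      stack <- array(truth, dim = c(H, W, 1L))
    } else {
      argmax <- matrix(sample.int(n_slices, H * W, replace = TRUE), H, W)
      stack <- array(0, dim = c(H, W, n_slices))
      for (k in seq_len(n_slices)) {
        frac <- matrix(stats::runif(H * W, 0, 0.8), H, W)
        sl <- truth * frac
        sl[argmax == k] <- truth[argmax == k]
        stack[, , k] <- sl
      }
    }
    stack <- stack + spec$background
    if (spec$noise_sd > 0) {
      stack <- stack + array(stats::rnorm(length(stack), sd = spec$noise_sd),
                             dim = dim(stack))
      stack <- pmax(stack, 0)
    }
    list(stack = stack, roi_masks = labels, truth = truth,
         true_roi_means = vals)
  })
}
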