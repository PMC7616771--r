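# Fluorescence-assay quantifiers: nuclei counting by edge detection with
# per-cell collagen intensity for the fibroblast-to-myofibroblast (FMT)
# assay, and z-stack projection + rolling-ball background subtraction with
# per-organoid ROI intensities.

sobel_gradient <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- as.matrix(EBImage::filter2(EBImage::Image(img), kx))
  gy <- as.matrix(EBImage::filter2(EBImage::Image(img), t(kx)))
  sqrt(gx^2 + gy^2)
}

#' Detect nuclei by edge detection
#'
#' Pipeline: Gaussian smoothing, Sobel gradient magnitude, hysteresis
#' thresholding, morphological closing, hole filling, connected-component
#' labeling and a minimum-area filter. By default the strong hysteresis
#' threshold is the Otsu split of the gradient-magnitude distribution and the
#' weak threshold is `hysteresis_ratio` times it — scale-free, so the
#' detector adapts to exposure and to how much of the field is foreground.
#' `threshold_method = "quantile"` instead takes both thresholds as
#' quantiles of the gradient distribution. Deterministic for fixed
#' parameters. Touching nuclei are not split.
#'
#' @param img 2-D numeric matrix (grayscale nuclei channel).
#' @param sigma Gaussian smoothing SD in pixels, default 2.
#' @param threshold_method `"otsu"` (default) or `"quantile"`.
#' @param hysteresis_ratio Weak threshold as a fraction of the strong one
#'   (Otsu mode), default 0.5.
#' @param low_quantile,high_quantile Gradient quantiles for the weak and
#'   strong thresholds in quantile mode, defaults 0.7 and 0.9.
#' @param closing_radius Disc radius (px) of the morphological closing.
#' @param min_area_px Minimum object area in pixels; smaller components are
#'   discarded, default 20.
#' @return Object of class `nuclei_segmentation`: `labels` (integer H x W
#'   matrix, 0 = background), `n_cells`, `cells` (data frame with label,
#'   area_px, centroid row/col) and `params`.
#' @export
detect_nuclei <- function(img, sigma = 2,
                          threshold_method = c("otsu", "quantile"),
                          hysteresis_ratio = 0.5, low_quantile = 0.7,
                          high_quantile = 0.9, closing_radius = 2,
                          min_area_px = 20) {
  threshold_method <- match.arg(threshold_method)
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("'img' must be a 2-D numeric matrix", call. = FALSE)
  }
  stopifnot_scalar_number(sigma, "sigma", min = 0.1)
  stopifnot_scalar_number(hysteresis_ratio, "hysteresis_ratio", 1e-6, 1)
  stopifnot_scalar_number(low_quantile, "low_quantile", 0, 1)
  stopifnot_scalar_number(high_quantile, "high_quantile", low_quantile, 1)
  params <- list(sigma = sigma, threshold_method = threshold_method,
                 hysteresis_ratio = hysteresis_ratio,
                 low_quantile = low_quantile,
                 high_quantile = high_quantile,
                 closing_radius = closing_radius, min_area_px = min_area_px)
  empty <- function() {
    structure(list(labels = matrix(0L, nrow(img), ncol(img)), n_cells = 0L,
                   cells = data.frame(label = integer(0), area_px = integer(0),
                                      centroid_row = numeric(0),
                                      centroid_col = numeric(0)),
                   params = params), class = "nuclei_segmentation")
  }
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))
  grad <- sobel_gradient(sm)
  if (max(grad) - min(grad) < 1e-12) return(empty())   # flat field, no edges
  if (threshold_method == "otsu") {
    hi <- otsu_threshold(as.vector(grad))
    lo <- hysteresis_ratio * hi
  } else {
    lo <- stats::quantile(grad, low_quantile, names = FALSE)
    hi <- stats::quantile(grad, high_quantile, names = FALSE)
  }
  # noise floor: on a structureless field the gradient distribution is
  # unimodal and its Otsu split sits within a few multiples of the median;
  # genuine edges are orders of magnitude above it
  if (hi < 5 * stats::median(grad)) return(empty())
  strong <- grad > hi
  weak <- grad > lo
  if (!any(strong)) return(empty())
  # hysteresis: keep weak components that contain at least one strong pixel
  wl <- EBImage::bwlabel(EBImage::Image(weak * 1))
  keep <- unique(as.integer(wl[strong]))
  keep <- keep[keep > 0]
  edges <- matrix(as.integer(wl) %in% keep, nrow(img), ncol(img))
  if (!any(edges)) return(empty())
  closed <- EBImage::closing(EBImage::Image(edges * 1),
                             EBImage::makeBrush(2L * closing_radius + 1L,
                                                shape = "disc"))
  filled <- EBImage::fillHull(closed)
  lbl <- EBImage::bwlabel(filled)
  areas <- tabulate(as.integer(lbl))
  keep_lbl <- which(areas >= min_area_px)
  if (length(keep_lbl) == 0L) return(empty())
  relabel <- integer(length(areas))
  relabel[keep_lbl] <- seq_along(keep_lbl)
  lm <- matrix(0L, nrow(img), ncol(img))
  nz <- as.integer(lbl) > 0L
  lm[nz] <- relabel[as.integer(lbl)[nz]]
  rows <- row(lm); cols <- col(lm)
  cells <- data.frame(
    label = seq_along(keep_lbl),
    area_px = as.integer(tabulate(lm[lm > 0], nbins = length(keep_lbl))),
    centroid_row = as.numeric(tapply(rows[lm > 0], lm[lm > 0], mean)),
    centroid_col = as.numeric(tapply(cols[lm > 0], lm[lm > 0], mean)))
  structure(list(labels = lm, n_cells = length(keep_lbl), cells = cells,
                 params = params), class = "nuclei_segmentation")
}

#' @export
print.nuclei_segmentation <- function(x, ...) {
  cat(sprintf("nuclei_segmentation: %d cells", x$n_cells))
  if (x$n_cells > 0) {
    cat(sprintf(", median area %.0f px", stats::median(x$cells$area_px)))
  }
  cat("\n")
  invisible(x)
}

#' Per-cell collagen intensity for one field
#'
#' Default mode `"per_count"`: integrated collagen intensity over the whole
#' field divided by the nuclei count (the assay's per-cell mean without
#' cytoplasm segmentation). Mode `"per_mask"`: mean collagen intensity
#' within the dilated nuclei masks. Zero detected cells is an error (the
#' per-cell value is undefined); batch wrappers flag and exclude such
#' fields.
#'
#' @param collagen 2-D collagen-channel matrix, same shape as the
#'   segmentation.
#' @param seg A [detect_nuclei()] result.
#' @param mode `"per_count"` (default) or `"per_mask"`.
#' @param dilate_radius Disc radius for mask dilation in `"per_mask"` mode.
#' @param field_id,condition,well_id Metadata propagated into the record.
#' @return Object of class `field_quant` (also a list): field_id, n_cells,
#'   collagen_sum, per_cell_intensity, mode, condition, well_id.
#' @export
per_cell_collagen <- function(collagen, seg, mode = c("per_count", "per_mask"),
                              dilate_radius = 2, field_id = "field",
                              condition = NA_character_,
                              well_id = NA_character_) {
  mode <- match.arg(mode)
  if (!inherits(seg, "nuclei_segmentation")) {
    stop("'seg' must come from detect_nuclei()", call. = FALSE)
  }
  if (!all(dim(collagen) == dim(seg$labels))) {
    stop("collagen image and segmentation shapes differ", call. = FALSE)
  }
  if (seg$n_cells == 0L) {
    stop("zero cells detected: per-cell intensity undefined", call. = FALSE)
  }
  if (mode == "per_count") {
    total <- sum(collagen)
    val <- total / seg$n_cells
  } else {
    mask <- seg$labels > 0L
    if (dilate_radius > 0) {
      mask <- as.matrix(EBImage::dilate(
        EBImage::Image(mask * 1),
        EBImage::makeBrush(2L * dilate_radius + 1L, shape = "disc"))) > 0
    }
    total <- sum(collagen[mask])
    val <- mean(collagen[mask])
  }
  structure(list(field_id = field_id, n_cells = seg$n_cells,
                 collagen_sum = total, per_cell_intensity = val,
                 mode = mode, condition = condition, well_id = well_id),
            class = "field_quant")
}

#' @export
print.field_quant <- function(x, ...) {
  cat(sprintf("field_quant '%s': %d cells, per-cell intensity %.2f (%s)\n",
              x$field_id, x$n_cells, x$per_cell_intensity, x$mode))
  invisible(x)
}

#' Quantify one FMT field from a nuclei/collagen image pair
#'
#' Convenience wrapper: [detect_nuclei()] on the nuclei channel then
#' [per_cell_collagen()] on the collagen channel.
#'
#' @param nuclei,collagen 2-D matrices of the two channels.
#' @param ... Passed to [per_cell_collagen()] (`mode`, metadata).
#' @param detect_params List of arguments for [detect_nuclei()].
#' @return A `field_quant`.
#' @export
fmt_quantify_field <- function(nuclei, collagen, ...,
                               detect_params = list()) {
  seg <- do.call(detect_nuclei, c(list(nuclei), detect_params))
  per_cell_collagen(collagen, seg, ...)
}

#' Normalize per-cell intensities to a control condition
#'
#' Each condition's mean per-cell intensity is divided by the control
#' condition's mean, so the control maps to fold change 1.0. Per-field
#' normalized values are also returned for group testing.
#'
#' @param fields Data frame with columns `condition` and
#'   `per_cell_intensity` (e.g. rows built from `field_quant` records), or a
#'   list of `field_quant`.
#' @param control_condition Label of the control (no-stimulus) condition.
#' @return List: `fold_changes` (data frame condition / n_fields /
#'   mean_intensity / fold_change) and `fields` (input with a
#'   `normalized_intensity` column).
#' @export
normalize_to_control <- function(fields, control_condition = "control") {
  if (is.list(fields) && !is.data.frame(fields)) {
    fields <- do.call(rbind, lapply(fields, function(f) {
      data.frame(field_id = f$field_id, condition = f$condition,
                 n_cells = f$n_cells,
                 per_cell_intensity = f$per_cell_intensity,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!control_condition %in% fields$condition) {
    stop(sprintf("control condition '%s' has no fields", control_condition),
         call. = FALSE)
  }
  ctrl_mean <- mean(fields$per_cell_intensity[
    fields$condition == control_condition])
  means <- stats::aggregate(per_cell_intensity ~ condition, fields, mean)
  counts <- stats::aggregate(per_cell_intensity ~ condition, fields, length)
  fc <- data.frame(condition = means$condition,
                   n_fields = counts$per_cell_intensity,
                   mean_intensity = means$per_cell_intensity,
                   fold_change = means$per_cell_intensity / ctrl_mean,
                   stringsAsFactors = FALSE)
  fields$normalized_intensity <- fields$per_cell_intensity / ctrl_mean
  list(fold_changes = fc, fields = fields)
}

#' Maximum intensity projection of a z-stack
#'
#' @param zstack H x W x n_slices array, or list of equal-shape matrices.
#' @return H x W matrix of per-pixel maxima.
#' @export
max_intensity_projection <- function(zstack) {
  if (is.list(zstack)) {
    if (length(zstack) == 0L) stop("empty stack", call. = FALSE)
    return(Reduce(pmax, zstack))
  }
  d <- dim(zstack)
  if (is.null(d) || length(d) != 3L || d[3] < 1L) {
    stop("'zstack' must be an H x W x n_slices array with >= 1 slice",
         call. = FALSE)
  }
  out <- zstack[, , 1L]
  for (k in seq_len(d[3])[-1L]) out <- pmax(out, zstack[, , k])
  out
}

# Non-flat grayscale erosion/dilation with a ball (sphere-cap) structuring
# element of radius r px, height normalized to 0 at the center:
# B(o) = sqrt(r^2 - |o|^2) - r  (<= 0). Offsets outside the image are
# ignored (treated as +/- Inf as appropriate).
ball_morph <- function(img, radius, op = c("erode", "dilate")) {
  op <- match.arg(op)
  H <- nrow(img); W <- ncol(img)
  r <- as.integer(floor(radius))
  off <- expand.grid(dy = -r:r, dx = -r:r)
  d2 <- off$dy^2 + off$dx^2
  off <- off[d2 <= radius^2, ]
  height <- sqrt(radius^2 - (off$dy^2 + off$dx^2)) - radius
  out <- matrix(if (op == "erode") Inf else -Inf, H, W)
  for (i in seq_len(nrow(off))) {
    dy <- off$dy[i]; dx <- off$dx[i]; h <- height[i]
    # target region in out, source region in img (shifted by the offset)
    ty <- max(1, 1 - dy):min(H, H - dy)
    tx <- max(1, 1 - dx):min(W, W - dx)
    sy <- ty + dy; sx <- tx + dx
    if (op == "erode") {
      out[ty, tx] <- pmin(out[ty, tx], img[sy, sx] - h)
    } else {
      out[ty, tx] <- pmax(out[ty, tx], img[sy, sx] + h)
    }
  }
  out
}

#' Rolling-ball background subtraction
#'
#' The background is the grayscale opening of the image with a ball
#' (sphere-cap) structuring element of the stated radius — the surface a
#' ball of that radius traces while rolling under the intensity landscape.
#' The output is image minus background, floored at zero. A flat image is
#' its own background, so it maps to all zeros; output is always bounded by
#' the input.
#'
#' @param img 2-D numeric matrix.
#' @param radius_px Ball radius in pixels (>= 1 and at most the smaller
#'   image dimension).
#' @return List: `subtracted` and `background`, both H x W matrices.
#' @export
rolling_ball_subtract <- function(img, radius_px = 50) {
  if (!is.matrix(img)) stop("'img' must be a 2-D matrix", call. = FALSE)
  stopifnot_scalar_number(radius_px, "radius_px", min = 1)
  if (radius_px > min(dim(img))) {
    stop("ball radius exceeds the image size", call. = FALSE)
  }
  background <- ball_morph(ball_morph(img, radius_px, "erode"),
                           radius_px, "dilate")
  list(subtracted = pmax(img - background, 0), background = background)
}

# 3x3 median filter (edge pixels use the available neighborhood)
median_filter3 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  stackv <- array(NA_real_, c(H, W, 9L))
  k <- 0L
  for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1L
    ty <- max(1, 1 - dy):min(H, H - dy)
    tx <- max(1, 1 - dx):min(W, W - dx)
    stackv[ty, tx, k] <- img[ty + dy, tx + dx]
  }
  apply(stackv, c(1, 2), stats::median, na.rm = TRUE)
}

#' Per-organoid ROI intensity from a projected stack
#'
#' Pipeline: 3x3 median denoising, rolling-ball background subtraction,
#' then the mean subtracted intensity within each labeled ROI. Empty ROIs
#' are skipped with a warning.
#'
#' @param img Projected 2-D image (e.g. from
#'   [max_intensity_projection()]).
#' @param roi_masks Integer label matrix (0 = background), same shape.
#' @param radius_px Rolling-ball radius, default 50.
#' @param denoise Apply the median filter first, default `TRUE`.
#' @param channel Channel label recorded per record (e.g. `"Collagen-1"`).
#' @return Data frame: organoid_id, roi_area_px, mean_intensity, channel.
#' @export
organoid_roi_intensity <- function(img, roi_masks, radius_px = 50,
                                   denoise = TRUE, channel = "Collagen-1") {
  if (!all(dim(img) == dim(roi_masks))) {
    stop("image and ROI mask shapes differ", call. = FALSE)
  }
  work <- if (denoise) median_filter3(img) else img
  work <- rolling_ball_subtract(work, radius_px)$subtracted
  ids <- sort(unique(as.integer(roi_masks)))
  ids <- ids[ids > 0]
  rows <- lapply(ids, function(i) {
    inside <- roi_masks == i
    if (!any(inside)) {
      warning(sprintf("ROI %d is empty; skipped", i), call. = FALSE)
      return(NULL)
    }
    data.frame(organoid_id = i, roi_area_px = sum(inside),
               mean_intensity = mean(work[inside]), channel = channel,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
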