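# Positivity calling and spatial summarization of the chromogen signal:
# tissue masking, pooled-cohort Otsu cutoff, micron-gridded tile heatmaps,
# per-field statistics and correlation with an external fibrosis-density map.

#' Tissue mask from total optical density
#'
#' A pixel is tissue when its total OD (summed over channels) exceeds
#' `od_min`; unstained background (intensity near I0) has OD near zero and
#' is excluded.
#'
#' @param slide An `rgb_slide`.
#' @param model A `stain_model` (supplies the background intensity I0).
#' @param od_min Total-OD threshold, >= 0; default 0.15.
#' @return Logical H x W matrix.
#' @export
tissue_mask <- function(slide, model = hdab_stain_model(), od_min = 0.15) {
  stopifnot_scalar_number(od_min, "od_min", min = 0)
  od <- od_transform(slide, I0 = model$background_intensity)
  od[, , 1] + od[, , 2] + od[, , 3] > od_min
}

#' Otsu threshold
#'
#' Histogram threshold maximizing the between-class variance of the two
#' classes it induces (values below vs at/above the returned bin edge).
#' Ties are broken by the lowest qualifying edge. Constant input has no
#' split and is an error.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param n_bins Number of equal-width histogram bins, default 256.
#' @param range Optional `c(lo, hi)` histogram range; defaults to the data
#'   range.
#' @return The threshold (a bin edge) as a single number.
#' @export
otsu_threshold <- function(values, n_bins = 256, range = NULL) {
  values <- values[!is.na(values)]
  stopifnot_scalar_number(n_bins, "n_bins", min = 2, integer = TRUE)
  if (length(values) < 2L || min(values) == max(values)) {
    stop("Otsu threshold needs at least two distinct values", call. = FALSE)
  }
  lo <- if (is.null(range)) min(values) else range[1]
  hi <- if (is.null(range)) max(values) else range[2]
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- as.numeric(tabulate(pmin(pmax(findInterval(values, edges,
                                                       rightmost.closed = TRUE),
                                          1L),
                                     n_bins), nbins = n_bins))
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w <- cumsum(counts)                       # pixels below edge k+1
  s <- cumsum(counts * mids)
  n <- w[n_bins]; total <- s[n_bins]
  # candidate thresholds: edges 2..n_bins (class0 = bins 1..k)
  k <- seq_len(n_bins - 1L)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- s[k] / w0
  mu1 <- (total - s[k]) / w1
  bcv <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  if (!any(is.finite(bcv))) {
    stop("Otsu threshold needs at least two occupied bins", call. = FALSE)
  }
  best <- which.max(bcv)   # first maximum = lowest qualifying edge
  edges[best + 1L]
}

#' Pooled-cohort positivity cutoff
#'
#' Deconvolved chromogen concentrations of all tissue pixels from all slides
#' are pooled into one distribution and a single Otsu cutoff is computed on
#' it — the cutoff is cohort-level, not per slide.
#'
#' @param slides List of `rgb_slide` objects (or of lists with elements
#'   `slide` and optional `mask`).
#' @param model A `stain_model`.
#' @param od_min Tissue-mask threshold used for slides without a supplied
#'   mask.
#' @param n_bins Histogram bins for Otsu, default 256.
#' @return Object of class `positivity_cutoff`: `cutoff`,
#'   `n_pixels_pooled`, `histogram_bins`, `cohort_ids`.
#' @export
pooled_positive_cutoff <- function(slides, model = hdab_stain_model(),
                                   od_min = 0.15, n_bins = 256) {
  if (inherits(slides, "rgb_slide")) slides <- list(slides)
  if (length(slides) < 1L) stop("empty cohort", call. = FALSE)
  pooled <- vector("list", length(slides))
  ids <- character(length(slides))
  for (i in seq_along(slides)) {
    el <- slides[[i]]
    sl <- if (inherits(el, "rgb_slide")) el else el$slide
    msk <- if (inherits(el, "rgb_slide")) NULL else el$mask
    if (is.null(msk)) msk <- tissue_mask(sl, model, od_min)
    conc <- deconvolve(od_transform(sl, model$background_intensity), model)
    pooled[[i]] <- conc$chromogen[msk]
    ids[i] <- sl$sample_id
  }
  pooled <- unlist(pooled)
  if (length(pooled) < 2L) stop("pooled tissue-pixel set is empty",
                                call. = FALSE)
  structure(list(cutoff = otsu_threshold(pooled, n_bins = n_bins),
                 n_pixels_pooled = length(pooled),
                 histogram_bins = as.integer(n_bins),
                 cohort_ids = ids),
            class = "positivity_cutoff")
}

#' @export
print.positivity_cutoff <- function(x, ...) {
  cat(sprintf(
    "positivity_cutoff: %.4f (Otsu, %d bins, %d pooled pixels, %d slides)\n",
    x$cutoff, x$histogram_bins, x$n_pixels_pooled, length(x$cohort_ids)))
  invisible(x)
}

# Shared tiling engine: per-tile tissue/positive counts on a micron grid
# anchored at the top-left pixel; partial edge tiles retained and flagged.
tile_counts <- function(positive, tissue, tile_size_um, microns_per_pixel,
                        value = NULL) {
  H <- nrow(tissue); W <- ncol(tissue)
  tile_px <- max(1L, round(tile_size_um / microns_per_pixel))
  row_tile <- (seq_len(H) - 1L) %/% tile_px
  col_tile <- (seq_len(W) - 1L) %/% tile_px
  n_r <- max(row_tile) + 1L; n_c <- max(col_tile) + 1L
  idx <- factor(rep(row_tile, times = W) + n_r * rep(col_tile, each = H),
                levels = 0:(n_r * n_c - 1L))
  tiss_ct <- as.integer(tapply(as.vector(tissue), idx, sum, default = 0L))
  pos_ct <- as.integer(tapply(as.vector(positive & tissue), idx, sum,
                              default = 0L))
  mean_val <- if (!is.null(value)) {
    num <- tapply(as.vector(value) * as.vector(tissue), idx, sum,
                  default = 0)
    ifelse(tiss_ct > 0, as.numeric(num) / tiss_ct, NA_real_)
  } else NULL
  grid <- expand.grid(row = 0:(n_r - 1L), col = 0:(n_c - 1L))
  partial <- (grid$row == n_r - 1L & H %% tile_px != 0L) |
             (grid$col == n_c - 1L & W %% tile_px != 0L)
  out <- data.frame(row = grid$row, col = grid$col,
                    tissue_px = tiss_ct, positive_px = pos_ct,
                    ratio = ifelse(tiss_ct > 0, pos_ct / tiss_ct, NA_real_),
                    partial = partial)
  if (!is.null(mean_val)) out$mean_chromogen <- mean_val
  attr(out, "tile_px") <- tile_px
  attr(out, "grid_dim") <- c(n_r, n_c)
  out
}

#' Tiled positive-pixel ratio heatmap
#'
#' Partitions the slide into an axis-aligned grid of square tiles of
#' `tile_size_um` microns (default 256) anchored at the top-left pixel and
#' computes, per tile, the tissue pixel count, the count of tissue pixels
#' whose chromogen concentration exceeds the cutoff, and their ratio. Tiles
#' without tissue carry a missing ratio; partial edge tiles are kept and
#' flagged. By construction tile counts sum to the slide-level counts.
#'
#' @param conc A `concentration_maps` (or a chromogen matrix).
#' @param tissue Logical tissue mask of matching size.
#' @param cutoff A `positivity_cutoff` or a single number.
#' @param tile_size_um Tile side in microns, default 256.
#' @param microns_per_pixel Pixel pitch in microns.
#' @param sample_id Sample id recorded in the result.
#' @return Object of class `positivity_heatmap`: list with `tiles` (data
#'   frame row/col/tissue_px/positive_px/ratio/partial/mean_chromogen),
#'   `tile_size_um`, `tile_px`, `microns_per_pixel`, `cutoff`, `sample_id`.
#' @export
positivity_heatmap <- function(conc, tissue, cutoff, tile_size_um = 256,
                               microns_per_pixel = 1,
                               sample_id = "slide") {
  chrom <- if (inherits(conc, "concentration_maps")) conc$chromogen else conc
  if (!all(dim(chrom) == dim(tissue))) {
    stop("concentration map and tissue mask shapes differ", call. = FALSE)
  }
  cut <- if (inherits(cutoff, "positivity_cutoff")) cutoff$cutoff else cutoff
  stopifnot_scalar_number(tile_size_um, "tile_size_um", min = 1e-9)
  stopifnot_scalar_number(microns_per_pixel, "microns_per_pixel", min = 1e-9)
  tiles <- tile_counts(chrom > cut, tissue, tile_size_um, microns_per_pixel,
                       value = chrom)
  structure(list(tiles = tiles, tile_size_um = tile_size_um,
                 tile_px = attr(tiles, "tile_px"),
                 grid_dim = attr(tiles, "grid_dim"),
                 microns_per_pixel = microns_per_pixel,
                 cutoff = cut, sample_id = sample_id),
            class = "positivity_heatmap")
}

#' @export
print.positivity_heatmap <- function(x, ...) {
  n_tissue <- sum(x$tiles$tissue_px)
  n_pos <- sum(x$tiles$positive_px)
  cat(sprintf(
    "positivity_heatmap '%s': %d x %d tiles of %g um (%d px), cutoff %.4f\n",
    x$sample_id, x$grid_dim[1], x$grid_dim[2], x$tile_size_um, x$tile_px,
    x$cutoff))
  cat(sprintf("  slide positive ratio %.4f (%d / %d tissue px)\n",
              if (n_tissue > 0) n_pos / n_tissue else NA, n_pos, n_tissue))
  invisible(x)
}

#' Whole-slide positive ratio of a heatmap
#'
#' @param heatmap A `positivity_heatmap`.
#' @return Slide-level positive / tissue pixel ratio.
#' @export
slide_positive_ratio <- function(heatmap) {
  sum(heatmap$tiles$positive_px) / sum(heatmap$tiles$tissue_px)
}

#' Plot a positivity heatmap
#'
#' Renders the per-tile positive ratio on a blue-to-red diverging scale
#' (blue = low, red = high); tiles without tissue are blank.
#'
#' @param x A `positivity_heatmap`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the ratio matrix that was drawn.
#' @export
plot.positivity_heatmap <- function(x, ...) {
  m <- matrix(NA_real_, x$grid_dim[1], x$grid_dim[2])
  m[cbind(x$tiles$row + 1L, x$tiles$col + 1L)] <- x$tiles$ratio
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(64)
  graphics::image(t(m)[, nrow(m):1, drop = FALSE], col = pal,
                  zlim = c(0, 1), axes = FALSE,
                  main = sprintf("%s: positive-pixel ratio", x$sample_id),
                  ...)
  invisible(m)
}

#' Per-field positivity records
#'
#' Cuts the slide into square fields of `field_size_um` (the high-power-field
#' analogue) and emits one record per field with tissue: positive-pixel
#' ratio, mean chromogen concentration and the slide's group label.
#' Fields without tissue are excluded.
#'
#' @inheritParams positivity_heatmap
#' @param field_size_um Field side in microns; default 487 um
#'   (a square of ~0.237 mm^2, a common 40x high-power field).
#' @param group Group label (e.g. HD / ET / PV / MF) propagated to records.
#' @return Data frame: field_id, row, col, tissue_px, positive_ratio,
#'   mean_chromogen, group, sample_id.
#' @export
per_field_positivity <- function(conc, tissue, cutoff, field_size_um = 487,
                                 microns_per_pixel = 1, group = NA_character_,
                                 sample_id = "slide") {
  hm <- positivity_heatmap(conc, tissue, cutoff, field_size_um,
                           microns_per_pixel, sample_id)
  t <- hm$tiles[hm$tiles$tissue_px > 0, , drop = FALSE]
  data.frame(field_id = sprintf("%s_r%d_c%d", sample_id, t$row, t$col),
             row = t$row, col = t$col, tissue_px = t$tissue_px,
             positive_ratio = t$ratio, mean_chromogen = t$mean_chromogen,
             group = group, sample_id = sample_id,
             stringsAsFactors = FALSE)
}

#' Correlate tile positivity with an external density map
#'
#' Spearman rank correlation between a heatmap's per-tile positive ratios
#' and an externally supplied per-tile density (e.g. a fibrosis-severity
#' map on the same grid), over tiles where both are present.
#'
#' @param heatmap A `positivity_heatmap`.
#' @param density_map Either a numeric vector aligned with `heatmap$tiles`
#'   rows, or a data frame with columns `row`, `col`, `density` keyed on the
#'   same tile grid.
#' @return List: `rho`, `p`, `n` (tiles used).
#' @export
intensity_density_correlation <- function(heatmap, density_map) {
  t <- heatmap$tiles
  dens <- if (is.data.frame(density_map)) {
    key <- paste(t$row, t$col)
    dm <- density_map[match(key, paste(density_map$row, density_map$col)), ]
    dm$density
  } else {
    if (length(density_map) != nrow(t)) {
      stop("density vector length must match the tile grid", call. = FALSE)
    }
    as.numeric(density_map)
  }
  ok <- !is.na(t$ratio) & !is.na(dens)
  if (sum(ok) < 3L) {
    stop("fewer than 3 tiles with both positivity and density values",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(t$ratio[ok], dens[ok],
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
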