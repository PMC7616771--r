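# Beer-Lambert color model: optical-density conversion, stain-matrix
# deconvolution, and cross-batch stain normalization.

#' Construct a stain model
#'
#' A stain model holds three unit-length optical-density (OD) color vectors —
#' the chromogen of interest (e.g. DAB), the counterstain (e.g. hematoxylin)
#' and a complement completing the basis — plus the background (unstained)
#' intensity `I0`. Stains mix linearly in OD space (Beer-Lambert), so the
#' model is a 3x3 matrix `M` with `OD = concentrations %*% M`.
#'
#' @param chromogen,counterstain Unit 3-vectors (rows of `M`). Values within
#'   `1e-9` of unit length are accepted; anything else is an error.
#' @param complement Optional third unit vector; defaults to the normalized
#'   cross product of the first two (see [complete_stain_matrix()]).
#' @param background_intensity Background (I0) intensity in `(0, 255]`.
#' @return An object of class `stain_model`: list with `vectors` (3x3 matrix,
#'   rows `chromogen`, `counterstain`, `complement`) and
#'   `background_intensity`.
#' @seealso [hdab_stain_model()] for the bundled H-DAB defaults.
#' @export
stain_model <- function(chromogen, counterstain, complement = NULL,
                        background_intensity = 255) {
  check_unit <- function(v, name) {
    if (!is.numeric(v) || length(v) != 3L) {
      stop(sprintf("'%s' must be a numeric 3-vector", name), call. = FALSE)
    }
    if (abs(sqrt(sum(v^2)) - 1) > 1e-9) {
      stop(sprintf("'%s' must have unit Euclidean norm (got %.6f)",
                   name, sqrt(sum(v^2))), call. = FALSE)
    }
    v
  }
  chromogen <- check_unit(chromogen, "chromogen")
  counterstain <- check_unit(counterstain, "counterstain")
  if (is.null(complement)) {
    complement <- cross3(chromogen, counterstain)
    if (sqrt(sum(complement^2)) < 1e-8) {
      stop("chromogen and counterstain vectors are collinear", call. = FALSE)
    }
    complement <- unitize(complement)
  } else {
    complement <- check_unit(complement, "complement")
  }
  stopifnot_scalar_number(background_intensity, "background_intensity",
                          min = 1e-12, max = 255)
  M <- rbind(chromogen = chromogen, counterstain = counterstain,
             complement = complement)
  colnames(M) <- c("R", "G", "B")
  if (!is.finite(rcond(M)) || rcond(M) < 1e-10) {
    stop("stain matrix is rank-deficient (not invertible)", call. = FALSE)
  }
  structure(list(vectors = M, background_intensity = background_intensity),
            class = "stain_model")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Complete a two-stain basis to an invertible stain matrix
#'
#' Two measured stain vectors span only a plane of OD space; inverting the
#' 3x3 mixing system needs a third, which is taken as the normalized cross
#' product of the first two (orthogonal to both, so it absorbs residual color
#' not explained by either stain).
#'
#' @param v1,v2 Unit 3-vectors (chromogen, counterstain). Non-unit inputs are
#'   rejected; collinear inputs are an error.
#' @param background_intensity Passed through to [stain_model()].
#' @return A `stain_model`.
#' @export
complete_stain_matrix <- function(v1, v2, background_intensity = 255) {
  stain_model(v1, v2, complement = NULL,
              background_intensity = background_intensity)
}

#' Bundled H-DAB stain model
#'
#' Standard published unit OD vectors for hematoxylin and DAB brightfield
#' IHC; stain 1 is the DAB chromogen, stain 2 the hematoxylin counterstain,
#' and the third row is their normalized cross product. Override with
#' [stain_model()] when measured vectors are available.
#'
#' @param background_intensity Background intensity I0, default 255.
#' @return A `stain_model`.
#' @export
hdab_stain_model <- function(background_intensity = 255) {
  dab <- unitize(c(0.268, 0.570, 0.776))
  hema <- unitize(c(0.650, 0.704, 0.286))
  stain_model(dab, hema, background_intensity = background_intensity)
}

#' @export
print.stain_model <- function(x, ...) {
  cat("stain_model: 3-stain Beer-Lambert OD mixing matrix\n")
  print(round(x$vectors, 4))
  cat(sprintf("background intensity I0 = %g\n", x$background_intensity))
  invisible(x)
}

#' Construct a brightfield RGB slide
#'
#' @param pixels H x W x 3 array of 8-bit intensities (0-255).
#' @param microns_per_pixel Pixel pitch in microns (> 0).
#' @param sample_id Sample identifier string.
#' @return Object of class `rgb_slide`.
#' @export
rgb_slide <- function(pixels, microns_per_pixel, sample_id = "slide") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("'pixels' must be an H x W x 3 array", call. = FALSE)
  }
  if (any(dim(pixels)[1:2] < 1L)) stop("empty image", call. = FALSE)
  stopifnot_scalar_number(microns_per_pixel, "microns_per_pixel", min = 1e-12)
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("'pixels' must lie in [0, 255]", call. = FALSE)
  }
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel,
                 sample_id = as.character(sample_id)),
            class = "rgb_slide")
}

#' @export
print.rgb_slide <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("rgb_slide '%s': %d x %d px, %.3f um/px\n",
              x$sample_id, d[1], d[2], x$microns_per_pixel))
  invisible(x)
}

#' Convert intensities to optical density
#'
#' Per channel, `OD = log10(I0 / max(I, 1))`; the floor of 1 keeps the OD of
#' fully absorbed (zero-intensity) pixels finite.
#'
#' @param slide An `rgb_slide`, or an H x W x 3 intensity array.
#' @param I0 Background intensity (> 0), default 255.
#' @return H x W x 3 array of optical densities.
#' @export
od_transform <- function(slide, I0 = 255) {
  stopifnot_scalar_number(I0, "I0", min = 1e-12)
  px <- if (inherits(slide, "rgb_slide")) slide$pixels else slide
  log10(I0 / pmax(px, 1))
}

#' Deconvolve an OD image into per-stain concentration maps
#'
#' Solves `OD = concentrations %*% M` per pixel by applying the inverse of the
#' stain matrix. Physically impossible negative concentrations (noise,
#' off-model color) are clipped at zero under the default policy; `"raw"`
#' keeps them for diagnostics.
#'
#' @param od H x W x 3 optical-density array (from [od_transform()]).
#' @param model A `stain_model`.
#' @param clipping_policy `"clip_at_zero"` (default) or `"raw"`.
#' @return Object of class `concentration_maps`: list of H x W matrices
#'   `chromogen`, `counterstain`, `complement`, plus `clipping_policy`.
#' @export
deconvolve <- function(od, model, clipping_policy = c("clip_at_zero", "raw")) {
  clipping_policy <- match.arg(clipping_policy)
  if (!inherits(model, "stain_model")) stop("'model' must be a stain_model",
                                            call. = FALSE)
  d <- dim(od)
  if (length(d) != 3L || d[3] != 3L) stop("'od' must be H x W x 3",
                                          call. = FALSE)
  flat <- matrix(od, ncol = 3L)               # pixels x channels
  conc <- flat %*% solve(model$vectors)       # pixels x stains
  if (clipping_policy == "clip_at_zero") conc[conc < 0] <- 0
  maps <- lapply(1:3, function(j) matrix(conc[, j], d[1], d[2]))
  names(maps) <- rownames(model$vectors)
  structure(c(maps, list(clipping_policy = clipping_policy)),
            class = "concentration_maps")
}

#' @export
print.concentration_maps <- function(x, ...) {
  d <- dim(x$chromogen)
  cat(sprintf("concentration_maps: %d x %d px, clipping = %s\n",
              d[1], d[2], x$clipping_policy))
  for (s in c("chromogen", "counterstain", "complement")) {
    cat(sprintf("  %-12s range [%.4f, %.4f]\n", s, min(x[[s]]), max(x[[s]])))
  }
  invisible(x)
}

#' Per-stain reference statistics for normalization
#'
#' Computes the robust maximum (a high percentile, default the 99th) of each
#' stain's concentration over tissue pixels, the anchor used by
#' [normalize_stains()] to align staining batches.
#'
#' @param conc A `concentration_maps`.
#' @param tissue_mask Logical matrix marking tissue pixels; `NULL` uses all.
#' @param prob Percentile in (0, 1], default 0.99.
#' @return Named numeric vector (chromogen, counterstain, complement).
#' @export
stain_reference_stats <- function(conc, tissue_mask = NULL, prob = 0.99) {
  stopifnot_scalar_number(prob, "prob", min = 1e-6, max = 1)
  vapply(c("chromogen", "counterstain", "complement"), function(s) {
    v <- conc[[s]]
    if (!is.null(tissue_mask)) v <- v[tissue_mask]
    if (length(v) == 0L) return(NA_real_)
    unname(stats::quantile(v, prob, names = FALSE, type = 7))
  }, numeric(1))
}

#' Normalize stain concentrations to a reference cohort
#'
#' Rescales each stain map by (reference robust max / source robust max),
#' computed over tissue pixels, so slides stained in different batches share a
#' common concentration scale. A stain whose source robust max is zero is left
#' unscaled with a warning (nothing to anchor on). Scaling factors are
#' recorded in the `"scale_factors"` attribute.
#'
#' @param conc A `concentration_maps`.
#' @param reference_stats Named vector from [stain_reference_stats()] on the
#'   reference cohort.
#' @param tissue_mask Logical matrix restricting the source statistics.
#' @param prob Percentile matching the reference statistics, default 0.99.
#' @return A rescaled `concentration_maps` with attribute `scale_factors`.
#' @export
normalize_stains <- function(conc, reference_stats, tissue_mask = NULL,
                             prob = 0.99) {
  src <- stain_reference_stats(conc, tissue_mask, prob)
  out <- conc
  factors <- c(chromogen = 1, counterstain = 1, complement = 1)
  for (s in names(factors)) {
    ref <- reference_stats[[s]]
    if (is.null(ref) || is.na(ref)) next
    if (!is.na(src[[s]]) && src[[s]] > 0) {
      factors[[s]] <- ref / src[[s]]
      out[[s]] <- conc[[s]] * factors[[s]]
    } else {
      warning(sprintf("stain '%s': source robust max is 0; scaling skipped", s),
              call. = FALSE)
    }
  }
  attr(out, "scale_factors") <- factors
  out
}
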