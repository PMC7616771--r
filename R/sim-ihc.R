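# Synthetic brightfield IHC slides with known positive-pixel ground truth.
# Forward Beer-Lambert model: designed per-pixel stain concentrations are
# mixed through the stain matrix into OD, optionally perturbed by Gaussian OD
# noise (multiplicative in intensity), exponentiated back to intensity and
# quantized to 8 bits. The deconvolution pipeline must invert this exactly up
# to quantization, which is what makes the IHC stages testable.

#' Specification for a synthetic IHC slide
#'
#' @param width_px,height_px Image size in pixels.
#' @param microns_per_pixel Pixel pitch (um/px), default 1.
#' @param positive_fraction Designed fraction of tissue pixels carrying the
#'   high chromogen level, in `[0, 1]`.
#' @param chromogen_conc_pos,chromogen_conc_neg Chromogen concentration (OD
#'   units) of positive and negative tissue pixels; `pos` must exceed `neg`.
#' @param counterstain_conc Counterstain concentration on all tissue pixels.
#' @param noise_sd SD of additive Gaussian noise in OD space.
#' @param tissue_fraction Fraction of the image covered by tissue, in (0, 1].
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return Object of class `ihc_sim_spec`.
#' @export
ihc_sim_spec <- function(width_px = 512, height_px = 512,
                         microns_per_pixel = 1,
                         positive_fraction = 0.3,
                         chromogen_conc_pos = 1.0,
                         chromogen_conc_neg = 0.1,
                         counterstain_conc = 0.4,
                         noise_sd = 0,
                         tissue_fraction = 1,
                         seed = 1L) {
  stopifnot_scalar_number(width_px, "width_px", min = 1, integer = TRUE)
  stopifnot_scalar_number(height_px, "height_px", min = 1, integer = TRUE)
  stopifnot_scalar_number(microns_per_pixel, "microns_per_pixel", min = 1e-9)
  stopifnot_scalar_number(positive_fraction, "positive_fraction", 0, 1)
  stopifnot_scalar_number(chromogen_conc_pos, "chromogen_conc_pos", min = 0)
  stopifnot_scalar_number(chromogen_conc_neg, "chromogen_conc_neg", min = 0)
  if (chromogen_conc_pos <= chromogen_conc_neg) {
    stop("chromogen_conc_pos must exceed chromogen_conc_neg", call. = FALSE)
  }
  stopifnot_scalar_number(counterstain_conc, "counterstain_conc", min = 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  stopifnot_scalar_number(tissue_fraction, "tissue_fraction", min = 1e-9,
                          max = 1)
  stopifnot_scalar_number(seed, "seed", integer = TRUE)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 microns_per_pixel = microns_per_pixel,
                 positive_fraction = positive_fraction,
                 chromogen_conc_pos = chromogen_conc_pos,
                 chromogen_conc_neg = chromogen_conc_neg,
                 counterstain_conc = counterstain_conc,
                 noise_sd = noise_sd,
                 tissue_fraction = tissue_fraction,
                 seed = as.integer(seed)),
            class = "ihc_sim_spec")
}

#' Generate a synthetic IHC slide with ground truth
#'
#' Tissue occupies a top-anchored band of rows covering `tissue_fraction` of
#' the image; a seeded random subset of tissue pixels (size
#' `round(positive_fraction * n_tissue)`) carries the high chromogen level.
#' Non-tissue pixels are noise-free background white so the tissue mask has an
#' unambiguous truth. OD noise is added before exponentiation, i.e. noise is
#' multiplicative in intensity as Beer-Lambert implies.
#'
#' @param spec An [ihc_sim_spec()].
#' @param model A [stain_model()]; defaults to [hdab_stain_model()].
#' @return List with `slide` (an `rgb_slide`), `positive_mask` and
#'   `tissue_mask` (logical matrices), and `concentrations` (the designed
#'   noise-free `concentration_maps`).
#' @export
gen_ihc_slide <- function(spec, model = hdab_stain_model()) {
  if (!inherits(spec, "ihc_sim_spec")) stop("'spec' must be an ihc_sim_spec",
                                            call. = FALSE)
  if (!inherits(model, "stain_model")) stop("'model' must be a stain_model",
                                            call. = FALSE)
  H <- spec$height_px; W <- spec$width_px
  n_px <- H * W
  n_tissue <- max(1L, round(spec$tissue_fraction * n_px))
  # top-anchored band: first n_tissue pixels in column-major order
  tissue <- matrix(seq_len(n_px) <= n_tissue, H, W)
  tissue_idx <- which(tissue)

  with_rng_seed(stream_seed(spec$seed, "ihc"), {
    n_pos <- round(spec$positive_fraction * n_tissue)
    pos_idx <- if (n_pos > 0) sample(tissue_idx, n_pos) else integer(0)
    positive <- matrix(FALSE, H, W)
    positive[pos_idx] <- TRUE

    chrom <- matrix(0, H, W)
    chrom[tissue] <- spec$chromogen_conc_neg
    chrom[positive] <- spec$chromogen_conc_pos
    cstain <- matrix(0, H, W)
    cstain[tissue] <- spec$counterstain_conc

    conc <- cbind(as.vector(chrom), as.vector(cstain), 0)
    od <- conc %*% model$vectors                       # pixels x 3
    if (spec$noise_sd > 0) {
      noise <- matrix(stats::rnorm(3L * n_px, sd = spec$noise_sd), ncol = 3L)
      noise[!tissue, ] <- 0                            # background stays clean
      od <- od + noise
    }
    od[od < 0] <- 0
    I0 <- model$background_intensity
    px <- pmin(pmax(round(I0 * 10^(-od)), 0), 255)
    pixels <- array(px, dim = c(H, W, 3L))  # non-tissue: OD 0, exactly I0

    maps <- structure(list(chromogen = chrom, counterstain = cstain,
                           complement = matrix(0, H, W),
                           clipping_policy = "clip_at_zero"),
                      class = "concentration_maps")
    list(slide = rgb_slide(pixels, spec$microns_per_pixel,
                           sample_id = sprintf("sim-ihc-%d", spec$seed)),
         positive_mask = positive,
         tissue_mask = tissue,
         concentrations = maps)
  })
}
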