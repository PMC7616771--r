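# Format I/O: 8-bit RGB / 16-bit grayscale TIFF, PNG masks, MatrixMarket
# counts, gene-set and group CSVs.

#' Write an RGB slide as 8-bit TIFF
#'
#' @param slide An `rgb_slide`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_slide_tiff <- function(slide, path) {
  tiff::writeTIFF(slide$pixels / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an RGB slide from TIFF
#'
#' @param path TIFF file with 3 channels.
#' @param microns_per_pixel Pixel pitch (not stored in plain TIFF).
#' @param sample_id Sample id; defaults to the file name.
#' @return An `rgb_slide`.
#' @export
read_slide_tiff <- function(path, microns_per_pixel,
                            sample_id = basename(path)) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) != 3L) stop("expected an RGB TIFF", call. = FALSE)
  rgb_slide(round(px[, , 1:3] * 255), microns_per_pixel, sample_id)
}

#' Write a grayscale image as 16-bit TIFF
#'
#' @param img Numeric matrix; values are clipped to `[0, max_value]` and
#'   scaled to the 16-bit range.
#' @param path Output path.
#' @param max_value Full-scale value, default 65535.
#' @return `path`, invisibly.
#' @export
write_gray_tiff <- function(img, path, max_value = 65535) {
  tiff::writeTIFF(pmin(pmax(img / max_value, 0), 1), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Read a grayscale TIFF as a matrix scaled to `[0, max_value]`
#'
#' @param path TIFF path.
#' @param max_value Full-scale value, default 65535.
#' @return Numeric matrix.
#' @export
read_gray_tiff <- function(path, max_value = 65535) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  px * max_value
}

#' Write a binary or label mask as PNG
#'
#' @param mask Logical or small-integer matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (is.logical(mask)) mask * 1 else mask / max(1, max(mask))
  png::writePNG(m, path)
  invisible(path)
}

#' Read a mask PNG
#'
#' @param path PNG path.
#' @param n_labels If > 1, rescale back to integer labels `0..n_labels`.
#' @return Logical matrix (default) or integer label matrix.
#' @export
read_mask_png <- function(path, n_labels = 1) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  if (n_labels > 1) round(m * n_labels) else m > 0.5
}

#' Export concentration maps as 32-bit float TIFF
#'
#' One single-channel float TIFF per stain. TIFF float storage is defined on
#' `[0, 1]`, so each map is divided by a per-stain scale (its maximum, or 1
#' if smaller) recorded in a `<prefix>_scale.json` sidecar; multiply back on
#' read to recover OD units.
#'
#' @param conc A `concentration_maps`.
#' @param prefix Output path prefix; files are written as
#'   `<prefix>_<stain>.tiff`.
#' @return Character vector of the written paths, invisibly.
#' @export
write_concentration_tiff <- function(conc, prefix) {
  stains <- c("chromogen", "counterstain", "complement")
  scales <- vapply(stains, function(s) max(1, max(conc[[s]])), numeric(1))
  paths <- vapply(stains, function(s) {
    p <- sprintf("%s_%s.tiff", prefix, s)
    tiff::writeTIFF(conc[[s]] / scales[[s]], p, bits.per.sample = 32L)
    p
  }, character(1))
  jsonlite::write_json(as.list(scales), sprintf("%s_scale.json", prefix),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read UMI counts from a MatrixMarket directory
#'
#' Expects `matrix.mtx` (genes x cells), `features.tsv` (gene ids in the
#' first column) and `barcodes.tsv` (cell ids), the layout droplet
#' pipelines emit.
#'
#' @param dir Directory with the three files.
#' @param cell_groups,compartment Passed to [umi_counts()]; `cell_groups`
#'   may also be a CSV path with columns `cell_id`, `group` (and optionally
#'   `compartment`).
#' @return A [umi_counts()].
#' @export
read_umi_counts <- function(dir, cell_groups = NULL,
                            compartment = "unspecified") {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- utils::read.delim(file.path(dir, "features.tsv"), header = FALSE,
                             stringsAsFactors = FALSE)
  bcs <- utils::read.delim(file.path(dir, "barcodes.tsv"), header = FALSE,
                           stringsAsFactors = FALSE)
  dimnames(m) <- list(feats[[1]], bcs[[1]])
  if (is.character(cell_groups) && length(cell_groups) == 1L &&
      file.exists(cell_groups)) {
    g <- utils::read.csv(cell_groups, stringsAsFactors = FALSE)
    cell_groups <- g$group[match(colnames(m), g$cell_id)]
    if ("compartment" %in% names(g) && compartment == "unspecified") {
      compartment <- g$compartment[1]
    }
  }
  umi_counts(m, cell_groups = cell_groups, compartment = compartment)
}

#' Write UMI counts as a MatrixMarket directory
#'
#' @param counts A [umi_counts()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_umi_counts <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(counts$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(rownames(counts$counts),
                     file.path(dir, "features.tsv"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  utils::write.table(colnames(counts$counts),
                     file.path(dir, "barcodes.tsv"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  if (!is.null(counts$cell_groups)) {
    utils::write.csv(data.frame(cell_id = colnames(counts$counts),
                                group = as.character(counts$cell_groups),
                                compartment = counts$compartment),
                     file.path(dir, "groups.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a gene set from a CSV file
#'
#' Two-column CSV `gene_id, category` (header required; `category` column
#' optional).
#'
#' @param path CSV path.
#' @param name Set name; defaults to the file name without extension.
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) {
    stop("gene-set CSV must have a 'gene_id' column", call. = FALSE)
  }
  gene_set(name, df$gene_id,
           categories = if ("category" %in% names(df)) df$category else NULL)
}
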