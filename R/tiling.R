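#' Tile an image into nonoverlapping square patches
#'
#' The image is cut into `floor(H / patch_px) x floor(W / patch_px)`
#' disjoint tiles; partial edge strips are dropped, not padded, so every
#' tile has the full physical footprint (128 um at the default scale of
#' 0.25 um/px and 512 px).
#'
#' @param image RGB array (`H x W x 3`, values in `[0, 1]`) or a path to a
#'   PNG (or TIFF, if the tiff package is installed) file.
#' @param patch_px Patch side length in pixels.
#' @return List of tiles; each tile is a list with `row`, `col` (0-based
#'   grid indices), `pixel_origin` (`c(x, y)`, 0-based top-left, with
#'   `x = col * patch_px`), and `image`.
#' @examples
#' img <- array(runif(64 * 64 * 3), c(64, 64, 3))
#' length(tile_image(img, 32))  # 4 tiles
#' @export
tile_image <- function(image, patch_px = 512) {
  image <- load_image(image)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (h < patch_px || w < patch_px) {
    stop("image is smaller than one patch in at least one dimension")
  }
  n_rows <- h %/% patch_px
  n_cols <- w %/% patch_px
  tiles <- vector("list", n_rows * n_cols)
  k <- 1L
  for (r in 0:(n_rows - 1L)) {
    for (cl in 0:(n_cols - 1L)) {
      ys <- r * patch_px + seq_len(patch_px)
      xs <- cl * patch_px + seq_len(patch_px)
      tiles[[k]] <- list(row = r, col = cl,
                         pixel_origin = c(x = cl * patch_px,
                                          y = r * patch_px),
                         image = image[ys, xs, , drop = FALSE])
      k <- k + 1L
    }
  }
  tiles
}

#' Reassemble tiles into the cropped image
#'
#' Inverse of [tile_image()] over the covered region; tiling then
#' reassembly reproduces the cropped image exactly.
#'
#' @param tiles List of tiles from [tile_image()].
#' @return RGB array covering `max(row) + 1` by `max(col) + 1` patches.
#' @export
assemble_tiles <- function(tiles) {
  if (!length(tiles)) stop("no tiles to assemble")
  px <- dim(tiles[[1L]]$image)[1L]
  n_rows <- max(vapply(tiles, `[[`, 0L, "row")) + 1L
  n_cols <- max(vapply(tiles, `[[`, 0L, "col")) + 1L
  out <- array(0, c(n_rows * px, n_cols * px, 3L))
  for (t in tiles) {
    out[t$row * px + seq_len(px), t$col * px + seq_len(px), ] <- t$image
  }
  out
}

load_image <- function(image) {
  if (is.character(image)) {
    if (grepl("\\.tiff?$", image, ignore.case = TRUE)) {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package")
      }
      image <- tiff::readTIFF(image)
    } else {
      image <- png::readPNG(image)
    }
  }
  if (length(dim(image)) == 2L) {
    image <- array(rep(image, 3L), c(dim(image), 3L))
  }
  if (dim(image)[3L] > 3L) image <- image[, , 1:3, drop = FALSE]
  image
}

#' Saturation-based tile quality control
#'
#' Classifies pixels as tissue when their HSV saturation exceeds a
#' threshold (stained tissue is colored; glass background is near-white,
#' saturation ~ 0). A tile passes QC when the tissue fraction reaches
#' `min_tissue_fraction`.
#'
#' @param tile A tile from [tile_image()] or an RGB array.
#' @param min_tissue_fraction Minimum tissue pixel fraction to pass
#'   (default 0.25).
#' @param saturation_threshold Saturation above which a pixel counts as
#'   tissue (default 0.07).
#' @return List with `qc_pass` (logical) and `tissue_fraction` in
#'   `[0, 1]`.
#' @export
qc_tile <- function(tile, min_tissue_fraction = 0.25,
                    saturation_threshold = 0.07) {
  img <- if (is.list(tile)) tile$image else tile
  mx <- pmax(img[, , 1L], img[, , 2L], img[, , 3L])
  mn <- pmin(img[, , 1L], img[, , 2L], img[, , 3L])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  tf <- mean(sat > saturation_threshold)
  list(qc_pass = tf >= min_tissue_fraction, tissue_fraction = tf)
}

#' Apply the 20-cell patch labeling rule
#'
#' A patch is tumor-flagged when it contains at least `min_cells` tumor
#' cells and lymph-flagged when it contains at least `min_cells`
#' lymphocytes; the flags are independent, so a patch may carry both.
#'
#' @param tumor_cells,lymph_cells Nonnegative cell counts (vectorized).
#' @param min_cells Labeling threshold (default 20).
#' @return data.frame with logical columns `has_tumor`, `has_lymph`.
#' @examples
#' label_from_counts(c(19, 20, 0), c(0, 20, 400))
#' @export
label_from_counts <- function(tumor_cells, lymph_cells, min_cells = 20) {
  if (length(tumor_cells) != length(lymph_cells)) {
    stop("count vectors must have equal length")
  }
  if (any(tumor_cells < 0) || any(lymph_cells < 0)) {
    stop("cell counts must be nonnegative")
  }
  data.frame(has_tumor = tumor_cells >= min_cells,
             has_lymph = lymph_cells >= min_cells)
}
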