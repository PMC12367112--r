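#' Patch-grid container
#'
#' A `patch_grid` is the pipeline's central object: a rectangular lattice of
#' patches covering a slide region, with per-patch tissue / tumor /
#' lymphocyte-aggregate flags. Rows are 0-based grid coordinates in row-major
#' order. Flags are forced to `FALSE` on non-tissue (QC-failed) patches.
#'
#' @param patches data.frame with columns `row`, `col` (0-based integers),
#'   `is_tissue`, `has_tumor`, `has_lymph` (logical) and optionally
#'   `gt_region` (generator ground truth).
#' @param n_rows,n_cols Grid dimensions; defaults inferred from coordinates.
#' @param subject_id Identifier attached to exported tables.
#' @param patch_um Physical patch side length in microns (default 128).
#' @return An object of class `patch_grid`.
#' @examples
#' g <- patch_grid_from_matrices(
#'   is_tissue = matrix(TRUE, 3, 3),
#'   has_tumor = matrix(c(rep(TRUE, 6), rep(FALSE, 3)), 3, 3),
#'   has_lymph = matrix(FALSE, 3, 3))
#' g
#' @export
patch_grid <- function(patches, n_rows = NULL, n_cols = NULL,
                       subject_id = "subject01", patch_um = 128) {
  req <- c("row", "col", "is_tissue", "has_tumor", "has_lymph")
  missing_cols <- setdiff(req, names(patches))
  if (length(missing_cols)) {
    stop("patches is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(n_rows)) n_rows <- max(patches$row) + 1L
  if (is.null(n_cols)) n_cols <- max(patches$col) + 1L
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid dimensions must be >= 1")
  if (nrow(patches) != n_rows * n_cols) {
    stop("patches must contain exactly one record per grid cell")
  }
  patches <- patches[order(patches$row, patches$col), , drop = FALSE]
  expect_row <- rep(0:(n_rows - 1L), each = n_cols)
  expect_col <- rep(0:(n_cols - 1L), times = n_rows)
  if (!all(patches$row == expect_row) || !all(patches$col == expect_col)) {
    stop("patch coordinates do not tile the grid exactly once")
  }
  patches$is_tissue <- as.logical(patches$is_tissue)
  patches$has_tumor <- as.logical(patches$has_tumor) & patches$is_tissue
  patches$has_lymph <- as.logical(patches$has_lymph) & patches$is_tissue
  rownames(patches) <- NULL
  structure(
    list(patches = patches, n_rows = n_rows, n_cols = n_cols,
         subject_id = subject_id, patch_um = patch_um),
    class = "patch_grid")
}

#' Build a patch grid from flag matrices
#'
#' Convenience constructor: matrices are indexed `[row + 1, col + 1]`.
#'
#' @param is_tissue,has_tumor,has_lymph Logical matrices of equal dimension.
#' @param gt_region Optional character matrix of generator ground-truth
#'   regions (`"inside"`, `"border"`, `"outside"`, `NA` off tissue).
#' @inheritParams patch_grid
#' @return A `patch_grid`.
#' @export
patch_grid_from_matrices <- function(is_tissue, has_tumor, has_lymph,
                                     gt_region = NULL,
                                     subject_id = "subject01",
                                     patch_um = 128) {
  d <- dim(is_tissue)
  if (!identical(dim(has_tumor), d) || !identical(dim(has_lymph), d)) {
    stop("flag matrices must share dimensions")
  }
  nr <- d[1L]; nc <- d[2L]
  df <- data.frame(
    row = rep(0:(nr - 1L), each = nc),
    col = rep(0:(nc - 1L), times = nr))
  idx <- cbind(df$row + 1L, df$col + 1L)
  df$is_tissue <- is_tissue[idx]
  df$has_tumor <- has_tumor[idx]
  df$has_lymph <- has_lymph[idx]
  if (!is.null(gt_region)) df$gt_region <- gt_region[idx]
  patch_grid(df, nr, nc, subject_id = subject_id, patch_um = patch_um)
}

#' Extract a per-patch field as a matrix
#'
#' @param grid A `patch_grid`.
#' @param field Column name in the patch table.
#' @return A `n_rows x n_cols` matrix indexed `[row + 1, col + 1]`.
#' @export
grid_matrix <- function(grid, field) {
  stopifnot(inherits(grid, "patch_grid"))
  v <- grid$patches[[field]]
  if (is.null(v)) stop("no such field: ", field)
  m <- matrix(v[1L], grid$n_rows, grid$n_cols)
  m[cbind(grid$patches$row + 1L, grid$patches$col + 1L)] <- v
  m
}

#' Three-way patch category under the precedence rule
#'
#' Tissue patches are categorized `lymph` if flagged as a lymphocyte
#' aggregate, else `tumor` if tumor-flagged, else `other`; lymph takes
#' precedence so intranest lymphoid infiltration is preserved in the
#' category map (nest detection always uses the raw tumor flag instead).
#' Non-tissue patches are `NA`.
#'
#' @param grid A `patch_grid`.
#' @return Character matrix (`n_rows x n_cols`) of categories.
#' @export
patch_category <- function(grid) {
  stopifnot(inherits(grid, "patch_grid"))
  ti <- grid_matrix(grid, "is_tissue")
  tu <- grid_matrix(grid, "has_tumor")
  ly <- grid_matrix(grid, "has_lymph")
  cat <- matrix(NA_character_, grid$n_rows, grid$n_cols)
  cat[ti] <- "other"
  cat[ti & tu] <- "tumor"
  cat[ti & ly] <- "lymph"
  cat
}

#' @export
print.patch_grid <- function(x, ...) {
  p <- x$patches
  cat(sprintf("patch_grid '%s': %d x %d patches (%.0f um each)\n",
              x$subject_id, x$n_rows, x$n_cols, x$patch_um))
  cat(sprintf("  tissue %d | tumor-flagged %d | lymph-flagged %d\n",
              sum(p$is_tissue), sum(p$has_tumor), sum(p$has_lymph)))
  invisible(x)
}

#' Write / read patch tables
#'
#' Patch grids round-trip through plain CSV with one row per patch and
#' columns `subject_id, row, col, is_tissue, has_tumor, has_lymph`
#' (plus `gt_region` when present). Multiple subjects may share one file.
#'
#' @param grid A `patch_grid` or list of them.
#' @param path CSV path.
#' @return `write_patch_table` returns `path` invisibly;
#'   `read_patch_table` returns a named list of `patch_grid` objects.
#' @export
write_patch_table <- function(grid, path) {
  grids <- if (inherits(grid, "patch_grid")) list(grid) else grid
  tabs <- lapply(grids, function(g) {
    df <- g$patches
    df$subject_id <- g$subject_id
    df[, c("subject_id", setdiff(names(df), "subject_id"))]
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patch_table
#' @export
read_patch_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$subject_id), function(d) {
    patch_grid(d[setdiff(names(d), "subject_id")],
               subject_id = d$subject_id[1L])
  })
  out[unique(df$subject_id)]
}
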