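#' Density-based clustering of tumor patches into nests
#'
#' DBSCAN on the patch lattice: patch centers are integer coordinates,
#' distance is Euclidean, and the neighborhood of radius 2 is the 12
#' offsets with `dr^2 + dc^2 <= 4`. A tumor patch is a core patch when at
#' least `min_neighborhood_size` other tumor patches lie within the
#' radius; clusters are connected components of core patches plus
#' density-reachable (non-core) tumor patches, which join the nearest
#' core's cluster with ties broken by the lowest cluster id. Tumor
#' patches reachable from no core are noise (`cluster_id` 0). Non-tissue
#' patches never participate.
#'
#' @param grid A [patch_grid].
#' @param radius Neighborhood radius in patch units (default 2).
#' @param min_neighborhood_size Minimum in-radius tumor neighbors for a
#'   core patch, excluding the patch itself (default 4).
#' @return A `cluster_map`: list with `cluster_id` matrix (0 = no nest),
#'   `n_clusters`, and the parameters used.
#' @examples
#' g <- patch_grid_from_matrices(matrix(TRUE, 5, 5),
#'   has_tumor = matrix(c(rep(TRUE, 15), rep(FALSE, 10)), 5, 5),
#'   has_lymph = matrix(FALSE, 5, 5))
#' cluster_tumor_patches(g)$n_clusters
#' @export
cluster_tumor_patches <- function(grid, radius = 2,
                                  min_neighborhood_size = 4) {
  stopifnot(inherits(grid, "patch_grid"))
  if (radius <= 0) stop("radius must be > 0")
  if (min_neighborhood_size < 1) stop("min_neighborhood_size must be >= 1")
  if (!any(grid$patches$is_tissue)) stop("grid has no tissue patches")
  nr <- grid$n_rows; nc <- grid$n_cols
  tumor <- grid_matrix(grid, "has_tumor") & grid_matrix(grid, "is_tissue")
  offs <- disk_offsets(radius)
  cnt <- neighbor_count(tumor, offs)
  core <- tumor & cnt >= min_neighborhood_size
  lab <- matrix(0L, nr, nc)
  cid <- 0L
  # connected components of core patches (row-major scan for determinism)
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      if (!core[r, cl] || lab[r, cl] != 0L) next
      cid <- cid + 1L
      queue <- matrix(c(r, cl), 1L, 2L)
      lab[r, cl] <- cid
      while (nrow(queue) > 0L) {
        cur <- queue[1L, ]
        queue <- queue[-1L, , drop = FALSE]
        for (k in seq_len(nrow(offs))) {
          rr <- cur[1L] + offs[k, 1L]
          cc <- cur[2L] + offs[k, 2L]
          if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
              core[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- cid
            queue <- rbind(queue, c(rr, cc))
          }
        }
      }
    }
  }
  # density-reachable border points: nearest core's cluster, ties -> lowest id
  border_pts <- which(tumor & !core & lab == 0L, arr.ind = TRUE)
  if (nrow(border_pts) > 0L) {
    d2 <- offs[, 1L]^2 + offs[, 2L]^2
    dist_groups <- sort(unique(d2))
    for (i in seq_len(nrow(border_pts))) {
      r <- border_pts[i, 1L]; cl <- border_pts[i, 2L]
      for (d in dist_groups) {
        ids <- integer(0)
        for (k in which(d2 == d)) {
          rr <- r + offs[k, 1L]; cc <- cl + offs[k, 2L]
          if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
              core[rr, cc]) {
            ids <- c(ids, lab[rr, cc])
          }
        }
        if (length(ids)) {
          lab[r, cl] <- min(ids)
          break
        }
      }
    }
  }
  structure(list(cluster_id = lab, n_clusters = cid, radius = radius,
                 min_neighborhood_size = min_neighborhood_size),
            class = "cluster_map")
}

#' Internal and external margins of tumor nests
#'
#' The internal margin is the set of clustered patches with at least one
#' non-clustered tissue neighbor; the external margin is the set of
#' non-clustered tissue patches with at least one clustered neighbor.
#' Adjacency is 8-connected by default (diagonal contact counts at patch
#' scale); out-of-grid and non-tissue cells never count as neighbors, so
#' a nest flush against the grid edge has no internal margin on that
#' side.
#'
#' @param grid A [patch_grid].
#' @param clusters A [cluster_tumor_patches()] result for this grid.
#' @param connectivity 8 (default) or 4.
#' @return List of logical matrices `internal` and `external`, plus
#'   `connectivity`.
#' @export
identify_margins <- function(grid, clusters, connectivity = 8) {
  stopifnot(inherits(grid, "patch_grid"), inherits(clusters, "cluster_map"))
  offs <- adjacency_offsets(connectivity)
  ti <- grid_matrix(grid, "is_tissue")
  clustered <- clusters$cluster_id > 0L
  open_tissue <- ti & !clustered
  internal <- clustered & neighbor_count(open_tissue, offs) >= 1L
  external <- open_tissue & neighbor_count(clustered, offs) >= 1L
  list(internal = internal, external = external,
       connectivity = connectivity)
}

#' Partition tissue into inside / border / outside regions
#'
#' Inside = clustered patches minus the internal margin; border = the
#' union of internal and external margins; outside = remaining tissue.
#' Every tissue patch receives exactly one region; non-tissue patches are
#' `NA`.
#'
#' @param grid A [patch_grid].
#' @param clusters A [cluster_tumor_patches()] result.
#' @param margins An [identify_margins()] result.
#' @return A `region_partition`: list with `region` (character matrix
#'   with values `inside`, `border_internal`, `border_external`,
#'   `outside`) and `counts`.
#' @export
partition_regions <- function(grid, clusters, margins) {
  stopifnot(inherits(grid, "patch_grid"), inherits(clusters, "cluster_map"))
  ti <- grid_matrix(grid, "is_tissue")
  clustered <- clusters$cluster_id > 0L
  region <- matrix(NA_character_, grid$n_rows, grid$n_cols)
  region[ti] <- "outside"
  region[clustered] <- "inside"
  region[margins$internal] <- "border_internal"
  region[margins$external] <- "border_external"
  counts <- table(factor(region[ti], levels = c(
    "inside", "border_internal", "border_external", "outside")))
  structure(list(region = region, counts = counts),
            class = "region_partition")
}

#' The 12 spatial indicator names
#'
#' Tumor / Lymph / Other percentages overall and in the inside, border,
#' and outside regions.
#'
#' @return Character vector of length 12.
#' @export
indicator_names <- function() {
  as.vector(outer(c("Tumor", "Lymph", "Other"),
                  c("", "_inside", "_border", "_outside"), paste0))
}

#' Compute the 12 spatial distribution indicators
#'
#' For each region (overall, inside, border = internal + external margin,
#' outside), the percentage of that region's tissue patches in each of
#' the three categories (lymph taking precedence over tumor, see
#' [patch_category()]). Each defined triple sums to exactly 100. Regions
#' with zero patches yield missing values, never zeros; the denominators
#' are retained.
#'
#' @param grid A [patch_grid].
#' @param partition A [partition_regions()] result.
#' @return A `spatial_indicators` one-row data.frame: the 12 indicators
#'   (percent scale) plus `n_tissue`, `n_inside`, `n_border`,
#'   `n_outside`.
#' @export
compute_indicators <- function(grid, partition) {
  stopifnot(inherits(grid, "patch_grid"),
            inherits(partition, "region_partition"))
  ti <- grid_matrix(grid, "is_tissue")
  if (!any(ti)) stop("grid has no tissue patches")
  cat <- patch_category(grid)
  reg <- partition$region
  pooled <- matrix(NA_character_, grid$n_rows, grid$n_cols)
  pooled[reg %in% c("border_internal", "border_external")] <- "border"
  pooled[reg == "inside"] <- "inside"
  pooled[reg == "outside"] <- "outside"
  pct <- function(mask) {
    n <- sum(mask, na.rm = TRUE)
    if (n == 0L) {
      return(c(Tumor = NA_real_, Lymph = NA_real_, Other = NA_real_,
               n = 0))
    }
    c(Tumor = 100 * sum(cat[mask] == "tumor", na.rm = TRUE) / n,
      Lymph = 100 * sum(cat[mask] == "lymph", na.rm = TRUE) / n,
      Other = 100 * sum(cat[mask] == "other", na.rm = TRUE) / n,
      n = n)
  }
  overall <- pct(ti)
  inside <- pct(!is.na(pooled) & pooled == "inside")
  border <- pct(!is.na(pooled) & pooled == "border")
  outside <- pct(!is.na(pooled) & pooled == "outside")
  out <- data.frame(
    Tumor = overall[["Tumor"]], Lymph = overall[["Lymph"]],
    Other = overall[["Other"]],
    Tumor_inside = inside[["Tumor"]], Lymph_inside = inside[["Lymph"]],
    Other_inside = inside[["Other"]],
    Tumor_border = border[["Tumor"]], Lymph_border = border[["Lymph"]],
    Other_border = border[["Other"]],
    Tumor_outside = outside[["Tumor"]], Lymph_outside = outside[["Lymph"]],
    Other_outside = outside[["Other"]],
    n_tissue = overall[["n"]], n_inside = inside[["n"]],
    n_border = border[["n"]], n_outside = outside[["n"]])
  class(out) <- c("spatial_indicators", "data.frame")
  out
}

#' Run the full spatial analysis on one grid
#'
#' Convenience wrapper: clustering, margin identification, region
#' partition, and indicator computation with the standard parameters.
#'
#' @inheritParams cluster_tumor_patches
#' @param connectivity Margin adjacency (default 8).
#' @return List with `clusters`, `margins`, `partition`, `indicators`.
#' @examples
#' g <- generate_label_grid(grid_config(seed = 2))
#' analyze_spatial(g)$indicators
#' @export
analyze_spatial <- function(grid, radius = 2, min_neighborhood_size = 4,
                            connectivity = 8) {
  clusters <- cluster_tumor_patches(grid, radius, min_neighborhood_size)
  margins <- identify_margins(grid, clusters, connectivity)
  partition <- partition_regions(grid, clusters, margins)
  indicators <- compute_indicators(grid, partition)
  list(clusters = clusters, margins = margins, partition = partition,
       indicators = indicators)
}

nestmargin_palette <- function() {
  list(tumor = c(0.77, 0.29, 0.25), lymph = c(0.20, 0.43, 0.65),
       other = c(0.85, 0.85, 0.85), nontissue = c(1, 1, 1),
       margin = c(0, 0, 0))
}

#' Render a spatial distribution map
#'
#' One `block_px`-square pixel block per patch, colored by category
#' (tumor red, lymph blue, other grey, non-tissue white); patches in the
#' border region (internal or external margin) are outlined in black so
#' nest boundaries are visible. Optionally appends a legend strip and/or
#' writes a PNG.
#'
#' @param grid A [patch_grid].
#' @param partition A [partition_regions()] result.
#' @param block_px Pixels per patch block (default 8).
#' @param file Optional PNG path.
#' @param legend Append a color-legend strip below the map.
#' @return The RGB array, invisibly.
#' @export
render_map <- function(grid, partition, block_px = 8, file = NULL,
                       legend = FALSE) {
  stopifnot(inherits(grid, "patch_grid"),
            inherits(partition, "region_partition"))
  pal <- nestmargin_palette()
  cat <- patch_category(grid)
  reg <- partition$region
  s <- as.integer(block_px)
  nr <- grid$n_rows; nc <- grid$n_cols
  img <- array(0, c(nr * s, nc * s, 3))
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      col <- if (is.na(cat[r, cl])) pal$nontissue else pal[[cat[r, cl]]]
      ys <- (r - 1L) * s + seq_len(s)
      xs <- (cl - 1L) * s + seq_len(s)
      for (ch in 1:3) img[ys, xs, ch] <- col[ch]
      if (!is.na(reg[r, cl]) &&
          reg[r, cl] %in% c("border_internal", "border_external")) {
        frame_y <- c(ys[1L], ys[s])
        frame_x <- c(xs[1L], xs[s])
        for (ch in 1:3) {
          img[frame_y, xs, ch] <- pal$margin[ch]
          img[ys, frame_x, ch] <- pal$margin[ch]
        }
      }
    }
  }
  if (legend) {
    strip <- array(1, c(s + 2L, nc * s, 3))
    keys <- list(pal$tumor, pal$lymph, pal$other)
    w <- max(1L, (nc * s) %/% 8L)
    for (i in seq_along(keys)) {
      xs <- (i - 1L) * 2L * w + seq_len(w)
      xs <- xs[xs <= nc * s]
      for (ch in 1:3) strip[2:(s + 1L), xs, ch] <- keys[[i]][ch]
    }
    img2 <- array(1, c(nr * s + s + 2L, nc * s, 3))
    img2[seq_len(nr * s), , ] <- img
    img2[nr * s + seq_len(s + 2L), , ] <- strip
    img <- img2
  }
  if (!is.null(file)) png::writePNG(img, file)
  invisible(img)
}
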