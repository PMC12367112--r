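test_that("density clustering handles degenerate tumor layouts", {
  g_none <- patch_grid_from_matrices(matrix(TRUE, 6, 6),
                                     matrix(FALSE, 6, 6),
                                     matrix(FALSE, 6, 6))
  expect_equal(cluster_tumor_patches(g_none)$n_clusters, 0L)

  tu <- matrix(FALSE, 6, 6); tu[3, 3] <- TRUE
  g_one <- patch_grid_from_matrices(matrix(TRUE, 6, 6), tu,
                                    matrix(FALSE, 6, 6))
  cm <- cluster_tumor_patches(g_one)
  expect_equal(cm$n_clusters, 0L)          # isolated patch is noise
  expect_equal(cm$cluster_id[3, 3], 0L)

  tu3 <- matrix(FALSE, 7, 7); tu3[3:5, 3:5] <- TRUE
  g3 <- patch_grid_from_matrices(matrix(TRUE, 7, 7), tu3,
                                 matrix(FALSE, 7, 7))
  cm3 <- cluster_tumor_patches(g3)
  expect_equal(cm3$n_clusters, 1L)
  expect_equal(sum(cm3$cluster_id == 1L), 9L)  # all 9 in one nest

  expect_error(cluster_tumor_patches(g3, radius = 0), "radius")
  expect_error(cluster_tumor_patches(g3, min_neighborhood_size = 0),
               "min_neighborhood_size")
})

test_that("clustering equals the brute-force reachability oracle", {
  with_seed_local(31, {
    for (rep in 1:30) {
      nr <- sample(4:20, 1); nc <- sample(4:20, 1)
      g <- random_tumor_grid(nr, nc, runif(1, 0.1, 0.7))
      cm <- cluster_tumor_patches(g)
      expect_identical(cm$cluster_id,
                       brute_dbscan(grid_matrix(g, "has_tumor")))
    }
  })
})

test_that("5x5 solid nest yields the enumerated margins and interior", {
  g <- solid_nest_grid(10, 3:7, 3:7)
  sp <- analyze_spatial(g)
  expect_equal(sp$clusters$n_clusters, 1L)
  expect_equal(sum(sp$margins$internal), 16L)   # perimeter of the 5x5
  expect_equal(sum(sp$margins$external), 24L)   # surrounding ring
  expect_equal(sum(sp$partition$region == "inside", na.rm = TRUE), 9L)
  expect_equal(sum(sp$partition$region == "outside", na.rm = TRUE),
               100L - 25L - 24L)
})

test_that("nests flush against the grid edge lose that side's margins", {
  # 3x3 solid nest in the grid corner of a 6x6 all-tissue grid
  g <- solid_nest_grid(6, 1:3, 1:3)
  sp <- analyze_spatial(g)
  expect_equal(sp$clusters$n_clusters, 1L)
  internal <- which(sp$margins$internal, arr.ind = TRUE)
  # only patches touching open tissue (row 4 or col 4 side) qualify
  expect_equal(nrow(internal), 5L)
  expect_true(all(internal[, 1] == 3 | internal[, 2] == 3))
  expect_false(sp$margins$internal[1, 1])
  expect_equal(sum(sp$partition$region == "inside", na.rm = TRUE), 4L)
  expect_equal(sum(sp$margins$external), 7L)
})

test_that("region partition is disjoint and exhaustive on tissue", {
  for (s in 1:20) {
    g <- generate_label_grid(grid_config(
      n_rows = 25, n_cols = 25, n_nests = sample(0:3, 1),
      nest_radius_range = c(3, 6), tissue_fraction = 0.9,
      seed = 400 + s))
    sp <- analyze_spatial(g)
    ti <- grid_matrix(g, "is_tissue")
    reg <- sp$partition$region
    expect_true(all(!is.na(reg[ti])))
    expect_true(all(is.na(reg[!ti])))
    expect_equal(sum(sp$partition$counts), sum(ti))
    # inside + internal margin = clustered; external margin disjoint
    clustered <- sp$clusters$cluster_id > 0
    expect_identical(clustered,
                     !is.na(reg) & reg %in% c("inside", "border_internal"))
    expect_false(any(clustered & reg == "border_external", na.rm = TRUE))
  }
})

test_that("each defined indicator triple sums to exactly 100", {
  for (s in 1:10) {
    g <- generate_label_grid(grid_config(
      n_rows = 30, n_cols = 30, seed = 600 + s))
    ind <- analyze_spatial(g)$indicators
    for (suf in c("", "_inside", "_border", "_outside")) {
      triple <- c(ind[[paste0("Tumor", suf)]],
                  ind[[paste0("Lymph", suf)]],
                  ind[[paste0("Other", suf)]])
      if (!anyNA(triple)) expect_equal(sum(triple), 100)
    }
  }
})

test_that("hand-counted fixture gives Lymph_inside% = 400/9", {
  ly <- matrix(FALSE, 10, 10); ly[4:5, 4:5] <- TRUE  # 4 interior patches
  g <- solid_nest_grid(10, 3:7, 3:7, lymph = ly)
  ind <- analyze_spatial(g)$indicators
  expect_equal(ind$Lymph_inside, 400 / 9)
  expect_equal(ind$n_inside, 9)
})

test_that("grids without nests put all tissue outside", {
  g <- patch_grid_from_matrices(matrix(TRUE, 8, 8), matrix(FALSE, 8, 8),
                                matrix(c(TRUE, FALSE), 8, 8))
  ind <- analyze_spatial(g)$indicators
  expect_true(is.na(ind$Tumor_inside))
  expect_true(is.na(ind$Lymph_border))
  expect_equal(ind$n_inside, 0)
  expect_equal(ind$Lymph_outside, ind$Lymph)
  expect_equal(ind$Tumor_outside, ind$Tumor)
  expect_equal(ind$Other_outside, ind$Other)
})

test_that("indicators are invariant to transposition and rotation", {
  for (s in 1:5) {
    g <- generate_label_grid(grid_config(n_rows = 25, n_cols = 20,
                                         seed = 700 + s))
    ti <- grid_matrix(g, "is_tissue")
    tu <- grid_matrix(g, "has_tumor")
    ly <- grid_matrix(g, "has_lymph")
    base <- analyze_spatial(g)$indicators
    variants <- list(
      transpose = list(t(ti), t(tu), t(ly)),
      rot90 = list(t(ti)[ncol(ti):1, ], t(tu)[ncol(tu):1, ],
                   t(ly)[ncol(ly):1, ]),
      rot180 = list(ti[nrow(ti):1, ncol(ti):1],
                    tu[nrow(tu):1, ncol(tu):1],
                    ly[nrow(ly):1, ncol(ly):1]))
    for (v in variants) {
      gv <- patch_grid_from_matrices(v[[1]], v[[2]], v[[3]])
      iv <- analyze_spatial(gv)$indicators
      for (nm in indicator_names()) expect_equal(iv[[nm]], base[[nm]])
    }
  }
})

test_that("computed Lymph_inside% tracks the generating probability", {
  ps <- seq(0, 0.8, length.out = 50)
  vals <- vapply(seq_along(ps), function(i) {
    g <- generate_label_grid(grid_config(
      n_rows = 40, n_cols = 40, n_nests = 2, nest_radius_range = c(5, 7),
      p_lymph_inside = ps[i], seed = 900 + i))
    analyze_spatial(g)$indicators$Lymph_inside
  }, 0)
  keep <- !is.na(vals)
  expect_gt(spearman_cor(ps[keep], vals[keep])$rho, 0.9)
})

test_that("rendered maps have block geometry and match enumeration", {
  g <- solid_nest_grid(10, 3:7, 3:7)
  sp <- analyze_spatial(g)
  img <- render_map(g, sp$partition, block_px = 4, legend = FALSE)
  expect_equal(dim(img), c(40, 40, 3))

  # golden image enumerated independently from the known partition
  pal <- list(tumor = c(0.77, 0.29, 0.25), other = c(0.85, 0.85, 0.85))
  golden <- array(0, c(40, 40, 3))
  cat <- matrix("other", 10, 10)
  cat[3:7, 3:7] <- "tumor"
  border <- matrix(FALSE, 10, 10)
  border[3:7, 3:7] <- TRUE; border[4:6, 4:6] <- FALSE  # internal margin
  border[2:8, 2:8][!(row(matrix(0, 7, 7)) %in% 2:6 &
                       col(matrix(0, 7, 7)) %in% 2:6)] <- TRUE  # external
  for (r in 1:10) {
    for (cl in 1:10) {
      ys <- (r - 1) * 4 + 1:4; xs <- (cl - 1) * 4 + 1:4
      for (ch in 1:3) golden[ys, xs, ch] <- pal[[cat[r, cl]]][ch]
      if (border[r, cl]) {
        for (ch in 1:3) {
          golden[c(ys[1], ys[4]), xs, ch] <- 0
          golden[ys, c(xs[1], xs[4]), ch] <- 0
        }
      }
    }
  }
  expect_identical(img, golden)

  with_legend <- render_map(g, sp$partition, block_px = 4, legend = TRUE)
  expect_gt(dim(with_legend)[1], 40)
})
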