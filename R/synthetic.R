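#' Configuration for synthetic label grids
#'
#' Describes a slide-like patch lattice containing tumor-cell nests with
#' lymphocyte aggregates scattered at region-specific rates. Nests are
#' irregular connected blobs (a disk dilated by a short random walk), the
#' ground-truth border is the one-patch band on either side of each nest
#' boundary, and lymph flags are drawn independently per tissue patch with
#' the probability of its ground-truth region.
#'
#' @param n_rows,n_cols Grid dimensions (patches), each >= 1.
#' @param n_nests Number of tumor nests (>= 0).
#' @param nest_radius_range Integer (min, max) nest core radius in patch
#'   units, both >= 1.
#' @param p_lymph_inside,p_lymph_border,p_lymph_outside Per-patch
#'   probabilities of a lymphocyte-aggregate flag by ground-truth region.
#' @param tissue_fraction Probability a patch passes QC (is tissue);
#'   non-tissue patches carry no flags and enter no denominator.
#' @param seed RNG seed.
#' @return A `synthetic_grid_config` list.
#' @export
grid_config <- function(n_rows = 48, n_cols = 48, n_nests = 3,
                        nest_radius_range = c(4, 8),
                        p_lymph_inside = 0.15, p_lymph_border = 0.25,
                        p_lymph_outside = 0.20, tissue_fraction = 1,
                        seed = 1L) {
  if (n_rows < 1 || n_cols < 1) stop("grid dimensions must be >= 1")
  if (n_nests < 0) stop("n_nests must be >= 0")
  if (length(nest_radius_range) != 2L || any(nest_radius_range < 1) ||
      nest_radius_range[1] > nest_radius_range[2]) {
    stop("nest_radius_range must be (min, max) with min >= 1")
  }
  stopifnot_scalar_prob(p_lymph_inside, "p_lymph_inside")
  stopifnot_scalar_prob(p_lymph_border, "p_lymph_border")
  stopifnot_scalar_prob(p_lymph_outside, "p_lymph_outside")
  stopifnot_scalar_prob(tissue_fraction, "tissue_fraction")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_nests = as.integer(n_nests),
                 nest_radius_range = as.integer(nest_radius_range),
                 p_lymph_inside = p_lymph_inside,
                 p_lymph_border = p_lymph_border,
                 p_lymph_outside = p_lymph_outside,
                 tissue_fraction = tissue_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_grid_config")
}

#' Generate a synthetic label grid
#'
#' Places `n_nests` connected tumor blobs, derives ground-truth
#' inside/border/outside regions from the nest geometry (border = nest
#' patches within one patch of the complement plus complement patches
#' within one patch of the nest, 8-connected), and draws lymph flags
#' independently per tissue patch at the region's rate. Lymph flags may
#' co-occur with tumor flags.
#'
#' @param cfg A [grid_config()].
#' @return A [patch_grid] whose patch table carries a `gt_region` column
#'   (`"inside"`, `"border"`, `"outside"`, `NA` on non-tissue).
#' @examples
#' g <- generate_label_grid(grid_config(n_rows = 30, n_cols = 30, seed = 7))
#' table(g$patches$gt_region, useNA = "ifany")
#' @export
generate_label_grid <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_grid_config"))
  nr <- cfg$n_rows; nc <- cfg$n_cols
  rmin <- cfg$nest_radius_range[1L]; rmax <- cfg$nest_radius_range[2L]
  if (cfg$n_nests > 0 && (2L * rmin + 1L > nr || 2L * rmin + 1L > nc)) {
    stop("smallest admissible nest does not fit in the grid")
  }
  with_seed(cfg$seed, {
    tissue <- matrix(TRUE, nr, nc)
    if (cfg$tissue_fraction < 1) {
      tissue <- matrix(stats::runif(nr * nc) < cfg$tissue_fraction, nr, nc)
    }
    nest <- matrix(FALSE, nr, nc)
    rr <- matrix(rep(seq_len(nr), nc), nr, nc)
    cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    for (k in seq_len(cfg$n_nests)) {
      r <- if (rmin == rmax) rmin else sample(rmin:rmax, 1L)
      r <- min(r, (min(nr, nc) - 1L) %/% 2L)  # largest disk the grid holds
      ci <- sample(seq(r + 1L, nr - r), 1L)
      cj <- sample(seq(r + 1L, nc - r), 1L)
      blob <- (rr - ci)^2 + (cc - cj)^2 <= r^2
      # random-walk dilation: grow irregular but connected lobes
      steps <- 4L * r
      for (s in seq_len(steps)) {
        cand <- which(blob)
        from <- cand[sample.int(length(cand), 1L)]
        fi <- (from - 1L) %% nr + 1L
        fj <- (from - 1L) %/% nr + 1L
        step <- sample.int(4L, 1L)
        ni <- fi + c(-1L, 1L, 0L, 0L)[step]
        nj <- fj + c(0L, 0L, -1L, 1L)[step]
        if (ni >= 1L && ni <= nr && nj >= 1L && nj <= nc) blob[ni, nj] <- TRUE
      }
      nest <- nest | blob
    }
    nest <- nest & tissue
    has_tumor <- nest

    off8 <- adjacency_offsets(8)
    non_nest_tissue <- tissue & !nest
    internal <- nest & neighbor_count(non_nest_tissue, off8) >= 1L
    external <- non_nest_tissue & neighbor_count(nest, off8) >= 1L
    gt <- matrix(NA_character_, nr, nc)
    gt[tissue] <- "outside"
    gt[nest] <- "inside"
    gt[internal | external] <- "border"

    p <- matrix(0, nr, nc)
    p[tissue & gt == "inside"] <- cfg$p_lymph_inside
    p[tissue & gt == "border"] <- cfg$p_lymph_border
    p[tissue & gt == "outside"] <- cfg$p_lymph_outside
    has_lymph <- matrix(stats::runif(nr * nc) < p, nr, nc) & tissue

    patch_grid_from_matrices(tissue, has_tumor, has_lymph, gt_region = gt)
  })
}

#' Configuration for synthetic patch images
#'
#' Patch images emulate H&E morphology at the level the patch classifiers
#' need: an eosin-pink stromal background with dark-stained nuclei, tumor
#' nuclei strictly larger than lymphocyte nuclei so the two classes are
#' morphologically separable by construction. Defaults correspond to
#' 128 um patches at 40x (0.25 um/px, 512 px).
#'
#' @param patch_px Pixels per patch side (> 0).
#' @param um_per_px Microns per pixel.
#' @param tumor_nucleus_radius_px,lymph_nucleus_radius_px Nucleus radii in
#'   pixels; tumor must exceed lymph.
#' @param cell_count_range Named list of `(min, max)` nucleus counts for
#'   `tumor` and `lymph` categories; minima must be >= 20 so the 20-cell
#'   labeling rule classifies generated patches correctly.
#' @param background_color,tumor_color,lymph_color RGB triples in `[0, 1]`.
#' @param noise_sd Gaussian pixel noise SD (intensity units in `[0, 1]`).
#' @return A `synthetic_image_config` list.
#' @export
image_config <- function(patch_px = 512, um_per_px = 0.25,
                         tumor_nucleus_radius_px = patch_px / 56,
                         lymph_nucleus_radius_px = patch_px / 160,
                         cell_count_range = list(tumor = c(30, 80),
                                                 lymph = c(40, 150)),
                         background_color = c(0.91, 0.74, 0.80),
                         tumor_color = c(0.42, 0.24, 0.55),
                         lymph_color = c(0.22, 0.12, 0.45),
                         noise_sd = 0.02) {
  if (patch_px <= 0) stop("patch_px must be > 0")
  if (tumor_nucleus_radius_px <= lymph_nucleus_radius_px) {
    stop("tumor nuclei must be strictly larger than lymphocyte nuclei")
  }
  if (cell_count_range$tumor[1] < 20 || cell_count_range$lymph[1] < 20) {
    stop("cell_count_range minima must be >= 20 for tumor and lymph")
  }
  structure(list(patch_px = as.integer(patch_px), um_per_px = um_per_px,
                 tumor_nucleus_radius_px = tumor_nucleus_radius_px,
                 lymph_nucleus_radius_px = lymph_nucleus_radius_px,
                 cell_count_range = cell_count_range,
                 background_color = background_color,
                 tumor_color = tumor_color, lymph_color = lymph_color,
                 noise_sd = noise_sd),
            class = "synthetic_image_config")
}

draw_nuclei <- function(img, n, radius, color) {
  px <- dim(img)[1L]
  for (k in seq_len(n)) {
    r <- radius * stats::runif(1, 0.8, 1.2)
    cx <- stats::runif(1, r + 1, px - r)
    cy <- stats::runif(1, r + 1, px - r)
    xs <- max(1L, floor(cx - r)):min(px, ceiling(cx + r))
    ys <- max(1L, floor(cy - r)):min(px, ceiling(cy + r))
    dmask <- outer((xs - cx)^2, (ys - cy)^2, "+") <= r^2
    for (ch in 1:3) {
      sub <- img[xs, ys, ch]
      sub[dmask] <- color[ch]
      img[xs, ys, ch] <- sub
    }
  }
  img
}

#' Generate one synthetic patch image
#'
#' @param category One of `"tumor"`, `"lymph"`, `"other"`,
#'   `"tumor+lymph"`.
#' @param cfg An [image_config()].
#' @param seed RNG seed.
#' @return List with `image` (array `patch_px x patch_px x 3` in `[0, 1]`)
#'   and `cell_counts` (named vector, tumor and lymph nuclei drawn).
#' @examples
#' p <- generate_patch_image("tumor", image_config(patch_px = 64), seed = 1)
#' p$cell_counts
#' @export
generate_patch_image <- function(category, cfg = image_config(), seed = 1L) {
  category <- match.arg(category, c("tumor", "lymph", "other", "tumor+lymph"))
  stopifnot(inherits(cfg, "synthetic_image_config"))
  with_seed(seed, {
    px <- cfg$patch_px
    img <- array(rep(cfg$background_color, each = px * px), c(px, px, 3))
    n_tumor <- 0L; n_lymph <- 0L
    if (category %in% c("tumor", "tumor+lymph")) {
      rng <- cfg$cell_count_range$tumor
      n_tumor <- sample(rng[1]:rng[2], 1L)
      img <- draw_nuclei(img, n_tumor, cfg$tumor_nucleus_radius_px,
                         cfg$tumor_color)
    }
    if (category %in% c("lymph", "tumor+lymph")) {
      rng <- cfg$cell_count_range$lymph
      n_lymph <- sample(rng[1]:rng[2], 1L)
      img <- draw_nuclei(img, n_lymph, cfg$lymph_nucleus_radius_px,
                         cfg$lymph_color)
    }
    if (cfg$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, cfg$noise_sd)
      img[img < 0] <- 0; img[img > 1] <- 1
    }
    list(image = img, cell_counts = c(tumor = n_tumor, lymph = n_lymph))
  })
}

#' Configuration for survival simulation
#'
#' Event times follow a proportional-hazards exponential model,
#' `h(t | z) = baseline_rate * exp(beta * z)` with `z` the driving spatial
#' indicator on the fraction scale, independent exponential censoring at
#' `censor_rate`, and administrative censoring at `max_followup`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param beta Log hazard ratio per unit of the driving indicator
#'   (fraction scale; negative = protective).
#' @param baseline_rate,censor_rate Event / censoring rates per time unit
#'   (> 0).
#' @param max_followup Administrative censoring time (> 0).
#' @param seed RNG seed.
#' @return A `survival_sim_config` list.
#' @export
survival_sim_config <- function(n_subjects = 200, beta = -3,
                                baseline_rate = 0.1, censor_rate = 0.05,
                                max_followup = 60, seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (baseline_rate <= 0 || censor_rate <= 0 || max_followup <= 0) {
    stop("rates and max_followup must be > 0")
  }
  structure(list(n_subjects = as.integer(n_subjects), beta = beta,
                 baseline_rate = baseline_rate, censor_rate = censor_rate,
                 max_followup = max_followup, seed = as.integer(seed)),
            class = "survival_sim_config")
}

#' Simulate right-censored survival times from indicator values
#'
#' @param z Numeric vector of per-subject indicator values on the fraction
#'   scale (typically in `[0, 1]`).
#' @param cfg A [survival_sim_config()]; `cfg$n_subjects` is ignored in
#'   favor of `length(z)`.
#' @return data.frame with columns `time` (> 0) and `event` (1 = death,
#'   0 = censored), one row per element of `z`.
#' @examples
#' simulate_survival(c(0.1, 0.5, 0.9), survival_sim_config(seed = 3))
#' @export
simulate_survival <- function(z, cfg = survival_sim_config()) {
  stopifnot(inherits(cfg, "survival_sim_config"))
  if (length(z) == 0L) stop("z must contain at least one subject")
  if (anyNA(z)) stop("z must not contain missing values")
  with_seed(cfg$seed, {
    n <- length(z)
    rate <- cfg$baseline_rate * exp(cfg$beta * z)
    t_event <- stats::rexp(n, rate)
    t_cens <- pmin(stats::rexp(n, cfg$censor_rate), cfg$max_followup)
    time <- pmin(t_event, t_cens)
    time[time <= 0] <- .Machine$double.eps
    data.frame(time = time, event = as.integer(t_event <= t_cens))
  })
}

#' Generate a cohort of subjects with grids, indicators, and survival
#'
#' Each subject receives a label grid with subject-specific lymphocyte
#' infiltration rates (each regional probability drawn uniformly on
#' `[0, 0.8]`), the full spatial analysis is run, and survival is
#' simulated from the subject's value of the driving indicator (on the
#' fraction scale) under the proportional-hazards model of
#' [simulate_survival()]. Age, sex, and stage covariates are simulated as
#' outcome-independent noise.
#'
#' @param n_subjects Cohort size.
#' @param grid_cfg Template [grid_config()]; per-subject seeds and lymph
#'   probabilities are re-drawn from it.
#' @param surv_cfg A [survival_sim_config()].
#' @param driving_indicator One of [indicator_names()] (default
#'   `"Lymph_inside"`).
#' @param radius,min_neighborhood_size Nest-detection parameters passed to
#'   [analyze_spatial()].
#' @return A `cohort`: list with `subjects` (each holding `subject_id`,
#'   `grid`, `indicators`, `survival`) plus the configs used. Use
#'   [cohort_indicators()] and [cohort_survival()] for flat tables.
#' @export
generate_cohort <- function(n_subjects, grid_cfg = grid_config(),
                            surv_cfg = survival_sim_config(),
                            driving_indicator = "Lymph_inside",
                            radius = 2, min_neighborhood_size = 4) {
  if (!driving_indicator %in% indicator_names()) {
    stop("unknown driving indicator: ", driving_indicator)
  }
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  with_seed(grid_cfg$seed, {
    subject_seeds <- sample.int(.Machine$integer.max %/% 2L, n_subjects)
    p_draw <- matrix(stats::runif(3L * n_subjects, 0, 0.8), ncol = 3L)
    age <- round(stats::rnorm(n_subjects, 65, 10))
    sex <- stats::rbinom(n_subjects, 1L, 0.5)
    stage <- sample(2:4, n_subjects, replace = TRUE)
    surv_seed <- sample.int(.Machine$integer.max %/% 2L, 1L)

    subjects <- vector("list", n_subjects)
    z <- numeric(n_subjects)
    for (i in seq_len(n_subjects)) {
      cfg_i <- grid_cfg
      cfg_i$p_lymph_inside <- p_draw[i, 1L]
      cfg_i$p_lymph_border <- p_draw[i, 2L]
      cfg_i$p_lymph_outside <- p_draw[i, 3L]
      cfg_i$seed <- subject_seeds[i]
      g <- generate_label_grid(cfg_i)
      g$subject_id <- sprintf("S%03d", i)
      sp <- analyze_spatial(g, radius = radius,
                            min_neighborhood_size = min_neighborhood_size)
      ind <- sp$indicators
      zi <- ind[[driving_indicator]] / 100
      z[i] <- if (is.na(zi)) 0 else zi
      subjects[[i]] <- list(subject_id = g$subject_id, grid = g,
                            indicators = ind)
    }
    scfg <- surv_cfg
    scfg$seed <- surv_seed
    surv <- simulate_survival(z, scfg)
    for (i in seq_len(n_subjects)) {
      subjects[[i]]$survival <- data.frame(
        subject_id = subjects[[i]]$subject_id,
        time = surv$time[i], event = surv$event[i],
        age = age[i], sex = sex[i], stage = stage[i])
    }
    structure(list(subjects = subjects, grid_cfg = grid_cfg,
                   surv_cfg = surv_cfg,
                   driving_indicator = driving_indicator),
              class = "cohort")
  })
}

#' Flat per-subject tables from a cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @return `cohort_indicators`: data.frame of subject_id plus the 12
#'   indicators and region denominators. `cohort_survival`: data.frame of
#'   subject_id, time, event, age, sex, stage.
#' @export
cohort_indicators <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(cohort$subjects, function(s) {
    cbind(subject_id = s$subject_id, as.data.frame(s$indicators))
  }))
}

#' @rdname cohort_indicators
#' @export
cohort_survival <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(cohort$subjects, function(s) s$survival))
}
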