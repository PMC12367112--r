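# Independent oracles and fixture builders used across the suite.

# Seeded draws for test inputs without disturbing the global RNG stream.
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Brute-force DBSCAN on the patch lattice: full pairwise distance matrix,
# reachability closure over core points, border points to the nearest
# core's cluster (ties -> lowest id), clusters numbered in row-major scan
# order of their first core patch. Independent of the package's
# shifted-mask implementation.
brute_dbscan <- function(tumor, radius = 2, mns = 4) {
  nr <- nrow(tumor); nc <- ncol(tumor)
  pts <- which(tumor, arr.ind = TRUE)
  lab <- matrix(0L, nr, nc)
  n <- nrow(pts)
  if (n == 0L) return(lab)
  D <- as.matrix(stats::dist(pts))
  within <- D <= radius
  core <- (rowSums(within) - 1) >= mns
  scan <- order(pts[, 1], pts[, 2])
  comp <- rep(0L, n); cid <- 0L
  for (i in scan) {
    if (!core[i] || comp[i] != 0L) next
    cid <- cid + 1L
    stack <- i; comp[i] <- cid
    while (length(stack)) {
      cur <- stack[1]; stack <- stack[-1]
      nb <- which(within[cur, ] & core & comp == 0L)
      comp[nb] <- cid
      stack <- c(stack, nb)
    }
  }
  for (i in seq_len(n)) {
    if (core[i]) {
      lab[pts[i, 1], pts[i, 2]] <- comp[i]
      next
    }
    cand <- setdiff(which(core & within[i, ]), i)
    if (!length(cand)) next
    dmin <- min(D[i, cand])
    lab[pts[i, 1], pts[i, 2]] <- min(comp[cand[D[i, cand] == dmin]])
  }
  lab
}

# Hand tabulation of the two-group log-rank statistic: O - E with
# hypergeometric variance accumulated over distinct event times.
logrank_oracle <- function(time, event, group) {
  g <- as.integer(as.factor(group)) - 1L
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, O = O, E = E, V = V,
       p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Exhaustive cutpoint scan built on the hand-tabulation log-rank above,
# entirely independent of the package's survdiff-based path.
cutpoint_oracle <- function(time, event, values, minprop = 0.1) {
  v <- sort(unique(values))
  n <- length(values)
  mn <- ceiling(minprop * n)
  cands <- (v[-length(v)] + v[-1]) / 2
  cands <- cands[vapply(cands, function(ct) {
    sum(values <= ct) >= mn && sum(values > ct) >= mn
  }, TRUE)]
  ps <- vapply(cands, function(ct) {
    gr <- values > ct
    if (sum(event[gr]) + sum(event[!gr]) == 0) return(NA_real_)
    logrank_oracle(time, event, gr)$p
  }, 0)
  best <- which.min(ps)
  list(cutpoint = cands[best], p = ps[best])
}

# All-tissue grid with a solid square tumor nest.
solid_nest_grid <- function(n = 10, nest_rows = 3:7, nest_cols = 3:7,
                            lymph = NULL) {
  tu <- matrix(FALSE, n, n)
  tu[nest_rows, nest_cols] <- TRUE
  ly <- matrix(FALSE, n, n)
  if (!is.null(lymph)) ly[lymph] <- TRUE
  patch_grid_from_matrices(matrix(TRUE, n, n), tu, ly)
}

# Random tumor grid wrapped in a patch_grid.
random_tumor_grid <- function(nr, nc, p) {
  tumor <- matrix(stats::runif(nr * nc) < p, nr, nc)
  patch_grid_from_matrices(matrix(TRUE, nr, nc), tumor,
                           matrix(FALSE, nr, nc))
}

# Small synthetic image fixture for classifier tests.
make_image_fixture <- function(n, patch_px = 32, categories = c("other",
                                                                "tumor"),
                               seed_base = 0L) {
  cfg <- image_config(patch_px = patch_px)
  imgs <- vector("list", n)
  labs <- integer(n)
  for (i in seq_len(n)) {
    cat_i <- categories[(i %% length(categories)) + 1L]
    labs[i] <- as.integer(cat_i == categories[2L])
    imgs[[i]] <- generate_patch_image(cat_i, cfg, seed = seed_base + i)$image
  }
  list(images = imgs, labels = labs)
}
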