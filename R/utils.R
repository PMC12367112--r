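# Internal helpers shared across modules.

#' Run code with a temporary RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded generators do not perturb the global stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Shift a logical matrix by (dr, dc); cells shifted in from outside are FALSE.
shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr
  cok <- cs >= 1L & cs <= nc
  if (any(rok) && any(cok)) {
    out[rok, cok] <- m[rs[rok], cs[cok]]
  }
  out
}

# Count, for every cell, how many TRUE cells of `mask` lie at the given
# offsets (a 2-column matrix of dr, dc). Out-of-grid neighbors do not count.
neighbor_count <- function(mask, offsets) {
  cnt <- matrix(0L, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offsets))) {
    cnt <- cnt + shift_mask(mask, offsets[k, 1L], offsets[k, 2L])
  }
  cnt
}

# All nonzero integer offsets with dr^2 + dc^2 <= radius^2 (Euclidean disk
# on the lattice). radius = 2 yields the 12-offset neighborhood.
disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2 & !(g$dr == 0 & g$dc == 0), , drop = FALSE]
  as.matrix(g)
}

# 8- or 4-connected neighbor offsets.
adjacency_offsets <- function(connectivity = 8) {
  if (connectivity == 8) {
    g <- expand.grid(dr = -1:1, dc = -1:1)
    as.matrix(g[!(g$dr == 0 & g$dc == 0), ])
  } else if (connectivity == 4) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else {
    stop("connectivity must be 4 or 8")
  }
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name))
  }
  invisible(x)
}
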