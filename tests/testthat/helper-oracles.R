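# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: connected components come from igraph, the
# studentized range tail from raw Monte Carlo, and the brute-force bilateral
# filter from a direct triple loop with exact Gaussian weights.

# connected component of the seed among voxels <= threshold inside [lo, hi],
# via an igraph adjacency graph (independent of the C++ flood fill)
oracle_flood_fill <- function(values, seed, threshold, lo, hi, connectivity) {
  d <- dim(values)
  cand <- array(FALSE, d)
  cand[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  cand <- cand & (values <= threshold)
  idx <- which(cand)
  node <- integer(prod(d))
  node[idx] <- seq_along(idx)
  co <- arrayInd(idx, d)

  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  # undirected: keep lexicographically positive directions only
  offs <- offs[offs$dx > 0 | (offs$dx == 0 & offs$dy > 0) |
                 (offs$dx == 0 & offs$dy == 0 & offs$dz > 0), ]

  e_from <- integer(0); e_to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- cbind(co[, 1] + offs$dx[r], co[, 2] + offs$dy[r],
                co[, 3] + offs$dz[r])
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1 + d[2] * (nb[ok, 3] - 1))
    has <- node[nb_lin] > 0L
    e_from <- c(e_from, node[idx[ok]][has])
    e_to <- c(e_to, node[nb_lin][has])
  }
  g <- igraph::make_graph(rbind(e_from, e_to), n = length(idx),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  seed_lin <- seed[1] + d[1] * (seed[2] - 1 + d[2] * (seed[3] - 1))
  stopifnot(node[seed_lin] > 0L)
  keep <- idx[comp == comp[node[seed_lin]]]
  out <- array(FALSE, d)
  out[keep] <- TRUE
  out
}

# Monte-Carlo tail of the studentized range: P(range(Z_1..Z_k)/S > q)
mc_tukey_p <- function(q_obs, k, df, n = 1e6, seed = 99L) {
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(n * k), ncol = k)
    r <- do.call(pmax, asplit(z, 2)) - do.call(pmin, asplit(z, 2))
    s <- sqrt(stats::rchisq(n, df) / df)
    mean(r / s > q_obs)
  })
}

# direct brute-force bilateral filter (exact exp weights, 3-sigma truncation)
oracle_bilateral <- function(arr, spacing, sigma_s, sigma_r) {
  d <- dim(arr)
  r <- pmax(1, ceiling(3 * sigma_s / spacing))
  out <- arr
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    xs <- max(1, x - r[1]):min(d[1], x + r[1])
    ys <- max(1, y - r[2]):min(d[2], y + r[2])
    zs <- max(1, z - r[3]):min(d[3], z + r[3])
    vc <- arr[x, y, z]
    wsum <- 0; vsum <- 0
    for (zz in zs) for (yy in ys) for (xx in xs) {
      d2 <- ((xx - x) * spacing[1])^2 + ((yy - y) * spacing[2])^2 +
        ((zz - z) * spacing[3])^2
      w <- exp(-d2 / (2 * sigma_s^2)) *
        exp(-(arr[xx, yy, zz] - vc)^2 / (2 * sigma_r^2))
      wsum <- wsum + w
      vsum <- vsum + w * arr[xx, yy, zz]
    }
    out[x, y, z] <- vsum / wsum
  }
  out
}

# direct truncated Gaussian convolution (the sigma_range -> Inf limit)
oracle_gaussian <- function(arr, spacing, sigma_s) {
  oracle_bilateral(arr, spacing, sigma_s, sigma_r = Inf)
}

# small phantom used throughout unit tests (fast: ~0.1 s)
tiny_phantom <- function(grid_n = 48, ...) {
  generate_phantom(phantom_spec(grid_n = grid_n, ...))
}

# full-grid bounding box usable as a segmentation ROI
full_roi <- function(d) {
  structure(list(lo = c(1L, 1L, 1L), hi = as.integer(d), carina_z = NA),
            class = "bounding_roi")
}
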