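# Independent oracles and fixture builders shared across the test files.

# Brute-force minimum s-t cut by exhaustive enumeration of all
# 2^(n-2) partitions of the non-terminal vertices.  Exact for any capacities;
# independent of the Dinic implementation.
brute_force_min_cut <- function(n, from, to, cap, s, t) {
  mid <- setdiff(seq_len(n), c(s, t))
  best <- Inf
  for (bits in 0:(2^length(mid) - 1)) {
    in_S <- logical(n)
    in_S[s] <- TRUE
    if (length(mid)) in_S[mid] <- bitwAnd(bits, 2^(seq_along(mid) - 1)) > 0
    cut <- sum(cap[in_S[from] & !in_S[to]])
    if (cut < best) best <- cut
  }
  best
}

# Random directed flow network: <= n_max vertices, <= m_max arcs, integer
# capacities <= cap_max; vertex 1 is s, vertex n is t.
random_flow_graph <- function(n_max = 8, m_max = 16, cap_max = 10) {
  n <- sample(3:n_max, 1)
  m <- sample(2:m_max, 1)
  from <- sample.int(n, m, replace = TRUE)
  to <- sample.int(n, m, replace = TRUE)
  keep <- from != to & from != n & to != 1
  from <- from[keep]; to <- to[keep]
  if (length(from) == 0) { from <- 1L; to <- n }
  list(n = n, s = 1L, t = n, from = as.integer(from), to = as.integer(to),
       cap = as.numeric(sample.int(cap_max, length(from), replace = TRUE)))
}

# The diamond network of the worked max-flow example: min cut 5.
diamond_network <- function() {
  list(n = 4L, s = 1L, t = 4L,
       from = c(1L, 1L, 2L, 2L, 3L), to = c(2L, 3L, 3L, 4L, 4L),
       cap = c(3, 2, 1, 2, 3))
}

# Exhaustive min cut over pixel labelings of a small flow network (<= 9
# pixels): the oracle for seed-respecting minimum cuts.
enumerate_pixel_cuts <- function(net) {
  npx <- net$n_pixels
  stopifnot(npx <= 12)
  best <- Inf; best_lab <- NULL
  for (bits in 0:(2^npx - 1)) {
    in_S <- logical(net$n)
    in_S[net$s] <- TRUE
    in_S[seq_len(npx)] <- bitwAnd(bits, 2^(seq_len(npx) - 1)) > 0
    cut <- sum(net$cap[in_S[net$from] & !in_S[net$to]])
    if (cut < best) { best <- cut; best_lab <- in_S[seq_len(npx)] }
  }
  list(min_cut = best, labeling = best_lab)
}

# Noiseless two-level scene with non-overlapping disks/ellipses (no enclosed
# background, so midpoint thresholding is the exact reference segmentation).
make_two_level_scene <- function(rng_seed, size = 64) {
  particlecut:::with_local_seed(rng_seed, {
    n_blobs <- sample(1:3, 1)
    centers <- matrix(numeric(0), 0, 2)
    parts <- list()
    radii <- numeric(0)
    tries <- 0
    while (length(parts) < n_blobs && tries < 200) {
      tries <- tries + 1
      a <- runif(1, 4, 10)
      b <- if (runif(1) < 0.5) a else a * runif(1, 0.6, 1)
      ctr <- runif(2, a + 3, size - a - 3)
      if (nrow(centers) &&
          any(sqrt(rowSums(t(t(centers) - ctr)^2)) < max(radii) + a + 3)) next
      centers <- rbind(centers, ctr)
      radii <- c(radii, a)
      parts[[length(parts) + 1]] <- particle_spec(
        if (a == b) "disk" else "ellipse", center = ctr, axes = c(a, b),
        rotation = runif(1, 0, 180),
        object_intensity = 200, background_intensity = 50)
    }
    generate_particle_image(size, parts, noise_spec(0, 0, 0), rng_seed = rng_seed)
  })
}

# Coordinates of a rasterized disk (pixel centers within radius r).
disk_coords <- function(r, center = c(r + 11, r + 11), size = 2 * r + 21) {
  g <- expand.grid(row = seq_len(size), col = seq_len(size))
  keep <- (g$row - center[1])^2 + (g$col - center[2])^2 <= r^2
  as.matrix(g[keep, ])
}

rect_coords <- function(h, w, top = 3, left = 3) {
  as.matrix(expand.grid(row = top:(top + h - 1), col = left:(left + w - 1)))
}

# Flat image large enough for a given coordinate set.
flat_image <- function(coords, value = 200L) {
  image2d(matrix(value, max(coords[, 1]) + 2, max(coords[, 2]) + 2))
}
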