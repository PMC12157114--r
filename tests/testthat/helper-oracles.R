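# Independent brute-force oracles, deliberately written as plain per-point
# loops so they share no code path with the package implementations.

# Boundary via explicit neighbour checks (4-connectivity, off-image = bg).
oracle_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pts <- NULL
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      if (mask[r, c] != 1) next
      nb <- c(
        if (r > 1) mask[r - 1, c] else 0,
        if (r < h) mask[r + 1, c] else 0,
        if (c > 1) mask[r, c - 1] else 0,
        if (c < w) mask[r, c + 1] else 0
      )
      if (any(nb == 0)) pts <- rbind(pts, c(r, c))
    }
  }
  if (is.null(pts)) matrix(numeric(0), 0, 2) else pts
}

oracle_directed_hd <- function(A, B) {
  worst <- 0
  for (i in seq_len(nrow(A))) {
    d <- sqrt(min((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2))
    if (d > worst) worst <- d
  }
  worst
}

oracle_hd <- function(pred, gt) {
  A <- oracle_boundary(pred); B <- oracle_boundary(gt)
  if (nrow(A) == 0 && nrow(B) == 0) return(0)
  if (nrow(A) == 0 || nrow(B) == 0) return(NA_real_)
  max(oracle_directed_hd(A, B), oracle_directed_hd(B, A))
}

oracle_iou <- function(pred, gt) {
  un <- sum(pred == 1 | gt == 1)
  if (un == 0) return(1)
  sum(pred == 1 & gt == 1) / un
}

# Random 0/1 matrix; p is the foreground probability.
random_mask <- function(h, w, p = 0.3) {
  matrix(rbinom(h * w, 1L, p), h, w)
}

# A random mask guaranteed non-empty.
random_nonempty_mask <- function(h, w, p = 0.3) {
  m <- random_mask(h, w, p)
  if (sum(m) == 0) m[sample.int(h, 1), sample.int(w, 1)] <- 1L
  m
}

# Build a mask from 1-based (row, col) coordinate pairs.
mask_from_points <- function(h, w, pts) {
  m <- matrix(0L, h, w)
  for (p in pts) m[p[1], p[2]] <- 1L
  m
}

# Small phantom + simulated models, shared by pipeline-level tests.
tiny_bundle_config <- function(seed = 1L) {
  phantom_config(n_slices = 7L, height = 48L, width = 48L,
                 base_radius = 12, seed = seed)
}
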