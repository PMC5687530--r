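# Independent oracles used across tests.

# Ellipse perimeter by numerical arc-length integration.
ellipse_perimeter <- function(a, b) {
  stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                   0, 2 * pi, rel.tol = 1e-12)$value
}

# Regular n-gon inscribed in a circle of radius r: area and perimeter.
polygon_circle <- function(n, r = 1) {
  list(area = 0.5 * n * r^2 * sin(2 * pi / n),
       perimeter = 2 * n * r * sin(pi / n))
}

# Kruskal-Wallis H from the rank-sum formula with tie correction.
kw_by_hand <- function(groups) {
  pooled <- unlist(groups)
  r <- rank(pooled)
  n <- length(pooled)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  rs <- vapply(seq_along(groups), function(i) sum(r[starts[i]:ends[i]]),
               numeric(1))
  h <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
  ties <- table(pooled)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Benjamini-Hochberg step-up by direct enumeration.
bh_by_hand <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# Displacement field for a constant affine map about the grid centre.
affine_field <- function(dm, A, spacing = c(1, 1, 1)) {
  w <- lungqct:::grid_world(dm, spacing)
  ctr <- (dm - 1) * spacing / 2
  Ai <- A - diag(3)
  u <- array(0, c(dm, 3))
  for (i in 1:3) {
    u[, , , i] <- Ai[i, 1] * (w$x - ctr[1]) + Ai[i, 2] * (w$y - ctr[2]) +
      Ai[i, 3] * (w$z - ctr[3])
  }
  qct_field(u, spacing)
}

full_lung_mask <- function(dm, spacing = c(1, 1, 1)) {
  qct_lobe_mask(array(1L, dm), spacing)
}
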