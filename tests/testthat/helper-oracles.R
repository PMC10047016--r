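# Independent brute-force oracles and small fixtures shared across tests.
# The oracles deliberately use plain double loops so they share no code with
# the implementations they check.

# center of mass by explicit double loop (0-based coordinates)
com_oracle <- function(image, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  sw <- sr <- sc <- 0
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      if (mask[i, j]) {
        w <- image[i, j]
        sw <- sw + w
        sr <- sr + w * (i - 1)
        sc <- sc + w * (j - 1)
      }
    }
  }
  c(row = sr / sw, col = sc / sw)
}

# radial histogram by explicit per-pixel distance binning
radial_oracle <- function(image, center, n_bands) {
  nr <- nrow(image); nc <- ncol(image)
  r_max <- 0
  for (cr in c(0, nr - 1)) for (cc in c(0, nc - 1))
    r_max <- max(r_max, sqrt((cr - center[1])^2 + (cc - center[2])^2))
  edges <- seq(0, r_max, length.out = n_bands + 1)
  mass <- numeric(n_bands); area <- numeric(n_bands)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      r <- sqrt((i - 1 - center[1])^2 + (j - 1 - center[2])^2)
      b <- n_bands
      for (k in seq_len(n_bands)) {
        if (r >= edges[k] && r < edges[k + 1]) { b <- k; break }
      }
      mass[b] <- mass[b] + image[i, j]
      area[b] <- area[b] + 1
    }
  }
  v <- ifelse(area > 0, mass / area, 0)
  list(values = v / sum(v), mass = mass, area = area, edges = edges)
}

# classical Fisher LDA direction from the explicit matrix solve
fisher_oracle <- function(X, y) {
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  c1 <- sweep(X[y == 1, , drop = FALSE], 2, mu1)
  c0 <- sweep(X[y == 0, , drop = FALSE], 2, mu0)
  sw <- (crossprod(c1) + crossprod(c0)) / (nrow(X) - 2)
  solve(sw, mu1 - mu0)
}

# AUC by direct concordance counting over all positive-negative pairs
auc_oracle <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# random star-shaped simple polygon (vertices off the pixel grid so no pixel
# center falls on an edge)
random_polygon <- function(n_vert = 8, center = c(5.3, 5.7), rad = 4) {
  ang <- sort(runif(n_vert, 0, 2 * pi))
  r <- runif(n_vert, 0.4, 1) * rad
  data.frame(x = center[1] + r * cos(ang), y = center[2] + r * sin(ang))
}

# a small, fast cohort configuration for pipeline-level tests
tiny_config <- function(seed = 1L, n = 40, size = 64, ...) {
  cohort_config(n_findings = n, image_size = size, seed = seed, ...)
}
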