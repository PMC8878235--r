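# Independent brute-force oracles and fixture builders used across tests.

# Random normalized co-occurrence matrix.
random_glcm_matrix <- function(levels) {
  p <- matrix(stats::runif(levels^2), levels, levels)
  p / sum(p)
}

# Brute-force double-loop GLCM features (kept deliberately naive and
# separate from the package's vectorized implementations).
bf_glcm_features <- function(p, dims) {
  L1 <- nrow(p); L2 <- ncol(p)
  hom <- 0; dis <- 0; con <- 0; ene <- 0
  for (i in seq_len(L1)) {
    for (j in seq_len(L2)) {
      d <- (i - 1) - (j - 1)
      hom <- hom + p[i, j] / (1 + d^2)
      dis <- dis + abs(d) * p[i, j]
      con <- con + d^2 * p[i, j]
      ene <- ene + p[i, j]^2
    }
  }
  c(homogeneity = hom, max_probability = max(p), energy = ene,
    dissimilarity = dis, contrast = con, mean = sum(p) / prod(dims))
}

# Brute-force co-occurrence pair counter (asymmetric, no mask).
bf_glcm_counts <- function(img, levels, offset) {
  q <- pmin(floor(pmin(pmax(img, 0), 1) * levels), levels - 1)
  h <- nrow(img); w <- ncol(img)
  counts <- matrix(0, levels, levels)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + offset[1]; c2 <- c + offset[2]
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
        counts[q[r, c] + 1, q[r2, c2] + 1] <-
          counts[q[r, c] + 1, q[r2, c2] + 1] + 1
      }
    }
  }
  counts
}

# Brute-force GLCM correlation over 0-based indices.
bf_joint_correlation <- function(p) {
  L1 <- nrow(p); L2 <- ncol(p)
  mi <- 0; mj <- 0
  for (i in seq_len(L1)) for (j in seq_len(L2)) {
    mi <- mi + (i - 1) * p[i, j]
    mj <- mj + (j - 1) * p[i, j]
  }
  si <- 0; sj <- 0; cc <- 0
  for (i in seq_len(L1)) for (j in seq_len(L2)) {
    si <- si + (i - 1 - mi)^2 * p[i, j]
    sj <- sj + (j - 1 - mj)^2 * p[i, j]
    cc <- cc + (i - 1 - mi) * (j - 1 - mj) * p[i, j]
  }
  cc / sqrt(si * sj)
}

# Hand bilinear resampler mirroring the documented pixel-center convention,
# written as explicit per-pixel loops.
bf_bilinear <- function(img, th, tw) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, th, tw)
  for (r in seq_len(th)) {
    for (c in seq_len(tw)) {
      sr <- min(max((r - 0.5) * h / th + 0.5, 1), h)
      sc <- min(max((c - 0.5) * w / tw + 0.5, 1), w)
      r0 <- floor(sr); c0 <- floor(sc)
      r1 <- min(r0 + 1, h); c1 <- min(c0 + 1, w)
      fr <- sr - r0; fc <- sc - c0
      out[r, c] <- (1 - fr) * ((1 - fc) * img[r0, c0] + fc * img[r0, c1]) +
        fr * ((1 - fc) * img[r1, c0] + fc * img[r1, c1])
    }
  }
  out
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# A small low-contrast phantom for enhancement tests.
low_contrast_phantom <- function(seed = 5) {
  ph <- generate_phantom(phantom_spec(width = 128, height = 128,
                                      n_lesions = 2, vessel_count = 2,
                                      noise_sigma = 0.005, seed = seed))
  0.4 + 0.2 * ph$image
}
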