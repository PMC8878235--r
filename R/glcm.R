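# Gray-level co-occurrence matrices and the texture features used to
# separate microaneurysm candidates from other dark structures.

#' Compute a gray-level co-occurrence matrix
#'
#' Intensities in `[0, 1]` are quantized uniformly into `levels` bins
#' (0-based level indices `0 .. levels - 1`); pairs of pixels separated by
#' `offset = c(drow, dcol)` are counted, the transpose is added when
#' `symmetric`, and counts are normalized to a joint probability matrix.
#' An optional mask restricts counting to pairs whose *both* pixels lie in
#' the mask.
#'
#' @param img Grayscale matrix in `[0, 1]`.
#' @param levels Number of gray levels (>= 2). Default 16: candidate regions
#'   are small, and finer quantization leaves the matrix too sparse to carry
#'   texture information.
#' @param offset Integer `c(drow, dcol)`, not `c(0, 0)`.
#' @param symmetric Count each pair in both directions (matrix equals its own
#'   transpose).
#' @param mask Optional logical matrix, same shape as `img`.
#' @return A `glcm` object: list with `p` (probabilities), `counts`,
#'   `levels`, `offset`, `symmetric`.
#' @export
compute_glcm <- function(img, levels = 16, offset = c(0, 1),
                         symmetric = TRUE, mask = NULL) {
  stopifnot(is.matrix(img), levels >= 2, length(offset) == 2)
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  if (dr == 0 && dc == 0) stop("offset must not be (0, 0)")
  levels <- as.integer(levels)
  h <- nrow(img); w <- ncol(img)
  q <- pmin(floor(clamp01(img) * levels), levels - 1L)

  rs <- max(1L, 1L - dr):min(h, h - dr)
  cs <- max(1L, 1L - dc):min(w, w - dc)
  if (length(rs) < 1 || length(cs) < 1 || rs[1] > rs[length(rs)] ||
      cs[1] > cs[length(cs)]) {
    stop("no valid pixel pairs for this offset (image too small)")
  }
  a <- q[rs, cs, drop = FALSE]
  b <- q[rs + dr, cs + dc, drop = FALSE]
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(img)))
    keep <- mask[rs, cs, drop = FALSE] & mask[rs + dr, cs + dc, drop = FALSE]
    a <- a[keep]; b <- b[keep]
  }
  if (length(a) == 0) stop("no valid pixel pairs for this offset")
  counts <- matrix(tabulate(as.integer(a) * levels + as.integer(b) + 1L,
                            nbins = levels^2),
                   levels, levels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  structure(list(p = counts / sum(counts), counts = counts,
                 levels = levels, offset = c(dr, dc), symmetric = symmetric),
            class = "glcm")
}

as_glcm_p <- function(g) {
  if (inherits(g, "glcm")) g$p else as.matrix(g)
}

glcm_level_diff <- function(p) {
  i <- seq_len(nrow(p)) - 1
  j <- seq_len(ncol(p)) - 1
  outer(i, j, "-")
}

#' GLCM homogeneity
#'
#' \eqn{\sum_{ij} p_{ij} / (1 + (i - j)^2)}; 1 for a diagonal-only matrix.
#' @param g A `glcm` object or bare probability matrix.
#' @export
glcm_homogeneity <- function(g) {
  p <- as_glcm_p(g)
  sum(p / (1 + glcm_level_diff(p)^2))
}

#' GLCM maximum probability
#'
#' \eqn{\max_{ij} p_{ij}}.
#' @inheritParams glcm_homogeneity
#' @export
glcm_max_probability <- function(g) max(as_glcm_p(g))

#' GLCM energy
#'
#' \eqn{\sum_{ij} p_{ij}^2} (angular second moment); never exceeds the
#' maximum probability.
#' @inheritParams glcm_homogeneity
#' @export
glcm_energy <- function(g) sum(as_glcm_p(g)^2)

#' GLCM dissimilarity
#'
#' \eqn{\sum_{ij} |i - j| \, p_{ij}}; 0 for a diagonal-only matrix, and by
#' Cauchy-Schwarz at most \eqn{\sqrt{contrast}}.
#' @inheritParams glcm_homogeneity
#' @export
glcm_dissimilarity <- function(g) {
  p <- as_glcm_p(g)
  sum(abs(glcm_level_diff(p)) * p)
}

#' GLCM contrast
#'
#' \eqn{\sum_{ij} (i - j)^2 \, p_{ij}}, summed over the matrix support.
#' @inheritParams glcm_homogeneity
#' @export
glcm_contrast <- function(g) {
  p <- as_glcm_p(g)
  sum(glcm_level_diff(p)^2 * p)
}

#' GLCM mean
#'
#' \eqn{\sum_{ij} p_{ij} / (N \cdot M)} for image dimensions `(N, M)`. For a
#' normalized matrix this is the constant `1 / (N * M)` by construction; it
#' is retained in that literal form for fidelity, and `normalized = FALSE`
#' substitutes raw pair counts for `p` so the quantity can carry information
#' (pair count per image pixel).
#'
#' @inheritParams glcm_homogeneity
#' @param image_dims `c(N, M)` image (or region bounding box) dimensions.
#' @param normalized Use probabilities (default, the literal formula) or raw
#'   counts.
#' @export
glcm_mean <- function(g, image_dims, normalized = TRUE) {
  stopifnot(length(image_dims) == 2, all(image_dims >= 1))
  top <- if (normalized) {
    sum(as_glcm_p(g))
  } else {
    if (!inherits(g, "glcm")) stop("count variant requires a glcm object")
    sum(g$counts)
  }
  top / prod(image_dims)
}

#' All six GLCM features of one matrix
#'
#' @inheritParams glcm_mean
#' @return Named vector: `homogeneity`, `max_probability`, `energy`,
#'   `dissimilarity`, `contrast`, `mean`.
#' @export
glcm_features <- function(g, image_dims, normalized = TRUE) {
  c(homogeneity = glcm_homogeneity(g),
    max_probability = glcm_max_probability(g),
    energy = glcm_energy(g),
    dissimilarity = glcm_dissimilarity(g),
    contrast = glcm_contrast(g),
    mean = glcm_mean(g, image_dims, normalized))
}

#' Texture features of a masked region
#'
#' Builds GLCMs over the region's bounding box restricted to mask pixels
#' (only pairs with both pixels inside the mask are counted) for each spatial
#' offset, and averages the six features over the offsets that yield at least
#' one pair. The default offsets are the four standard directions
#' (0,1), (1,0), (1,1), (1,-1).
#'
#' @param img Grayscale matrix in `[0, 1]`.
#' @param mask Logical matrix, same shape, non-empty.
#' @param levels Gray levels for quantization.
#' @param offsets List of `c(drow, dcol)` offsets.
#' @param symmetric Symmetric GLCMs.
#' @return Named feature vector as in [glcm_features()]; attribute
#'   `n_offsets` records how many offsets contributed.
#' @export
region_features <- function(img, mask, levels = 16,
                            offsets = list(c(0, 1), c(1, 0),
                                           c(1, 1), c(1, -1)),
                            symmetric = TRUE) {
  stopifnot(is.matrix(img), identical(dim(mask), dim(img)))
  mask <- mask > 0
  if (!any(mask)) stop("region mask is empty")
  rr <- range(which(rowSums(mask) > 0))
  cr <- range(which(colSums(mask) > 0))
  sub <- img[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  smask <- mask[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  dims <- dim(sub)
  acc <- NULL
  n_ok <- 0L
  for (off in offsets) {
    g <- tryCatch(compute_glcm(sub, levels, off, symmetric, mask = smask),
                  error = function(e) NULL)
    if (is.null(g)) next
    fv <- glcm_features(g, dims)
    acc <- if (is.null(acc)) fv else acc + fv
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0L) {
    stop("region has no valid pixel pairs for any offset (area ",
         sum(mask), " px)")
  }
  structure(acc / n_ok, n_offsets = n_ok)
}
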