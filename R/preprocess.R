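# Preprocessing: resize, grayscale conversion, fuzzy-clipped CLAHE, and
# whole-image statistics.

#' Configuration for fuzzy-clipped CLAHE
#'
#' Free parameters of the contrast-enhancement step. The image is divided
#' into `tile_grid` contextual tiles; each tile's histogram (over `bins`
#' levels) is clipped at a limit chosen by a small fuzzy inference system
#' (see [fuzzy_clip_multiplier()]) and equalized; pixel mappings are blended
#' bilinearly between neighbouring tiles.
#'
#' @param tile_grid `c(rows, cols)` of contextual tiles (each >= 1).
#' @param base_clip Maximum clip limit as a multiple of the uniform histogram
#'   bin height (> 1).
#' @param fuzzy_low,fuzzy_high Intensity anchors in `[0, 1]` of the
#'   dark-dominant / bright-dominant membership functions; `fuzzy_low <
#'   fuzzy_high`.
#' @param bins Number of histogram bins.
#' @return An `enhancement_config` list.
#' @export
enhancement_config <- function(tile_grid = c(8, 8), base_clip = 4,
                               fuzzy_low = 0.25, fuzzy_high = 0.75,
                               bins = 256L) {
  stopifnot(length(tile_grid) == 2, all(tile_grid >= 1),
            base_clip > 1, bins >= 2,
            fuzzy_low >= 0, fuzzy_high <= 1, fuzzy_low < fuzzy_high)
  structure(list(tile_grid = as.integer(tile_grid), base_clip = base_clip,
                 fuzzy_low = fuzzy_low, fuzzy_high = fuzzy_high,
                 bins = as.integer(bins)),
            class = "enhancement_config")
}

#' Bilinear image resize
#'
#' Resamples a grayscale matrix (or each channel of an H x W x C array) to
#' `target = c(height, width)` by bilinear interpolation with a pixel-center
#' alignment convention: output pixel `r'` samples source coordinate
#' `(r' - 0.5) * h / h' + 0.5`, clamped to the source extent. Resizing to the
#' current shape is an exact identity; values stay within the input range.
#'
#' @param img Numeric matrix in `[0, 1]`, or 3-d array (channels last).
#' @param target `c(height, width)`.
#' @return Resized image of the same kind.
#' @export
resize_image <- function(img, target = c(250, 250)) {
  stopifnot(length(target) == 2, all(target >= 1))
  if (length(dim(img)) == 3) {
    out <- array(0, c(target, dim(img)[3]))
    for (ch in seq_len(dim(img)[3])) {
      out[, , ch] <- resize_image(img[, , ch], target)
    }
    return(out)
  }
  stopifnot(is.matrix(img))
  if (nrow(img) == 0 || ncol(img) == 0) stop("cannot resize an empty image")
  h <- nrow(img); w <- ncol(img)
  th <- as.integer(target[1]); tw <- as.integer(target[2])

  axis_map <- function(n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) * (n_in / n_out) + 0.5
    s <- pmin(pmax(s, 1), n_in)
    i0 <- floor(s)
    f <- s - i0
    i1 <- pmin(i0 + 1, n_in)
    list(i0 = as.integer(i0), i1 = as.integer(i1), f = f)
  }
  rm_ <- axis_map(th, h)
  cm_ <- axis_map(tw, w)
  rows <- img[rm_$i0, , drop = FALSE] * (1 - rm_$f) +
    img[rm_$i1, , drop = FALSE] * rm_$f
  sweep(rows[, cm_$i0, drop = FALSE], 2, 1 - cm_$f, "*") +
    sweep(rows[, cm_$i1, drop = FALSE], 2, cm_$f, "*")
}

#' Convert a color image to grayscale
#'
#' `green_channel` (the default elsewhere in the pipeline) extracts the green
#' plane, which carries the highest red-lesion contrast in fundus
#' photography; `luminance` uses the Rec. 601 weights
#' `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param img H x W x 3 numeric array in `[0, 1]`.
#' @param mode `"green_channel"` or `"luminance"`.
#' @return Grayscale matrix.
#' @export
to_grayscale <- function(img, mode = c("green_channel", "luminance")) {
  mode <- match.arg(mode)
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop("to_grayscale expects an H x W x 3 array")
  }
  out <- switch(mode,
                green_channel = img[, , 2],
                luminance = 0.299 * img[, , 1] + 0.587 * img[, , 2] +
                  0.114 * img[, , 3])
  matrix(out, dim(img)[1], dim(img)[2])
}

#' Fuzzy clip-limit from tile statistics
#'
#' The fuzzy inference step behind [fuzzy_clahe()]. Inputs are the tile mean
#' intensity and the tile histogram's normalized entropy `uniformity`
#' (1 = already uniform). Three rules fire: *extreme tiles* (dark-dominant or
#' bright-dominant membership, triangles anchored at `fuzzy_low` /
#' `fuzzy_high`) ask for a LOW clip (centroid 1, i.e. strong clipping, little
#' amplification - these tiles are mostly border or glare where equalization
#' amplifies noise); *already-uniform tiles* also ask for LOW; *mid-toned,
#' non-uniform tiles* ask for a HIGH clip (centroid `base_clip`). The crisp
#' multiplier is the activation-weighted centroid, always in
#' `[1, base_clip]`.
#'
#' @param tile_mean Tile mean intensity in `[0, 1]`.
#' @param uniformity Normalized histogram entropy in `[0, 1]`.
#' @param cfg An [enhancement_config()].
#' @return Clip multiplier in `[1, base_clip]`.
#' @export
fuzzy_clip_multiplier <- function(tile_mean, uniformity, cfg) {
  mu_dark <- pmax(0, 1 - tile_mean / cfg$fuzzy_low)
  mu_bright <- pmax(0, 1 - (1 - tile_mean) / (1 - cfg$fuzzy_high))
  extreme <- pmax(mu_dark, mu_bright)
  a_low <- extreme + uniformity
  a_high <- (1 - extreme) * (1 - uniformity)
  tot <- a_low + a_high
  ifelse(tot > 0, (a_low * 1 + a_high * cfg$base_clip) / tot, 1)
}

#' Fuzzy-clipped contrast-limited adaptive histogram equalization
#'
#' CLAHE in which the per-tile clip limit is not a global constant but is
#' modulated by a fuzzy inference over local tile statistics
#' ([fuzzy_clip_multiplier()]): tiles dominated by very dark or very bright
#' content, or whose histogram is already near-uniform, are clipped hard,
#' while mid-toned low-uniformity tiles receive up to `base_clip` times the
#' uniform bin height. Clipped mass is redistributed uniformly; per-tile
#' equalization mappings are monotone and pixel values are blended bilinearly
#' between the four surrounding tile mappings. Deterministic; output in
#' `[0, 1]`.
#'
#' @param img Grayscale matrix in `[0, 1]`.
#' @param cfg An [enhancement_config()].
#' @return Enhanced image, same shape.
#' @export
fuzzy_clahe <- function(img, cfg = enhancement_config()) {
  stopifnot(is.matrix(img))
  h <- nrow(img); w <- ncol(img)
  tr <- cfg$tile_grid[1]; tc <- cfg$tile_grid[2]
  if (tr > h || tc > w) stop("tile grid larger than image")
  bins <- cfg$bins
  q <- pmin(floor(clamp01(img) * bins), bins - 1L)  # 0-based bin index

  rb <- floor(seq(0, h, length.out = tr + 1))
  cb <- floor(seq(0, w, length.out = tc + 1))
  maps <- array(0, c(tr, tc, bins))
  for (ti in seq_len(tr)) {
    for (tj in seq_len(tc)) {
      rows <- (rb[ti] + 1):rb[ti + 1]
      cols <- (cb[tj] + 1):cb[tj + 1]
      tile_bins <- q[rows, cols]
      npx <- length(tile_bins)
      hc <- tabulate(tile_bins + 1L, nbins = bins)
      pr <- hc[hc > 0] / npx
      uniformity <- -sum(pr * log(pr)) / log(bins)
      cm <- fuzzy_clip_multiplier(mean(img[rows, cols]), uniformity, cfg)
      clip <- cm * npx / bins
      # redistribute clipped mass uniformly; a few passes converge
      for (it in 1:10) {
        excess <- sum(pmax(hc - clip, 0))
        if (excess < 1e-9) break
        hc <- pmin(hc, clip) + excess / bins
      }
      hc <- pmin(hc, clip * 1.0001)
      maps[ti, tj, ] <- cumsum(hc) / sum(hc)
    }
  }

  # bilinear blend of tile mappings, clamped at the image border
  centers_of <- function(b) (b[-length(b)] + 1 + b[-1]) / 2
  rc <- centers_of(rb); cc_ <- centers_of(cb)
  axis_blend <- function(coord, centers) {
    nt <- length(centers)
    i0 <- findInterval(coord, centers)
    f <- numeric(length(coord))
    lo <- i0 < 1; hi <- i0 >= nt
    mid <- !lo & !hi
    i0[lo] <- 1L
    f[mid] <- (coord[mid] - centers[i0[mid]]) /
      (centers[i0[mid] + 1] - centers[i0[mid]])
    i1 <- pmin(i0 + 1L, nt)
    i1[lo] <- 1L
    f[lo | hi] <- 0
    list(i0 = as.integer(i0), i1 = as.integer(i1), f = f)
  }
  rbl <- axis_blend(seq_len(h), rc)
  cbl <- axis_blend(seq_len(w), cc_)

  pr_ <- rep(seq_len(h), times = w)
  pc_ <- rep(seq_len(w), each = h)
  bin1 <- as.vector(q) + 1L
  ti0 <- rbl$i0[pr_]; ti1 <- rbl$i1[pr_]; fr <- rbl$f[pr_]
  tj0 <- cbl$i0[pc_]; tj1 <- cbl$i1[pc_]; fc <- cbl$f[pc_]
  g00 <- maps[cbind(ti0, tj0, bin1)]
  g01 <- maps[cbind(ti0, tj1, bin1)]
  g10 <- maps[cbind(ti1, tj0, bin1)]
  g11 <- maps[cbind(ti1, tj1, bin1)]
  out <- (1 - fr) * ((1 - fc) * g00 + fc * g01) +
    fr * ((1 - fc) * g10 + fc * g11)
  matrix(clamp01(out), h, w)
}

#' Whole-image statistics
#'
#' Mean, unbiased variance, skewness and kurtosis (moment convention, see
#' [sample_kurtosis()]) of the pixel population, plus the co-occurrence
#' correlation of the image's default GLCM. A constant image yields variance
#' 0 and degenerate-flagged zero skewness/kurtosis/correlation.
#'
#' @param img Grayscale matrix with at least 2 pixels.
#' @param levels Gray levels for the correlation GLCM.
#' @return List with `mean`, `variance`, `correlation`, `kurtosis`,
#'   `skewness`, and `degenerate` (TRUE when the moment statistics were
#'   undefined).
#' @export
compute_image_stats <- function(img, levels = 16) {
  stopifnot(is.matrix(img), length(img) >= 2)
  v <- as.numeric(img)
  sk <- sample_skewness(v)
  ku <- sample_kurtosis(v)
  co <- joint_correlation(compute_glcm(img, levels = levels)$p)
  list(mean = mean(v),
       variance = sample_variance(v),
       correlation = as.numeric(co),
       kurtosis = as.numeric(ku),
       skewness = as.numeric(sk),
       degenerate = is_degenerate(sk) || is_degenerate(ku))
}
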