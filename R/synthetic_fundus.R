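# Ground-truthed synthetic fundus phantoms and labelled Gaussian point clouds.
# These stand in for real fundus photographs so every downstream stage
# (enhancement, segmentation, feature extraction, detection scoring) can be
# exercised against known truth.

#' Specification of a synthetic fundus phantom
#'
#' The phantom is a bright circular retinal field with a smooth radial
#' illumination falloff, dark curvilinear vessels (random-walk polylines with
#' a Gaussian cross-profile), small dark disc lesions emulating
#' microaneurysms, and additive Gaussian noise inside the field. Intensities
#' are reals in `[0, 1]`.
#'
#' The analytic background inside the field is
#' `base_intensity * (1 - illumination_amplitude * (d / R)^2)` where `d` is
#' the distance from the image center and `R = field_radius_frac * min(width,
#' height)` is the field radius; vessels and lesions are multiplicative
#' intensity dips on top of it.
#'
#' @param width,height Image size in pixels (>= 64).
#' @param n_lesions Number of microaneurysm-like dot lesions (>= 0).
#' @param lesion_radius Range `c(rmin, rmax)` of lesion radii in pixels;
#'   `rmax` must stay below `min(width, height) / 10`.
#' @param lesion_contrast Fractional intensity drop of a lesion against its
#'   local background, in `(0, 1]`.
#' @param vessel_count Number of vessel polylines (>= 0).
#' @param illumination_amplitude Relative center-to-edge falloff of the
#'   background field, in `[0, 1)`.
#' @param noise_sigma Standard deviation of additive Gaussian noise (intensity
#'   units, >= 0).
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#' @param base_intensity Background intensity at the field center.
#' @param field_radius_frac Field radius as a fraction of `min(width, height)`.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(width = 250, height = 250,
                         n_lesions = 5,
                         lesion_radius = c(2, 5),
                         lesion_contrast = 0.4,
                         vessel_count = 6,
                         illumination_amplitude = 0.3,
                         noise_sigma = 0.01,
                         seed = 1L,
                         base_intensity = 0.78,
                         field_radius_frac = 0.475) {
  stopifnot(width >= 64, height >= 64,
            n_lesions >= 0, vessel_count >= 0,
            length(lesion_radius) == 2, lesion_radius[1] <= lesion_radius[2],
            lesion_radius[1] > 0,
            lesion_contrast > 0, lesion_contrast <= 1,
            illumination_amplitude >= 0, illumination_amplitude < 1,
            noise_sigma >= 0,
            base_intensity > 0, base_intensity <= 1,
            field_radius_frac > 0, field_radius_frac <= 0.5)
  if (lesion_radius[2] >= min(width, height) / 10) {
    stop("lesion_radius[2] must be below min(width, height) / 10")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_lesions = as.integer(n_lesions),
                 lesion_radius = as.numeric(lesion_radius),
                 lesion_contrast = lesion_contrast,
                 vessel_count = as.integer(vessel_count),
                 illumination_amplitude = illumination_amplitude,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed),
                 base_intensity = base_intensity,
                 field_radius_frac = field_radius_frac),
            class = "phantom_spec")
}

# Analytic illumination background (zero outside the field mask).
illumination_field <- function(spec) {
  h <- spec$height; w <- spec$width
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  d <- sqrt((rr - cy)^2 + (cc - cx)^2)
  R <- spec$field_radius_frac * min(w, h)
  field <- d <= R
  illum <- spec$base_intensity * (1 - spec$illumination_amplitude * (d / R)^2)
  list(illum = illum * field, field_mask = field, d = d, radius = R,
       center = c(cy, cx))
}

# Stamp a multiplicative dip profile into `dip` (taking pointwise max so
# overlapping stamps do not over-darken).
stamp_max <- function(dip, row0, col0, halfwidth, profile_fun) {
  h <- nrow(dip); w <- ncol(dip)
  rs <- max(1L, floor(row0 - halfwidth)):min(h, ceiling(row0 + halfwidth))
  cs <- max(1L, floor(col0 - halfwidth)):min(w, ceiling(col0 + halfwidth))
  if (!length(rs) || !length(cs)) return(dip)
  dr <- outer(rs - row0, rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - col0)
  d <- sqrt(dr^2 + dc^2)
  dip[rs, cs] <- pmax(dip[rs, cs], profile_fun(d))
  dip
}

#' Generate a synthetic fundus phantom with ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: radial illumination
#' times the field mask, vessels as dark random-walk polylines, lesions as
#' disc-shaped intensity dips of fractional depth `lesion_contrast`, then
#' Gaussian noise inside the field. Lesions are placed fully inside the field,
#' apart from each other, and with at most 20% of their area overlapping
#' vessels; placement retries are capped (100 per lesion) and exhausting them
#' raises an error rather than silently dropping lesions.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (matrix in `[0, 1]`) and `truth`, itself a list
#'   of `lesion_mask`, `vessel_mask`, `field_mask` (logical matrices),
#'   and `lesion_centers` (data.frame `center_row`, `center_col`, `radius`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    bg <- illumination_field(spec)
    h <- spec$height; w <- spec$width
    img <- bg$illum
    R <- bg$radius; cy <- bg$center[1]; cx <- bg$center[2]

    # vessels: random walks starting near the center, drifting outward
    vessel_dip <- matrix(0, h, w)
    for (v in seq_len(spec$vessel_count)) {
      theta <- stats::runif(1, 0, 2 * pi)
      pos <- c(cy, cx) + 0.08 * R * c(sin(theta), cos(theta))
      dir <- theta + stats::rnorm(1, 0, 0.3)
      sigma <- stats::runif(1, 0.8, 1.6)
      depth <- stats::runif(1, 0.25, 0.4)
      n_steps <- ceiling(1.2 * R / 1.5)
      for (s in seq_len(n_steps)) {
        dir <- dir + stats::rnorm(1, 0, 0.22)
        pos <- pos + 1.5 * c(sin(dir), cos(dir))
        if (sqrt((pos[1] - cy)^2 + (pos[2] - cx)^2) > 0.97 * R) break
        vessel_dip <- stamp_max(vessel_dip, pos[1], pos[2], 3 * sigma,
                                function(d) depth * exp(-d^2 / (2 * sigma^2)))
      }
    }
    vessel_mask <- vessel_dip > 0.1

    # lesions: disc dips with a short cosine taper at the rim
    lesion_dip <- matrix(0, h, w)
    lesion_mask <- matrix(FALSE, h, w)
    centers <- data.frame(center_row = numeric(0), center_col = numeric(0),
                          radius = numeric(0))
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (l in seq_len(spec$n_lesions)) {
      placed <- FALSE
      for (try in seq_len(100L)) {
        r_les <- stats::runif(1, spec$lesion_radius[1], spec$lesion_radius[2])
        rad_pos <- R - r_les - 3
        u <- stats::runif(1); ang <- stats::runif(1, 0, 2 * pi)
        p0 <- c(cy, cx) + rad_pos * sqrt(u) * c(sin(ang), cos(ang))
        if (nrow(centers)) {
          dd <- sqrt((centers$center_row - p0[1])^2 +
                     (centers$center_col - p0[2])^2)
          if (any(dd < centers$radius + r_les + 3)) next
        }
        disc <- (rr - p0[1])^2 + (cc - p0[2])^2 <= r_les^2
        if (sum(disc & vessel_mask) > 0.2 * sum(disc)) next
        lesion_mask <- lesion_mask | disc
        lesion_dip <- stamp_max(
          lesion_dip, p0[1], p0[2], 1.2 * r_les,
          function(d) {
            s <- ifelse(d <= 0.85 * r_les, 1,
                        ifelse(d >= 1.15 * r_les, 0,
                               0.5 * (1 + cos(pi * (d - 0.85 * r_les) /
                                                (0.3 * r_les)))))
            spec$lesion_contrast * s
          })
        centers <- rbind(centers,
                         data.frame(center_row = p0[1], center_col = p0[2],
                                    radius = r_les))
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("phantom placement failed: could not place lesion ", l,
             " after 100 retries (field too crowded)")
      }
    }

    img <- img * (1 - vessel_dip) * (1 - lesion_dip)
    if (spec$noise_sigma > 0) {
      img <- img + spec$noise_sigma * matrix(stats::rnorm(h * w), h, w) *
        bg$field_mask
    }
    img <- clamp01(img)

    list(image = img,
         truth = list(lesion_mask = lesion_mask & bg$field_mask,
                      vessel_mask = vessel_mask & bg$field_mask,
                      field_mask = bg$field_mask,
                      lesion_centers = centers),
         spec = spec)
  })
}

#' Generate labelled Gaussian blobs
#'
#' `k` isotropic unit-variance Gaussian clusters of `per_cluster` points each,
#' with cluster centers at least `separation` apart (rejection-sampled in a
#' box that grows until placement succeeds). A standard fixture for testing
#' clustering recovery.
#'
#' @param k Number of clusters (>= 1).
#' @param per_cluster Points per cluster (>= 1).
#' @param separation Minimum distance between cluster centers (> 0).
#' @param dim Dimensionality.
#' @param seed Integer seed.
#' @return List with `points` (N x dim matrix, N = k * per_cluster), `labels`
#'   (integers 1..k, each occurring `per_cluster` times), `k`, and `centers`.
#' @export
generate_labelled_points <- function(k, per_cluster, separation = 10,
                                     dim = 2, seed = 1L) {
  stopifnot(k >= 1, per_cluster >= 1, separation > 0, dim >= 1)
  with_seed(seed, {
    side <- separation * (ceiling(k^(1 / dim)) + 1)
    centers <- NULL
    repeat {
      centers <- matrix(stats::runif(dim, 0, side), 1, dim)
      ok <- TRUE
      for (i in seq_len(k - 1)) {
        placed <- FALSE
        for (try in seq_len(1000L)) {
          cand <- stats::runif(dim, 0, side)
          if (min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= separation) {
            centers <- rbind(centers, cand)
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
      side <- side * 1.5
    }
    labels <- rep(seq_len(k), each = per_cluster)
    pts <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(k * per_cluster * dim), ncol = dim)
    dimnames(pts) <- NULL
    rownames(centers) <- NULL
    list(points = pts, labels = as.integer(labels), k = as.integer(k),
         centers = centers)
  })
}
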