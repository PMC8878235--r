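# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. All stochastic entry points route their randomness through
# this so a run is a pure function of (inputs, seed).
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mark a statistic that is undefined for the input (e.g. zero spread) and is
# reported as 0 by convention instead of NaN.
degenerate_zero <- function() structure(0, degenerate = TRUE)

#' Was a statistic reported under the degenerate-input convention?
#'
#' Moment statistics of a constant sample (zero spread) are undefined; the
#' package reports them as `0` carrying a `degenerate` attribute rather than
#' `NaN`, so downstream rules stay total. This predicate inspects that flag.
#'
#' @param x A value returned by one of the moment statistics.
#' @return `TRUE` if `x` was flagged degenerate, else `FALSE`.
#' @export
is_degenerate <- function(x) isTRUE(attr(x, "degenerate"))

# 4-neighbour (cross structuring element) binary erosion / dilation.
erode_mask <- function(mask, r = 1) {
  mask <- mask > 0
  h <- nrow(mask); w <- ncol(mask)
  for (i in seq_len(r)) {
    out <- mask
    out[-1, ] <- out[-1, ] & mask[-h, ]
    out[-h, ] <- out[-h, ] & mask[-1, ]
    out[, -1] <- out[, -1] & mask[, -w]
    out[, -w] <- out[, -w] & mask[, -1]
    mask <- out
  }
  mask
}

dilate_mask <- function(mask, r = 1) {
  mask <- mask > 0
  h <- nrow(mask); w <- ncol(mask)
  for (i in seq_len(r)) {
    out <- mask
    out[-1, ] <- out[-1, ] | mask[-h, ]
    out[-h, ] <- out[-h, ] | mask[-1, ]
    out[, -1] <- out[, -1] | mask[, -w]
    out[, -w] <- out[, -w] | mask[, -1]
    mask <- out
  }
  mask
}

# Morphological opening: removes structures thinner than the element and
# cuts single-pixel bridges without shifting larger shapes.
open_mask <- function(mask, r = 1) {
  if (r <= 0) return(mask > 0)
  dilate_mask(erode_mask(mask, r), r)
}

#' Label connected components of a binary mask
#'
#' Breadth-first labelling of foreground pixels with 8-connectivity by default
#' (diagonal neighbours belong to the same component), matching the adjacency
#' used for candidate lesion regions.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of the same shape; 0 = background, components are
#'   numbered 1..n in raster order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- mask > 0
  h <- nrow(mask)
  w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (!any(mask)) return(lab)
  offs <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8) {
    offs <- rbind(offs, c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  }
  fg <- which(mask)  # column-major linear indices
  nextlab <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    nextlab <- nextlab + 1L
    lab[seed] <- nextlab
    frontier <- seed
    while (length(frontier)) {
      fr <- ((frontier - 1L) %% h) + 1L
      fc <- ((frontier - 1L) %/% h) + 1L
      nr <- rep(fr, nrow(offs)) + rep(offs[, 1L], each = length(frontier))
      nc <- rep(fc, nrow(offs)) + rep(offs[, 2L], each = length(frontier))
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      nb <- unique((nc[ok] - 1L) * h + nr[ok])
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nextlab
      frontier <- nb
    }
  }
  lab
}
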