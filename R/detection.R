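# End-to-end microaneurysm detection: cluster merging, candidate extraction,
# rule-based classification, evaluation against ground truth, and the
# pipeline orchestrator.

#' Detection configuration
#'
#' Thresholds for candidate filtering and the conjunctive classification
#' rule. All cutoffs are exposed so they can be calibrated against a user's
#' own ground truth.
#'
#' @param area_range `c(amin, amax)` candidate area in pixels.
#' @param eccentricity_max Maximum eccentricity (0 = disc, near 1 =
#'   elongated); vessels fragments are elongated and fail this.
#' @param contrast_min Minimum local contrast: mean intensity of the
#'   surrounding annulus minus mean intensity of the region.
#' @param feature_thresholds Named list mapping a candidate-table column to
#'   `list(dir, cutoff)` with `dir` one of `">="`, `"<="`; a candidate is
#'   called a microaneurysm iff every threshold is satisfied (an empty map
#'   therefore calls every candidate a microaneurysm - a vacuous
#'   conjunction).
#' @param open_radius Radius (px) of the morphological opening applied to
#'   the lesion-cluster mask before connected components; cuts the thin
#'   noise bridges that would otherwise fuse a dot lesion with the vessel
#'   network or dark background patches. 0 disables.
#' @param merge_tol,merge_alpha Parameters of the cluster-merge rule
#'   ([should_merge()]). The default `merge_tol` here is much tighter than
#'   [should_merge()]'s generic default because segmentation clusters are
#'   pixel populations of tens of thousands: the sampling error of kurtosis
#'   at that size is about 0.03, so 0.05 already means "equal at sampling
#'   precision", while a loose tolerance would merge distinct tissue classes
#'   whose distribution shapes coincide by chance.
#' @param match_radius Centroid match radius (px) for evaluation.
#' @return A `detection_config` list.
#' @export
detection_config <- function(area_range = c(9, 150),
                             eccentricity_max = 0.85,
                             contrast_min = 0.1,
                             feature_thresholds = list(
                               homogeneity = list(dir = ">=", cutoff = 0.5),
                               eccentricity = list(dir = "<=", cutoff = 0.85),
                               dissimilarity = list(dir = "<=", cutoff = 3.0),
                               local_contrast = list(dir = ">=",
                                                     cutoff = 0.18)),
                             open_radius = 1,
                             merge_tol = 0.05, merge_alpha = 0.05,
                             match_radius = 5) {
  stopifnot(length(area_range) == 2, area_range[1] <= area_range[2],
            eccentricity_max >= 0, eccentricity_max < 1,
            match_radius > 0)
  structure(list(area_range = area_range,
                 eccentricity_max = eccentricity_max,
                 contrast_min = contrast_min,
                 feature_thresholds = feature_thresholds,
                 open_radius = open_radius,
                 merge_tol = merge_tol, merge_alpha = merge_alpha,
                 match_radius = match_radius),
            class = "detection_config")
}

#' Merge statistically indistinguishable segmentation clusters
#'
#' Applies [should_merge()] to the pixel-intensity populations of cluster
#' pairs, most-similar pair (smallest combined kurtosis + skewness
#' difference) first, until no pair qualifies; labels are then compacted.
#' The cluster count never increases and the procedure terminates because
#' each merge strictly decreases it.
#'
#' @param seg A `madpso_segmentation` with matrix labels (from
#'   [segment_image()]).
#' @param img The intensity image the segmentation refers to.
#' @param tol,alpha Merge-rule parameters.
#' @return The segmentation with merged, compacted labels and updated
#'   `cluster_means`; `merge_log` records the decisions taken.
#' @export
merge_segmentation_clusters <- function(seg, img, tol = 0.5, alpha = 0.05) {
  stopifnot(inherits(seg, "madpso_segmentation"), is.matrix(seg$labels),
            identical(dim(seg$labels), dim(img)))
  lab <- seg$labels
  log_ <- list()
  repeat {
    ids <- setdiff(sort(unique(as.integer(lab))), 0L)  # 0 = outside ROI
    if (length(ids) < 2) break
    pops <- lapply(ids, function(i) img[lab == i])
    pairs <- utils::combn(seq_along(ids), 2)
    sim <- apply(pairs, 2, function(pr) {
      # undersized clusters can never merge (should_merge rejects them)
      if (length(pops[[pr[1]]]) < 8 || length(pops[[pr[2]]]) < 8) return(Inf)
      abs(as.numeric(sample_kurtosis(pops[[pr[1]]])) -
            as.numeric(sample_kurtosis(pops[[pr[2]]]))) +
        abs(as.numeric(sample_skewness(pops[[pr[1]]])) -
              as.numeric(sample_skewness(pops[[pr[2]]])))
    })
    merged <- FALSE
    for (ord in order(sim)) {
      if (!is.finite(sim[ord])) next
      a <- ids[pairs[1, ord]]; b <- ids[pairs[2, ord]]
      dec <- should_merge(img[lab == a], img[lab == b], tol, alpha)
      if (dec$merge) {
        lab[lab == b] <- a
        log_[[length(log_) + 1]] <- list(a = a, b = b, reason = dec$reason)
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  remap <- integer(max(ids))
  remap[ids] <- seq_along(ids)
  pos <- lab > 0
  lab[pos] <- remap[lab[pos]]
  seg$labels <- lab
  seg$k <- length(ids)
  seg$cluster_means <- vapply(seq_len(seg$k),
                              function(b) mean(img[lab == b]), 0)
  seg$merge_log <- log_
  seg
}

region_eccentricity <- function(rows, cols) {
  n <- length(rows)
  if (n < 2) return(0)
  m <- cbind(rows, cols)
  cv <- stats::cov(m) * (n - 1) / n
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  l1 <- max(ev)
  l2 <- max(min(ev), 0)
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

#' Extract candidate lesion regions from a merged segmentation
#'
#' The lesion cluster is taken as the cluster with minimum mean intensity
#' (microaneurysms are red, i.e. dark in the green channel). Its 8-connected
#' components are filtered by area, eccentricity, and local contrast (mean
#' of a 3-px surrounding annulus minus region mean), and the survivors are
#' featurized with [region_features()].
#'
#' @param seg Merged `madpso_segmentation`.
#' @param img Intensity image.
#' @param cfg A [detection_config()].
#' @param levels Gray levels for region GLCMs.
#' @return Data frame with one row per candidate: `region_id`,
#'   `centroid_row`, `centroid_col`, `area_px`, `eccentricity`,
#'   `mean_intensity`, `local_contrast`, the six GLCM features
#'   (`homogeneity`, `max_probability`, `energy`, `dissimilarity`,
#'   `contrast`, `glcm_mean`), and `call` (filled by
#'   [classify_candidates()]). The component label image rides along as
#'   attribute `component_labels`. Zero rows (with a warning) if the
#'   segmentation collapsed to one cluster.
#' @export
extract_candidates <- function(seg, img, cfg = detection_config(),
                               levels = 16) {
  stopifnot(inherits(seg, "madpso_segmentation"), is.matrix(seg$labels))
  empty <- data.frame(region_id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = integer(0),
                      eccentricity = numeric(0), mean_intensity = numeric(0),
                      local_contrast = numeric(0), homogeneity = numeric(0),
                      max_probability = numeric(0), energy = numeric(0),
                      dissimilarity = numeric(0), contrast = numeric(0),
                      glcm_mean = numeric(0), call = character(0),
                      stringsAsFactors = FALSE)
  if (seg$k < 2) {
    warning("segmentation has a single cluster; no lesion cluster available")
    return(empty)
  }
  lesion_cluster <- which.min(seg$cluster_means)
  mask <- seg$labels == lesion_cluster
  mask <- open_mask(mask, cfg$open_radius %||% 0)
  comp <- label_components(mask, connectivity = 8)
  ncomp <- max(comp)
  if (ncomp == 0) return(empty)
  h <- nrow(img); w <- ncol(img)
  rows_of <- row(comp); cols_of <- col(comp)
  out <- empty
  rid <- 0L
  for (ci in seq_len(ncomp)) {
    sel <- comp == ci
    area <- sum(sel)
    if (area < cfg$area_range[1] || area > cfg$area_range[2]) next
    rr <- rows_of[sel]; cc <- cols_of[sel]
    ecc <- region_eccentricity(rr, cc)
    if (ecc > cfg$eccentricity_max) next
    # local contrast against a 3-px annulus around the bounding box
    r0 <- max(1, min(rr) - 3); r1 <- min(h, max(rr) + 3)
    c0 <- max(1, min(cc) - 3); c1 <- min(w, max(cc) + 3)
    ring <- matrix(FALSE, h, w)
    ring[r0:r1, c0:c1] <- TRUE
    ring <- ring & !sel
    mi <- mean(img[sel])
    contrast_local <- mean(img[ring]) - mi
    if (contrast_local < cfg$contrast_min) next
    fv <- tryCatch(region_features(img, sel, levels = levels),
                   error = function(e) NULL)
    if (is.null(fv)) next
    rid <- rid + 1L
    out <- rbind(out, data.frame(
      region_id = rid,
      centroid_row = mean(rr), centroid_col = mean(cc),
      area_px = area, eccentricity = ecc,
      mean_intensity = mi, local_contrast = contrast_local,
      homogeneity = fv[["homogeneity"]],
      max_probability = fv[["max_probability"]],
      energy = fv[["energy"]],
      dissimilarity = fv[["dissimilarity"]],
      contrast = fv[["contrast"]],
      glcm_mean = fv[["mean"]],
      call = NA_character_, stringsAsFactors = FALSE))
  }
  attr(out, "component_labels") <- comp
  attr(out, "lesion_cluster") <- lesion_cluster
  out
}

#' Classify candidate regions with the conjunctive threshold rule
#'
#' A candidate is called `"microaneurysm"` iff every threshold in
#' `cfg$feature_thresholds` is satisfied, `"non_microaneurysm"` otherwise.
#' Deterministic; an empty threshold map calls everything a microaneurysm
#' (vacuous conjunction, by design).
#'
#' @param candidates Data frame from [extract_candidates()].
#' @param cfg A [detection_config()].
#' @return The data frame with `call` filled in.
#' @export
classify_candidates <- function(candidates, cfg = detection_config()) {
  if (nrow(candidates) == 0) return(candidates)
  ok <- rep(TRUE, nrow(candidates))
  for (feat in names(cfg$feature_thresholds)) {
    if (!feat %in% names(candidates)) {
      stop("feature '", feat, "' in thresholds map is not a candidate column")
    }
    th <- cfg$feature_thresholds[[feat]]
    v <- candidates[[feat]]
    ok <- ok & switch(th$dir,
                      ">=" = v >= th$cutoff,
                      "<=" = v <= th$cutoff,
                      stop("threshold direction must be '>=' or '<='"))
  }
  candidates$call <- ifelse(ok, "microaneurysm", "non_microaneurysm")
  candidates
}

#' Score detections against ground truth
#'
#' Region level: each called candidate is a true positive if its centroid
#' lies within `match_radius` of a not-yet-matched true lesion center
#' (greedy globally-nearest matching); unmatched calls are false positives
#' and unmatched lesions false negatives (true negatives are not defined at
#' region level and are reported as 0). Image level: the image is positive
#' if it has any lesion, predicted positive if it has any call.
#'
#' @param candidates Classified candidate data frame.
#' @param truth Ground-truth list with `lesion_centers`.
#' @param match_radius Pixels.
#' @return List with `region` (`tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `precision`, `accuracy`) and `image` (`truth_positive`,
#'   `call_positive`).
#' @export
evaluate_detections <- function(candidates, truth, match_radius = 5) {
  calls <- candidates[!is.na(candidates$call) &
                        candidates$call == "microaneurysm", , drop = FALSE]
  centers <- truth$lesion_centers
  n_call <- nrow(calls)
  n_les <- nrow(centers)
  tp <- 0L
  if (n_call > 0 && n_les > 0) {
    d <- outer(seq_len(n_call), seq_len(n_les), function(i, j) {
      sqrt((calls$centroid_row[i] - centers$center_row[j])^2 +
             (calls$centroid_col[i] - centers$center_col[j])^2)
    })
    while (TRUE) {
      m <- which(d == min(d), arr.ind = TRUE)[1, , drop = TRUE]
      if (!is.finite(d[m[1], m[2]]) || d[m[1], m[2]] > match_radius) break
      tp <- tp + 1L
      d[m[1], ] <- Inf
      d[, m[2]] <- Inf
      if (all(!is.finite(d))) break
    }
  }
  fp <- n_call - tp
  fn <- n_les - tp
  tot <- tp + fp + fn
  region <- list(tp = tp, fp = fp, fn = fn, tn = 0L,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 accuracy = if (tot > 0) tp / tot else NA_real_)
  image <- list(truth_positive = n_les > 0, call_positive = n_call > 0)
  list(region = region, image = image)
}

#' Aggregate per-image evaluations
#'
#' Sums region-level counts and builds the image-level confusion matrix
#' (a true negative is an image with no lesions and no calls).
#'
#' @param evals List of results from [evaluate_detections()].
#' @return List with `region` and `image` confusion summaries.
#' @export
aggregate_evaluations <- function(evals) {
  rtp <- sum(vapply(evals, function(e) e$region$tp, 0L))
  rfp <- sum(vapply(evals, function(e) e$region$fp, 0L))
  rfn <- sum(vapply(evals, function(e) e$region$fn, 0L))
  tpos <- vapply(evals, function(e) e$image$truth_positive, TRUE)
  cpos <- vapply(evals, function(e) e$image$call_positive, TRUE)
  itp <- sum(tpos & cpos); ifp <- sum(!tpos & cpos)
  ifn <- sum(tpos & !cpos); itn <- sum(!tpos & !cpos)
  list(region = list(tp = rtp, fp = rfp, fn = rfn,
                     sensitivity = if (rtp + rfn > 0) rtp / (rtp + rfn)
                                   else NA_real_,
                     fp_per_image = rfp / length(evals)),
       image = list(tp = itp, fp = ifp, fn = ifn, tn = itn,
                    accuracy = (itp + itn) / length(evals),
                    sensitivity = if (itp + ifn > 0) itp / (itp + ifn)
                                  else NA_real_,
                    specificity = if (itn + ifp > 0) itn / (itn + ifp)
                                  else NA_real_))
}

#' Split a file list into train and test sets
#'
#' Deterministic shuffled split; `round(frac * n)` items go to training
#' (130 items at 80% give 104 train / 26 test).
#'
#' @param items Character or other vector.
#' @param train_frac Training fraction.
#' @param seed Integer seed.
#' @return List with `train` and `test`.
#' @export
train_test_split <- function(items, train_frac = 0.8, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  n <- length(items)
  n_train <- round(train_frac * n)
  with_seed(seed, {
    ix <- sample.int(n)
    list(train = items[ix[seq_len(n_train)]],
         test = items[ix[seq.int(n_train + 1, n)]])
  })
}

#' Pipeline configuration bundle
#'
#' @param target Resize target `c(height, width)`.
#' @param gray_mode Grayscale conversion for color input.
#' @param enhance An [enhancement_config()].
#' @param swarm A [swarm_config()]. The pipeline default uses `k = 4`
#'   (aperture-adjacent dark periphery, vessels + lesions, mid background,
#'   bright structures): the fourth cluster absorbs the dark tail of the
#'   background so the darkest cluster stays specific to lesions and
#'   vessels, and the statistical merge step folds redundant background
#'   clusters back together.
#' @param spatial_weight Passed to [segment_image()].
#' @param detect A [detection_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(target = c(250, 250),
                            gray_mode = "green_channel",
                            enhance = enhancement_config(),
                            swarm = swarm_config(k = 4),
                            spatial_weight = 0.2,
                            detect = detection_config()) {
  structure(list(target = target, gray_mode = gray_mode, enhance = enhance,
                 swarm = swarm, spatial_weight = spatial_weight,
                 detect = detect),
            class = "pipeline_config")
}

#' Run the full microaneurysm-detection pipeline
#'
#' resize -> grayscale (for color input) -> fuzzy CLAHE -> PBPSO
#' segmentation -> statistical cluster merging -> candidate extraction ->
#' GLCM featurization -> conjunctive classification. Deterministic for a
#' fixed `cfg$swarm$seed`.
#'
#' @param img File path (PNG/TIFF), grayscale matrix, or H x W x 3 array.
#' @param cfg A [pipeline_config()].
#' @param seed Optional override of the swarm seed.
#' @return List with `candidates` (classified data frame), `segmentation`
#'   (merged), `enhanced`, `gray` images, `stats` (enhanced-image
#'   statistics), and per-stage `timings` (seconds).
#' @export
run_pipeline <- function(img, cfg = pipeline_config(), seed = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(seed)) cfg$swarm$seed <- as.integer(seed)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  if (is.character(img)) img <- read_image(img)
  gray <- if (length(dim(img)) == 3) to_grayscale(img, cfg$gray_mode) else img
  gray <- resize_image(gray, cfg$target)
  timings["preprocess"] <- tic() - t0

  t0 <- tic()
  field <- estimate_field_mask(gray)
  enhanced <- fuzzy_clahe(gray, cfg$enhance)
  stats_ <- compute_image_stats(enhanced)
  timings["enhance"] <- tic() - t0

  t0 <- tic()
  seg <- segment_image(enhanced, cfg$swarm, cfg$spatial_weight, mask = field)
  timings["segment"] <- tic() - t0

  t0 <- tic()
  seg <- merge_segmentation_clusters(seg, enhanced,
                                     tol = cfg$detect$merge_tol,
                                     alpha = cfg$detect$merge_alpha)
  cand <- extract_candidates(seg, enhanced, cfg$detect)
  cand <- classify_candidates(cand, cfg$detect)
  timings["detect"] <- tic() - t0

  list(candidates = cand, segmentation = seg, enhanced = enhanced,
       gray = gray, field_mask = field, stats = stats_, timings = timings)
}
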