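make_seg <- function(labels, img) {
  structure(list(labels = labels, k = max(labels),
                 cluster_means = vapply(seq_len(max(labels)),
                                        function(b) mean(img[labels == b]), 0)),
            class = "madpso_segmentation")
}

test_that("connected-component labeller honours connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[4, 4] <- TRUE; m[5, 5] <- TRUE
  expect_equal(max(label_components(m, 8)), 2)  # diagonals connect
  expect_equal(max(label_components(m, 4)), 4)  # ... but not at 4-conn
  expect_equal(max(label_components(matrix(FALSE, 3, 3))), 0)
})

test_that("one normal population split in two merges back to one cluster", {
  set.seed(1)
  v <- rnorm(800, 0.5, 0.08)
  img <- matrix(v, 20, 40)
  labels <- matrix(rep(c(1L, 2L), each = 400), 20, 40)  # arbitrary halves
  seg <- make_seg(labels, img)
  out <- merge_segmentation_clusters(seg, img)
  expect_equal(out$k, 1)
})

test_that("a skewed lesion-like cluster resists merging", {
  set.seed(2)
  bg <- rnorm(600, 0.6, 0.05)
  les <- 0.25 + rlnorm(200, -2.5, 0.8)   # heavy right tail
  img <- matrix(c(les, bg), 20, 40)
  labels <- matrix(c(rep(1L, 200), rep(2L, 600)), 20, 40)
  seg <- make_seg(labels, img)
  out <- merge_segmentation_clusters(seg, img)
  expect_equal(out$k, 2)
})

test_that("merging never increases the cluster count", {
  set.seed(3)
  for (i in 1:5) {
    img <- matrix(runif(400), 20, 20)
    labels <- matrix(sample(1:4, 400, replace = TRUE), 20, 20)
    out <- merge_segmentation_clusters(make_seg(labels, img), img)
    expect_lte(out$k, 4)
    expect_true(all(sort(unique(as.integer(out$labels))) ==
                      seq_len(out$k)))
  }
})

test_that("candidates recover phantom lesions with permissive thresholds", {
  ph <- generate_phantom(phantom_spec(seed = 103))
  permissive <- detection_config(area_range = c(4, 300), contrast_min = 0,
                                 feature_thresholds = list())
  res <- run_pipeline(ph$image, pipeline_config(detect = permissive),
                      seed = 1003)
  cand <- res$candidates
  expect_gte(nrow(cand), 5)
  ctr <- ph$truth$lesion_centers
  hit <- vapply(seq_len(nrow(ctr)), function(i) {
    any(sqrt((cand$centroid_row - ctr$center_row[i])^2 +
               (cand$centroid_col - ctr$center_col[i])^2) <= 3)
  }, TRUE)
  expect_true(all(hit))
})

test_that("a blank phantom yields no candidates", {
  ph <- generate_phantom(phantom_spec(n_lesions = 0, vessel_count = 0,
                                      seed = 5))
  res <- run_pipeline(ph$image, seed = 11)
  expect_equal(nrow(res$candidates), 0)
})

test_that("area filter excludes an elongated vessel-like fragment", {
  img <- matrix(0.7, 60, 60)
  img[30, 10:50] <- 0.2            # a 41-px dark line
  img[10:12, 10:12] <- 0.2         # a 9-px compact dot
  labels <- matrix(2L, 60, 60)
  labels[img == 0.2] <- 1L
  seg <- make_seg(labels, img)
  cfg <- detection_config(area_range = c(5, 30), open_radius = 0,
                          contrast_min = 0)
  cand <- extract_candidates(seg, img, cfg)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$area_px, 9)
  # with a permissive area range the line is still stopped by eccentricity
  cfg2 <- detection_config(area_range = c(5, 300), open_radius = 0,
                           contrast_min = 0)
  cand2 <- extract_candidates(seg, img, cfg2)
  expect_equal(nrow(cand2), 1)
})

test_that("single-cluster segmentation warns and returns nothing", {
  img <- matrix(0.5, 20, 20)
  seg <- make_seg(matrix(1L, 20, 20), img)
  expect_warning(cand <- extract_candidates(seg, img), "single cluster")
  expect_equal(nrow(cand), 0)
})

test_that("classification is a conjunctive threshold rule", {
  df <- data.frame(region_id = 1:3,
                   homogeneity = c(0.9, 0.4, 0.9),
                   eccentricity = c(0.2, 0.2, 0.95),
                   dissimilarity = c(0.5, 0.5, 0.5),
                   local_contrast = c(0.3, 0.3, 0.3),
                   call = NA_character_)
  cfg <- detection_config()
  out <- classify_candidates(df, cfg)
  expect_equal(out$call,
               c("microaneurysm", "non_microaneurysm", "non_microaneurysm"))

  # vacuous conjunction: empty map calls everything a microaneurysm
  cfg0 <- detection_config(feature_thresholds = list())
  expect_true(all(classify_candidates(df, cfg0)$call == "microaneurysm"))

  cfg_bad <- detection_config(feature_thresholds = list(
    nonexistent = list(dir = ">=", cutoff = 1)))
  expect_error(classify_candidates(df, cfg_bad), "not a candidate column")
})

test_that("evaluation identities hold on hand-checkable instances", {
  truth <- list(lesion_centers = data.frame(
    center_row = c(10, 30, 50, 70, 90), center_col = rep(50, 5)))
  perfect <- data.frame(centroid_row = c(10, 30, 50, 70, 90) + 0.5,
                        centroid_col = rep(50, 5),
                        call = "microaneurysm")
  ev <- evaluate_detections(perfect, truth)
  expect_equal(ev$region$sensitivity, 1)
  expect_equal(ev$region$fp, 0)

  none <- data.frame(centroid_row = numeric(0), centroid_col = numeric(0),
                     call = character(0))
  ev0 <- evaluate_detections(none, truth)
  expect_equal(ev0$region$fn, 5)
  expect_equal(ev0$region$sensitivity, 0)

  # 4 of 5 matched plus 2 spurious
  some <- data.frame(centroid_row = c(10, 30, 50, 70, 200, 150),
                     centroid_col = c(50, 50, 50, 50, 10, 200),
                     call = "microaneurysm")
  ev2 <- evaluate_detections(some, truth)
  expect_equal(ev2$region$tp, 4)
  expect_equal(ev2$region$fp, 2)
  expect_equal(ev2$region$fn, 1)

  # greedy matching consumes each lesion at most once
  double <- data.frame(centroid_row = c(10, 11), centroid_col = c(50, 50),
                       call = "microaneurysm")
  ev3 <- evaluate_detections(double, truth)
  expect_equal(ev3$region$tp, 1)
  expect_equal(ev3$region$fp, 1)
})

test_that("image-level aggregation counts lesion-free images as negatives", {
  evs <- list(
    list(region = list(tp = 5L, fp = 0L, fn = 0L),
         image = list(truth_positive = TRUE, call_positive = TRUE)),
    list(region = list(tp = 0L, fp = 0L, fn = 0L),
         image = list(truth_positive = FALSE, call_positive = FALSE)),
    list(region = list(tp = 0L, fp = 1L, fn = 0L),
         image = list(truth_positive = FALSE, call_positive = TRUE)))
  agg <- aggregate_evaluations(evs)
  expect_equal(agg$image$tn, 1)
  expect_equal(agg$image$fp, 1)
  expect_equal(agg$image$accuracy, 2 / 3)
  expect_equal(agg$region$tp, 5)
})

test_that("train/test split is exact, disjoint, and seeded", {
  items <- sprintf("image%03d", 1:130)
  sp <- train_test_split(items, 0.8, seed = 4)
  expect_equal(length(sp$train), 104)
  expect_equal(length(sp$test), 26)
  expect_equal(sort(c(sp$train, sp$test)), sort(items))
  sp2 <- train_test_split(items, 0.8, seed = 4)
  expect_identical(sp, sp2)
  expect_false(identical(sp, train_test_split(items, 0.8, seed = 5)))
})

test_that("phantom round-trips through PNG I/O", {
  ph <- generate_phantom(phantom_spec(width = 96, height = 96, seed = 2))
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  img <- read_image(file.path(dir, "image.png"))
  expect_equal(dim(img), dim(ph$image))
  expect_lt(max(abs(img - ph$image)), 1 / 255)  # 8-bit quantization only
  mask <- read_image(file.path(dir, "lesion_mask.png"))
  expect_identical(mask > 0.5, ph$truth$lesion_mask)
  csv <- read.csv(file.path(dir, "lesions.csv"))
  expect_equal(nrow(csv), nrow(ph$truth$lesion_centers))
})
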