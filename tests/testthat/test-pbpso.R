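test_that("swarm initialization covers the trivial k cases and is seeded", {
  set.seed(1)
  X <- matrix(rnorm(20), 10, 2)

  sw1 <- initialize_swarm(X, swarm_config(k = 1, seed = 3))
  for (p in sw1) {
    expect_equal(p$k, 1)
    expect_equal(sort(p$blocks[[1]]), 1:10)
  }

  swN <- initialize_swarm(X, swarm_config(k = 10, seed = 3))
  for (p in swN) expect_true(all(lengths(p$blocks) == 1))

  a <- initialize_swarm(X, swarm_config(k = 3, seed = 5))
  b <- initialize_swarm(X, swarm_config(k = 3, seed = 5))
  expect_identical(a, b)
  for (p in a) expect_true(is_valid_particle(p, 10))
  expect_error(initialize_swarm(X[1:2, ], swarm_config(k = 3)))
})

test_that("particle sequence encoding carries k - 1 separators", {
  set.seed(2)
  X <- matrix(rnorm(16), 8, 2)
  p <- initialize_swarm(X, swarm_config(k = 3, seed = 1))[[1]]
  s <- particle_sequence(p)
  expect_equal(length(s), 8 + 2)
  expect_equal(sum(is.na(s)), 2)
  expect_equal(sort(s[!is.na(s)]), 1:8)
})

test_that("velocity pool deduplicates and stays within bounds", {
  set.seed(3)
  X <- matrix(rnorm(12), 6, 2)
  p <- initialize_swarm(X, swarm_config(k = 2, seed = 2))[[1]]
  # p == pbest == gbest: pool collapses to the particle's own k clusters
  v <- compute_velocity(p, p)
  expect_equal(length(v$pool), 2)

  # fully disjoint k=2 partitions from three sources: pool size in [2, 6]
  p1 <- madpso:::new_particle(X, list(1:3, 4:6), c(1, 0, 0, 0, 1))
  p2 <- madpso:::new_particle(X, list(c(1L, 4L), c(2L, 3L, 5L, 6L)),
                              c(1, 0, 0, 0, 1))
  p1$pbest_blocks <- list(c(1L, 2L, 6L), c(3L, 4L, 5L))
  v2 <- compute_velocity(p1, p2)
  expect_gte(length(v2$pool), 2)
  expect_lte(length(v2$pool), 6)
  for (cl in v2$pool) {
    expect_gt(length(cl), 0)
    expect_true(all(cl %in% 1:6))
  }
})

test_that("construction from a particle's own blocks is closed", {
  set.seed(4)
  X <- matrix(rnorm(20), 10, 2)
  p <- initialize_swarm(X, swarm_config(k = 3, seed = 9))[[1]]
  v <- list(pool = p$blocks, source = rep("current", 3))
  set.seed(1)
  q <- construct_particle(v, X, 3)
  # identical as a set of sets
  key <- function(blocks) sort(vapply(blocks, function(b)
    paste(sort(b), collapse = ","), ""))
  expect_equal(key(q$blocks), key(p$blocks))
  expect_error(construct_particle(list(pool = list(), source = character(0)),
                                  X, 2), "empty")
})

test_that("overlapping pool resolves to an enumerable outcome", {
  X <- matrix(c(0, 0, 10, 10, 0, 1, 0, 1), 4, 2)
  v <- list(pool = list(c(1L, 2L, 3L), c(3L, 4L)), source = c("a", "b"))
  # draw order (A, B): A keeps {1,2,3}, B keeps {4};
  # draw order (B, A): B keeps {3,4}, A keeps {1,2}
  key <- function(blocks) paste(sort(vapply(blocks, function(b)
    paste(sort(b), collapse = ","), "")), collapse = " | ")
  reachable <- c("1,2,3 | 4", "1,2 | 3,4")
  for (s in 1:25) {
    set.seed(s)
    q <- construct_particle(v, X, 2)
    expect_true(is_valid_particle(q, 4))
    expect_true(key(q$blocks) %in% reachable)
  }
})

test_that("construction always yields a permutation with k blocks", {
  set.seed(5)
  for (rep in 1:200) {
    n <- sample(6:20, 1)
    k <- sample(2:4, 1)
    X <- matrix(rnorm(2 * n), n, 2)
    # random pool: random subsets that jointly cover 1..n
    pool <- lapply(1:sample(3:7, 1), function(i)
      sort(sample(n, sample(1:n, 1))))
    pool <- c(pool, list(setdiff(1:n, unlist(pool))))
    pool <- Filter(length, pool)
    if (length(pool) < k) pool <- c(pool, lapply(1:k, function(i) sort(sample(n, 2))))
    q <- construct_particle(list(pool = pool, source = rep("x", length(pool))),
                            X, k)
    expect_true(is_valid_particle(q, n))
    expect_equal(length(q$blocks), k)
  }
})

test_that("centroid update fixes a single misassigned point, never worsens", {
  bl <- generate_labelled_points(2, 5, separation = 12, seed = 6)
  truth <- lapply(1:2, function(b) which(bl$labels == b))
  wrong <- list(c(truth[[1]], truth[[2]][1]), truth[[2]][-1])
  p <- madpso:::new_particle(bl$points, wrong, c(1, 0, 0, 0, 1))
  q <- update_centroids(p, bl$points)
  expect_equal(lapply(q$blocks, sort), lapply(truth, sort))
  expect_lte(q$fitness, p$fitness)

  # already-optimal partition is a fixed point
  opt <- madpso:::new_particle(bl$points, truth, c(1, 0, 0, 0, 1))
  expect_equal(update_centroids(opt, bl$points)$blocks,
               lapply(truth, function(b) sort(b)))

  set.seed(7)
  for (i in 1:20) {
    X <- matrix(rnorm(24), 12, 2)
    p0 <- initialize_swarm(X, swarm_config(k = 3, seed = i))[[1]]
    expect_lte(update_centroids(p0, X)$fitness, p0$fitness)
  }
})

test_that("pbpso recovers separated blobs and never backtracks", {
  perfect <- 0
  for (s in 1:5) {
    bl <- generate_labelled_points(3, 30, separation = 10, seed = 100 + s)
    seg <- run_pbpso(bl$points, swarm_config(k = 3, seed = s))
    expect_true(all(diff(seg$history) <= 1e-12))
    if (ari(seg$labels, bl$labels) == 1) perfect <- perfect + 1
  }
  expect_gte(perfect, 4)
})

test_that("pbpso is deterministic and matches enumeration on a tiny case", {
  set.seed(8)
  X <- matrix(rnorm(14), 7, 2)
  a <- run_pbpso(X, swarm_config(k = 2, seed = 13))
  b <- run_pbpso(X, swarm_config(k = 2, seed = 13))
  expect_identical(a$labels, b$labels)
  expect_identical(a$history, b$history)

  ex <- exhaustive_best_partition(X)
  expect_lt(abs(a$gbest_fitness - ex$fitness), 1e-9)
})

test_that("exhaustive oracle finds the obvious split", {
  X <- rbind(matrix(rnorm(6, 0, 0.1), 3, 2),
             matrix(rnorm(6, 20, 0.1), 3, 2))
  ex <- exhaustive_best_partition(X)
  expect_equal(lapply(ex$blocks, sort), list(1:3, 4:6))
})

test_that("baseline PSO clusters blobs and handles k = 1", {
  good <- 0
  for (s in 1:5) {
    bl <- generate_labelled_points(3, 30, separation = 10, seed = 200 + s)
    seg <- run_baseline_pso(bl$points, swarm_config(k = 3, seed = s))
    if (ari(seg$labels, bl$labels) >= 0.9) good <- good + 1
  }
  expect_gte(good, 4)

  bl <- generate_labelled_points(1, 20, seed = 9)
  seg1 <- run_baseline_pso(bl$points, swarm_config(k = 1, seed = 1))
  expect_true(all(seg1$labels == 1))
  expect_equal(as.numeric(seg1$centroids), colMeans(bl$points),
               tolerance = 1e-12)
  a <- run_baseline_pso(bl$points, swarm_config(k = 1, seed = 2))
  b <- run_baseline_pso(bl$points, swarm_config(k = 1, seed = 2))
  expect_identical(a$labels, b$labels)
})

test_that("two-tone image separates exactly with pure intensity features", {
  img <- cbind(matrix(0.2, 20, 10), matrix(0.8, 20, 10))
  seg <- segment_image(img, swarm_config(k = 2, seed = 3),
                       spatial_weight = 0)
  expect_equal(length(unique(seg$labels[img == 0.2])), 1)
  expect_equal(length(unique(seg$labels[img == 0.8])), 1)
  expect_false(seg$labels[1, 1] == seg$labels[1, 20])

  a <- segment_image(img, swarm_config(k = 2, seed = 5), spatial_weight = 0)
  b <- segment_image(img, swarm_config(k = 2, seed = 5), spatial_weight = 0)
  expect_identical(a$labels, b$labels)
})

test_that("lesion pixels concentrate in the darkest cluster of a phantom", {
  ph <- generate_phantom(phantom_spec(width = 160, height = 160,
                                      n_lesions = 4, vessel_count = 4,
                                      seed = 15))
  field <- estimate_field_mask(ph$image)
  enh <- fuzzy_clahe(ph$image)
  seg <- segment_image(enh, swarm_config(k = 4, seed = 2),
                       spatial_weight = 0.2, mask = field)
  dark <- which.min(seg$cluster_means)
  expect_gte(mean(seg$labels[ph$truth$lesion_mask] == dark), 0.8)
})
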