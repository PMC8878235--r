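# Probability-based discrete PSO (PBPSO) clustering.
#
# A particle encodes a partition of the N data points into k non-empty
# cluster blocks: a permutation of the point indices with k - 1 separator
# markers between contiguous blocks. Movement is discrete: each step a
# particle harvests a pool of candidate clusters from itself, its personal
# best and the swarm's global best (the "velocity"), draws k of them with
# probability proportional to exp(-cluster fitness), rebuilds a valid
# partition from the draw (eliminating duplicate points, appending missing
# ones), then hill-climbs with one centroid-update pass.

#' Swarm configuration for PBPSO and the baseline PSO
#'
#' @param n_particles Swarm size (>= 2).
#' @param k Number of clusters (>= 1). Default 3 for fundus images:
#'   background, dark structures (vessels and lesions), bright structures.
#' @param max_iter Iteration cap (>= 1).
#' @param seed Integer seed; one RNG stream per run, so a run is a pure
#'   function of (data, config).
#' @param fitness_weights Length-5 weights for [aggregate_fitness()].
#' @param stagnation_patience Stop after this many iterations without
#'   global-best improvement.
#' @param use_pbest Include the personal best's clusters in the velocity
#'   pool (standard PSO practice; switchable for ablation).
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(n_particles = 20L, k = 3L, max_iter = 50L,
                         seed = 1L, fitness_weights = c(1, 0, 0, 0, 1),
                         stagnation_patience = 10L, use_pbest = TRUE) {
  stopifnot(n_particles >= 2, k >= 1, max_iter >= 1,
            stagnation_patience >= 1, length(fitness_weights) == 5,
            all(fitness_weights >= 0), any(fitness_weights > 0))
  structure(list(n_particles = as.integer(n_particles), k = as.integer(k),
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 fitness_weights = as.numeric(fitness_weights),
                 stagnation_patience = as.integer(stagnation_patience),
                 use_pbest = isTRUE(use_pbest)),
            class = "swarm_config")
}

# ---- partition bookkeeping ----------------------------------------------

blocks_from_labels <- function(labels, k) {
  b <- split(seq_along(labels), factor(labels, levels = seq_len(k)))
  lapply(unname(b), as.integer)
}

labels_from_blocks <- function(blocks, n = sum(lengths(blocks))) {
  lab <- integer(n)
  for (b in seq_along(blocks)) lab[blocks[[b]]] <- b
  lab
}

#' Validate the particle encoding invariants
#'
#' Checks that the blocks of a particle form a partition: every point index
#' `1..N` appears exactly once and all `k` blocks are non-empty.
#'
#' @param p A particle (or a bare list of blocks).
#' @param n Number of data points.
#' @return `TRUE`/`FALSE`.
#' @export
is_valid_particle <- function(p, n) {
  blocks <- if (is.list(p) && !is.null(p$blocks)) p$blocks else p
  if (any(lengths(blocks) == 0)) return(FALSE)
  all_ix <- sort(unlist(blocks, use.names = FALSE))
  identical(all_ix, seq_len(n))
}

#' Separator-sequence encoding of a particle
#'
#' The flat discrete encoding: point indices in block order with `NA`
#' separators between consecutive blocks.
#'
#' @param p A particle.
#' @return Integer vector of length `N + k - 1` with `NA` separators.
#' @export
particle_sequence <- function(p) {
  blocks <- p$blocks
  out <- blocks[[1]]
  for (b in blocks[-1]) out <- c(out, NA_integer_, b)
  out
}

cluster_centroids <- function(data, blocks) {
  mu <- vapply(blocks,
               function(ix) colMeans(data[ix, , drop = FALSE]),
               numeric(ncol(data)))
  # vapply drops to a vector for 1-D data; always return k x D
  if (is.null(dim(mu))) matrix(mu, ncol = 1) else t(mu)
}

sqdist_to_centroids <- function(data, mu) {
  k <- nrow(mu)
  d2 <- matrix(0, nrow(data), k)
  for (c_ in seq_len(k)) {
    acc <- 0
    for (j in seq_len(ncol(data))) acc <- acc + (data[, j] - mu[c_, j])^2
    d2[, c_] <- acc
  }
  d2
}

dist_to_centroids <- function(data, mu) sqrt(sqdist_to_centroids(data, mu))

# ---- fitness of a partition ---------------------------------------------

#' Fitness vector of a partition
#'
#' The five measures evaluated on a clustering of `data`: fuzzy entropy of
#' the normalized inverse-distance soft memberships (total mass 1 over all
#' point x cluster entries), pooled within-cluster variance
#' (sum of squared residuals to the block centroid over `N - 1`), and the
#' skewness/kurtosis of the pooled centered residuals. The correlation slot
#' is a co-occurrence statistic with no analogue for point clouds and is
#' reported as degenerate 0 here (it enters via image statistics instead).
#'
#' @param data N x D numeric matrix.
#' @param blocks List of k index blocks partitioning `1..N`.
#' @return Named vector from [fitness_vector()].
#' @export
partition_fitness_vector <- function(data, blocks) {
  n <- nrow(data)
  if (n < 2) {
    return(fitness_vector(0, 0, 0, 0, 0))
  }
  mu <- cluster_centroids(data, blocks)
  d2 <- sqdist_to_centroids(data, mu)
  u <- 1 / (sqrt(d2) + 1e-9)
  u <- u / rowSums(u)
  y <- u / n
  ent <- -sum(y * log(pmax(y, 1e-300)))
  lab <- labels_from_blocks(blocks, n)
  variance <- sum(d2[cbind(seq_len(n), lab)]) / (n - 1)
  resid <- data - mu[lab, , drop = FALSE]
  rv <- as.numeric(resid)
  fitness_vector(ent,
                 as.numeric(sample_kurtosis(rv)),
                 as.numeric(sample_skewness(rv)),
                 0,
                 variance)
}

#' Scalar fitness of a partition (lower is better)
#'
#' With the default weights only entropy and within-cluster variance enter
#' the scalar, and only those are computed (the optimizer's hot path);
#' non-zero weights on the other measures fall back to the full vector.
#'
#' @inheritParams partition_fitness_vector
#' @param weights Passed to [aggregate_fitness()].
#' @export
partition_fitness <- function(data, blocks, weights = c(1, 0, 0, 0, 1)) {
  if (any(weights[2:4] != 0)) {
    return(aggregate_fitness(partition_fitness_vector(data, blocks), weights))
  }
  n <- nrow(data)
  if (n < 2) return(0)
  mu <- cluster_centroids(data, blocks)
  d2 <- sqdist_to_centroids(data, mu)
  acc <- 0
  if (weights[1] > 0) {
    u <- 1 / (sqrt(d2) + 1e-9)
    u <- u / rowSums(u)
    y <- u / n
    acc <- acc + weights[1] * -sum(y * log(pmax(y, 1e-300)))
  }
  if (weights[5] > 0) {
    lab <- labels_from_blocks(blocks, n)
    acc <- acc + weights[5] * sum(d2[cbind(seq_len(n), lab)]) / (n - 1)
  }
  acc
}

# Fitness of a single candidate cluster, used for selection probabilities:
# the cluster is scored as a one-block partition of its own members.
# Fast closed form on the default weight pattern: the entropy of a single
# block's memberships is log(m) and its variance is the within sum of
# squares over (m - 1).
cluster_fitness <- function(data, ix, weights) {
  if (any(weights[2:4] != 0)) {
    return(partition_fitness(data[ix, , drop = FALSE],
                             list(seq_along(ix)), weights))
  }
  m <- length(ix)
  if (m < 2) return(0)
  acc <- 0
  if (weights[1] > 0) acc <- acc + weights[1] * log(m)
  if (weights[5] > 0) {
    ss <- 0
    for (j in seq_len(ncol(data))) {
      v <- data[ix, j]
      ss <- ss + sum((v - mean(v))^2)
    }
    acc <- acc + weights[5] * ss / (m - 1)
  }
  acc
}

new_particle <- function(data, blocks, weights) {
  f <- partition_fitness(data, blocks, weights)
  list(blocks = lapply(blocks, sort), k = length(blocks), fitness = f,
       pbest_blocks = lapply(blocks, sort), pbest_fitness = f)
}

# ---- swarm operations ----------------------------------------------------

init_particle <- function(data, k, weights) {
  n <- nrow(data)
  seeds <- sample.int(n, k)
  d <- dist_to_centroids(data, data[seeds, , drop = FALSE])
  lab <- max.col(-d, ties.method = "first")
  lab[seeds] <- seq_len(k)  # each seed anchors its own block
  new_particle(data, blocks_from_labels(lab, k), weights)
}

#' Initialize a PBPSO swarm
#'
#' Each particle draws `k` distinct seed points, assigns every remaining
#' point to its nearest seed (Euclidean distance in feature space), and
#' encodes the result as a separator sequence; the personal best starts as
#' the particle itself.
#'
#' @param data N x D numeric matrix (N >= k).
#' @param cfg A [swarm_config()].
#' @return List of particles.
#' @export
initialize_swarm <- function(data, cfg) {
  data <- as.matrix(data)
  if (nrow(data) < cfg$k) stop("need at least k data points")
  with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_particles),
           function(i) init_particle(data, cfg$k, cfg$fitness_weights))
  })
}

dedup_blocks <- function(pool, tags) {
  keep <- rep(TRUE, length(pool))
  for (i in seq_along(pool)) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (keep[j] && length(pool[[i]]) == length(pool[[j]]) &&
          identical(pool[[i]], pool[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  list(pool = pool[keep], source = tags[keep])
}

#' Velocity of a particle: the candidate-cluster pool
#'
#' Harvests every cluster of the current particle, its personal best, and
#' the global best, deduplicated by set equality; each surviving cluster is
#' tagged with its provenance.
#'
#' @param p Particle.
#' @param gbest Global-best particle over the same data.
#' @param use_pbest Include the personal best's clusters.
#' @return List with `pool` (list of index sets) and `source` tags.
#' @export
compute_velocity <- function(p, gbest, use_pbest = TRUE) {
  pool <- c(p$blocks,
            if (use_pbest) p$pbest_blocks,
            gbest$blocks)
  tags <- c(rep("current", length(p$blocks)),
            if (use_pbest) rep("pbest", length(p$pbest_blocks)),
            rep("gbest", length(gbest$blocks)))
  dedup_blocks(pool, tags)
}

#' Construct a new particle from a velocity pool
#'
#' Each pool cluster gets selection weight proportional to
#' `exp(-cluster fitness)` (better clusters more likely, all weights
#' positive); `k` clusters are drawn without replacement by sequential
#' inverse-CDF sampling over the normalized weights. The chosen clusters are
#' concatenated into a pseudo sequence in draw order; second and later
#' occurrences of a point are eliminated; points missing from the draw are
#' appended to the chosen cluster with the nearest centroid; a block emptied
#' by elimination is repaired by moving in the farthest member of the
#' largest block. The result always satisfies the particle invariants.
#'
#' @param v Velocity from [compute_velocity()].
#' @param data N x D matrix.
#' @param k Number of clusters.
#' @param weights Fitness weights.
#' @return A new particle (pbest fields initialized to itself; the caller
#'   carries over swarm memory).
#' @export
construct_particle <- function(v, data, k, weights = c(1, 0, 0, 0, 1)) {
  pool <- v$pool
  if (length(pool) == 0) stop("empty cluster pool")
  n <- nrow(data)
  f <- vapply(pool, function(ix) cluster_fitness(data, ix, weights), 0)
  w <- exp(-(f - min(f)))
  chosen_idx <- sample.int(length(pool), k, prob = w)
  chosen <- pool[chosen_idx]

  seqv <- unlist(chosen, use.names = FALSE)
  bid <- rep.int(seq_len(k), lengths(chosen))
  first <- !duplicated(seqv)
  lab <- integer(n)
  lab[seqv[first]] <- bid[first]

  missing <- which(lab == 0L)
  if (length(missing)) {
    mu <- matrix(0, k, ncol(data))
    for (b in seq_len(k)) {
      members <- which(lab == b)
      src <- if (length(members)) members else chosen[[b]]
      mu[b, ] <- colMeans(data[src, , drop = FALSE])
    }
    dmiss <- dist_to_centroids(data[missing, , drop = FALSE], mu)
    lab[missing] <- max.col(-dmiss, ties.method = "first")
  }

  counts <- tabulate(lab, k)
  while (any(counts == 0L)) {
    empty <- which(counts == 0L)[1]
    donor <- which.max(counts)
    members <- which(lab == donor)
    mu_d <- colMeans(data[members, , drop = FALSE])
    far <- members[which.max(rowSums(sweep(data[members, , drop = FALSE],
                                           2, mu_d, "-")^2))]
    lab[far] <- empty
    counts <- tabulate(lab, k)
  }
  new_particle(data, blocks_from_labels(lab, k), weights)
}

#' One centroid-update (hill-climb) pass
#'
#' Computes the block centroids, reassigns every point to its nearest
#' centroid, and re-encodes; an emptied block is re-seeded with the point
#' farthest from its assigned centroid. If the refined partition has worse
#' aggregate fitness than the input, the input particle is returned
#' unchanged, so this step never worsens fitness.
#'
#' @param p Particle.
#' @param data N x D matrix.
#' @param weights Fitness weights.
#' @return Particle (pbest memory preserved from `p`).
#' @export
update_centroids <- function(p, data, weights = c(1, 0, 0, 0, 1)) {
  n <- nrow(data)
  k <- p$k
  mu <- cluster_centroids(data, p$blocks)
  d <- dist_to_centroids(data, mu)
  lab <- max.col(-d, ties.method = "first")
  counts <- tabulate(lab, k)
  if (any(counts == 0L)) {
    di <- d[cbind(seq_len(n), lab)]
    for (empty in which(counts == 0L)) {
      ord <- order(di, decreasing = TRUE)
      for (i in ord) {
        if (counts[lab[i]] > 1L) {
          counts[lab[i]] <- counts[lab[i]] - 1L
          lab[i] <- empty
          counts[empty] <- 1L
          di[i] <- -Inf
          break
        }
      }
    }
  }
  blocks <- blocks_from_labels(lab, k)
  f_new <- partition_fitness(data, blocks, weights)
  if (f_new <= p$fitness) {
    p$blocks <- lapply(blocks, sort)
    p$fitness <- f_new
  }
  p
}

segmentation_from_blocks <- function(data, blocks, fitness, history, iters) {
  structure(list(labels = labels_from_blocks(blocks, nrow(data)),
                 centroids = cluster_centroids(data, blocks),
                 k = length(blocks),
                 gbest_fitness = fitness,
                 history = history,
                 iterations = iters),
            class = "madpso_segmentation")
}

#' Run PBPSO clustering
#'
#' Full loop: initialize the swarm, then iterate velocity harvesting,
#' probabilistic particle construction, centroid update, and
#' personal-best/global-best bookkeeping until `max_iter` iterations or
#' `stagnation_patience` iterations without global-best improvement. The
#' global-best fitness history is monotone non-increasing.
#'
#' @param data N x D numeric matrix (rows = observations).
#' @param cfg A [swarm_config()].
#' @return A `madpso_segmentation`: `labels` (1..k), `centroids` (cluster
#'   means), `k`, `gbest_fitness`, per-iteration `history`, `iterations`.
#' @export
run_pbpso <- function(data, cfg = swarm_config()) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < cfg$k) stop("need at least k data points")
  w <- cfg$fitness_weights
  with_seed(cfg$seed, {
    particles <- lapply(seq_len(cfg$n_particles),
                        function(i) init_particle(data, cfg$k, w))
    fit0 <- vapply(particles, `[[`, 0, "fitness")
    gb_i <- which.min(fit0)
    gbest <- particles[[gb_i]]
    history <- numeric(0)
    stall <- 0L
    iters <- 0L
    for (it in seq_len(cfg$max_iter)) {
      iters <- it
      improved <- FALSE
      for (i in seq_along(particles)) {
        p <- particles[[i]]
        v <- compute_velocity(p, gbest, cfg$use_pbest)
        np <- construct_particle(v, data, cfg$k, w)
        np <- update_centroids(np, data, w)
        if (np$fitness < p$pbest_fitness) {
          np$pbest_blocks <- np$blocks
          np$pbest_fitness <- np$fitness
        } else {
          np$pbest_blocks <- p$pbest_blocks
          np$pbest_fitness <- p$pbest_fitness
        }
        particles[[i]] <- np
        if (np$pbest_fitness < gbest$fitness - 1e-12) {
          gbest <- list(blocks = np$pbest_blocks, k = np$k,
                        fitness = np$pbest_fitness,
                        pbest_blocks = np$pbest_blocks,
                        pbest_fitness = np$pbest_fitness)
          improved <- TRUE
        }
      }
      history <- c(history, gbest$fitness)
      stall <- if (improved) 0L else stall + 1L
      if (stall >= cfg$stagnation_patience) break
    }
    segmentation_from_blocks(data, gbest$blocks, gbest$fitness,
                             history, iters)
  })
}

#' Baseline continuous-centroid PSO clustering
#'
#' Standard real-valued PSO over the concatenated centroid coordinates
#' (inertia 0.72, cognitive and social coefficients 1.49), with
#' nearest-centroid labelling and the same fitness as [run_pbpso()]. Kept as
#' the comparison baseline for the discrete algorithm.
#'
#' @inheritParams run_pbpso
#' @param inertia,cognitive,social PSO coefficients.
#' @return A `madpso_segmentation` (centroids are the empirical means of the
#'   final clusters).
#' @export
run_baseline_pso <- function(data, cfg = swarm_config(),
                             inertia = 0.72, cognitive = 1.49,
                             social = 1.49) {
  data <- as.matrix(data)
  n <- nrow(data)
  k <- cfg$k
  if (n < k) stop("need at least k data points")
  w <- cfg$fitness_weights
  dlo <- apply(data, 2, min)
  dhi <- apply(data, 2, max)

  eval_pos <- function(mu) {
    d <- dist_to_centroids(data, mu)
    lab <- max.col(-d, ties.method = "first")
    counts <- tabulate(lab, k)
    if (any(counts == 0L)) {
      di <- d[cbind(seq_len(n), lab)]
      for (empty in which(counts == 0L)) {
        ord <- order(di, decreasing = TRUE)
        for (i in ord) {
          if (counts[lab[i]] > 1L) {
            counts[lab[i]] <- counts[lab[i]] - 1L
            lab[i] <- empty
            counts[empty] <- 1L
            di[i] <- -Inf
            break
          }
        }
      }
    }
    blocks <- blocks_from_labels(lab, k)
    list(lab = lab, blocks = blocks,
         fitness = partition_fitness(data, blocks, w))
  }

  with_seed(cfg$seed, {
    pos <- lapply(seq_len(cfg$n_particles),
                  function(i) data[sample.int(n, k), , drop = FALSE])
    vel <- lapply(pos, function(x) x * 0)
    ev <- lapply(pos, eval_pos)
    fit <- vapply(ev, `[[`, 0, "fitness")
    pbest <- pos
    pbest_fit <- fit
    gb_i <- which.min(fit)
    gbest_pos <- pos[[gb_i]]
    gbest_fit <- fit[gb_i]
    history <- numeric(0)
    stall <- 0L
    iters <- 0L
    for (it in seq_len(cfg$max_iter)) {
      iters <- it
      improved <- FALSE
      for (i in seq_len(cfg$n_particles)) {
        r1 <- matrix(stats::runif(k * ncol(data)), k)
        r2 <- matrix(stats::runif(k * ncol(data)), k)
        vel[[i]] <- inertia * vel[[i]] +
          cognitive * r1 * (pbest[[i]] - pos[[i]]) +
          social * r2 * (gbest_pos - pos[[i]])
        pos[[i]] <- pos[[i]] + vel[[i]]
        pos[[i]] <- pmin(pmax(pos[[i]],
                              matrix(dlo, k, ncol(data), byrow = TRUE)),
                         matrix(dhi, k, ncol(data), byrow = TRUE))
        e <- eval_pos(pos[[i]])
        if (e$fitness < pbest_fit[i]) {
          pbest[[i]] <- pos[[i]]
          pbest_fit[i] <- e$fitness
        }
        if (e$fitness < gbest_fit - 1e-12) {
          gbest_pos <- pos[[i]]
          gbest_fit <- e$fitness
          improved <- TRUE
        }
      }
      history <- c(history, gbest_fit)
      stall <- if (improved) 0L else stall + 1L
      if (stall >= cfg$stagnation_patience) break
    }
    final <- eval_pos(gbest_pos)
    segmentation_from_blocks(data, final$blocks, final$fitness,
                             history, iters)
  })
}

#' Segment a grayscale image by PBPSO clustering
#'
#' Pixels are featurized as `(intensity, sw * row / height, sw * col /
#' width)` with spatial weight `sw`, clustered with [run_pbpso()] (or the
#' baseline PSO), and the labels are reshaped to the image geometry. A small
#' positive spatial weight keeps lesion clusters spatially coherent; weight
#' 0 recovers pure intensity clustering.
#'
#' @param img Grayscale matrix in `[0, 1]` (typically enhanced).
#' @param cfg A [swarm_config()].
#' @param spatial_weight Weight of the normalized pixel coordinates.
#' @param algorithm `"pbpso"` or `"pso"`.
#' @param mask Optional logical matrix restricting clustering to a region of
#'   interest (e.g. the retinal field from [estimate_field_mask()]); pixels
#'   outside it get label 0.
#' @return A `madpso_segmentation` whose `labels` is a matrix of the image
#'   shape; also carries `image_dim` and `cluster_means` (mean intensity per
#'   cluster).
#' @export
segment_image <- function(img, cfg = swarm_config(), spatial_weight = 0.2,
                          algorithm = c("pbpso", "pso"), mask = NULL) {
  stopifnot(is.matrix(img), spatial_weight >= 0)
  algorithm <- match.arg(algorithm)
  h <- nrow(img); w <- ncol(img)
  sel <- if (is.null(mask)) rep(TRUE, h * w) else {
    stopifnot(identical(dim(mask), dim(img)))
    as.vector(mask > 0)
  }
  # standardize the intensity channel so the clustering objective sees a
  # unit-scale feature (the fitness mixes entropy, which is scale-free, with
  # within-cluster variance, which is not); spatial coordinates are scaled
  # relative to that same unit
  iv <- as.numeric(img)[sel]
  isd <- stats::sd(iv)
  if (!is.finite(isd) || isd <= 0) isd <- 1
  feats <- cbind(as.numeric(img) / isd,
                 spatial_weight * as.numeric(row(img)) / h / 0.29,
                 spatial_weight * as.numeric(col(img)) / w / 0.29)[sel, ,
                                                                   drop = FALSE]
  seg <- if (algorithm == "pbpso") run_pbpso(feats, cfg) else
    run_baseline_pso(feats, cfg)
  lab <- integer(h * w)
  lab[sel] <- seg$labels
  lab <- matrix(lab, h, w)
  seg$labels <- lab
  seg$image_dim <- c(h, w)
  seg$spatial_weight <- spatial_weight
  seg$cluster_means <- vapply(seq_len(seg$k),
                              function(b) mean(img[lab == b]), 0)
  seg
}

#' Estimate the retinal field mask of a fundus image
#'
#' The camera aperture leaves a near-black border around the circular
#' retinal field. Pixels above `threshold` are kept, the largest 8-connected
#' component is selected, and the result is eroded by `erode` pixels so the
#' steep aperture rim does not leak into downstream clustering.
#'
#' @param img Grayscale matrix in `[0, 1]` (pre-enhancement).
#' @param threshold Intensity cut separating field from border.
#' @param erode Erosion radius in pixels (box structuring element).
#' @return Logical matrix.
#' @export
estimate_field_mask <- function(img, threshold = 0.05, erode = 2) {
  stopifnot(is.matrix(img))
  mask <- img > threshold
  comp <- label_components(mask, connectivity = 8)
  if (max(comp) == 0) return(mask)
  sizes <- tabulate(comp[comp > 0])
  mask <- comp == which.max(sizes)
  for (i in seq_len(erode)) {
    h <- nrow(mask); w <- ncol(mask)
    shr <- mask
    shr[-1, ] <- shr[-1, ] & mask[-h, ]
    shr[-h, ] <- shr[-h, ] & mask[-1, ]
    shr[, -1] <- shr[, -1] & mask[, -w]
    shr[, -w] <- shr[, -w] & mask[, -1]
    mask <- shr
  }
  mask
}

#' Exhaustive best 2-partition (enumeration oracle)
#'
#' Enumerates every partition of the points into two non-empty blocks and
#' returns the one with minimum [partition_fitness()]. Exponential in N;
#' guarded to N <= 16. Used to validate the stochastic optimizer on small
#' instances.
#'
#' @param data N x D matrix, N <= 16.
#' @param weights Fitness weights.
#' @return List with `blocks` and `fitness`.
#' @export
exhaustive_best_partition <- function(data, weights = c(1, 0, 0, 0, 1)) {
  data <- as.matrix(data)
  n <- nrow(data)
  stopifnot(n >= 2, n <= 16)
  best <- NULL
  best_f <- Inf
  # point 1 always in block A; iterate subsets of 2..N joining it
  for (m in 0:(2^(n - 1) - 2)) {
    in_a <- c(TRUE, as.logical(bitwAnd(m, 2^(0:(n - 2)))))
    blocks <- list(which(in_a), which(!in_a))
    f <- partition_fitness(data, blocks, weights)
    if (f < best_f) {
      best_f <- f
      best <- blocks
    }
  }
  list(blocks = best, fitness = best_f)
}
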