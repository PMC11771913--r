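# Independent brute-force oracles used to validate the implementation.
# These re-evaluate the published definitions literally and share no code
# with the package internals.

# Literal DBSCAN: neighbourhoods by exhaustive pairwise scan (strict d < eps,
# self included); cores by |N_eps| >= minPts; clusters as connected
# components of the direct-density-reachability relation restricted to core
# points; border points attached to every cluster whose cores reach them.
oracle_dbscan <- function(coords, eps, min_pts) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] < eps))
  core <- lengths(nb) >= min_pts
  # union-find over mutually reachable cores
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (p in which(core)) {
    for (q in intersect(nb[[p]], which(core))) {
      rp <- find(p); rq <- find(q)
      if (rp != rq) parent[rq] <- rp
    }
  }
  comp <- vapply(seq_len(n), function(i) if (core[i]) find(i) else NA_integer_,
                 integer(1))
  core_cluster <- match(comp, sort(unique(comp[!is.na(comp)])))
  # border points: every cluster whose core neighbourhood holds them
  # (q in N_eps(p) iff p in N_eps(q), by symmetry of the distance)
  border_clusters <- lapply(seq_len(n), function(q) {
    if (core[q]) return(integer(0))
    owners <- unique(core_cluster[intersect(nb[[q]], which(core))])
    owners[!is.na(owners)]
  })
  cls <- ifelse(core, "core",
                ifelse(lengths(border_clusters) > 0, "border", "noise"))
  list(core = core, point_class = cls, core_cluster = core_cluster,
       border_clusters = border_clusters, nb = nb)
}

# Agreement of two partitions up to relabeling (exact on cores; borders may
# legitimately sit in any cluster that reaches them).
partitions_equivalent <- function(impl, oracle) {
  if (!identical(impl$point_class == "core", unname(oracle$core))) {
    return("core labels differ")
  }
  if (!identical(impl$point_class, unname(oracle$point_class))) {
    return("border/noise classification differs")
  }
  ci <- impl$cluster[oracle$core]
  co <- oracle$core_cluster[oracle$core]
  if (length(ci) > 0) {
    tab <- table(ci, co)
    if (any(rowSums(tab > 0) != 1) || any(colSums(tab > 0) != 1)) {
      return("core partition differs")
    }
  }
  borders <- which(impl$point_class == "border")
  for (q in borders) {
    # impl cluster of q must correspond to an oracle cluster reaching q
    oc <- oracle$core_cluster[oracle$core & impl$cluster == impl$cluster[q]][1]
    if (!oc %in% oracle$border_clusters[[q]]) {
      return(sprintf("border point %d in a cluster that does not reach it", q))
    }
  }
  TRUE
}

# Rand index between two label vectors
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}

# literal k-nearest-neighbour sets with ascending-index tie-break
oracle_knn_sets <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  lapply(seq_len(n), function(i) {
    cand <- setdiff(seq_len(n), i)
    cand[order(d[i, cand], cand)][seq_len(k)]
  })
}

# Andrew monotone-chain convex hull (area), independent of grDevices::chull
oracle_hull_area <- function(pts) {
  pts <- unique(as.matrix(pts))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  n <- nrow(pts)
  if (n < 3) return(0)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(pts[h[length(h) - 1], ], pts[h[length(h)], ],
                   pts[i, ]) <= 0) {
        h <- h[-length(h)]
      }
      h <- c(h, i)
    }
    h[-length(h)]
  }
  hull <- c(build(seq_len(n)), build(rev(seq_len(n))))
  v <- pts[hull, , drop = FALSE]
  k <- nrow(v)
  if (k < 3) return(0)
  abs(sum(v[, 1] * v[c(2:k, 1), 2] - v[c(2:k, 1), 1] * v[, 2])) / 2
}

# Moran's-I-style spatial autocorrelation with a row-standardised weight
# matrix (S0 = n for row-standardised W)
moran_i <- function(z, W) {
  zc <- z - mean(z)
  as.numeric((length(z) / sum(W)) * (t(zc) %*% (W %*% zc)) / sum(zc^2))
}

# small random clustered point set for clustering tests
random_instance <- function(n, seed, box = 100) {
  set.seed(seed)
  k <- sample(0:3, 1)
  pts <- matrix(runif(2 * n, 0, box), ncol = 2)
  if (k > 0) {
    centers <- matrix(runif(2 * k, 10, box - 10), ncol = 2)
    for (i in seq_len(nrow(pts))) {
      if (runif(1) < 0.5) {
        c_i <- centers[sample(k, 1), ]
        pts[i, ] <- c_i + rnorm(2, sd = box / 30)
      }
    }
  }
  pts
}

two_disc_config <- function(seed = 11) {
  synthetic_config(
    hotspots = data.frame(x = c(2000, 7000), y = c(2000, 7000),
                          radius = 50, n = 50),
    background_count = 20,
    bounding_box = c(0, 0, 10000, 10000),
    covariates = list(cov_continuous("z")),
    beta = c(1, -1), rho = 0.5, seed = seed)
}

recovery_config <- function(seed, n_background = 400, rho = 0.5,
                            beta = c(1, -1)) {
  # spatially unstructured points (kNN weights still connect them)
  synthetic_config(hotspots = data.frame(x = numeric(0), y = numeric(0),
                                         radius = numeric(0), n = integer(0)),
                   background_count = n_background,
                   bounding_box = c(0, 0, 1000, 1000),
                   covariates = list(cov_continuous("z")),
                   beta = beta, rho = rho, seed = seed)
}
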