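# Shared fixtures and independent oracles used across the suite.

# Best-fit RMSD allowing reflection (for embeddings, which are chiral-blind).
fit_rmsd_reflection <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  s <- svd(H)
  R <- s$u %*% t(s$v)  # orthogonal, reflection allowed
  sqrt(mean(rowSums((sweep(sweep(A, 2, ca) %*% R, 2, cb, "+") - B)^2)))
}

# Proper-rotation RMSD via the package-independent closed form is what the
# package itself computes; for oracle purposes we only need the plain RMSD.
plain_rmsd <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

# Rotation matrix from ZYZ Euler angles (for the brute-force rotation grid).
euler_rotation <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# Brute-force best RMSD over a rotation grid (translation solved exactly by
# centroid matching at each grid rotation). `resolution_bound` is the largest
# extra RMSD the finite grid can cost: a rotation within the grid spacing of
# the optimum moves no point by more than 2 sin(spacing) * max radius.
grid_min_rmsd <- function(mobile, target, n_per_axis = 24) {
  ca <- colMeans(mobile); cb <- colMeans(target)
  A <- sweep(mobile, 2, ca); B <- sweep(target, 2, cb)
  alphas <- seq(0, 2 * pi, length.out = n_per_axis + 1)[-(n_per_axis + 1)]
  betas <- seq(0, pi, length.out = n_per_axis)
  best <- Inf
  for (a in alphas) for (b in betas) for (c in alphas) {
    R <- euler_rotation(a, b, c)
    best <- min(best, plain_rmsd(A %*% t(R), B))
  }
  bound <- 2 * sin(2 * pi / n_per_axis) *
    max(sqrt(rowSums(A^2)))
  list(rmsd = best, resolution_bound = bound)
}

# Reference DBSCAN: explicit neighbourhood graph over core points + BFS,
# border points attached to the cluster of the first core point (in index
# order) that reaches them. Independent of the package implementation.
dbscan_bruteforce <- function(points, eps, min_samples) {
  points <- as.matrix(points)
  F <- nrow(points)
  d <- as.matrix(stats::dist(points))
  nbr <- lapply(seq_len(F), function(r) which(d[r, ] <= eps))
  core <- lengths(nbr) >= min_samples
  # connected components of the core-core graph
  comp <- rep(NA_integer_, F)
  cl <- -1L
  for (s in seq_len(F)) {
    if (!core[s] || !is.na(comp[s])) next
    cl <- cl + 1L
    stack <- s
    while (length(stack)) {
      p <- stack[[1]]; stack <- stack[-1]
      if (!is.na(comp[p])) next
      comp[p] <- cl
      stack <- c(stack, Filter(function(q) core[q] && is.na(comp[q]), nbr[[p]]))
    }
  }
  labels <- ifelse(is.na(comp), -1L, comp)
  for (p in seq_len(F)) {
    if (core[p] || labels[p] != -1L) next
    for (q in seq_len(F)) {
      if (core[q] && d[p, q] <= eps) { labels[p] <- labels[q]; break }
    }
  }
  list(labels = labels, core = core)
}

# Compare two flat partitions up to label permutation (noise must match
# exactly as -1).
same_partition <- function(l1, l2) {
  if (length(l1) != length(l2)) return(FALSE)
  if (!identical(l1 == -1L, l2 == -1L)) return(FALSE)
  ok <- l1 != -1L
  if (!any(ok)) return(TRUE)
  key1 <- as.integer(factor(l1[ok], levels = unique(l1[ok])))
  key2 <- as.integer(factor(l2[ok], levels = unique(l2[ok])))
  identical(key1, key2)
}

# Random proper rotation (uniform via QR of Gaussian matrix).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# A bent variant of a duplex configuration: rotate the ids in `tail_ids`
# (0-based) by `angle` degrees about the z axis through the pivot particle.
bend_configuration <- function(conf, tail_ids, pivot_id, angle_deg = 90) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  idx <- tail_ids + 1L
  pivot <- conf$positions[pivot_id + 1L, ]
  conf$positions[idx, ] <- sweep(
    sweep(conf$positions[idx, , drop = FALSE], 2, pivot) %*% t(R),
    2, pivot, "+")
  conf$a1[idx, ] <- conf$a1[idx, , drop = FALSE] %*% t(R)
  conf$a3[idx, ] <- conf$a3[idx, , drop = FALSE] %*% t(R)
  conf
}

# Two rigid 12-bp duplexes whose axes meet at `angle_deg`, merged into one
# system (4 strands, no inter-duplex connectivity). Returns topology,
# configuration and the union of designed pairs.
two_duplex_fixture <- function(angle_deg = 60, n_bp = 12, gap = 4) {
  d1 <- build_duplex(n_bp)
  d2 <- build_duplex(n_bp)
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
              3, 3, byrow = TRUE)  # rotate +z towards +x by angle
  c2 <- d2$configuration
  c2$positions <- c2$positions %*% t(R)
  c2$a1 <- c2$a1 %*% t(R)
  c2$a3 <- c2$a3 %*% t(R)
  c2$positions <- sweep(c2$positions, 2, c(gap, 0, 0), "+")
  n <- d1$topology$n
  topo <- topology(
    strand_id = c(d1$topology$strand_id, d2$topology$strand_id + 2L),
    base = c(d1$topology$base, d2$topology$base),
    neighbor3 = c(d1$topology$neighbor3, d2$topology$neighbor3 + n),
    neighbor5 = c(d1$topology$neighbor5, d2$topology$neighbor5 + n))
  conf <- configuration(rbind(d1$configuration$positions, c2$positions),
                        rbind(d1$configuration$a1, c2$a1),
                        rbind(d1$configuration$a3, c2$a3),
                        box = d1$configuration$box)
  pairs <- designed_pairs(c(d1$pairs[, 1], d2$pairs[, 1] + n),
                          c(d1$pairs[, 2], d2$pairs[, 2] + n))
  list(topology = topo, configuration = conf, pairs = pairs)
}
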