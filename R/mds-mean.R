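# Mean structure from mean local contact distances via multidimensional
# scaling, plus per-nucleotide local contact deviation.
#
# Full-structure superposition collapses flexible structures towards a centre
# line; reconstructing the mean from local interparticle distances instead
# preserves helical geometry at the cost of losing orientation data.

#' Mean local contact map of a trajectory
#'
#' Computes the trajectory mean of all pairwise centre-of-mass distances and
#' retains the pairs whose mean is at most `r_cut_nm` (default 2.07 nm,
#' approximately the interhelix gap in an origami).
#'
#' @param traj An `oxdna_traj`.
#' @param r_cut_nm Cutoff on the mean distance, nanometres.
#' @param n_cpus Worker processes.
#' @return A `contact_map`: list with `pairs` (data frame `i`, `j` 0-based
#'   with `i < j`, and `dist`, the mean distance in simulation units),
#'   `r_cut` (simulation units) and `n` (particle count).
#' @export
mean_distance_map <- function(traj, r_cut_nm = 2.07, n_cpus = 1L) {
  n <- traj$topology$n
  F <- n_frames(traj)
  dsum <- .traj_reduce(traj, function(fr) as.matrix(stats::dist(fr$positions)),
                       function(acc, x) if (is.null(acc)) x else acc + x,
                       n_cpus = n_cpus)
  dmean <- dsum / F
  r_cut <- r_cut_nm / .LENGTH_NM
  keep <- which(upper.tri(dmean) & dmean <= r_cut, arr.ind = TRUE)
  structure(list(
    pairs = data.frame(i = keep[, 1] - 1L, j = keep[, 2] - 1L,
                       dist = dmean[keep]),
    r_cut = r_cut, n = n
  ), class = "contact_map")
}

# igraph over the retained pairs (vertices named 0..n-1 as characters).
.contact_graph <- function(map) {
  g <- igraph::make_empty_graph(n = map$n, directed = FALSE)
  igraph::add_edges(g, rbind(map$pairs$i + 1L, map$pairs$j + 1L))
}

#' Embed a contact map in 3D by stress minimisation
#'
#' Minimises the raw stress `sum over retained pairs of (mean_dist - d)^2`.
#' Three deterministic stages: classical MDS of the shortest-path (geodesic)
#' completion of the sparse map as initialisation; SMACOF majorisation
#' iterations; and a quasi-Newton (L-BFGS) polish on the stress with its
#' analytic gradient. The polish matters for elongated structures, where
#' pure majorisation converges only linearly through slow long-wavelength
#' bending modes. Pairs beyond the cutoff carry weight zero. The embedding
#' is only defined up to a rigid transform and reflection.
#'
#' @param map A `contact_map` whose contact graph is connected.
#' @param seed Unused by the deterministic solver; kept so callers can treat
#'   all embedding routes uniformly.
#' @param max_iter Iteration cap for the majorisation loop (the polish gets
#'   `10 * max_iter` gradient evaluations).
#' @param tol Relative stress-decrease tolerance for convergence.
#' @return An `mds_embedding`: list with `coordinates` (N x 3, centred at the
#'   origin, simulation units), `stress` and `iterations` (majorisation
#'   count).
#' @export
mds_embed <- function(map, seed = 1, max_iter = 300, tol = 1e-6) {
  n <- map$n
  if (nrow(map$pairs) == 0L) .stopf("contact map is empty")
  g <- .contact_graph(map)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    sizes <- paste(comp$csize, collapse = ", ")
    .stopf("contact graph is disconnected: %d fragments of sizes %s; cannot embed",
           comp$no, sizes)
  }
  # classical MDS on geodesic completion as initialisation
  igraph::E(g)$weight <- map$pairs$dist
  D <- igraph::distances(g)
  X <- stats::cmdscale(D, k = min(3L, n - 1L))
  if (ncol(X) < 3L) X <- cbind(X, matrix(0, n, 3L - ncol(X)))

  ii <- map$pairs$i + 1L; jj <- map$pairs$j + 1L
  delta <- map$pairs$dist
  # weighted Laplacian V (weights 1 on retained pairs) and its pseudo-inverse
  V <- matrix(0, n, n)
  V[cbind(ii, jj)] <- -1; V[cbind(jj, ii)] <- -1
  diag(V) <- -rowSums(V)
  Vp <- solve(V + 1 / n) - 1 / n

  stress_of <- function(X) {
    d <- sqrt(rowSums((X[ii, , drop = FALSE] - X[jj, , drop = FALSE])^2))
    sum((delta - d)^2)
  }
  s_old <- stress_of(X)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    d <- sqrt(rowSums((X[ii, , drop = FALSE] - X[jj, , drop = FALSE])^2))
    ratio <- ifelse(d > 1e-12, delta / d, 0)
    B <- matrix(0, n, n)
    B[cbind(ii, jj)] <- -ratio; B[cbind(jj, ii)] <- -ratio
    diag(B) <- -rowSums(B)
    X <- Vp %*% (B %*% X)
    s_new <- stress_of(X)
    if (s_old - s_new < tol * max(s_old, 1e-300) && s_new <= s_old) break
    s_old <- s_new
  }
  # quasi-Newton polish of the raw stress (analytic gradient)
  lv <- factor(c(ii, jj), levels = seq_len(n))
  gr <- function(v) {
    X <- matrix(v, ncol = 3)
    dif <- X[ii, , drop = FALSE] - X[jj, , drop = FALSE]
    d <- sqrt(rowSums(dif^2))
    gi <- dif * (2 * (d - delta) / pmax(d, 1e-12))
    G <- matrix(0, n, 3)
    for (c in 1:3)
      G[, c] <- tapply(c(gi[, c], -gi[, c]), lv, sum, default = 0)
    as.vector(G)
  }
  opt <- stats::optim(as.vector(X), function(v) stress_of(matrix(v, ncol = 3)),
                      gr, method = "L-BFGS-B",
                      control = list(maxit = 10L * max_iter, factr = 10))
  X <- matrix(opt$par, ncol = 3)
  X <- sweep(X, 2, colMeans(X))
  # documented failure mode of manifold embedding at large scale: everything
  # lands at the origin
  bbox <- sqrt(sum((apply(X, 2, max) - apply(X, 2, min))^2))
  if (n > 3L && bbox < 1e-4 * max(delta))
    warning("MDS embedding collapsed to the origin; the structure is likely too large or the map too sparse for a faithful embedding")
  structure(list(coordinates = X, stress = stress_of(X), iterations = iter),
            class = "mds_embedding")
}

#' Per-nucleotide local contact deviation
#'
#' For each nucleotide, the spread of its distance to each retained contact
#' partner across the trajectory (standard deviation by default, mean
#' absolute deviation optionally), averaged over partners. This measures
#' local flexibility without any global fit, so it is free of the alignment
#' artifacts that affect RMSF on floppy structures. Values are in simulation
#' length units.
#'
#' @param traj An `oxdna_traj`.
#' @param map A `contact_map` for the same trajectory.
#' @param method `"sd"` or `"mad"` (mean absolute deviation about the mean).
#' @param n_cpus Worker processes.
#' @return List with `deviation` (numeric, length N) and `overlay` (a
#'   `color_overlay` named "local contact deviation").
#' @export
local_deviation <- function(traj, map, method = c("sd", "mad"),
                            n_cpus = 1L) {
  method <- match.arg(method)
  F <- n_frames(traj)
  ii <- map$pairs$i + 1L; jj <- map$pairs$j + 1L
  pair_dist <- function(fr)
    sqrt(rowSums((fr$positions[ii, , drop = FALSE] -
                  fr$positions[jj, , drop = FALSE])^2))
  sums <- .traj_reduce(traj, function(fr) {
    d <- pair_dist(fr)
    list(s = d, s2 = d^2, sa = NULL)
  }, function(acc, x) {
    if (is.null(acc)) x else list(s = acc$s + x$s, s2 = acc$s2 + x$s2)
  }, n_cpus = n_cpus)
  m1 <- sums$s / F
  if (method == "sd") {
    v <- pmax(sums$s2 / F - m1^2, 0)
    per_pair <- sqrt(v * F / max(F - 1L, 1L))   # sample sd
  } else {
    abs_sum <- .traj_reduce(traj, function(fr) abs(pair_dist(fr) - m1),
                            function(acc, x) if (is.null(acc)) x else acc + x,
                            n_cpus = n_cpus)
    per_pair <- abs_sum / F
  }
  dev <- numeric(map$n)
  cnt <- numeric(map$n)
  for (k in seq_along(ii)) {
    dev[ii[k]] <- dev[ii[k]] + per_pair[k]; cnt[ii[k]] <- cnt[ii[k]] + 1
    dev[jj[k]] <- dev[jj[k]] + per_pair[k]; cnt[jj[k]] <- cnt[jj[k]] + 1
  }
  dev <- ifelse(cnt > 0, dev / pmax(cnt, 1), 0)
  list(deviation = dev,
       overlay = color_overlay("local contact deviation", dev))
}

#' Mean structure via multidimensional scaling
#'
#' Convenience pipeline: contact map, 3D embedding, local deviation overlay.
#' The result carries centre-of-mass coordinates only (orientation is lost in
#' the embedding); nucleotides are to be visualised as spheres.
#'
#' @param traj An `oxdna_traj`.
#' @param r_cut_nm Contact cutoff, nm.
#' @param n_cpus Worker processes.
#' @param ... Passed to [mds_embed()].
#' @return List with `embedding`, `map` and `deviation` (as returned by
#'   [local_deviation()]).
#' @export
mds_mean_structure <- function(traj, r_cut_nm = 2.07, n_cpus = 1L, ...) {
  map <- mean_distance_map(traj, r_cut_nm, n_cpus = n_cpus)
  emb <- mds_embed(map, ...)
  dev <- local_deviation(traj, map, n_cpus = n_cpus)
  list(embedding = emb, map = map, deviation = dev)
}
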