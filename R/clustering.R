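# DBSCAN over per-frame order parameters, trajectory splitting by cluster,
# and per-cluster representative frames.

#' Density-based clustering (DBSCAN)
#'
#' Standard semantics: a core point has at least `min_samples` points
#' (itself included) within `eps`; clusters are the connected components of
#' core points together with the non-core points reachable from them; the
#' rest is noise, labelled -1. Cluster labels are 0-based and numbered by
#' first-seen point order, so the output is deterministic.
#'
#' @param points F x k numeric matrix (rows are observations).
#' @param eps Neighbourhood radius (> 0), Euclidean metric.
#' @param min_samples Minimum neighbourhood size for a core point (>= 1).
#' @return A `cluster_assignment`: list with `labels` (integer per row, -1 =
#'   noise), `n_clusters` and `core` (logical per row).
#' @export
dbscan <- function(points, eps, min_samples) {
  points <- as.matrix(points)
  if (eps <= 0 || min_samples < 1) .stopf("eps > 0 and min_samples >= 1 required")
  F <- nrow(points)
  if (F == 0L)
    return(structure(list(labels = integer(0), n_clusters = 0L,
                          core = logical(0)), class = "cluster_assignment"))
  d <- as.matrix(stats::dist(points))
  nbr <- lapply(seq_len(F), function(r) which(d[r, ] <= eps))  # includes self
  core <- lengths(nbr) >= min_samples
  labels <- rep(-1L, F)
  cl <- -1L
  for (s in seq_len(F)) {
    if (!core[s] || labels[s] != -1L) next
    cl <- cl + 1L
    labels[s] <- cl
    queue <- s
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in nbr[[p]]) {
        if (labels[q] == -1L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  structure(list(labels = labels, n_clusters = cl + 1L, core = core),
            class = "cluster_assignment")
}

# Elbow of the sorted k-distance curve: the point furthest from the chord
# joining the curve's endpoints (max-curvature heuristic).
.suggest_eps <- function(points, min_samples) {
  d <- as.matrix(stats::dist(points))
  kd <- apply(d, 1, function(r) sort(r)[min(min_samples, length(r))])
  kd <- sort(kd)
  m <- length(kd)
  if (m < 3L) return(max(kd) + 1e-12)
  x <- seq_len(m)
  chord <- c(m - 1, kd[m] - kd[1])
  chord <- chord / sqrt(sum(chord^2))
  dist_to_chord <- abs((x - 1) * chord[2] - (kd - kd[1]) * chord[1])
  eps <- kd[which.max(dist_to_chord)]
  if (eps <= 0) eps <- max(kd[kd > 0], 1e-12)
  eps
}

#' Cluster trajectory frames and split by cluster
#'
#' Runs DBSCAN on per-frame order parameters and writes one trajectory file
#' per non-noise cluster (frame order preserved) plus a per-frame label CSV.
#' By default the order parameters are the projections onto the leading
#' principal components covering 90 percent of the variance (capped at 10),
#' and `eps` comes from the k-distance elbow heuristic; both defaults are
#' heuristics to be overridden when the system is understood.
#'
#' @param traj An `oxdna_traj`.
#' @param order_params Optional F x k matrix (e.g. [pca_project()] output or
#'   distance columns); computed from PCA when `NULL`.
#' @param eps DBSCAN radius; `NULL` for the k-distance heuristic.
#' @param min_samples DBSCAN minimum neighbourhood size.
#' @param output_dir Where to write `cluster_<n>.dat` files and
#'   `cluster_labels.csv`; `NULL` skips writing.
#' @param save_noise Also write `cluster_noise.dat` when noise frames exist.
#' @return List with `assignment` (a `cluster_assignment`), `order_params`,
#'   `eps` used, and `files` (named character vector of written paths).
#' @export
cluster_trajectory <- function(traj, order_params = NULL, eps = NULL,
                               min_samples = 5L, output_dir = NULL,
                               save_noise = FALSE) {
  if (is.null(order_params)) {
    ms <- mean_structure(traj)
    basis <- compute_pca(traj, ms)
    k <- min(which(cumsum(basis$explained) >= 0.9), 10L)
    order_params <- pca_project(traj, basis, k)
  }
  order_params <- as.matrix(order_params)
  if (nrow(order_params) != n_frames(traj))
    .stopf("order parameter rows (%d) must match frame count (%d)",
           nrow(order_params), n_frames(traj))
  if (is.null(eps)) eps <- .suggest_eps(order_params, min_samples)
  asg <- dbscan(order_params, eps, min_samples)
  files <- character(0)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    labs <- sort(unique(asg$labels[asg$labels >= 0L]))
    for (l in labs) {
      sel <- which(asg$labels == l)
      sub <- trajectory(traj$topology,
                        lapply(sel, function(k) get_frame(traj, k)))
      path <- file.path(output_dir, sprintf("cluster_%d.dat", l))
      write_trajectory(sub, path)
      files[sprintf("cluster_%d", l)] <- path
    }
    if (save_noise && any(asg$labels == -1L)) {
      sel <- which(asg$labels == -1L)
      path <- file.path(output_dir, "cluster_noise.dat")
      write_trajectory(
        trajectory(traj$topology, lapply(sel, function(k) get_frame(traj, k))),
        path)
      files["noise"] <- path
    }
    lab_path <- file.path(output_dir, "cluster_labels.csv")
    utils::write.csv(data.frame(frame = seq_len(n_frames(traj)),
                                label = asg$labels),
                     lab_path, row.names = FALSE)
    files["labels"] <- lab_path
    if (asg$n_clusters == 0L)
      warning("all frames labelled noise; no cluster files written")
  }
  list(assignment = asg, order_params = order_params, eps = eps,
       files = files)
}

#' Representative frame per cluster
#'
#' For each cluster, the member frame minimising the mean distance (in
#' order-parameter space) to the other members; ties break to the lowest
#' frame index.
#'
#' @param traj An `oxdna_traj`.
#' @param order_params F x k matrix used for the clustering.
#' @param assignment A `cluster_assignment`.
#' @return Named list (one entry per cluster label) of lists with `index`
#'   (1-based frame) and `configuration`.
#' @export
cluster_centroids <- function(traj, order_params, assignment) {
  order_params <- as.matrix(order_params)
  out <- list()
  for (l in sort(unique(assignment$labels[assignment$labels >= 0L]))) {
    sel <- which(assignment$labels == l)
    sub <- order_params[sel, , drop = FALSE]
    d <- as.matrix(stats::dist(sub))
    mean_d <- rowSums(d) / max(1L, nrow(d) - 1L)
    best <- sel[which.min(mean_d)]  # which.min takes the first = lowest index
    out[[sprintf("cluster_%d", l)]] <-
      list(index = best, configuration = get_frame(traj, best))
  }
  out
}
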