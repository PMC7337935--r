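# Principal component analysis of aligned trajectories: motion modes,
# projections for clustering, and weighted-mode arrow overlays.
#
# Deviations use positions only (no orientation versors); each frame is
# flattened to a 3N-vector in (x1, y1, z1, x2, ...) order.

.deviation_matrix <- function(traj, ref, subset = NULL, n_cpus = 1L) {
  rows <- .traj_map(traj, function(fr) {
    al <- apply_transform(fr, kabsch_fit(fr$positions, ref$positions, subset))
    as.vector(t(al$positions - ref$positions))
  }, n_cpus = n_cpus)
  do.call(rbind, rows)
}

#' Principal component analysis of a trajectory
#'
#' Each frame is superimposed onto the mean structure to remove rigid-body
#' motion; the covariance matrix of the flattened positional deviations is
#' then diagonalised. Eigenpairs are sorted by descending eigenvalue; for
#' rigid-transform-free data at most 3N - 6 eigenvalues are materially
#' nonzero. Eigenvector signs are fixed so each vector's largest-magnitude
#' component is positive (reproducible overlays).
#'
#' For very large structures (3N > 4000) the spectrum is obtained from the
#' SVD of the F x 3N deviation matrix instead, which shares the nonzero
#' eigenvalues and is much cheaper when F < 3N; only min(F, 3N) components
#' are then available.
#'
#' @param traj An `oxdna_traj` (>= 2 frames).
#' @param mean A `mean_structure_result` or an `oxdna_conf` reference; the
#'   trajectory is aligned to it internally.
#' @param subset Optional 0-based fitting ids for the alignment.
#' @param n_cpus Worker processes for the alignment pass.
#' @return A `pca_basis`: list with `mean` (`oxdna_conf`), `eigenvalues`
#'   (descending, length 3N), `eigenvectors` (3N x m orthonormal columns),
#'   `explained` (variance fractions) and `n` (particle count).
#' @export
compute_pca <- function(traj, mean, subset = NULL, n_cpus = 1L) {
  if (n_frames(traj) < 2L) .stopf("PCA needs at least 2 frames")
  ref <- if (inherits(mean, "mean_structure_result")) mean$mean else mean
  if (is.null(subset) && inherits(mean, "mean_structure_result"))
    subset <- mean$subset
  dev <- .deviation_matrix(traj, ref, subset, n_cpus)
  F <- nrow(dev); p <- ncol(dev)
  # covariance about the empirical mean of the deviations (the re-alignment
  # to `ref` leaves a small nonzero mean; the spectrum must not absorb it)
  dev <- sweep(dev, 2, colMeans(dev))
  if (p <= 4000L) {
    C <- crossprod(dev) / (F - 1L)
    eg <- eigen(C, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    vec <- eg$vectors
  } else {
    s <- svd(dev / sqrt(F - 1L), nu = 0)
    ev <- c(s$d^2, rep(0, max(0L, p - length(s$d))))[seq_len(length(s$d))]
    vec <- s$v
  }
  for (m in seq_len(ncol(vec))) {
    mx <- which.max(abs(vec[, m]))
    if (vec[mx, m] < 0) vec[, m] <- -vec[, m]
  }
  structure(list(mean = ref, eigenvalues = ev, eigenvectors = vec,
                 explained = if (sum(ev) > 0) ev / sum(ev) else ev,
                 n = p %/% 3L, subset = subset),
            class = "pca_basis")
}

#' Project a trajectory onto principal components
#'
#' @param traj An `oxdna_traj`.
#' @param basis A `pca_basis`.
#' @param k Number of leading components (default all available).
#' @param n_cpus Worker processes.
#' @return F x k matrix of per-frame coordinates in component space.
#' @export
pca_project <- function(traj, basis, k = ncol(basis$eigenvectors),
                        n_cpus = 1L) {
  dev <- .deviation_matrix(traj, basis$mean, basis$subset, n_cpus)
  dev %*% basis$eigenvectors[, seq_len(k), drop = FALSE]
}

#' Motion-mode arrow overlay
#'
#' Per-nucleotide 3-vector equal to the sum of the leading `n_components`
#' eigenvectors weighted by their eigenvalues (or their square roots, i.e.
#' modal amplitudes, with `weight = "sqrt"`), reshaped per particle. Loaded
#' in the viewer this draws an arrow from each nucleotide showing where the
#' dominant collective motions carry it.
#'
#' @param basis A `pca_basis`.
#' @param n_components Number of leading components to sum (0 gives a zero
#'   overlay).
#' @param weight `"eigenvalue"` or `"sqrt"`.
#' @return A `vector_overlay` named "pca modes".
#' @export
mode_overlay <- function(basis, n_components = 1L,
                         weight = c("eigenvalue", "sqrt")) {
  weight <- match.arg(weight)
  p <- 3L * basis$n
  v <- numeric(p)
  for (m in seq_len(min(n_components, ncol(basis$eigenvectors)))) {
    w <- if (weight == "eigenvalue") basis$eigenvalues[m]
      else sqrt(basis$eigenvalues[m])
    v <- v + w * basis$eigenvectors[, m]
  }
  vector_overlay("pca modes", matrix(v, ncol = 3, byrow = TRUE))
}

#' Explained-variance (scree) table
#'
#' @param basis A `pca_basis`.
#' @return Data frame with `component`, `eigenvalue`, `fraction`,
#'   `cumulative` (monotone to 1).
#' @export
scree <- function(basis) {
  data.frame(component = seq_along(basis$eigenvalues),
             eigenvalue = basis$eigenvalues,
             fraction = basis$explained,
             cumulative = cumsum(basis$explained))
}
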