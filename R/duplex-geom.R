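# Duplex identification, axis fitting (B and A form), interduplex angle
# statistics and inter-nucleotide distances.

# Walk maximal runs of consecutive base pairs (a,b),(n5[a],n3[b]),... along
# antiparallel strands. Returns a list of k x 2 matrices of 0-based ids,
# canonicalised so column 1 contains the smallest id of the run.
.pair_runs <- function(topo, pairs) {
  if (nrow(pairs) == 0L) return(list())
  partner <- rep(NA_integer_, topo$n)
  partner[pairs[, 1] + 1L] <- pairs[, 2]
  partner[pairs[, 2] + 1L] <- pairs[, 1]
  paired_with <- function(a, b) {
    !is.na(a) && !is.na(b) && !is.na(partner[a + 1L]) && partner[a + 1L] == b
  }
  succ <- function(a, b) c(topo$neighbor5[a + 1L], topo$neighbor3[b + 1L])
  pred <- function(a, b) c(topo$neighbor3[a + 1L], topo$neighbor5[b + 1L])
  ordered <- rbind(as.matrix(pairs[, 1:2]), as.matrix(pairs[, 2:1]))
  runs <- list()
  seen_min <- integer(0)
  for (r in seq_len(nrow(ordered))) {
    a <- ordered[r, 1]; b <- ordered[r, 2]
    p <- pred(a, b)
    if (paired_with(p[1], p[2])) next  # not a run start
    run <- matrix(c(a, b), ncol = 2)
    repeat {
      s <- succ(run[nrow(run), 1], run[nrow(run), 2])
      if (!paired_with(s[1], s[2])) break
      run <- rbind(run, s)
    }
    key <- min(run)
    if (key %in% seen_min) next        # same run found from the other end
    seen_min <- c(seen_min, key)
    if (min(run[, 1]) > min(run[, 2]))
      run <- run[rev(seq_len(nrow(run))), c(2, 1), drop = FALSE]
    runs[[length(runs) + 1L]] <- run
  }
  runs[order(vapply(runs, function(r) r[1, 1], numeric(1)))]
}

# Base-pair midpoints of a run, in run order.
.run_midpoints <- function(conf, run) {
  (conf$positions[run[, 1] + 1L, , drop = FALSE] +
   conf$positions[run[, 2] + 1L, , drop = FALSE]) / 2
}

#' Fit a duplex axis through base-pair midpoints (B form)
#'
#' Total-least-squares line through the base-pair centre points: the first
#' principal direction of the centred midpoints. Appropriate for B-form DNA,
#' where the centres are roughly collinear. The sign points from the first
#' towards the last base pair of the run (increasing strand-1 order).
#'
#' @param conf An `oxdna_conf`.
#' @param run k x 2 matrix of paired 0-based ids in run order (k >= 3), as
#'   produced by [find_duplexes()].
#' @return Unit 3-vector.
#' @export
fit_axis_b <- function(conf, run) {
  if (nrow(run) < 3L) .stopf("B-form axis fit needs >= 3 base pairs")
  mids <- .run_midpoints(conf, run)
  ctr <- sweep(mids, 2, colMeans(mids))
  ax <- svd(ctr, nu = 0, nv = 1)$v[, 1]
  if (sum(ax * (mids[nrow(mids), ] - mids[1, ])) < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}

#' Fit a duplex axis from backbone displacements (A form)
#'
#' The A-form helix axis does not pass through the base-pair centres, so the
#' axis is taken as the normal of the least-squares plane through the
#' successive backbone displacement vectors of both strands: for any regular
#' helix those displacements have a constant component along the axis and a
#' rotating in-plane component, so they lie in a plane whose normal is the
#' axis. Sign convention as in [fit_axis_b()].
#'
#' @param conf An `oxdna_conf`.
#' @param run k x 2 matrix of paired 0-based ids in run order (k >= 4).
#' @return Unit 3-vector.
#' @export
fit_axis_a <- function(conf, run) {
  if (nrow(run) < 4L) .stopf("A-form axis fit needs >= 4 base pairs")
  d1 <- diff(conf$positions[run[, 1] + 1L, , drop = FALSE])
  d2 <- diff(conf$positions[run[, 2] + 1L, , drop = FALSE])
  # run order advances both strands in the same spatial direction (strand 2
  # walks 3'-ward), so both displacement sets share the axial component
  disp <- rbind(d1, d2)
  ctr <- sweep(disp, 2, colMeans(disp))
  s <- svd(ctr, nu = 0)
  if (s$d[2] < 1e-8 * max(s$d[1], 1e-300) + 1e-12)
    .stopf("degenerate plane fit: backbone displacements are parallel")
  ax <- s$v[, 3]
  mids <- .run_midpoints(conf, run)
  if (sum(ax * (mids[nrow(mids), ] - mids[1, ])) < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}

#' Find duplexes in a configuration
#'
#' Identifies maximal runs of consecutive base pairs along antiparallel
#' strands and fits an axis through each run of at least `min_len` pairs.
#'
#' @param conf An `oxdna_conf`.
#' @param topo The matching `oxdna_topology`.
#' @param pairs Bonded pairs for this frame: a `designed_pairs` object or any
#'   2-column matrix of 0-based ids (e.g. from [detect_bonds()]).
#' @param min_len Minimum run length in bp (default 4).
#' @param form `"B"` (midpoint line fit) or `"A"` (backbone plane fit).
#' @return A data frame with one row per duplex: `strand1_start`,
#'   `strand1_end`, `strand2_start`, `strand2_end` (0-based ids),
#'   `length_bp`, axis components `axis_x/y/z` and midpoint `mid_x/y/z`
#'   (simulation units). A `runs` attribute holds the id matrices.
#' @export
find_duplexes <- function(conf, topo, pairs, min_len = 4L,
                          form = c("B", "A")) {
  form <- match.arg(form)
  runs <- .pair_runs(topo, pairs)
  runs <- runs[vapply(runs, nrow, integer(1)) >= min_len]
  rows <- lapply(runs, function(run) {
    ax <- if (form == "B") fit_axis_b(conf, run) else fit_axis_a(conf, run)
    mid <- colMeans(.run_midpoints(conf, run))
    k <- nrow(run)
    data.frame(strand1_start = run[1, 1], strand1_end = run[k, 1],
               strand2_start = run[1, 2], strand2_end = run[k, 2],
               length_bp = k,
               axis_x = ax[1], axis_y = ax[2], axis_z = ax[3],
               mid_x = mid[1], mid_y = mid[2], mid_z = mid[3])
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(strand1_start = integer(0), strand1_end = integer(0),
               strand2_start = integer(0), strand2_end = integer(0),
               length_bp = integer(0), axis_x = numeric(0),
               axis_y = numeric(0), axis_z = numeric(0),
               mid_x = numeric(0), mid_y = numeric(0), mid_z = numeric(0))
  attr(out, "runs") <- runs
  out
}

# Locate the run containing a probe id (either side); NULL if absent.
.run_with_id <- function(runs, id) {
  for (run in runs) if (id %in% run) return(run)
  NULL
}

.axis_angle_deg <- function(u, v, signed = FALSE) {
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  cs <- min(1, max(-1, if (signed) cs else abs(cs)))
  acos(cs) * 180 / pi
}

#' Interduplex angle statistics over a trajectory
#'
#' For each frame, locates the duplex containing each probe nucleotide id
#' (use an id at the edge of the duplex of interest, e.g. from a viewer
#' selection). When both duplexes exist, the angle between their fitted axes
#' is recorded. Because fitted axes carry an arbitrary sign, the default is
#' the unsigned angle `acos(|u . v|)` in [0, 90] degrees; `signed = TRUE`
#' keeps the orientation given by the strand-index sign convention, for
#' reflex junction angles.
#'
#' @param traj An `oxdna_traj`.
#' @param probe1,probe2 0-based nucleotide ids identifying the two duplexes.
#' @param pairs A `designed_pairs` object (assume the design is intact), a
#'   function `conf -> pairs` evaluated per frame (e.g. a bond detector), or
#'   `NULL` to detect bonds geometrically per frame.
#' @param form Axis fit used for both duplexes ("B" or "A").
#' @param min_len Minimum duplex length in bp.
#' @param signed Preserve axis sign (see above).
#' @return An `angle_series`: list with `angles_deg` (per frame, `NA` when
#'   either duplex is missing), `mean`, `median`, `sd` (over frames with
#'   both), and `fraction` (frames with both present / frames analysed).
#' @export
duplex_angle_series <- function(traj, probe1, probe2, pairs = NULL,
                                form = c("B", "A"), min_len = 4L,
                                signed = FALSE) {
  form <- match.arg(form)
  topo <- traj$topology
  pair_fun <- if (is.function(pairs)) pairs
    else if (is.null(pairs)) function(conf) detect_bonds(conf, topo)
    else function(conf) pairs
  F <- n_frames(traj)
  angles <- rep(NA_real_, F)
  for (k in seq_len(F)) {
    fr <- get_frame(traj, k)
    dup <- find_duplexes(fr, topo, pair_fun(fr), min_len = min_len,
                         form = form)
    runs <- attr(dup, "runs")
    r1 <- .run_with_id(runs, probe1)
    r2 <- .run_with_id(runs, probe2)
    if (is.null(r1) || is.null(r2)) next
    u <- if (form == "B") fit_axis_b(fr, r1) else fit_axis_a(fr, r1)
    v <- if (form == "B") fit_axis_b(fr, r2) else fit_axis_a(fr, r2)
    angles[k] <- .axis_angle_deg(u, v, signed)
  }
  ok <- !is.na(angles)
  structure(list(
    angles_deg = angles,
    mean = if (any(ok)) mean(angles[ok]) else NA_real_,
    median = if (any(ok)) stats::median(angles[ok]) else NA_real_,
    sd = if (any(ok)) stats::sd(angles[ok]) else NA_real_,
    fraction = mean(ok)
  ), class = "angle_series")
}

#' Per-frame distances between nucleotide pairs
#'
#' Euclidean centre-of-mass distance per frame for each requested id pair,
#' reported in nanometres, with optional minimum-image correction for pairs
#' straddling the periodic box.
#'
#' @param traj An `oxdna_traj`.
#' @param id_pairs 2-column matrix of 0-based ids (one row per pair).
#' @param use_minimum_image Apply the minimum-image convention using each
#'   frame's box.
#' @return List with `distances_nm` (F x n_pairs matrix, pairs in input
#'   order) and `summary` (data frame of mean/median/sd per pair, nm).
#' @export
distance_series <- function(traj, id_pairs, use_minimum_image = FALSE) {
  id_pairs <- matrix(as.integer(id_pairs), ncol = 2)
  F <- n_frames(traj)
  n <- traj$topology$n
  i <- .id_idx(id_pairs[, 1], n); j <- .id_idx(id_pairs[, 2], n)
  out <- matrix(NA_real_, F, nrow(id_pairs))
  for (k in seq_len(F)) {
    fr <- get_frame(traj, k)
    d <- fr$positions[i, , drop = FALSE] - fr$positions[j, , drop = FALSE]
    if (use_minimum_image) {
      box <- matrix(fr$box, nrow(d), 3, byrow = TRUE)
      d <- d - box * round(d / box)
    }
    out[k, ] <- sqrt(rowSums(d^2)) * .LENGTH_NM
  }
  list(distances_nm = out,
       summary = data.frame(
         i = id_pairs[, 1], j = id_pairs[, 2],
         mean = apply(out, 2, mean), median = apply(out, 2, stats::median),
         sd = apply(out, 2, stats::sd)))
}
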