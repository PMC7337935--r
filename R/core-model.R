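# Core domain types: topology, configuration, trajectory.
#
# Conventions used throughout the package:
#  * nucleotide global ids are 0-based (the oxDNA file convention, shared by
#    index files, designed-pair files and viewer selection exports);
#  * frame indices are 1-based (R convention);
#  * internal math is in simulation length units; user-facing distances are
#    reported in nm via the 0.8518 nm/unit conversion.

#' Unit conventions of the coarse-grained model
#'
#' One oxDNA simulation length unit corresponds to 0.8518 nm; energies are in
#' simulation units (of order k_B T at simulation temperature) and are never
#' converted. `pos_base` is the offset of the base interaction site from the
#' nucleotide centre along the `a1` versor for the DNA model; the RNA model
#' variant uses a different offset, which is why every function that needs it
#' takes `pos_base` as an argument.
#'
#' @return A list with elements `length_nm` (nm per simulation length unit)
#'   and `pos_base` (default base-site offset, simulation units).
#' @export
oxdna_units <- function() {
  list(length_nm = 0.8518, pos_base = 0.4)
}

# nm per simulation length unit (internal constant mirror of oxdna_units()).
.LENGTH_NM <- 0.8518
# Backbone -> base-site offset along a1, simulation units (DNA model).
.POS_BASE <- 0.4

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Map 0-based global ids to 1-based row indices, with bounds checking.
.id_idx <- function(ids, n, what = "nucleotide id") {
  ids <- as.integer(ids)
  bad <- ids < 0L | ids >= n | is.na(ids)
  if (any(bad)) {
    .stopf("invalid %s: %s (valid range 0..%d)", what,
           paste(ids[bad], collapse = ", "), n - 1L)
  }
  ids + 1L
}

#' Construct a topology
#'
#' A topology records, for every nucleotide, its strand membership, base
#' identity and 3'/5' neighbours. Connectivity must be mutual (if `b` is the
#' 5' neighbour of `a` then `a` is the 3' neighbour of `b`) and each strand
#' must form a single path, or a single cycle for circular strands; the
#' circular flag per strand is derived from the connectivity.
#'
#' @param strand_id Integer vector, strand id per nucleotide.
#' @param base Character vector of base symbols. A, C, G, T, U are understood
#'   by complementarity checks; other symbols (e.g. oxDNA integer base codes)
#'   are carried through opaquely and treated as non-complementary.
#' @param neighbor3,neighbor5 Integer vectors of 0-based global ids of the 3'
#'   and 5' neighbour, `NA` for none.
#' @return An object of class `oxdna_topology` with fields `n`, `n_strands`,
#'   `strand_id`, `base`, `neighbor3`, `neighbor5`, `strand_ids` (the distinct
#'   strand ids in first-seen order) and `circular` (named logical per strand).
#' @export
topology <- function(strand_id, base, neighbor3, neighbor5) {
  n <- length(strand_id)
  if (length(base) != n || length(neighbor3) != n || length(neighbor5) != n)
    .stopf("topology fields must all have length %d", n)
  topo <- structure(
    list(
      n = as.integer(n),
      strand_id = as.integer(strand_id),
      base = toupper(as.character(base)),
      neighbor3 = as.integer(neighbor3),
      neighbor5 = as.integer(neighbor5)
    ),
    class = "oxdna_topology"
  )
  topo$strand_ids <- unique(topo$strand_id)
  topo$n_strands <- length(topo$strand_ids)
  topo$circular <- .derive_circular(topo)
  validate_topology(topo)
  topo
}

# Walk each strand; returns named logical vector (one entry per strand).
.derive_circular <- function(topo) {
  circ <- logical(topo$n_strands)
  names(circ) <- as.character(topo$strand_ids)
  for (k in seq_along(topo$strand_ids)) {
    members <- which(topo$strand_id == topo$strand_ids[k]) - 1L
    n3 <- topo$neighbor3[members + 1L]
    circ[k] <- !anyNA(n3) && length(members) > 0L
  }
  circ
}

#' Validate a topology
#'
#' Checks mutual neighbour links, no self-neighbouring, strand-local
#' connectivity and that every strand is a single path or single cycle.
#'
#' @param topo An `oxdna_topology`.
#' @return `topo`, invisibly; errors describe the offending nucleotides.
#' @export
validate_topology <- function(topo) {
  n <- topo$n
  for (field in c("neighbor3", "neighbor5")) {
    v <- topo[[field]]
    ok <- is.na(v) | (v >= 0L & v < n)
    if (!all(ok))
      .stopf("topology: %s out of range for ids %s", field,
             paste(which(!ok) - 1L, collapse = ", "))
  }
  if (any(!is.na(topo$neighbor3) & topo$neighbor3 == seq_len(n) - 1L) ||
      any(!is.na(topo$neighbor5) & topo$neighbor5 == seq_len(n) - 1L))
    .stopf("topology: a nucleotide cannot neighbour itself")
  # mutuality: a --3'--> b requires b --5'--> a
  has3 <- which(!is.na(topo$neighbor3))
  b <- topo$neighbor3[has3]
  bad <- is.na(topo$neighbor5[b + 1L]) | topo$neighbor5[b + 1L] != has3 - 1L
  if (any(bad))
    .stopf("topology: asymmetric 3' link at ids %s",
           paste(has3[bad] - 1L, collapse = ", "))
  has5 <- which(!is.na(topo$neighbor5))
  b <- topo$neighbor5[has5]
  bad <- is.na(topo$neighbor3[b + 1L]) | topo$neighbor3[b + 1L] != has5 - 1L
  if (any(bad))
    .stopf("topology: asymmetric 5' link at ids %s",
           paste(has5[bad] - 1L, collapse = ", "))
  # neighbours stay within the strand, and each strand is one path / one cycle
  for (k in seq_along(topo$strand_ids)) {
    sid <- topo$strand_ids[k]
    members <- which(topo$strand_id == sid) - 1L
    nbrs <- c(topo$neighbor3[members + 1L], topo$neighbor5[members + 1L])
    nbrs <- nbrs[!is.na(nbrs)]
    if (!all(topo$strand_id[nbrs + 1L] == sid))
      .stopf("topology: strand %s links to another strand", sid)
    starts <- sum(is.na(topo$neighbor3[members + 1L]))
    ends <- sum(is.na(topo$neighbor5[members + 1L]))
    if (starts != ends || starts > 1L)
      .stopf("topology: strand %s is not a single path or cycle", sid)
    # walk 3'->5' and require full coverage (catches multiple cycles/paths)
    cur <- if (starts == 1L)
      members[is.na(topo$neighbor3[members + 1L])]
    else members[1L]
    seen <- integer(0)
    repeat {
      seen <- c(seen, cur)
      nxt <- topo$neighbor5[cur + 1L]
      if (is.na(nxt) || nxt == seen[1L]) break
      if (length(seen) > length(members))
        .stopf("topology: strand %s connectivity is not a simple chain", sid)
      cur <- nxt
    }
    if (length(seen) != length(members))
      .stopf("topology: strand %s splits into multiple fragments", sid)
  }
  invisible(topo)
}

#' Strand sequence in 5' to 3' order
#'
#' @param topo An `oxdna_topology`.
#' @param strand A strand id (as stored in `topo$strand_id`).
#' @return Character vector of base symbols, 5' to 3'. Circular strands start
#'   at the member with the lowest global id.
#' @export
strand_sequence <- function(topo, strand) {
  members <- which(topo$strand_id == strand) - 1L
  if (length(members) == 0L) .stopf("no strand with id %s", strand)
  start <- members[is.na(topo$neighbor5[members + 1L])]
  if (length(start) == 0L) start <- min(members)  # circular: lowest id first
  seq_ids <- integer(0)
  cur <- start
  repeat {
    seq_ids <- c(seq_ids, cur)
    nxt <- topo$neighbor3[cur + 1L]
    if (is.na(nxt) || nxt == start) break
    cur <- nxt
  }
  topo$base[seq_ids + 1L]
}

#' Construct a configuration
#'
#' A configuration is one frame of a trajectory: per-nucleotide positions and
#' the two orientation versors `a1` (towards the base site) and `a3` (along
#' the stacking axis), plus time/box/energy metadata. Versors must be unit
#' length within 1e-5 and mutually orthogonal within 1e-4.
#'
#' @param positions N x 3 numeric matrix, simulation length units.
#' @param a1,a3 N x 3 matrices of unit versors.
#' @param time Time step count of the frame.
#' @param box Simulation box, 3-vector.
#' @param energies 3-vector of energy metadata (total, potential, kinetic);
#'   carried through, never recomputed.
#' @return An object of class `oxdna_conf`.
#' @export
configuration <- function(positions, a1, a3, time = 0,
                          box = c(100, 100, 100), energies = c(0, 0, 0)) {
  conf <- structure(
    list(time = as.numeric(time), box = as.numeric(box),
         energies = as.numeric(energies),
         positions = as.matrix(positions), a1 = as.matrix(a1),
         a3 = as.matrix(a3)),
    class = "oxdna_conf"
  )
  validate_configuration(conf)
  conf
}

#' Validate a configuration
#'
#' @param conf An `oxdna_conf`.
#' @param topo Optional `oxdna_topology`; when given, the particle count must
#'   match.
#' @return `conf`, invisibly.
#' @export
validate_configuration <- function(conf, topo = NULL) {
  n <- nrow(conf$positions)
  if (ncol(conf$positions) != 3L || !all(dim(conf$a1) == c(n, 3L)) ||
      !all(dim(conf$a3) == c(n, 3L)))
    .stopf("configuration: positions/a1/a3 must be N x 3 with equal N")
  if (!is.null(topo) && n != topo$n)
    .stopf("configuration has %d particles but topology declares %d",
           n, topo$n)
  if (length(conf$box) != 3L)
    .stopf("configuration: box must be a 3-vector")
  n1 <- sqrt(rowSums(conf$a1^2))
  n3 <- sqrt(rowSums(conf$a3^2))
  if (any(abs(n1 - 1) > 1e-5) || any(abs(n3 - 1) > 1e-5))
    .stopf("configuration: non-unit versor (max deviation %.2e)",
           max(abs(c(n1, n3) - 1)))
  dots <- abs(rowSums(conf$a1 * conf$a3))
  if (any(dots > 1e-4))
    .stopf("configuration: a1/a3 not orthogonal (max |a1.a3| = %.2e)",
           max(dots))
  invisible(conf)
}

#' Number of particles in a configuration
#' @param conf An `oxdna_conf`.
#' @return Integer particle count.
#' @export
n_particles <- function(conf) nrow(conf$positions)

#' Base interaction site positions
#'
#' The base site sits at `position + pos_base * a1`; hydrogen bonds act
#' between base sites of paired nucleotides.
#'
#' @param conf An `oxdna_conf`.
#' @param ids 0-based global ids (default all).
#' @param pos_base Offset along `a1`, simulation units. The default is the
#'   DNA-model value; pass the appropriate offset for the RNA model.
#' @return length(ids) x 3 matrix of base-site positions.
#' @export
base_site_position <- function(conf, ids = seq_len(n_particles(conf)) - 1L,
                               pos_base = .POS_BASE) {
  i <- .id_idx(ids, n_particles(conf))
  conf$positions[i, , drop = FALSE] + pos_base * conf$a1[i, , drop = FALSE]
}

#' Second orientation versor
#'
#' `a2 = a3 x a1`, computed on demand (never stored).
#'
#' @param conf An `oxdna_conf`.
#' @return N x 3 matrix.
#' @export
a2_versors <- function(conf) {
  cbind(conf$a3[, 2] * conf$a1[, 3] - conf$a3[, 3] * conf$a1[, 2],
        conf$a3[, 3] * conf$a1[, 1] - conf$a3[, 1] * conf$a1[, 3],
        conf$a3[, 1] * conf$a1[, 2] - conf$a3[, 2] * conf$a1[, 1])
}

#' Construct an in-memory trajectory
#'
#' @param topo An `oxdna_topology`.
#' @param frames List of `oxdna_conf`, all validated against `topo`.
#' @return An object of class `oxdna_traj`.
#' @export
trajectory <- function(topo, frames) {
  for (f in frames) validate_configuration(f, topo)
  structure(list(topology = topo, frames = frames,
                 n_frames = length(frames)),
            class = "oxdna_traj")
}

#' Number of frames in a trajectory
#' @param traj An `oxdna_traj`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) traj$n_frames

#' Retrieve one frame of a trajectory
#'
#' Frames are 1-based. For file-backed trajectories (see [read_trajectory()])
#' the frame is parsed on demand via its recorded byte offset, so access is
#' O(frame size) regardless of position in the file.
#'
#' @param traj An `oxdna_traj`.
#' @param k Frame index, 1-based.
#' @return An `oxdna_conf`.
#' @export
get_frame <- function(traj, k) {
  k <- as.integer(k)
  if (k < 1L || k > traj$n_frames)
    .stopf("frame index %d out of range 1..%d", k, traj$n_frames)
  if (!is.null(traj$frames)) return(traj$frames[[k]])
  .read_frame_at(traj, k)
}

#' Extract all frames as a list
#'
#' Materialises a file-backed trajectory; in-memory trajectories return their
#' frame list directly.
#'
#' @param traj An `oxdna_traj`.
#' @return List of `oxdna_conf`.
#' @export
traj_frames <- function(traj) {
  if (!is.null(traj$frames)) return(traj$frames)
  lapply(seq_len(traj$n_frames), function(k) get_frame(traj, k))
}

#' @export
print.oxdna_topology <- function(x, ...) {
  cat(sprintf("oxDNA topology: %d nucleotides, %d strand(s)%s\n", x$n,
              x$n_strands,
              if (any(x$circular)) sprintf(" (%d circular)", sum(x$circular))
              else ""))
  invisible(x)
}

#' @export
print.oxdna_conf <- function(x, ...) {
  cat(sprintf("oxDNA configuration: %d particles, t = %g\n",
              n_particles(x), x$time))
  invisible(x)
}

#' @export
print.oxdna_traj <- function(x, ...) {
  cat(sprintf("oxDNA trajectory: %d frames x %d particles (%s)\n",
              x$n_frames, x$topology$n,
              if (is.null(x$frames)) "file-backed" else "in-memory"))
  invisible(x)
}
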