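# Synthetic structures and trajectories with known ground truth.
#
# The generators stand in for simulator output: ideal A-/B-form helices,
# duplexes interrupted by single-stranded gaps, Gaussian positional noise,
# a planted collective motion mode, and two-state mixtures. They make every
# analysis testable without running oxDNA; they do not attempt
# thermodynamically faithful sampling or sequence-dependent structure.

# Default helix geometry, simulation length units.
#  B-form: rise 0.3897 (~0.34 nm), twist 34.3 deg/bp, backbone radius 0.6.
#  A-form: rise ~0.28 nm equivalent, twist 32.7 deg/bp, base-pair midpoints
#  displaced 0.25 units off the axis so the plane-fit axis route is genuinely
#  exercised.
.HELIX_DEFAULTS <- list(
  B = list(rise = 0.3897, twist = 34.3, radius = 0.6, axis_disp = 0),
  A = list(rise = 0.28 / 0.8518, twist = 32.7, radius = 0.6, axis_disp = 0.25)
)

.COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G", U = "A")

# Evaluate expr with a private RNG stream; caller's RNG state is untouched.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Geometry of one straight helix along +z. bp positions are indexed 0-based;
# returns positions/versors for one nucleotide of each strand at each bp slot.
.helix_frame <- function(bp_index, geom) {
  th <- bp_index * geom$twist * pi / 180
  radial <- cbind(cos(th), sin(th), 0)
  z <- cbind(0, 0, bp_index * geom$rise)
  mid_off <- geom$axis_disp * radial
  list(
    pos1 = z + mid_off + geom$radius * radial,
    pos2 = z + mid_off - geom$radius * radial,
    a1_1 = -radial,
    a1_2 = radial
  )
}

#' Build an ideal duplex
#'
#' Constructs a straight double helix along +z with two antiparallel,
#' complementary strands. Base pair `i` joins nucleotide `i` of strand 1
#' (global ids `0..n_bp-1`, listed 3' to 5') with nucleotide `n_bp-1-i` of
#' strand 2 (ids `n_bp..2*n_bp-1`). For the B form the base-pair midpoints
#' lie exactly on the z axis; the A form displaces them radially so that the
#' midpoint line is a narrow helix, as in real A-form geometry. `a1` versors
#' of paired bases are exactly antiparallel.
#'
#' @param n_bp Number of base pairs (>= 1).
#' @param form `"B"` or `"A"`.
#' @param rise,twist,radius Helix parameters (simulation length units and
#'   degrees per bp); defaults are the canonical values for the chosen form.
#' @param sequence Optional strand-1 base string (5' to 3'), length `n_bp`;
#'   default is a repeating ATGC pattern.
#' @return List with elements `topology`, `configuration`, `pairs`
#'   (a `designed_pairs` of size `n_bp`).
#' @export
build_duplex <- function(n_bp, form = c("B", "A"), rise = NULL, twist = NULL,
                         radius = NULL, sequence = NULL) {
  form <- match.arg(form)
  geom <- .HELIX_DEFAULTS[[form]]
  if (!is.null(rise)) geom$rise <- rise
  if (!is.null(twist)) geom$twist <- twist
  if (!is.null(radius)) geom$radius <- radius
  if (n_bp < 1) .stopf("n_bp must be >= 1")
  if (geom$rise <= 0 || geom$twist <= 0 || geom$twist >= 360)
    .stopf("invalid helix parameters")
  seq1 <- if (is.null(sequence)) rep_len(c("A", "T", "G", "C"), n_bp)
    else strsplit(toupper(sequence), "")[[1]]
  if (length(seq1) != n_bp)
    .stopf("sequence length %d != n_bp %d", length(seq1), n_bp)

  n <- as.integer(n_bp)
  # strand 1: ids 0..n-1 in file (3'->5') order; sequence given 5'->3'
  base1 <- rev(seq1)
  # strand 2: ids n..2n-1; id n+k sits at bp slot n-1-k, whose strand-1 base
  # is seq1[k+1], so strand-2 bases in id order are simply the complements
  # of seq1 in order.
  base2 <- unname(.COMPLEMENT[seq1])
  if (anyNA(base2)) .stopf("sequence contains bases without a complement")
  topo <- topology(
    strand_id = rep(1:2, each = n),
    base = c(base1, base2),
    neighbor3 = c(NA, seq_len(n - 1L) - 1L, NA, n + seq_len(n - 1L) - 1L),
    neighbor5 = c(seq_len(n - 1L), NA, n + seq_len(n - 1L), NA)
  )
  slots1 <- 0:(n - 1)               # bp slot of strand-1 id i
  slots2 <- (n - 1):0               # bp slot of strand-2 id n+k
  g1 <- .helix_frame(slots1, geom)
  g2 <- .helix_frame(slots2, geom)
  pos <- rbind(g1$pos1, g2$pos2)
  a1 <- rbind(g1$a1_1, g2$a1_2)
  a3 <- rbind(matrix(rep(c(0, 0, 1), each = n), ncol = 3),
              matrix(rep(c(0, 0, -1), each = n), ncol = 3))
  conf <- configuration(pos, a1, a3, box = rep(2 * n * geom$rise + 20, 3))
  pairs <- designed_pairs(slots1, 2L * n - 1L - slots1)
  list(topology = topo, configuration = conf, pairs = pairs)
}

#' Build a duplex interrupted by single-stranded gaps
#'
#' Strand 1 is one continuous strand running the full length; the
#' complementary side is split into one short strand per duplexed segment,
#' leaving `gap_nt` unpaired strand-1 nucleotides between consecutive
#' segments. Designed pairs cover only the duplexed bases. With a single
#' segment the output is an uninterrupted duplex identical in geometry to
#' [build_duplex()].
#'
#' @param segments Integer vector of duplex segment lengths in bp. The
#'   default, `c(15, 15, 10)` with `gap_nt = 5`, gives a 50-nucleotide
#'   strand-1 pattern with two 5-nt gaps.
#' @param gap_nt Gap length between consecutive segments, nucleotides.
#' @param form,rise,twist,radius As in [build_duplex()].
#' @return List with `topology`, `configuration`, `pairs`.
#' @export
build_interrupted_duplex <- function(segments = c(15, 15, 10), gap_nt = 5,
                                     form = c("B", "A"), rise = NULL,
                                     twist = NULL, radius = NULL) {
  form <- match.arg(form)
  geom <- .HELIX_DEFAULTS[[form]]
  if (!is.null(rise)) geom$rise <- rise
  if (!is.null(twist)) geom$twist <- twist
  if (!is.null(radius)) geom$radius <- radius
  segments <- as.integer(segments)
  if (any(segments < 1) || (length(segments) > 1 && gap_nt < 1))
    .stopf("segments and gaps must be positive")
  n_seg <- length(segments)
  gap_nt <- if (n_seg > 1) as.integer(gap_nt) else 0L
  L <- sum(segments) + gap_nt * (n_seg - 1L)  # strand-1 length
  # bp slot of each strand-1 nucleotide (position along the helix)
  seg_start <- cumsum(c(0L, segments[-n_seg] + gap_nt))  # slot of segment k
  paired_slots <- unlist(lapply(seq_len(n_seg), function(k)
    seg_start[k] + 0:(segments[k] - 1L)))

  seq1 <- rep_len(c("A", "T", "G", "C"), L)  # 5'->3'
  base_by_slot1 <- rev(seq1)                 # strand-1 base at slot s = base of id s
  # strand 1: ids 0..L-1, file order 3'->5', id i at slot i
  strand_id <- rep(1L, L)
  base <- base_by_slot1
  nb3 <- c(NA, 0:(L - 2L))
  nb5 <- c(1:(L - 1L), NA)
  # complementary strands: one per segment, ids appended; each runs
  # antiparallel so within segment k (slots s0..s1) the first listed id
  # pairs slot s1 ... wait: keep the build_duplex convention per segment.
  next_id <- L
  pair_i <- integer(0); pair_j <- integer(0)
  slots2 <- integer(0)
  for (k in seq_len(n_seg)) {
    m <- segments[k]
    ids <- next_id + 0:(m - 1L)
    sl <- seg_start[k] + (m - 1L):0          # id next_id + t sits at slot s1 - t
    strand_id <- c(strand_id, rep(k + 1L, m))
    base <- c(base, unname(.COMPLEMENT[base_by_slot1[sl + 1L]]))
    nb3 <- c(nb3, NA, ids[-m])
    nb5 <- c(nb5, ids[-1L], NA)
    pair_i <- c(pair_i, sl)                  # strand-1 id at slot sl is sl
    pair_j <- c(pair_j, ids)
    slots2 <- c(slots2, sl)
    next_id <- next_id + m
  }
  topo <- topology(strand_id, base, nb3, nb5)
  g1 <- .helix_frame(0:(L - 1L), geom)
  g2 <- .helix_frame(slots2, geom)
  pos <- rbind(g1$pos1, g2$pos2)
  a1 <- rbind(g1$a1_1, g2$a1_2)
  n2 <- length(slots2)
  a3 <- rbind(matrix(rep(c(0, 0, 1), each = L), ncol = 3),
              matrix(rep(c(0, 0, -1), each = n2), ncol = 3))
  conf <- configuration(pos, a1, a3, box = rep(2 * L * geom$rise + 20, 3))
  list(topology = topo, configuration = conf,
       pairs = designed_pairs(pair_i, pair_j))
}

# Project an N x 3 displacement field onto the complement of the six
# rigid-body modes of `positions` (3 translations, 3 infinitesimal rotations
# about the centroid), via Gram-Schmidt on the flattened 3N-vectors.
.remove_rigid_modes <- function(field, positions) {
  n <- nrow(positions)
  ctr <- sweep(positions, 2, colMeans(positions))
  basis <- cbind(
    as.vector(t(matrix(rep(c(1, 0, 0), each = n), ncol = 3))),
    as.vector(t(matrix(rep(c(0, 1, 0), each = n), ncol = 3))),
    as.vector(t(matrix(rep(c(0, 0, 1), each = n), ncol = 3))),
    as.vector(t(cbind(0, -ctr[, 3], ctr[, 2]))),
    as.vector(t(cbind(ctr[, 3], 0, -ctr[, 1]))),
    as.vector(t(cbind(-ctr[, 2], ctr[, 1], 0))))
  q <- qr.Q(qr(basis))
  v <- as.vector(t(field))
  v <- v - q %*% crossprod(q, v)
  matrix(v, ncol = 3, byrow = TRUE)
}

# Rotate row vectors v by per-row axis k (unit rows) and angle phi (Rodrigues).
.rotate_rows <- function(v, k, phi) {
  cp <- cos(phi); sp <- sin(phi)
  kxv <- cbind(k[, 2] * v[, 3] - k[, 3] * v[, 2],
               k[, 3] * v[, 1] - k[, 1] * v[, 3],
               k[, 1] * v[, 2] - k[, 2] * v[, 1])
  kdv <- rowSums(k * v)
  v * cp + kxv * sp + k * kdv * (1 - cp)
}

#' Perturb a configuration into a noisy trajectory
#'
#' Each frame adds iid zero-mean Gaussian displacements (per axis, std
#' `sigma`) to every position, and rotates each nucleotide's versor pair by a
#' random axis with angle ~ Normal(0, (sigma/rise)^2) so positional and
#' orientational noise stay commensurate. Deterministic given `seed`.
#'
#' @param conf An `oxdna_conf`.
#' @param topo The matching `oxdna_topology` (frames validate against it).
#' @param sigma Per-axis displacement std, simulation length units.
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @return An in-memory `oxdna_traj` of `n_frames` frames.
#' @export
perturb <- function(conf, topo, sigma, n_frames, seed = 1) {
  if (sigma < 0 || n_frames < 1) .stopf("sigma >= 0 and n_frames >= 1 required")
  n <- n_particles(conf)
  ang_sd <- sigma / .HELIX_DEFAULTS$B$rise
  frames <- .with_seed(seed, lapply(seq_len(n_frames), function(f) {
    pos <- conf$positions +
      matrix(stats::rnorm(3 * n, sd = sigma), ncol = 3)
    if (sigma > 0) {
      ax <- matrix(stats::rnorm(3 * n), ncol = 3)
      ax <- ax / sqrt(rowSums(ax^2))
      phi <- stats::rnorm(n, sd = ang_sd)
      a1 <- .rotate_rows(conf$a1, ax, phi)
      a3 <- .rotate_rows(conf$a3, ax, phi)
      # guard against accumulated round-off
      a3 <- a3 / sqrt(rowSums(a3^2))
      a1 <- a1 - rowSums(a1 * a3) * a3
      a1 <- a1 / sqrt(rowSums(a1^2))
    } else {
      a1 <- conf$a1; a3 <- conf$a3
    }
    configuration(pos, a1, a3, time = f - 1, box = conf$box,
                  energies = conf$energies)
  }))
  trajectory(topo, frames)
}

#' Trajectory with one planted collective motion mode
#'
#' Frame f has positions `base + c_f * mode + noise`, with amplitude
#' `c_f ~ Normal(0, amp_std^2)` and iid per-axis Gaussian noise. Because
#' superposition removes rigid-body motion before any mode analysis, a
#' planted mode is only well-defined ground truth if it is an internal
#' deformation: the supplied field is therefore projected onto the
#' complement of the six rigid-body modes (translations and infinitesimal
#' rotations about the centroid) and then normalised to unit Frobenius norm.
#' Versors are left untouched (analyses of motion modes use positions only).
#'
#' @param conf Base `oxdna_conf`.
#' @param topo Matching topology.
#' @param mode N x 3 displacement field (normalised internally).
#' @param amp_std Std of the mode amplitude, simulation length units.
#' @param noise Per-axis isotropic noise std.
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @return List with `trajectory` (in-memory `oxdna_traj`), `mode` (the unit
#'   field actually used) and `amplitudes` (the c_f drawn).
#' @export
planted_mode_trajectory <- function(conf, topo, mode, amp_std, noise,
                                    n_frames, seed = 1) {
  mode <- as.matrix(mode)
  if (!all(dim(mode) == dim(conf$positions)))
    .stopf("mode must be N x 3 matching the configuration")
  mode <- .remove_rigid_modes(mode, conf$positions)
  if (sum(mode^2) < 1e-20)
    .stopf("mode is a pure rigid-body motion; no internal deformation left")
  mode <- mode / sqrt(sum(mode^2))
  n <- n_particles(conf)
  out <- .with_seed(seed, {
    amps <- stats::rnorm(n_frames, sd = amp_std)
    frames <- lapply(seq_len(n_frames), function(f) {
      pos <- conf$positions + amps[f] * mode +
        matrix(stats::rnorm(3 * n, sd = noise), ncol = 3)
      configuration(pos, conf$a1, conf$a3, time = f - 1, box = conf$box)
    })
    list(trajectory = trajectory(topo, frames), amplitudes = amps)
  })
  list(trajectory = out$trajectory, mode = mode, amplitudes = out$amplitudes)
}

#' Two-state mixture trajectory
#'
#' Each frame is drawn from configuration A (probability `frac_A`) or B, plus
#' iid Gaussian positional noise. Ground-truth labels are returned for
#' validating conformational clustering.
#'
#' @param confA,confB Two `oxdna_conf` over the same topology.
#' @param topo Matching topology.
#' @param frac_A Probability of state A per frame.
#' @param noise Per-axis noise std.
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @return List with `trajectory` and `labels` (character "A"/"B" per frame).
#' @export
two_state_trajectory <- function(confA, confB, topo, frac_A, noise,
                                 n_frames, seed = 1) {
  if (!all(dim(confA$positions) == dim(confB$positions)))
    .stopf("configurations A and B must have the same particle count")
  n <- n_particles(confA)
  .with_seed(seed, {
    labels <- ifelse(stats::runif(n_frames) < frac_A, "A", "B")
    frames <- lapply(seq_len(n_frames), function(f) {
      src <- if (labels[f] == "A") confA else confB
      pos <- src$positions + matrix(stats::rnorm(3 * n, sd = noise), ncol = 3)
      configuration(pos, src$a1, src$a3, time = f - 1, box = src$box)
    })
    list(trajectory = trajectory(topo, frames), labels = labels)
  })
}
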