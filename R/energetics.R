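# Hydrogen-bond detection, designed-pair occupancy and mean-energy overlays.
#
# The full coarse-grained force field is deliberately not reimplemented:
# energy-based detection consumes an interaction table produced externally by
# the simulation engine, while the geometric detector makes the occupancy
# logic fully testable on synthetic structures.

.WC <- list(A = c("T", "U"), T = "A", U = "A", G = "C", C = "G")
.WOBBLE <- list(G = c("C", "U", "T"), U = c("A", "G"), T = c("A", "G"))

.complementary <- function(b1, b2, wobble = FALSE) {
  tab <- if (wobble) utils::modifyList(.WC, .WOBBLE) else .WC
  ok1 <- !is.null(tab[[b1]]) && b2 %in% tab[[b1]]
  ok1
}

#' Hydrogen-bond detection criterion
#'
#' Two detection routes: `"energy"` reads hydrogen-bond energies from an
#' interaction table and declares a bond when the pair potential is below the
#' threshold (default -0.1 simulation energy units, about 10 percent of the
#' equilibrium base-pairing energy); `"geometric"` declares a bond when base
#' interaction sites are within `dist_cutoff`, the bases are complementary,
#' and the `a1` versors are antiparallel (`a1 . a1' < antiparallel_cutoff`).
#'
#' @param mode `"geometric"` or `"energy"`.
#' @param energy_threshold Bond threshold, simulation energy units (< 0).
#' @param dist_cutoff Base-site distance cutoff, simulation length units.
#' @param antiparallel_cutoff Upper bound on `a1 . a1'` (negative).
#' @param pos_base Base-site offset along `a1` (see [base_site_position()]).
#' @param wobble Also accept G-U/G-T wobble complementarity (RNA).
#' @return A `bond_criterion` list.
#' @export
bond_criterion <- function(mode = c("geometric", "energy"),
                           energy_threshold = -0.1, dist_cutoff = 0.85,
                           antiparallel_cutoff = -0.7, pos_base = .POS_BASE,
                           wobble = FALSE) {
  mode <- match.arg(mode)
  if (mode == "energy" && energy_threshold >= 0)
    .stopf("energy_threshold must be negative")
  structure(list(mode = mode, energy_threshold = energy_threshold,
                 dist_cutoff = dist_cutoff,
                 antiparallel_cutoff = antiparallel_cutoff,
                 pos_base = pos_base, wobble = wobble),
            class = "bond_criterion")
}

#' Read an interaction table
#'
#' Tab-separated with header columns `frame`, `i`, `j`, `kind`, `energy`:
#' one row per pairwise interaction per frame, energies in simulation units.
#' `frame` is 1-based; hydrogen-bond rows have `kind == "HB"`.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `interaction_table`.
#' @export
read_interaction_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("frame", "i", "j", "kind", "energy")
  if (!all(need %in% names(df)))
    .stopf("interaction table %s must have columns %s", path,
           paste(need, collapse = ", "))
  if (!all(is.finite(df$energy)))
    .stopf("interaction table %s: non-finite energies", path)
  structure(df, class = c("interaction_table", "data.frame"))
}

#' Detect hydrogen bonds in one configuration
#'
#' Applies the criterion and enforces one bond per base (an involution):
#' when a base qualifies for several bonds, the lowest-energy (energy mode)
#' or closest (geometric mode) candidate wins.
#'
#' @param conf An `oxdna_conf`.
#' @param topo The matching `oxdna_topology`.
#' @param criterion A [bond_criterion()].
#' @param energies In energy mode, the interaction-table rows for this frame.
#' @return 2-column integer matrix of bonded 0-based id pairs (`i < j`),
#'   sorted by first id.
#' @export
detect_bonds <- function(conf, topo, criterion = bond_criterion(),
                         energies = NULL) {
  if (criterion$mode == "energy") {
    if (is.null(energies))
      .stopf("energy-mode bond detection requires an interaction table slice")
    rows <- energies[energies$kind == "HB" &
                     energies$energy < criterion$energy_threshold, ,
                     drop = FALSE]
    cand <- cbind(pmin(rows$i, rows$j), pmax(rows$i, rows$j))
    score <- rows$energy
  } else {
    sites <- base_site_position(conf, pos_base = criterion$pos_base)
    d <- as.matrix(stats::dist(sites))
    dots <- conf$a1 %*% t(conf$a1)
    hit <- which(upper.tri(d) & d <= criterion$dist_cutoff &
                 dots < criterion$antiparallel_cutoff, arr.ind = TRUE)
    if (nrow(hit)) {
      comp <- vapply(seq_len(nrow(hit)), function(r)
        .complementary(topo$base[hit[r, 1]], topo$base[hit[r, 2]],
                       criterion$wobble) ||
        .complementary(topo$base[hit[r, 2]], topo$base[hit[r, 1]],
                       criterion$wobble),
        logical(1))
      hit <- hit[comp, , drop = FALSE]
    }
    cand <- cbind(hit[, 1] - 1L, hit[, 2] - 1L)
    score <- d[hit]
  }
  if (is.null(cand) || nrow(cand) == 0L)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j"))))
  ord <- order(score)  # best (closest / most negative) first
  taken <- logical(topo$n)
  keep <- logical(nrow(cand))
  for (r in ord) {
    a <- cand[r, 1] + 1L; b <- cand[r, 2] + 1L
    if (!taken[a] && !taken[b]) {
      keep[r] <- TRUE; taken[a] <- TRUE; taken[b] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out[, 1]), , drop = FALSE]
  colnames(out) <- c("i", "j")
  out
}

#' Designed base-pair occupancy over a trajectory
#'
#' For each designed pair, the fraction of frames in which it is detected as
#' hydrogen-bonded; per nucleotide, its pair's fraction. Nucleotides with no
#' designed complement have occupancy exactly 0.
#'
#' @param traj An `oxdna_traj`.
#' @param designed A `designed_pairs` object.
#' @param criterion A [bond_criterion()].
#' @param energies Full `interaction_table` (with its `frame` column) when
#'   the criterion is energy-based.
#' @return List with `pair_occupancy` (data frame `i`, `j`, `occupancy`),
#'   `nucleotide_occupancy` (length N) and `overlay` (a `color_overlay`
#'   named "bond occupancy").
#' @export
bond_occupancy <- function(traj, designed, criterion = bond_criterion(),
                           energies = NULL) {
  topo <- traj$topology
  F <- n_frames(traj)
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  want <- key(designed)
  counts <- integer(nrow(designed))
  for (k in seq_len(F)) {
    sl <- if (!is.null(energies))
      energies[energies$frame == k, , drop = FALSE] else NULL
    bonds <- detect_bonds(get_frame(traj, k), topo, criterion, sl)
    if (nrow(bonds)) counts <- counts + (want %in% key(bonds))
  }
  occ <- counts / F
  per_nt <- numeric(topo$n)
  per_nt[designed[, 1] + 1L] <- occ
  per_nt[designed[, 2] + 1L] <- occ
  list(pair_occupancy = data.frame(i = designed[, 1], j = designed[, 2],
                                   occupancy = occ),
       nucleotide_occupancy = per_nt,
       overlay = color_overlay("bond occupancy", per_nt))
}

#' Mean per-nucleotide energy overlay
#'
#' Each interaction's energy is split half-and-half between its two
#' participants; per-nucleotide sums are averaged over frames. Useful for
#' spotting excluded-volume clashes (which pop visually) and weak regions.
#'
#' @param table An `interaction_table` (all kinds, all frames).
#' @param n Particle count N.
#' @param frame_count Number of frames the table covers.
#' @return List with `mean_energy` (length N, simulation units) and
#'   `overlay` (a `color_overlay` named "mean energy").
#' @export
mean_energy_overlay <- function(table, n, frame_count) {
  acc <- numeric(n)
  if (nrow(table)) {
    half <- table$energy / 2
    acc <- acc +
      as.numeric(tapply(c(half, half),
                        factor(c(table$i, table$j), levels = 0:(n - 1L)),
                        sum, default = 0))
  }
  me <- acc / frame_count
  list(mean_energy = me, overlay = color_overlay("mean energy", me))
}

#' Designed pairs from the current base-pair arrangement
#'
#' Detects the bonds of a single configuration and returns them as a
#' designed-pairs set, e.g. to freeze the current pairing as the reference
#' for occupancy analysis or to convert to mutual traps via
#' [pairs_to_forces()].
#'
#' @param conf An `oxdna_conf`.
#' @param topo The matching topology.
#' @param criterion A [bond_criterion()].
#' @param energies Interaction-table slice for this configuration (energy
#'   mode).
#' @return A `designed_pairs` object.
#' @export
current_pairs_to_designed <- function(conf, topo,
                                      criterion = bond_criterion(),
                                      energies = NULL) {
  b <- detect_bonds(conf, topo, criterion, energies)
  designed_pairs(b[, 1], b[, 2])
}
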