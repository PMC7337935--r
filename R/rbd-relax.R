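# Rigid-body relaxation: partition a configuration into groups, apply spring
# forces at inter-group backbone bonds plus a linear centre-centre repulsion,
# and integrate damped rigid-body motion until the net forces vanish.
#
# Structures exported from lattice design tools arrive planar with hugely
# stretched inter-block bonds; nucleotide-level simulation cannot untangle
# them. Treating each spatial block as one rigid body and relaxing the
# blocks first yields a usable starting state.

#' Relaxation parameters
#'
#' Spring magnitude: `f_spr = c_spr * (l - l_r)` at each inter-group
#' backbone bond. Repulsion magnitude between group centres:
#' `f_rep = max(c_rep * (1 - d / (r_a + r_b)), 0)`, where `r_a + r_b` is the
#' sum of the group radii (the greatest distance at which they can still
#' overlap). Integration is damped first-order rigid-body motion; these are
#' relaxation hyperparameters, not physical constants, and are all exposed.
#'
#' @param c_spr Spring constant.
#' @param l_r Relaxed backbone bond length, simulation units (default the
#'   model's equilibrium backbone length, 0.76).
#' @param c_rep Repulsion constant.
#' @param step Integration step size.
#' @param damping Velocity damping factor in (0, 1].
#' @param max_iter Iteration cap.
#' @param tol Convergence threshold on the largest per-group net force.
#' @return A `relax_params` list.
#' @export
relax_params <- function(c_spr = 1, l_r = 0.76, c_rep = 10, step = 0.05,
                         damping = 0.95, max_iter = 1e5, tol = 1e-4) {
  stopifnot(c_spr > 0, l_r > 0, c_rep > 0, step > 0,
            damping > 0, damping <= 1, max_iter > 0, tol > 0)
  structure(list(c_spr = c_spr, l_r = l_r, c_rep = c_rep, step = step,
                 damping = damping, max_iter = as.integer(max_iter),
                 tol = tol),
            class = "relax_params")
}

#' Spring force magnitude
#' @param l Current bond length.
#' @param params A `relax_params`.
#' @return Signed magnitude `c_spr * (l - l_r)` along the inter-attachment
#'   direction (negative when compressed, pushing apart).
#' @export
spring_force <- function(l, params = relax_params()) {
  params$c_spr * (l - params$l_r)
}

#' Repulsion force magnitude
#' @param d Centre-centre distance.
#' @param r_a,r_b Group radii.
#' @param params A `relax_params`.
#' @return `max(c_rep * (1 - d / (r_a + r_b)), 0)` along the centre-centre
#'   direction.
#' @export
repulsion_force <- function(d, r_a, r_b, params = relax_params()) {
  pmax(params$c_rep * (1 - d / (r_a + r_b)), 0)
}

.new_group <- function(conf, members) {
  pos <- conf$positions[members + 1L, , drop = FALSE]
  ctr <- colMeans(pos)
  structure(list(members = as.integer(members), center = ctr,
                 radius = if (nrow(pos) > 1L)
                   max(sqrt(rowSums(sweep(pos, 2, ctr)^2))) else 0),
            class = "rigid_group")
}

#' Identify rigid groups by spatial clustering
#'
#' DBSCAN on nucleotide positions; each cluster becomes one rigid group.
#' Noise particles become singleton groups, since they must still be free to
#' move during relaxation.
#'
#' @param conf An `oxdna_conf`.
#' @param eps DBSCAN radius, simulation length units.
#' @param min_size DBSCAN minimum neighbourhood size.
#' @return List of `rigid_group` (members as 0-based ids, centre of mass and
#'   radius = greatest member distance from the centre).
#' @export
identify_groups <- function(conf, eps, min_size = 4L) {
  asg <- dbscan(conf$positions, eps, min_size)
  groups <- list()
  for (l in sort(unique(asg$labels[asg$labels >= 0L])))
    groups[[length(groups) + 1L]] <- .new_group(conf, which(asg$labels == l) - 1L)
  for (s in which(asg$labels == -1L))
    groups[[length(groups) + 1L]] <- .new_group(conf, s - 1L)
  groups
}

#' Inter-group springs at shared backbone bonds
#'
#' One spring per backbone-connected nucleotide pair whose endpoints lie in
#' different groups.
#'
#' @param topo An `oxdna_topology`.
#' @param groups List of `rigid_group` (need not cover all nucleotides;
#'   bonds touching ungrouped nucleotides are skipped).
#' @return Data frame with columns `group_a`, `group_b` (1-based group
#'   indices), `i`, `j` (0-based attachment nucleotide ids).
#' @export
inter_group_springs <- function(topo, groups) {
  gof <- rep(NA_integer_, topo$n)
  for (g in seq_along(groups)) gof[groups[[g]]$members + 1L] <- g
  from <- which(!is.na(topo$neighbor5)) - 1L
  to <- topo$neighbor5[from + 1L]
  ga <- gof[from + 1L]; gb <- gof[to + 1L]
  keep <- !is.na(ga) & !is.na(gb) & ga != gb
  data.frame(group_a = ga[keep], group_b = gb[keep],
             i = from[keep], j = to[keep])
}

.axis_angle_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-15) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Relax groups with damped rigid-body dynamics
#'
#' Iterates damped first-order updates: the net spring + repulsion force
#' translates each group; the torque of the spring forces about the group
#' centre rotates it (repulsion is central and applies no torque). Rotations
#' are applied by axis-angle exponentiation, so group geometry stays exactly
#' rigid. Terminates when the largest per-group net force drops below
#' `params$tol` or at the iteration cap; aborts with a diagnostic if the
#' total potential energy rises for 100 consecutive steps.
#'
#' @param conf An `oxdna_conf`.
#' @param topo The matching topology.
#' @param groups List of `rigid_group`, e.g. from [identify_groups()].
#' @param params A [relax_params()].
#' @param pinned Optional integer vector of 1-based group indices held fixed
#'   (substitute for interactive dragging).
#' @return List with `configuration` (relaxed, versors re-orthonormalised),
#'   `converged`, `iterations`, `max_force` and `energy` (trace of total
#'   potential energy, logged every 100 iterations and at the end).
#' @export
relax <- function(conf, topo, groups, params = relax_params(),
                  pinned = integer(0)) {
  springs <- inter_group_springs(topo, groups)
  G <- length(groups)
  centers0 <- t(vapply(groups, function(g) g$center, numeric(3)))
  radii <- vapply(groups, function(g) g$radius, numeric(1))
  centers <- centers0
  rots <- rep(list(diag(3)), G)
  # attachment-point local coordinates (relative to the initial centre)
  att_i <- conf$positions[springs$i + 1L, , drop = FALSE] -
    centers0[springs$group_a, , drop = FALSE]
  att_j <- conf$positions[springs$j + 1L, , drop = FALSE] -
    centers0[springs$group_b, , drop = FALSE]

  att_world <- function(local, gidx) {
    t(vapply(seq_along(gidx), function(r)
      centers[gidx[r], ] + as.numeric(rots[[gidx[r]]] %*% local[r, ]),
      numeric(3)))
  }
  potential <- function(pi, pj) {
    e <- 0
    if (nrow(springs)) {
      l <- sqrt(rowSums((pj - pi)^2))
      e <- e + sum(0.5 * params$c_spr * (l - params$l_r)^2)
    }
    if (G > 1L) for (a in seq_len(G - 1L)) for (b in (a + 1L):G) {
      s <- radii[a] + radii[b]
      d <- sqrt(sum((centers[b, ] - centers[a, ])^2))
      if (d < s) e <- e + params$c_rep * (s - d)^2 / (2 * s)
    }
    e
  }

  vel <- matrix(0, G, 3)
  avel <- matrix(0, G, 3)
  energy_log <- numeric(0)
  e_prev <- Inf
  rises <- 0L
  iter <- 0L
  max_force <- Inf
  while (iter < params$max_iter) {
    iter <- iter + 1L
    Fnet <- matrix(0, G, 3)
    Tnet <- matrix(0, G, 3)
    pi_w <- pj_w <- matrix(0, 0, 3)
    if (nrow(springs)) {
      pi_w <- att_world(att_i, springs$group_a)
      pj_w <- att_world(att_j, springs$group_b)
      dvec <- pj_w - pi_w
      l <- sqrt(rowSums(dvec^2))
      ok <- l > 1e-12
      fmag <- spring_force(l, params)
      fvec <- dvec
      fvec[ok, ] <- fvec[ok, , drop = FALSE] * (fmag[ok] / l[ok])
      fvec[!ok, ] <- 0
      for (r in seq_len(nrow(springs))) {
        a <- springs$group_a[r]; b <- springs$group_b[r]
        Fnet[a, ] <- Fnet[a, ] + fvec[r, ]
        Fnet[b, ] <- Fnet[b, ] - fvec[r, ]
        ra <- pi_w[r, ] - centers[a, ]
        rb <- pj_w[r, ] - centers[b, ]
        Tnet[a, ] <- Tnet[a, ] + c(ra[2] * fvec[r, 3] - ra[3] * fvec[r, 2],
                                   ra[3] * fvec[r, 1] - ra[1] * fvec[r, 3],
                                   ra[1] * fvec[r, 2] - ra[2] * fvec[r, 1])
        Tnet[b, ] <- Tnet[b, ] - c(rb[2] * fvec[r, 3] - rb[3] * fvec[r, 2],
                                   rb[3] * fvec[r, 1] - rb[1] * fvec[r, 3],
                                   rb[1] * fvec[r, 2] - rb[2] * fvec[r, 1])
      }
    }
    if (G > 1L) for (a in seq_len(G - 1L)) for (b in (a + 1L):G) {
      s <- radii[a] + radii[b]
      dv <- centers[b, ] - centers[a, ]
      d <- sqrt(sum(dv^2))
      f <- repulsion_force(d, radii[a], radii[b], params)
      if (f > 0) {
        u <- if (d > 1e-12) dv / d else c(1, 0, 0)
        Fnet[a, ] <- Fnet[a, ] - f * u
        Fnet[b, ] <- Fnet[b, ] + f * u
      }
    }
    if (length(pinned)) {
      Fnet[pinned, ] <- 0
      Tnet[pinned, ] <- 0
    }
    max_force <- if (G) max(sqrt(rowSums(Fnet^2))) else 0
    if (max_force < params$tol) break

    vel <- params$damping * vel + params$step * Fnet
    avel <- params$damping * avel + params$step * Tnet
    centers <- centers + params$step * vel
    for (g in seq_len(G)) {
      w <- params$step * avel[g, ]
      if (sum(w^2) > 0) rots[[g]] <- .axis_angle_matrix(w) %*% rots[[g]]
    }

    if (iter %% 100L == 0L || iter == 1L) {
      pi_w2 <- if (nrow(springs)) att_world(att_i, springs$group_a) else pi_w
      pj_w2 <- if (nrow(springs)) att_world(att_j, springs$group_b) else pj_w
      e <- potential(pi_w2, pj_w2)
      energy_log <- c(energy_log, e)
      if (e > e_prev) rises <- rises + 1L else rises <- 0L
      e_prev <- e
      if (rises >= 100L)
        .stopf("relaxation diverged: potential energy rose for 100 consecutive checkpoints (iteration %d, energy %.4g)",
               iter, e)
    }
  }

  pos <- conf$positions
  a1 <- conf$a1
  a3 <- conf$a3
  for (g in seq_len(G)) {
    idx <- groups[[g]]$members + 1L
    R <- rots[[g]]
    pos[idx, ] <- sweep((conf$positions[idx, , drop = FALSE] -
                         matrix(centers0[g, ], length(idx), 3, byrow = TRUE)) %*%
                          t(R), 2, centers[g, ], "+")
    a1[idx, ] <- conf$a1[idx, , drop = FALSE] %*% t(R)
    a3[idx, ] <- conf$a3[idx, , drop = FALSE] %*% t(R)
  }
  a3 <- a3 / sqrt(rowSums(a3^2))
  a1 <- a1 - rowSums(a1 * a3) * a3
  a1 <- a1 / sqrt(rowSums(a1^2))
  out <- configuration(pos, a1, a3, time = conf$time, box = conf$box,
                       energies = conf$energies)
  list(configuration = out, converged = max_force < params$tol,
       iterations = iter, max_force = max_force, energy = energy_log)
}
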