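# Two 8-bp duplex blocks whose strand 1 continues across a (stretched)
# backbone bond: the canonical two-group relaxation fixture.
two_block_fixture <- function(offset = c(12, 0, 0)) {
  b <- build_duplex(8)
  n <- b$topology$n
  conf <- b$configuration
  pos <- rbind(conf$positions, sweep(conf$positions, 2, offset, "+"))
  sid <- c(b$topology$strand_id, b$topology$strand_id + 2L)
  nb3 <- c(b$topology$neighbor3, b$topology$neighbor3 + n)
  nb5 <- c(b$topology$neighbor5, b$topology$neighbor5 + n)
  # ligate: 5' end of block-1 strand 1 (id 7) to 3' end of block-2 strand 1
  nb5[8] <- 16L
  nb3[17] <- 7L
  sid[sid == 3L] <- 1L
  topo <- topology(sid, rep(b$topology$base, 2), nb3, nb5)
  conf2 <- configuration(pos, rbind(conf$a1, conf$a1),
                         rbind(conf$a3, conf$a3), box = c(100, 100, 100))
  list(topology = topo, configuration = conf2)
}

test_that("printed force laws evaluate as stated", {
  p <- relax_params(c_spr = 2, l_r = 1, c_rep = 10)
  expect_equal(spring_force(1, p), 0)       # at rest length
  expect_equal(spring_force(3, p), 4)       # c_spr (l - l_r)
  expect_lt(spring_force(0.5, p), 0)        # compressed: pushes apart
  expect_equal(repulsion_force(5, 2, 2, p), 0)     # d >= r_a + r_b
  expect_equal(repulsion_force(0, 2, 2, p), 10)    # contact limit = c_rep
  expect_equal(repulsion_force(2, 2, 2, p), 5)     # half overlap
  expect_error(relax_params(damping = 1.5), "damping")
})

test_that("spatial group identification recovers separated blocks", {
  fx <- two_block_fixture()
  groups <- identify_groups(fx$configuration, eps = 2)
  expect_length(groups, 2L)
  expect_setequal(groups[[1]]$members, 0:15)
  expect_setequal(groups[[2]]$members, 16:31)
  # one connected blob -> one group
  d <- build_duplex(10)
  expect_length(identify_groups(d$configuration, eps = 2), 1L)
  # two-particle group: centre at the mean, radius = half the separation
  conf <- configuration(rbind(c(0, 0, 0), c(2, 0, 0)),
                        rbind(c(0, 1, 0), c(0, -1, 0)),
                        rbind(c(0, 0, 1), c(0, 0, 1)))
  g <- identify_groups(conf, eps = 3, min_size = 1L)
  expect_equal(g[[1]]$center, c(1, 0, 0))
  expect_equal(g[[1]]$radius, 1)
})

test_that("inter-group springs sit at backbone bonds crossing groups", {
  fx <- two_block_fixture()
  groups <- identify_groups(fx$configuration, eps = 2)
  spr <- inter_group_springs(fx$topology, groups)
  expect_equal(nrow(spr), 1L)
  expect_setequal(c(spr$i, spr$j), c(7L, 16L))
  # fully intra-group topology -> no springs
  d <- build_duplex(10)
  g1 <- identify_groups(d$configuration, eps = 2)
  expect_equal(nrow(inter_group_springs(d$topology, g1)), 0L)
})

test_that("a one-spring system relaxes to the rest length rigidly", {
  fx <- two_block_fixture()
  groups <- identify_groups(fx$configuration, eps = 2)
  d0 <- as.matrix(stats::dist(fx$configuration$positions[1:16, ]))
  rx <- relax(fx$configuration, fx$topology, groups)
  expect_true(rx$converged)
  p <- rx$configuration$positions
  l <- sqrt(sum((p[8, ] - p[17, ])^2))
  expect_equal(l, 0.76, tolerance = 1e-3 / 0.76)
  # rigidity: intra-group distances preserved through the whole motion
  d1 <- as.matrix(stats::dist(p[1:16, ]))
  expect_lt(max(abs(d1 - d0)), 1e-8)
  # versors stay orthonormal
  expect_equal(rowSums(rx$configuration$a1^2), rep(1, 32),
               tolerance = 1e-10)
  expect_lt(max(abs(rowSums(rx$configuration$a1 * rx$configuration$a3))),
            1e-10)
  # energy is non-increasing between checkpoints
  expect_true(all(diff(rx$energy) <= 1e-9))
})

test_that("overlapping spring-free groups separate beyond their radii", {
  d1 <- build_duplex(8)
  d2 <- build_duplex(8)
  n <- d1$topology$n
  topo <- topology(c(d1$topology$strand_id, d2$topology$strand_id + 2L),
                   rep(d1$topology$base, 2),
                   c(d1$topology$neighbor3, d2$topology$neighbor3 + n),
                   c(d1$topology$neighbor5, d2$topology$neighbor5 + n))
  conf <- configuration(
    rbind(d1$configuration$positions,
          sweep(d2$configuration$positions, 2, c(0.8, 0, 0), "+")),
    rbind(d1$configuration$a1, d2$configuration$a1),
    rbind(d1$configuration$a3, d2$configuration$a3),
    box = c(100, 100, 100))
  groups <- list(oxtraj:::.new_group(conf, 0:15),
                 oxtraj:::.new_group(conf, 16:31))
  rx <- relax(conf, topo, groups)
  expect_true(rx$converged)
  c1 <- colMeans(rx$configuration$positions[1:16, ])
  c2 <- colMeans(rx$configuration$positions[17:32, ])
  expect_gte(sqrt(sum((c2 - c1)^2)),
             groups[[1]]$radius + groups[[2]]$radius - 1e-6)
})

test_that("an already-relaxed state is a fixed point and pins hold", {
  fx <- two_block_fixture()
  groups <- identify_groups(fx$configuration, eps = 2)
  rx1 <- relax(fx$configuration, fx$topology, groups)
  groups2 <- identify_groups(rx1$configuration, eps = 2)
  rx2 <- relax(rx1$configuration, fx$topology, groups2)
  expect_lte(rx2$iterations, 1L)
  expect_equal(rx2$configuration$positions, rx1$configuration$positions,
               tolerance = 1e-6)
  # pinned group does not move
  rx3 <- relax(fx$configuration, fx$topology, groups, pinned = 1L)
  expect_equal(rx3$configuration$positions[1:16, ],
               fx$configuration$positions[1:16, ], tolerance = 1e-12)
  expect_true(rx3$converged)
})

test_that("a mirror-symmetric three-group chain relaxes symmetrically", {
  # one 6-nt strand through three 2-particle blocks; the whole arrangement
  # is exactly mirror-symmetric about x = 0, and the dynamics preserve that
  # symmetry, so the relaxed state must too
  x <- c(-10.5, -9.5, -0.5, 0.5, 9.5, 10.5)
  pos <- cbind(x, 0, 0)
  n <- 6L
  topo <- topology(rep(1L, n), rep("A", n),
                   c(NA, seq_len(n - 1L) - 1L), c(seq_len(n - 1L), NA))
  conf <- configuration(pos,
                        matrix(rep(c(0, 1, 0), n), ncol = 3, byrow = TRUE),
                        matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE))
  groups <- lapply(list(0:1, 2:3, 4:5),
                   function(m) oxtraj:::.new_group(conf, m))
  spr <- inter_group_springs(topo, groups)
  expect_equal(nrow(spr), 2L)
  rx <- relax(conf, topo, groups)
  expect_true(rx$converged)
  p <- rx$configuration$positions
  # mirror symmetry of the final state: particle k vs particle (5 - k)
  expect_equal(p[, 1], -p[6:1, 1], tolerance = 1e-6)
  expect_equal(p[, 2], p[6:1, 2], tolerance = 1e-6)
  # both springs end at the rest length
  expect_equal(sqrt(sum((p[2, ] - p[3, ])^2)), 0.76, tolerance = 2e-3)
  expect_equal(sqrt(sum((p[4, ] - p[5, ])^2)), 0.76, tolerance = 2e-3)
})
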