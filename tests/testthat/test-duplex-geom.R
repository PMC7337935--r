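test_that("find_duplexes reports one maximal run per intact duplex", {
  d <- build_duplex(10)
  dup <- find_duplexes(d$configuration, d$topology, d$pairs)
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$length_bp, 10L)
  expect_equal(nrow(find_duplexes(d$configuration, d$topology,
                                  designed_pairs())), 0L)
})

test_that("removing a central pair splits the run as the oracle predicts", {
  d <- build_duplex(10)
  # drop base pair at slot 4 (ids 4 and 15): runs of 4 and 5 remain
  keep <- d$pairs[d$pairs[, 1] != 4L, , drop = FALSE]
  dup <- find_duplexes(d$configuration, d$topology,
                       designed_pairs(keep[, 1], keep[, 2]), min_len = 4L)
  expect_equal(sort(dup$length_bp), c(4L, 5L))
  # with min_len 5 only the longer survives
  dup5 <- find_duplexes(d$configuration, d$topology,
                        designed_pairs(keep[, 1], keep[, 2]), min_len = 5L)
  expect_equal(dup5$length_bp, 5L)
})

test_that("a four-armed junction yields four duplex records", {
  # four separate 6-bp duplexes = a pulled-apart junction toy; the run
  # detector must report each arm once regardless of strand enumeration
  arms <- lapply(0:3, function(k) build_duplex(6))
  n <- 12L
  topo <- topology(
    strand_id = unlist(lapply(0:3, function(k)
      arms[[k + 1]]$topology$strand_id + 2L * k)),
    base = unlist(lapply(arms, function(a) a$topology$base)),
    neighbor3 = unlist(lapply(0:3, function(k)
      arms[[k + 1]]$topology$neighbor3 + n * k)),
    neighbor5 = unlist(lapply(0:3, function(k)
      arms[[k + 1]]$topology$neighbor5 + n * k)))
  offs <- rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0), c(30, 30, 0))
  conf <- configuration(
    do.call(rbind, lapply(1:4, function(k)
      sweep(arms[[k]]$configuration$positions, 2, offs[k, ], "+"))),
    do.call(rbind, lapply(arms, function(a) a$configuration$a1)),
    do.call(rbind, lapply(arms, function(a) a$configuration$a3)),
    box = c(200, 200, 200))
  pairs <- designed_pairs(
    unlist(lapply(0:3, function(k) arms[[k + 1]]$pairs[, 1] + n * k)),
    unlist(lapply(0:3, function(k) arms[[k + 1]]$pairs[, 2] + n * k)))
  dup <- find_duplexes(conf, topo, pairs)
  expect_equal(nrow(dup), 4L)
  expect_equal(dup$length_bp, rep(6L, 4))
})

test_that("axis fits honour their preconditions and degeneracies", {
  d <- build_duplex(10)
  runs <- attr(find_duplexes(d$configuration, d$topology, d$pairs), "runs")
  run <- runs[[1]]
  expect_error(fit_axis_b(d$configuration, run[1:2, ]), ">= 3")
  expect_error(fit_axis_a(d$configuration, run[1:3, ]), ">= 4")
  # collinear midpoints lie exactly on the fitted line (B-form fixture)
  ax <- fit_axis_b(d$configuration, run)
  mids <- (d$configuration$positions[run[, 1] + 1L, ] +
           d$configuration$positions[run[, 2] + 1L, ]) / 2
  ctr <- sweep(mids, 2, colMeans(mids))
  resid <- ctr - (ctr %*% ax) %*% t(ax)
  expect_lt(max(abs(resid)), 1e-10)
  # plane fit on parallel displacements is degenerate: straight "ladder"
  n <- 6L
  pos <- rbind(cbind(0, 0, 0:(n - 1)), cbind(1, 0, (n - 1):0))
  conf <- configuration(pos,
                        rbind(matrix(rep(c(1, 0, 0), n), ncol = 3,
                                     byrow = TRUE),
                              matrix(rep(c(-1, 0, 0), n), ncol = 3,
                                     byrow = TRUE)),
                        matrix(rep(c(0, 1, 0), 2 * n), ncol = 3,
                               byrow = TRUE))
  ladder_run <- cbind(0:(n - 1), (2 * n - 1):n)
  expect_error(fit_axis_a(conf, ladder_run), "parallel")
  # the A-form fit still recovers the axis of a B-form helix
  axA <- fit_axis_a(d$configuration, run)
  expect_lt(acos(min(1, abs(axA[3]))) * 180 / pi, 5)
})

test_that("duplex_angle_series recovers a constructed 60 degree angle", {
  fx <- two_duplex_fixture(angle_deg = 60)
  traj <- perturb(fx$configuration, fx$topology, sigma = 0, n_frames = 5,
                  seed = 1)
  s <- duplex_angle_series(traj, probe1 = 0L, probe2 = 24L, pairs = fx$pairs)
  expect_equal(s$fraction, 1.0)
  expect_equal(s$mean, 60, tolerance = 1 / 60)
  expect_lt(s$sd, 1e-6)
  # same duplex as both probes -> zero angle
  s0 <- duplex_angle_series(traj, probe1 = 0L, probe2 = 5L, pairs = fx$pairs)
  expect_equal(s0$mean, 0, tolerance = 1e-6)
  # probe in a never-duplexed strand -> fraction 0, stats undefined
  gap <- build_interrupted_duplex(segments = c(6L, 6L), gap_nt = 4L)
  trg <- perturb(gap$configuration, gap$topology, 0, 3, 1)
  unpaired <- setdiff(which(gap$topology$strand_id == 1L) - 1L,
                      c(gap$pairs[, 1], gap$pairs[, 2]))
  sg <- duplex_angle_series(trg, probe1 = unpaired[1], probe2 = 0L,
                            pairs = gap$pairs)
  expect_equal(sg$fraction, 0)
  expect_true(is.na(sg$mean))
})

test_that("interduplex angles are invariant to per-frame rigid transforms", {
  fx <- two_duplex_fixture(angle_deg = 42)
  set.seed(43)
  frames <- lapply(1:6, function(k) {
    tf <- structure(list(rotation = random_rotation(),
                         translation = stats::rnorm(3, sd = 5)),
                    class = "rigid_transform")
    apply_transform(fx$configuration, tf)
  })
  traj <- trajectory(fx$topology, frames)
  s <- duplex_angle_series(traj, probe1 = 0L, probe2 = 24L, pairs = fx$pairs)
  expect_equal(s$fraction, 1.0)
  expect_equal(s$mean, 42, tolerance = 0.02)
  # rigidly rotating frames leave the angle constant although axes vary
  expect_lt(s$sd, 1e-6)
  # symmetry in probe order
  s2 <- duplex_angle_series(traj, probe1 = 24L, probe2 = 0L,
                            pairs = fx$pairs)
  expect_equal(s$mean, s2$mean, tolerance = 1e-10)
})

test_that("distance_series reports nm with optional minimum image", {
  topo <- topology(1:2, c("A", "T"), c(NA, NA), c(NA, NA))
  mk <- function(x2, box = c(20, 20, 20)) {
    configuration(rbind(c(0, 0, 0), c(x2, 0, 0)),
                  rbind(c(0, 1, 0), c(0, -1, 0)),
                  rbind(c(0, 0, 1), c(0, 0, 1)), box = box)
  }
  static <- trajectory(topo, list(mk(2 / 0.8518), mk(2 / 0.8518)))
  ds <- distance_series(static, cbind(0L, 1L))
  expect_equal(as.vector(ds$distances_nm), rep(2, 2), tolerance = 1e-12)
  # straddling the box: raw distance 18, wrapped distance 2 (< box/2)
  wrap <- trajectory(topo, list(mk(18, box = c(20, 20, 20))))
  raw <- distance_series(wrap, cbind(0L, 1L), use_minimum_image = FALSE)
  cor <- distance_series(wrap, cbind(0L, 1L), use_minimum_image = TRUE)
  expect_equal(raw$distances_nm[1, 1], 18 * 0.8518, tolerance = 1e-12)
  expect_equal(cor$distances_nm[1, 1], 2 * 0.8518, tolerance = 1e-12)
  expect_lt(cor$distances_nm[1, 1] / 0.8518, 10)
  # multiple pairs preserve order
  d <- build_duplex(6)
  tr <- perturb(d$configuration, d$topology, 0, 2, 1)
  idp <- rbind(c(0L, 11L), c(0L, 1L), c(2L, 9L))
  m <- distance_series(tr, idp)
  expect_equal(dim(m$distances_nm), c(2L, 3L))
  expect_equal(m$summary$i, idp[, 1])
})
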