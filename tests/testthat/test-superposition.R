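test_that("kabsch_fit recovers planted transforms and guards chirality", {
  set.seed(21)
  P <- matrix(stats::rnorm(60), ncol = 3)
  tf0 <- kabsch_fit(P, P)
  expect_equal(tf0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(tf0$translation, rep(0, 3), tolerance = 1e-10)

  for (rep_i in 1:5) {
    R <- random_rotation()
    t <- stats::rnorm(3)
    Q <- sweep(P %*% R, 2, t, "+")
    tf <- kabsch_fit(P, Q)
    expect_equal(tf$rotation, R, tolerance = 1e-8)
    expect_equal(tf$translation, t, tolerance = 1e-8)
    expect_lt(plain_rmsd(apply_transform(P, tf), Q), 1e-8)
  }
  # rotation matrices are proper even for a mirror-image target
  M <- P; M[, 1] <- -M[, 1]
  tfm <- kabsch_fit(P, M)
  expect_equal(det(tfm$rotation), 1, tolerance = 1e-10)
  expect_equal(crossprod(tfm$rotation), diag(3), tolerance = 1e-10)
  # degenerate inputs
  expect_error(kabsch_fit(P[1:2, ], P[1:2, ]), "3 fitting points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line), "collinear")
})

test_that("kabsch matches a brute-force rotation grid on a 5-point toy", {
  set.seed(22)
  A <- matrix(stats::rnorm(15), ncol = 3)
  B <- sweep(A %*% random_rotation(), 2, c(1, -2, 0.5), "+")
  B <- B + matrix(stats::rnorm(15, sd = 0.1), ncol = 3)  # non-exact target
  tf <- kabsch_fit(A, B)
  kab <- plain_rmsd(apply_transform(A, tf), B)
  grid <- grid_min_rmsd(A, B, n_per_axis = 24)
  expect_lte(kab, grid$rmsd + 1e-12)   # optimality against brute force
  expect_lt(grid$rmsd - kab, grid$resolution_bound)  # grid approaches it
})

test_that("alignment is idempotent, optimal and versor-preserving", {
  d <- build_duplex(10)
  traj <- perturb(d$configuration, d$topology, sigma = 0.05, n_frames = 6,
                  seed = 2)
  # scatter frames with random rigid transforms
  frames <- lapply(traj_frames(traj), function(f) {
    tf <- structure(list(rotation = random_rotation(),
                         translation = stats::rnorm(3)),
                    class = "rigid_transform")
    apply_transform(f, tf)
  })
  set.seed(30)
  scattered <- trajectory(d$topology, frames)
  al <- align_trajectory(scattered, 1L)
  ref <- get_frame(al, 1)
  for (k in seq_len(6)) {
    pre <- plain_rmsd(get_frame(scattered, k)$positions, ref$positions)
    post <- plain_rmsd(get_frame(al, k)$positions, ref$positions)
    expect_lte(post, pre + 1e-12)
    a1 <- get_frame(al, k)$a1; a3 <- get_frame(al, k)$a3
    expect_equal(rowSums(a1^2), rep(1, 20), tolerance = 1e-10)
    expect_equal(rowSums(a1 * a3), rep(0, 20), tolerance = 1e-10)
  }
  al2 <- align_trajectory(al, 1L)
  for (k in seq_len(6))
    expect_equal(get_frame(al2, k)$positions, get_frame(al, k)$positions,
                 tolerance = 1e-10)
})

test_that("mean_structure averages out noise and rigid transforms", {
  d <- build_duplex(10)
  static <- perturb(d$configuration, d$topology, sigma = 0, n_frames = 4,
                    seed = 1)
  ms <- mean_structure(static)
  expect_equal(ms$mean$positions, d$configuration$positions,
               tolerance = 1e-12)
  expect_equal(ms$mean$a1, d$configuration$a1, tolerance = 1e-10)

  # 2 frames differing by a rigid transform -> mean = frame 1
  f2 <- apply_transform(d$configuration,
                        structure(list(rotation = random_rotation(),
                                       translation = c(3, -1, 2)),
                                  class = "rigid_transform"))
  set.seed(31)
  two <- trajectory(d$topology, list(d$configuration, f2))
  ms2 <- mean_structure(two)
  expect_equal(ms2$mean$positions, d$configuration$positions,
               tolerance = 1e-8)

  # CLT: mean of noisy frames aligned to the true base converges to it
  # (an internal noisy reference adds an O(sigma) rigid offset instead)
  noisy <- perturb(d$configuration, d$topology, sigma = 0.05,
                   n_frames = 5000, seed = 8)
  ms3 <- mean_structure(noisy, reference = d$configuration)
  expect_lt(max(abs(ms3$mean$positions - d$configuration$positions)),
            0.05 / sqrt(5000) * 5 + 0.01)
})

test_that("mean_structure is invariant to a global rigid transform", {
  d <- build_duplex(8)
  traj <- perturb(d$configuration, d$topology, sigma = 0.03, n_frames = 10,
                  seed = 4)
  set.seed(32)
  tf <- structure(list(rotation = random_rotation(),
                       translation = c(1, 2, 3)),
                  class = "rigid_transform")
  moved <- trajectory(d$topology,
                      lapply(traj_frames(traj),
                             function(f) apply_transform(f, tf)))
  m1 <- mean_structure(traj)$mean$positions
  m2 <- mean_structure(moved)$mean$positions
  # compare shapes, not poses
  expect_lt(plain_rmsd(apply_transform(m1, kabsch_fit(m1, m2)), m2), 1e-8)
})

test_that("rmsf vanishes on static data and is reference-insensitive", {
  d <- build_duplex(10)
  static <- perturb(d$configuration, d$topology, sigma = 0, n_frames = 3,
                    seed = 1)
  ms <- mean_structure(static)
  expect_equal(rmsf(static, ms)$rmsf_nm, rep(0, 20), tolerance = 1e-10)
  one <- trajectory(d$topology, list(d$configuration))
  expect_equal(rmsf(one, mean_structure(one))$rmsf_nm, rep(0, 20),
               tolerance = 1e-12)

  noisy <- perturb(d$configuration, d$topology, sigma = 0.08,
                   n_frames = 1500, seed = 5)
  r1 <- rmsf(noisy, mean_structure(noisy, reference = 1L))$rmsf_nm
  r2 <- rmsf(noisy, mean_structure(noisy, reference = 750L))$rmsf_nm
  expect_equal(mean(r1), mean(r2), tolerance = 0.02)
  ov <- rmsf(noisy, mean_structure(noisy))$overlay
  expect_s3_class(ov, "color_overlay")
  expect_equal(ov$name, "RMSF (nm)")
})

test_that("centroid returns the frame closest to the reference", {
  d <- build_duplex(8)
  traj <- perturb(d$configuration, d$topology, sigma = 0.1, n_frames = 20,
                  seed = 6)
  # reference present in the trajectory -> that frame wins
  hit <- centroid(traj, get_frame(traj, 13))
  expect_equal(hit$index, 13L)
  expect_lt(hit$rmsd, 1e-10)
  # exhaustive oracle
  ms <- mean_structure(traj)
  ct <- centroid(traj, ms)
  rmsds <- vapply(seq_len(20), function(k) {
    fr <- get_frame(traj, k)
    plain_rmsd(apply_transform(
      fr, kabsch_fit(fr$positions, ms$mean$positions))$positions,
      ms$mean$positions)
  }, numeric(1))
  expect_equal(ct$index, which.min(rmsds))
  # two-state: reference = state A picks an A frame
  b <- bend_configuration(d$configuration, 8:15, 8L)
  ts <- two_state_trajectory(d$configuration, b, d$topology, frac_A = 0.5,
                             noise = 0.02, n_frames = 40, seed = 7)
  ctA <- centroid(ts$trajectory, d$configuration)
  expect_equal(ts$labels[ctA$index], "A")
})

test_that("superimpose_configs collapses rotated copies", {
  d <- build_duplex(8)
  set.seed(33)
  copies <- lapply(1:4, function(k) {
    tf <- structure(list(rotation = random_rotation(),
                         translation = stats::rnorm(3)),
                    class = "rigid_transform")
    apply_transform(d$configuration, tf)
  })
  out <- superimpose_configs(copies)
  expect_equal(out[[1]]$positions, copies[[1]]$positions)  # first unchanged
  for (k in 2:4)
    expect_equal(out[[k]]$positions, out[[1]]$positions, tolerance = 1e-8)
  expect_equal(superimpose_configs(copies[1]), copies[1])
  bad <- build_duplex(6)$configuration
  expect_error(superimpose_configs(list(d$configuration, bad)), "particles")
})
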