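test_that("Kabsch recovers rigid motions and refuses degenerate input", {
  set.seed(31)
  ref <- matrix(rnorm(15, sd = 3), ncol = 3)
  # identity case
  fit <- kabsch_superpose(ref, ref)
  expect_lt(fit$rmsd, 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  # 90-degree rotation about z plus translation
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  mob <- sweep(ref %*% t(Rz), 2, c(1, 2, 3), "+")
  fit <- kabsch_superpose(mob, ref)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(fit$transform(mob) - ref)), 1e-9)
  # collinear selection
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line + 0, line), "rank error")
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "rank error")
})

test_that("Kabsch matches the SO(3) grid-search oracle on noisy pairs", {
  for (seed in 1:3) {
    set.seed(seed)
    ref <- matrix(rnorm(15, sd = 2), ncol = 3)
    mob <- sweep((ref + matrix(rnorm(15, sd = 0.3), ncol = 3)) %*%
                   t(random_rotation_matrix()), 2, runif(3, -4, 4), "+")
    fit <- kabsch_superpose(mob, ref)
    expect_equal(fit$rmsd, grid_min_rmsd(mob, ref), tolerance = 1e-3)
  }
})

test_that("superposition never increases the RMSD", {
  set.seed(77)
  for (i in 1:20) {
    ref <- matrix(rnorm(24, sd = 2), ncol = 3)
    mob <- ref + matrix(rnorm(24, sd = runif(1, 0, 2)), ncol = 3)
    expect_lte(kabsch_superpose(mob, ref)$rmsd, rmsd(mob, ref) + 1e-12)
  }
})

test_that("rmsd_series: zeros, rigid invariance, single displacement", {
  spec <- modal_trajectory_spec(n_atoms = 10, n_frames = 5,
                                amplitudes = 1e-9, noise_sd = 0, seed = 4)
  traj <- generate_modal_trajectory(spec)
  ref <- traj$frames[[1]]
  s <- rmsd_series(traj, ref, "calpha")
  expect_true(all(s$rmsd < 1e-6))
  expect_equal(s$time_ps, ensemble_times(traj))
  # rigid transformed copies are recovered to machine precision
  rigid <- modal_trajectory_spec(n_atoms = 10, n_frames = 5,
                                 amplitudes = 1e-12, noise_sd = 0,
                                 rigid_motion = TRUE, seed = 4)
  s <- rmsd_series(generate_modal_trajectory(rigid),
                   ca_frame(attr(generate_modal_trajectory(rigid),
                                 "reference")), "calpha")
  expect_true(all(s$rmsd < 1e-9))
  # 1 A displacement of one atom among N, superposition off: sqrt(1/N)
  base <- ca_frame(matrix(rnorm(30), ncol = 3), index = 0L, time_ps = 0)
  moved <- set_frame_coords(base, {
    xyz <- frame_coords(base)
    xyz[3, 1] <- xyz[3, 1] + 1
    xyz
  })
  moved$index <- 1L
  moved$time_ps <- 10
  ens <- new_ensemble(list(base, moved))
  s <- rmsd_series(ens, base, "calpha", fit = FALSE)
  expect_equal(s$rmsd, c(0, sqrt(1 / 10)), tolerance = 1e-12)
})

test_that("extract_window samples the trailing half-open window", {
  frames <- lapply(1:20, function(i) {
    ca_frame(matrix(rnorm(12), ncol = 3), index = i - 1L, time_ps = 10 * i)
  })
  ens <- new_ensemble(frames)
  # full span, interval = spacing -> identity
  all_ <- extract_window(ens, window_ns = 0.2, interval_ps = 10)
  expect_equal(n_frames(all_), 20L)
  # trailing 50 ps at 10 ps -> 5 frames (160, 200]
  w <- extract_window(ens, window_ns = 0.05, interval_ps = 10)
  expect_equal(ensemble_times(w), c(160, 170, 180, 190, 200))
  # coarser interval anchored at the last frame
  w <- extract_window(ens, window_ns = 0.1, interval_ps = 20)
  expect_equal(ensemble_times(w), c(120, 140, 160, 180, 200))
  expect_error(extract_window(ens, 1, 10), "range error")
  expect_error(extract_window(ens, 0.05, 15), "range error")
})

test_that("PCA identities: trace, orthonormality, zero-variance, oracle", {
  spec <- modal_trajectory_spec(n_atoms = 12, n_frames = 60,
                                amplitudes = c(0.8, 0.4), noise_sd = 0.05,
                                seed = 9)
  traj <- generate_modal_trajectory(spec)
  modes <- compute_pca(traj, modal_reference_frame(traj))
  expect_true(all(diff(modes$eigenvalues) <= 1e-12))
  expect_true(all(modes$eigenvalues >= -1e-10))
  G <- crossprod(modes$vectors)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_equal(sum(modes$variance_fraction), 1, tolerance = 1e-12)
  # trace identity against an explicit covariance (fit off so the data
  # matrix is unambiguous), plus a dense eigendecomposition oracle
  X <- t(vapply(traj$frames, function(fr) as.vector(t(frame_coords(fr))),
                numeric(36)))
  C <- stats::cov(X)
  direct <- eigen(C, symmetric = TRUE)
  unfit <- compute_pca(traj, modal_reference_frame(traj), fit = FALSE)
  expect_equal(sum(unfit$eigenvalues), sum(diag(C)), tolerance = 1e-8)
  k <- length(unfit$eigenvalues)
  expect_equal(unfit$eigenvalues, direct$values[seq_len(k)],
               tolerance = 1e-8)
  # only the planted (well-separated) modes have identifiable vectors;
  # the isotropic noise block is arbitrarily rotated
  for (j in 1:2) {
    expect_gt(abs_cosine(unfit$vectors[, j], direct$vectors[, j]), 1 - 1e-8)
  }
  # identical frames -> all eigenvalues 0
  still <- new_ensemble(lapply(1:4, function(i) {
    ca_frame(attr(traj, "reference"), index = i - 1L, time_ps = 10 * i)
  }))
  expect_lt(max(compute_pca(still)$eigenvalues), 1e-20)
  expect_error(compute_pca(new_ensemble(traj$frames[1])), "data error")
})

test_that("planted modes are recovered, also under rigid-body motion", {
  ok <- 0L
  for (seed in 1:20) {
    spec <- modal_trajectory_spec(n_atoms = 15, n_frames = 120,
                                  amplitudes = c(1.0, 0.5, 0.25),
                                  noise_sd = 0.025, rigid_motion = TRUE,
                                  seed = seed)
    traj <- generate_modal_trajectory(spec)
    modes <- compute_pca(traj, modal_reference_frame(traj))
    planted <- attr(traj, "modes")
    cosines <- vapply(1:3, function(k) {
      abs_cosine(modes$vectors[, k], planted[, k])
    }, 0)
    if (all(cosines >= 0.99)) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("porcupine arrows scale linearly from the reference coordinates", {
  spec <- modal_trajectory_spec(n_atoms = 10, n_frames = 50,
                                amplitudes = 0.8, noise_sd = 0.02, seed = 13)
  traj <- generate_modal_trajectory(spec)
  ref <- modal_reference_frame(traj)
  modes <- compute_pca(traj, ref)
  m1 <- get_mode(modes, 1)
  a0 <- porcupine_arrows(ref, m1, scale = 0)
  expect_equal(a0$length, rep(0, 10))
  a1 <- porcupine_arrows(ref, m1, scale = 3)
  a2 <- porcupine_arrows(ref, m1, scale = 6)
  expect_equal(a2$length, 2 * a1$length, tolerance = 1e-12)
  expect_equal(as.matrix(a1[, c("x0", "y0", "z0")]),
               frame_coords(ref), ignore_attr = TRUE)
  # a mode displacing mostly one atom gives that atom the longest arrow
  n <- 10
  v <- numeric(3 * n)
  v[3 * 5 - 2] <- 1  # atom 5, x component
  planted <- modal_trajectory_spec(n_atoms = n, n_frames = 60,
                                   amplitudes = 0.9, noise_sd = 0,
                                   modes = matrix(v, ncol = 1), seed = 2)
  tr2 <- generate_modal_trajectory(planted)
  md2 <- compute_pca(tr2, modal_reference_frame(tr2), fit = FALSE)
  arr <- porcupine_arrows(modal_reference_frame(tr2), get_mode(md2, 1),
                          scale = 5)
  expect_equal(which.max(arr$length), 5L)
  expect_error(porcupine_arrows(ref, list(vector = numeric(7)), 1),
               "shape error")
})
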