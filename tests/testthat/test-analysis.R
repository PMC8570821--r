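test_that("Kabsch superposition recovers rigid motions and matches brute force", {
  s <- make_toy(toy_spec(6))
  same <- superpose(s$coords, s$coords)
  expect_lt(same$rmsd, 1e-12)
  expect_equal(same$coords, s$coords, tolerance = 1e-9, ignore_attr = TRUE)
  moved <- apply_rigid(s$coords, fixed_rotation())
  fit <- superpose(moved, s$coords)
  expect_lt(fit$rmsd, 1e-9)
  set.seed(31)
  A <- matrix(rnorm(15), 5, 3); B <- matrix(rnorm(15), 5, 3)
  expect_equal(superpose(A, B)$rmsd, brute_force_rmsd(A, B),
               tolerance = 1e-6)
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("PCA of identical conformers has zero variance", {
  s <- make_toy(toy_spec(6))
  coords <- array(0, c(4, n_atoms(s), 3))
  for (i in 1:4) coords[i, , ] <- s$coords
  pc <- ensemble_pca(ensemble(coords), select_atoms(s, "calpha"), p = 2)
  expect_equal(pc$variances, c(0, 0), tolerance = 1e-12)
})

test_that("PCA recovers a planted one-dimensional deformation", {
  s <- make_toy(toy_spec(8))
  ca <- select_atoms(s, "calpha")
  # plant along a nonrigid ANM mode: orthogonal to the rigid-body subspace,
  # so superposition cannot tilt the recovered component
  mb <- anm_modes(s, anm_params(n_modes = 1))
  direction <- mb$node_vectors[1, ]
  amps <- seq(-0.05, 0.05, length.out = 9)
  coords <- array(0, c(9, n_atoms(s), 3))
  for (i in 1:9) {
    x <- s$coords
    x[which(ca), ] <- x[which(ca), ] +
      amps[i] * matrix(direction, ncol = 3, byrow = TRUE)
    coords[i, , ] <- x
  }
  ens <- ensemble(coords)
  pc <- ensemble_pca(ens, ca, p = 2, tol = 1e-12, max_iter = 200)
  cosang <- sum(pc$components[1, ] * direction)
  expect_gt(abs(cosang), 1 - 1e-6)
  expect_equal(pc$variances[1], var(amps), tolerance = 1e-4)
  proj <- project_ensemble(ens, pc)
  recovered <- proj$PC1 * sign(cosang)
  expect_equal(recovered - mean(recovered), amps, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("total PCA variance equals the mean squared fluctuation", {
  s <- make_toy(toy_spec(7))
  set.seed(8)
  M <- 12
  coords <- array(0, c(M, n_atoms(s), 3))
  for (i in seq_len(M))
    coords[i, , ] <- s$coords + matrix(rnorm(3 * n_atoms(s), sd = 0.3),
                                       ncol = 3)
  ca <- select_atoms(s, "calpha")
  pc <- ensemble_pca(ensemble(coords), ca, p = 3)
  # recompute fluctuation on the superposed, masked coordinates
  idx <- which(ca)
  X <- vapply(seq_len(M), function(i)
    as.vector(t(superpose(coords[i, idx, ], pc$mean_coords)$coords)),
    numeric(3 * length(idx)))
  Xc <- t(X) - rep(rowMeans(X), each = M)
  msf <- sum(Xc^2) / (M - 1)
  expect_equal(sum(pc$all_variances), msf, tolerance = 1e-6)
})

test_that("projection identities hold", {
  s <- make_toy(toy_spec(6))
  ca <- select_atoms(s, "calpha")
  set.seed(13)
  M <- 8
  coords <- array(0, c(M, n_atoms(s), 3))
  for (i in seq_len(M))
    coords[i, , ] <- s$coords + matrix(rnorm(3 * n_atoms(s), sd = 0.2),
                                       ncol = 3)
  ens <- ensemble(coords)
  p_full <- 3 * sum(ca) - 6
  pc <- ensemble_pca(ens, ca, p = min(p_full, M - 1), tol = 1e-12,
                     max_iter = 200)
  # the model mean projects to the origin
  mean_ens <- ensemble(array(cbind(pc$mean_coords,
                                   matrix(0, sum(ca), 0)),
                             c(1, sum(ca), 3)))
  pc_ca <- pc; pc_ca$mask <- rep(TRUE, sum(ca))
  proj0 <- project_ensemble(mean_ens, pc_ca)
  expect_true(all(abs(as.matrix(proj0[, seq_len(nrow(pc$components))])) < 1e-8))
  # completeness: full-rank reconstruction reproduces the masked coords
  idx <- which(ca)
  proj <- project_ensemble(ens, pc)
  P <- as.matrix(proj[, seq_len(nrow(pc$components))])
  for (i in seq_len(M)) {
    xi <- superpose(ens$coords[i, idx, ], pc$mean_coords)$coords
    recon <- as.vector(t(pc$mean_coords)) +
      drop(t(pc$components) %*% P[i, ])
    expect_equal(recon, as.vector(t(xi)), tolerance = 1e-8)
  }
})

test_that("KDE maps normalize, localize bimodality, and ignore duplication", {
  set.seed(3)
  cloud1 <- cbind(rnorm(120, -5, 0.3), rnorm(120, 0, 0.3))
  cloud2 <- cbind(rnorm(120, 5, 0.3), rnorm(120, 1, 0.3))
  pts <- rbind(cloud1, cloud2)
  map <- kde_map(pts, grid_n = 120)
  cell <- diff(map$grid_x[1:2]) * diff(map$grid_y[1:2])
  expect_equal(sum(map$density) * cell, 1, tolerance = 1e-3)
  expect_true(all(map$density >= 0))
  # the two highest well-separated local maxima sit at the cloud centers
  peak <- which(map$density == max(map$density), arr.ind = TRUE)[1, ]
  half <- map$density
  half[map$grid_x > 0, ] <- 0
  peak_left <- which(half == max(half), arr.ind = TRUE)[1, ]
  dx <- diff(map$grid_x[1:2]); dy <- diff(map$grid_y[1:2])
  expect_lt(abs(map$grid_x[peak_left[1]] - (-5)), 2 * dx + 0.15)
  expect_lt(abs(map$grid_y[peak_left[2]] - 0), 2 * dy + 0.15)
  right <- map$density; right[map$grid_x < 0, ] <- 0
  peak_right <- which(right == max(right), arr.ind = TRUE)[1, ]
  expect_lt(abs(map$grid_x[peak_right[1]] - 5), 2 * dx + 0.15)
  # duplicating every point leaves the normalized map nearly unchanged
  map2 <- kde_map(rbind(pts, pts), grid_n = 120,
                  bandwidth = sqrt(diag(map$bandwidth)))
  expect_lt(max(abs(map2$density - map$density)) / max(map$density), 1e-6)
  expect_error(kde_map(cbind(rep(1, 10), rnorm(10))), "zero-variance")
})

test_that("inter-domain angles reproduce hand geometries", {
  atoms <- data.frame(atom_serial = 1:3, atom_name = "CA", element = "C",
                      residue_index = 1:3, residue_name = "GLY",
                      chain_id = "A")
  spec <- angle_spec("resid 1", "resid 2", "resid 3")
  collinear <- Structure(atoms, rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                         coarse_grained = TRUE)
  expect_equal(interdomain_angle(collinear$coords, spec, collinear), 180)
  right <- Structure(atoms, rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
                     coarse_grained = TRUE)
  expect_equal(interdomain_angle(right$coords, spec, right), 90)
  expect_error(interdomain_angle(right$coords,
                                 angle_spec("resid 1", "resid 1-2", "resid 3"),
                                 right),
               "disjoint")
  tr <- angle_trace(ensemble(right$coords), spec, right)
  expect_equal(tr$angle, 90)
})

test_that("analysis outputs are invariant under rigid motion of the inputs", {
  s <- make_toy(toy_spec(8))
  ca <- select_atoms(s, "calpha")
  set.seed(44)
  M <- 6
  coords <- array(0, c(M, n_atoms(s), 3))
  for (i in seq_len(M))
    coords[i, , ] <- s$coords + matrix(rnorm(3 * n_atoms(s), sd = 0.3),
                                       ncol = 3)
  moved <- coords
  R <- fixed_rotation(7)
  for (i in seq_len(M)) moved[i, , ] <- apply_rigid(coords[i, , ], R)
  pc <- ensemble_pca(ensemble(coords), ca, p = 2)
  pcm <- ensemble_pca(ensemble(moved), ca, p = 2)
  expect_equal(pc$variances, pcm$variances, tolerance = 1e-6)
  spec <- angle_spec("resid 1-2", "resid 4-5", "resid 7-8")
  for (i in seq_len(M))
    expect_equal(interdomain_angle(coords[i, , ], spec, s),
                 interdomain_angle(moved[i, , ], spec, s), tolerance = 1e-8)
  D <- pairwise_rmsd(ensemble(coords), ca)
  Dm <- pairwise_rmsd(ensemble(moved), ca)
  expect_equal(D, Dm, tolerance = 1e-8)
})
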