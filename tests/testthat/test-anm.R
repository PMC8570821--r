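test_that("Hessian superelements follow the ANM formula", {
  # three nodes; pair (1,2) at distance 1 on x: off-diagonal block -diag(1,0,0)
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.2, 0))
  H <- build_hessian(coords, anm_params(cutoff = 1.5, gamma = 1))
  expect_equal(H[1:3, 4:6], -diag(c(1, 0, 0)), tolerance = 1e-12)
  # pair (2,3) farther than cutoff: zero block
  expect_equal(H[4:6, 7:9], matrix(0, 3, 3))
  expect_equal(H, t(H))
  # full matrix matches the explicit-loop construction
  s <- make_toy(toy_spec(9))
  ca <- s$coords[select_atoms(s, "calpha"), ]
  expect_equal(build_hessian(ca, anm_params(cutoff = 8, gamma = 2.5)),
               loop_hessian(ca, cutoff = 8, gamma = 2.5), tolerance = 1e-12)
})

test_that("Hessian is translation-invariant and positive semidefinite", {
  s <- make_toy(toy_spec(12, "two_domain", 3))
  ca <- s$coords[select_atoms(s, "calpha"), ]
  H <- build_hessian(ca, anm_params())
  n <- nrow(ca)
  for (ax in 1:3) {
    t_vec <- rep(0, 3 * n); t_vec[seq(ax, 3 * n, by = 3)] <- 1
    expect_lt(max(abs(H %*% t_vec)), 1e-10)
  }
  expect_gt(min(eigen(H, symmetric = TRUE)$values), -1e-10)
})

test_that("degenerate networks are rejected, not patched", {
  line <- cbind(seq(0, 12, by = 3), 0, 0)
  expect_error(build_hessian(line, anm_params(cutoff = 4)), "collinear")
  far <- rbind(c(0, 0, 0), c(1, 1, 0), c(100, 100, 100))
  expect_error(build_hessian(far, anm_params(cutoff = 5)), "node")
})

test_that("mode computation discards exactly six rigid-body modes", {
  for (spec in list(toy_spec(8), toy_spec(14, "two_domain", 2),
                    toy_spec(30, "two_domain", 5))) {
    s <- make_toy(spec)
    ca <- s$coords[select_atoms(s, "calpha"), ]
    H <- build_hessian(ca, anm_params())
    vals <- eigen(H, symmetric = TRUE)$values
    expect_equal(sum(vals < 1e-8 * max(vals)), 6L)
    mb <- compute_modes(H, anm_params(n_modes = 3))
    expect_equal(length(mb$eigenvalues), 3L)
    expect_true(all(diff(mb$eigenvalues) >= 0))
    expect_true(all(mb$eigenvalues > 0))
  }
})

test_that("modes are orthonormal eigenpairs of the Hessian", {
  s <- make_toy(toy_spec(10))
  ca <- s$coords[select_atoms(s, "calpha"), ]
  H <- build_hessian(ca, anm_params())
  mb <- compute_modes(H, anm_params(n_modes = 4))
  G <- mb$node_vectors %*% t(mb$node_vectors)
  expect_equal(G, diag(4), tolerance = 1e-8, ignore_attr = TRUE)
  for (k in 1:4) {
    v <- mb$node_vectors[k, ]
    expect_equal(drop(v %*% H %*% v), mb$eigenvalues[k], tolerance = 1e-8)
  }
  expect_error(compute_modes(H, anm_params(n_modes = 100)), "exceeds")
})

test_that("bent 3-node chain matches an independent dense eigensolve", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  p <- anm_params(cutoff = 1.5, n_modes = 3)
  H <- build_hessian(coords, p)
  mb <- compute_modes(H, p)
  oracle_vals <- sort(eigen(loop_hessian(coords, cutoff = 1.5), symmetric = TRUE,
                            only.values = TRUE)$values)
  nonzero <- oracle_vals[oracle_vals > 1e-8 * max(oracle_vals)]
  expect_equal(mb$eigenvalues, nonzero[1:3], tolerance = 1e-10)
})

test_that("eigenvalues are invariant under rigid motion and scale with gamma", {
  s <- make_toy(toy_spec(11))
  ca <- s$coords[select_atoms(s, "calpha"), ]
  p <- anm_params(n_modes = 3)
  ev <- compute_modes(build_hessian(ca, p), p)$eigenvalues
  moved <- apply_rigid(ca, fixed_rotation())
  ev_moved <- compute_modes(build_hessian(moved, p), p)$eigenvalues
  expect_equal(ev, ev_moved, tolerance = 1e-8)
  p3 <- anm_params(gamma = 3, n_modes = 3)
  mb1 <- compute_modes(build_hessian(ca, p), p)
  mb3 <- compute_modes(build_hessian(ca, p3), p3)
  expect_equal(mb3$eigenvalues, 3 * mb1$eigenvalues, tolerance = 1e-10)
  expect_equal(abs(rowSums(mb3$node_vectors * mb1$node_vectors)),
               rep(1, 3), tolerance = 1e-6)
})

test_that("rigid-residue extension copies each CA displacement to its CB", {
  s <- make_toy(toy_spec(9))
  mb <- anm_modes(s, anm_params(n_modes = 3))
  ca_idx <- which(select_atoms(s, "calpha"))
  cb_idx <- which(select_atoms(s, "name CB"))
  for (k in 1:3) {
    av <- matrix(mb$atom_vectors[k, ], ncol = 3, byrow = TRUE)
    nodev <- matrix(mb$node_vectors[k, ], ncol = 3, byrow = TRUE)
    expect_equal(av[ca_idx, ], nodev, ignore_attr = TRUE)   # CA rows unchanged
    expect_equal(av[cb_idx, ], nodev, ignore_attr = TRUE)   # CB copies its CA
    # with 2 atoms/residue the extended norm doubles the squared node norm
    expect_equal(sum(av^2), 2 * sum(nodev^2), tolerance = 1e-10)
  }
})

test_that("a CA-only structure extends to itself", {
  s0 <- make_toy(toy_spec(8))
  keep <- select_atoms(s0, "calpha")
  s <- Structure(s0$atoms[keep, ], s0$coords[keep, ], coarse_grained = TRUE)
  mb <- anm_modes(s, anm_params(n_modes = 2))
  expect_equal(mb$atom_vectors, mb$node_vectors, ignore_attr = TRUE)
})

test_that("softest mode of the two-domain fixture is the inter-domain motion", {
  s <- make_toy(toy_spec(40, "two_domain", 4))
  mb <- anm_modes(s, anm_params(n_modes = 6))
  ca_idx <- which(select_atoms(s, "calpha"))
  ca <- s$coords[ca_idx, ]
  n1 <- (40 - 4) %/% 2
  dom2_res <- (n1 + 4 + 1):40
  hinge <- colMeans(ca[(n1 + 1):(n1 + 4), ])     # linker centroid
  # basis of rigid rotations of domain 2 about the hinge, zero elsewhere
  hinge_fields <- vapply(1:3, function(ax) {
    axis <- c(0, 0, 0); axis[ax] <- 1
    field <- matrix(0, nrow(ca), 3)
    arm <- sweep(ca[dom2_res, , drop = FALSE], 2, hinge)
    field[dom2_res, ] <- t(apply(arm, 1, function(r)
      c(axis[2] * r[3] - axis[3] * r[2],
        axis[3] * r[1] - axis[1] * r[3],
        axis[1] * r[2] - axis[2] * r[1])))
    as.vector(t(field))
  }, numeric(3 * nrow(ca)))
  Q <- qr.Q(qr(hinge_fields))
  overlap <- vapply(seq_along(mb$eigenvalues), function(k) {
    v <- mb$node_vectors[k, ]
    sqrt(sum((t(Q) %*% v)^2)) / sqrt(sum(v^2))
  }, numeric(1))
  expect_equal(which.max(overlap), 1L)
})
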