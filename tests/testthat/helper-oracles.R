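# Independent oracles used across the suite.  These deliberately avoid the
# package's own numerical paths (Kabsch SVD, vectorised Hessian assembly,
# medoid search) so they can serve as cross-checks.

# rotation matrix from a unit quaternion
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rmsd_at_rotation <- function(A, B, R) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  sqrt(mean(rowSums((Ac %*% t(R) - Bc)^2)))
}

# brute-force minimum superposed RMSD: quaternion sampling followed by
# Nelder-Mead refinement of the best starts (translation handled in closed
# form by centroid alignment)
brute_force_rmsd <- function(A, B, n_grid = 4000L, n_refine = 5L) {
  set.seed(424242)
  qs <- matrix(rnorm(4L * n_grid), ncol = 4L)
  vals <- apply(qs, 1, function(q) rmsd_at_rotation(A, B, quat_to_rot(q)))
  best <- order(vals)[seq_len(n_refine)]
  refine <- function(q0) {
    stats::optim(q0, function(q) {
      if (sum(q^2) < 1e-12) return(1e9)
      rmsd_at_rotation(A, B, quat_to_rot(q))
    }, method = "Nelder-Mead",
    control = list(maxit = 4000, reltol = 1e-14))$value
  }
  min(vapply(best, function(i) refine(qs[i, ]), numeric(1)))
}

# exhaustive medoid: member with the smallest within-cluster distance sum,
# first index on ties
exhaustive_medoid <- function(dist_mat, members) {
  sums <- vapply(members, function(i) sum(dist_mat[i, members]), numeric(1))
  members[which.min(sums)]
}

# ANM Hessian assembled by explicit superelement loops (independent of the
# package's construction)
loop_hessian <- function(coords, cutoff = 15, gamma = 1) {
  n <- nrow(coords)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- coords[j, ] - coords[i, ]
    r2 <- sum(d^2)
    if (r2 > cutoff^2) next
    blk <- -(gamma / r2) * outer(d, d)
    ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
    H[ri, rj] <- blk
    H[ri, ri] <- H[ri, ri] - blk
  }
  H
}

# deterministic proper rotation for invariance tests
fixed_rotation <- function(seed = 99) {
  set.seed(seed)
  quat_to_rot(rnorm(4))
}

apply_rigid <- function(coords, R, t = c(1.5, -2.25, 3.75)) {
  sweep(coords %*% t(R), 2, t, "+")
}

# radius of gyration of a coordinate set
rgyr <- function(x) sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))

# small pipeline config used by several tests
toy_pipeline_config <- function(..., output_dir = NULL) {
  pipeline_config(
    n_gens = 2L,
    sampling = sampling_params(n_confs = 6L, target_rmsd = 0.75),
    anm = anm_params(n_modes = 3L),
    cluster = cluster_params(maxclust = 3L),
    relax = relax_params(max_steps = 120L),
    output_dir = output_dir,
    master_seed = 11L,
    ...)
}
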