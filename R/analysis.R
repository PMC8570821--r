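#' Kabsch superposition
#'
#' Least-squares optimal rigid-body fit of \code{mobile} onto
#' \code{reference}: rotation and translation are computed on the masked
#' atoms (proper rotation enforced, determinant +1) and applied to all atoms.
#'
#' @param mobile N x 3 coordinate matrix to move.
#' @param reference N x 3 coordinate matrix to fit onto.
#' @param mask logical atom mask used for the fit (default: all atoms).
#' @return list with \code{coords} (rotated+translated mobile, all atoms) and
#'   \code{rmsd} (Angstrom, over the masked atoms).
#' @export
superpose <- function(mobile, reference, mask = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, all(dim(mobile) == dim(reference)))
  if (is.null(mask)) mask <- rep(TRUE, nrow(mobile))
  idx <- mask_indices(mask, "superposition mask")
  if (length(idx) < 3L)
    stop("superposition needs at least 3 selected atoms", call. = FALSE)
  A <- mobile[idx, , drop = FALSE]
  B <- reference[idx, , drop = FALSE]
  if (qr(sweep(B, 2, colMeans(B)))$rank < 2L ||
      qr(sweep(A, 2, colMeans(A)))$rank < 2L)
    stop("collinear selection: superposition is ill-defined", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  R <- kabsch_rotation(sweep(A, 2, ca), sweep(B, 2, cb))
  moved <- sweep(sweep(mobile, 2, ca) %*% R, 2, cb, "+")
  list(coords = moved,
       rmsd = raw_rmsd(moved, reference, idx))
}

# proper rotation R (3x3, det +1) minimizing ||Ac R - Bc|| for centered sets
kabsch_rotation <- function(Ac, Bc) {
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Essential-dynamics PCA of an ensemble
#'
#' Conformers are iteratively superposed (on the masked atoms) onto the
#' running mean until the mean shifts by less than \code{tol} Angstrom, then
#' the covariance matrix of the masked coordinates is eigendecomposed.  The
#' top components span the essential subspace of the ensemble.  Component
#' signs follow the convention that each component's largest-magnitude entry
#' is positive, so results are deterministic.
#'
#' @param ens an \code{Ensemble} (M >= p + 1 conformers).
#' @param mask logical atom mask (typically the C-alpha atoms) defining the
#'   coordinates entering the covariance.
#' @param p number of principal components to keep.
#' @param tol mean-shift convergence threshold (Angstrom).
#' @param max_iter cap on superposition iterations.
#' @return a \code{PcModel}: list with \code{mean_coords} (n_mask x 3),
#'   \code{components} (p x 3 n_mask orthonormal rows), \code{variances}
#'   (non-increasing) and \code{mask}.
#' @export
ensemble_pca <- function(ens, mask, p = 2L, tol = 1e-6, max_iter = 50L) {
  stopifnot(inherits(ens, "Ensemble"))
  M <- n_conformers(ens)
  if (M <= p)
    stop("PCA with p = ", p, " components needs at least p + 1 = ", p + 1L,
         " conformers, got ", M, call. = FALSE)
  idx <- mask_indices(mask, "PCA mask")
  X <- lapply(seq_len(M), function(i) ens$coords[i, idx, , drop = TRUE])
  mean_c <- X[[1]]
  for (it in seq_len(max_iter)) {
    X <- lapply(X, function(xi) superpose(xi, mean_c)$coords)
    new_mean <- Reduce(`+`, X) / M
    shift <- sqrt(mean((new_mean - mean_c)^2))
    mean_c <- new_mean
    if (shift < tol) break
  }
  flat <- t(vapply(X, function(xi) as.vector(t(xi)), numeric(3L * length(idx))))
  mean_vec <- colMeans(flat)
  # report the flat-row mean so projections of the mean are exactly zero
  mean_c <- matrix(mean_vec, ncol = 3L, byrow = TRUE)
  flat <- sweep(flat, 2, mean_vec)
  cv <- crossprod(flat) / (M - 1L)
  eig <- eigen(cv, symmetric = TRUE)
  comp <- t(eig$vectors[, seq_len(p), drop = FALSE])
  for (k in seq_len(p)) {
    j <- which.max(abs(comp[k, ]))
    if (comp[k, j] < 0) comp[k, ] <- -comp[k, ]
  }
  structure(list(mean_coords = mean_c,
                 components = comp,
                 variances = pmax(eig$values[seq_len(p)], 0),
                 all_variances = pmax(eig$values, 0),
                 mask = mask),
            class = "PcModel")
}

#' @export
print.PcModel <- function(x, ...) {
  cat(sprintf("PcModel: %d component(s) on %d atoms\n",
              nrow(x$components), nrow(x$mean_coords)))
  cat("variances:", format(x$variances, digits = 4), "\n")
  invisible(x)
}

#' Project conformers onto a principal-component model
#'
#' Each conformer is superposed onto the model mean (masked atoms) and its
#' deviation from the mean is dotted with each component.
#'
#' @param ens an \code{Ensemble} on the same topology the model was built on.
#' @param pc_model a \code{PcModel} from [ensemble_pca()].
#' @return data frame with M rows and columns \code{PC1..PCp},
#'   \code{generation}, \code{parent}.
#' @export
project_ensemble <- function(ens, pc_model) {
  stopifnot(inherits(ens, "Ensemble"), inherits(pc_model, "PcModel"))
  idx <- which(pc_model$mask)
  if (dim(ens$coords)[2] != length(pc_model$mask))
    stop("ensemble atom count does not match the PCA mask", call. = FALSE)
  p <- nrow(pc_model$components)
  out <- matrix(0, n_conformers(ens), p)
  for (i in seq_len(n_conformers(ens))) {
    xi <- superpose(ens$coords[i, idx, , drop = TRUE], pc_model$mean_coords)$coords
    dev <- as.vector(t(xi - pc_model$mean_coords))
    out[i, ] <- pc_model$components %*% dev
  }
  colnames(out) <- paste0("PC", seq_len(p))
  cbind(as.data.frame(out), generation = ens$generation, parent = ens$parent)
}

#' Gaussian kernel-density population map
#'
#' Product Gaussian kernel on a regular 2-D grid with per-axis bandwidths
#' from Scott's rule, \eqn{h_j = \hat\sigma_j M^{-1/6}} (the 2-D case of
#' \eqn{M^{-1/(d+4)}}), computed from the sample covariance.  The returned
#' density integrates to 1 over the grid (cell-summed density times cell
#' area) to within the grid truncation error.
#'
#' @param points M x 2 matrix (e.g. PC projections or two angle coordinates).
#' @param grid_n grid points per axis.
#' @param expand grid margin as a multiple of the bandwidth beyond the data
#'   range, so the kernels' mass is captured.
#' @param bandwidth optional length-2 override of the Scott bandwidths.
#' @return a \code{DensityMap}: list with \code{grid_x}, \code{grid_y},
#'   \code{density} (grid_n x grid_n, x by y) and \code{bandwidth}.
#' @export
kde_map <- function(points, grid_n = 100L, expand = 4, bandwidth = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be M x 2", call. = FALSE)
  M <- nrow(points)
  if (M < 2L) stop("KDE needs at least 2 points", call. = FALSE)
  sds <- apply(points, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate (zero-variance) dimension: jitter the points or use a ",
         "1-D density instead", call. = FALSE)
  if (is.null(bandwidth)) bandwidth <- sds * M^(-1 / 6)
  gx <- seq(min(points[, 1]) - expand * bandwidth[1],
            max(points[, 1]) + expand * bandwidth[1], length.out = grid_n)
  gy <- seq(min(points[, 2]) - expand * bandwidth[2],
            max(points[, 2]) + expand * bandwidth[2], length.out = grid_n)
  # separable kernel: density = (Kx %*% t(Ky)) averaged over points
  Kx <- outer(gx, points[, 1], function(g, x) stats::dnorm(g, x, bandwidth[1]))
  Ky <- outer(gy, points[, 2], function(g, y) stats::dnorm(g, y, bandwidth[2]))
  dens <- (Kx %*% t(Ky)) / M
  structure(list(grid_x = gx, grid_y = gy, density = dens,
                 bandwidth = diag(bandwidth^2)),
            class = "DensityMap")
}

#' @export
print.DensityMap <- function(x, ...) {
  cat(sprintf("DensityMap: %d x %d grid, peak density %.4g\n",
              length(x$grid_x), length(x$grid_y), max(x$density)))
  invisible(x)
}

#' Plot a population density map
#'
#' Filled image plus contour lines, base graphics.
#'
#' @param x a \code{DensityMap}.
#' @param xlab,ylab axis labels.
#' @param ... passed to [graphics::image()].
#' @return invisibly, \code{x}.
#' @export
plot.DensityMap <- function(x, xlab = "coordinate 1", ylab = "coordinate 2",
                            ...) {
  graphics::image(x$grid_x, x$grid_y, x$density, xlab = xlab, ylab = ylab,
                  col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE), ...)
  graphics::contour(x$grid_x, x$grid_y, x$density, add = TRUE,
                    drawlabels = FALSE, col = "grey30")
  invisible(x)
}

#' Inter-domain angle specification
#'
#' Three atom selections: two domain groups and a vertex group (e.g. the LID,
#' CORE and NMP domains of adenylate kinase, whose LID-Core and NMP-Core
#' angles are classic open/closed reaction coordinates).  Residue range
#' definitions are system-specific inputs; none are hard-coded.
#'
#' @param group_a,vertex_group,group_b selection expressions (see
#'   [select_atoms()]); must be non-empty and pairwise disjoint on the
#'   structure they are used with.
#' @return a list of class \code{"AngleSpec"}.
#' @export
angle_spec <- function(group_a, vertex_group, group_b) {
  structure(list(group_a = group_a, vertex_group = vertex_group,
                 group_b = group_b),
            class = "AngleSpec")
}

#' Inter-domain angle of one conformer
#'
#' Angle at the vertex-group centroid between the two domain-group
#' centroids, in degrees within \[0, 180\].
#'
#' @param coords N x 3 coordinate matrix.
#' @param spec an \code{AngleSpec}.
#' @param structure the \code{Structure} the selections refer to.
#' @return angle in degrees.
#' @export
interdomain_angle <- function(coords, spec, structure) {
  stopifnot(inherits(spec, "AngleSpec"))
  coords <- as.matrix(coords)
  masks <- lapply(spec, function(e) select_atoms(structure, e))
  idx <- lapply(seq_along(masks), function(i)
    mask_indices(masks[[i]], paste0("angle selection '", spec[[i]], "'")))
  if (any(masks[[1]] & masks[[2]]) || any(masks[[2]] & masks[[3]]) ||
      any(masks[[1]] & masks[[3]]))
    stop("angle selections must be pairwise disjoint", call. = FALSE)
  cent <- lapply(idx, function(i) colMeans(coords[i, , drop = FALSE]))
  u <- cent[[1]] - cent[[2]]
  v <- cent[[3]] - cent[[2]]
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Inter-domain angle trace over an ensemble
#'
#' @param ens an \code{Ensemble}.
#' @param spec an \code{AngleSpec}.
#' @param structure the \code{Structure} the selections refer to.
#' @return data frame with columns \code{conformer}, \code{angle},
#'   \code{generation}.
#' @export
angle_trace <- function(ens, spec, structure) {
  stopifnot(inherits(ens, "Ensemble"))
  ang <- vapply(seq_len(n_conformers(ens)), function(i)
    interdomain_angle(ens$coords[i, , , drop = TRUE], spec, structure),
    numeric(1))
  data.frame(conformer = seq_along(ang), angle = ang,
             generation = ens$generation)
}

#' Write a density map as a delimited grid file
#'
#' Plain-text table: first row/column carry the grid axes.
#'
#' @param map a \code{DensityMap}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_density <- function(map, path) {
  stopifnot(inherits(map, "DensityMap"))
  tab <- rbind(c(NA, map$grid_y), cbind(map$grid_x, map$density))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}
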