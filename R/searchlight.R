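## Searchlight mapping: spherical neighborhoods in millimetre space,
## per-sphere LDC RDM + decomposition with coefficients written to the
## central voxel, and Gaussian smoothing of the resulting maps.

#' Spherical searchlight neighborhoods
#'
#' One sphere per in-mask voxel; membership is by Euclidean millimetre
#' distance (through the affine) less than or equal to the radius,
#' restricted to the mask.
#'
#' @param mask Logical 3D array.
#' @param affine 4 x 4 voxel-to-mm transform (default from
#'   \code{voxel_size_mm}).
#' @param radius_mm Sphere radius in mm (default 10).
#' @param voxel_size_mm Isotropic voxel size used when \code{affine} is
#'   missing.
#' @return List with \code{centers} (matrix of voxel coordinates),
#'   \code{members} (list of integer vectors indexing \code{centers}'
#'   linear in-mask order... see Details), \code{radius_mm},
#'   \code{affine}.
#' @details \code{members[[i]]} holds linear array indices (into
#'   \code{mask}) of the voxels of sphere \code{i}; the center's own
#'   linear index is \code{centers_linear[i]} and is always a member.
#' @export
sphere_neighborhoods <- function(mask, affine = NULL, radius_mm = 10,
                                 voxel_size_mm = 2) {
  stopifnot(radius_mm > 0)
  if (is.null(affine)) affine <- diag(c(rep(voxel_size_mm, 3), 1))
  A <- affine[1:3, 1:3]
  if (abs(det(A)) < 1e-12) stop("affine is not invertible")
  if (!any(mask)) stop("empty mask")
  dims <- dim(mask)

  # candidate integer offsets within radius: exhaustive scan of the
  # conservative voxel box radius / smallest singular value of A
  sv <- svd(A)$d
  r_vox <- ceiling(radius_mm / min(sv))
  off <- as.matrix(expand.grid(dx = -r_vox:r_vox, dy = -r_vox:r_vox,
                               dz = -r_vox:r_vox))
  mm2 <- colSums((A %*% t(off))^2)
  off <- off[mm2 <= radius_mm^2 + 1e-9, , drop = FALSE]

  centers <- which(mask, arr.ind = TRUE)
  centers_linear <- which(mask)
  members <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    pts <- sweep(off, 2L, centers[i, ], "+")
    ok <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
      pts[, 2] >= 1 & pts[, 2] <= dims[2] &
      pts[, 3] >= 1 & pts[, 3] <= dims[3]
    pts <- pts[ok, , drop = FALSE]
    lin <- pts[, 1] + (pts[, 2] - 1L) * dims[1] +
      (pts[, 3] - 1L) * dims[1] * dims[2]
    members[[i]] <- lin[mask[lin]]
  }
  list(centers = centers, centers_linear = centers_linear,
       members = members, radius_mm = radius_mm, affine = affine)
}

#' Searchlight decomposition maps
#'
#' For every sphere: estimate the per-run noise covariance from the GLM
#' residuals of the sphere's voxels, compute the 72 x 72 cross-validated
#' LDC RDM, fit the RDM decomposition, and assign the coefficients to the
#' sphere's central voxel. Spheres with fewer than \code{min_voxels}
#' members yield missing values.
#'
#' @param patterns1,patterns2 \code{condition_patterns} whose columns are
#'   the in-mask voxels (in \code{which(mask)} order).
#' @param mask Logical 3D array defining the analysis volume.
#' @param model A \code{model_rdm_set}.
#' @param residuals1,residuals2 Optional per-run GLM residual matrices
#'   (time x in-mask voxel) for noise normalization; when omitted the
#'   noise model is the identity (plain cross-validated squared
#'   Euclidean distances).
#' @param radius_mm Sphere radius in mm (default 10).
#' @param affine Voxel-to-mm transform.
#' @param min_voxels Minimum sphere size (default 10).
#' @return Named list of 3D coefficient arrays (\code{item}, \code{room},
#'   \code{task}, \code{step}, \code{visual}), NA outside the mask and at
#'   undersized spheres.
#' @export
searchlight_decomposition_maps <- function(patterns1, patterns2, mask,
                                           model, residuals1 = NULL,
                                           residuals2 = NULL,
                                           radius_mm = 10, affine = NULL,
                                           min_voxels = 10L,
                                           voxel_size_mm = 2) {
  P1 <- if (inherits(patterns1, "condition_patterns")) patterns1$patterns
        else as.matrix(patterns1)
  P2 <- if (inherits(patterns2, "condition_patterns")) patterns2$patterns
        else as.matrix(patterns2)
  nvox <- sum(mask)
  stopifnot(ncol(P1) == nvox, ncol(P2) == nvox)
  nb <- sphere_neighborhoods(mask, affine = affine, radius_mm = radius_mm,
                             voxel_size_mm = voxel_size_mm)
  # map linear array index -> column of the pattern matrices
  col_of <- integer(prod(dim(mask)))
  col_of[which(mask)] <- seq_len(nvox)

  coef_names <- c("item", "room", "task", "step", "visual")
  maps <- lapply(coef_names, function(nm) array(NA_real_, dim(mask)))
  names(maps) <- coef_names
  for (i in seq_along(nb$members)) {
    cols <- col_of[nb$members[[i]]]
    if (length(cols) < min_voxels) next
    n1 <- if (is.null(residuals1)) "identity"
          else estimate_noise_covariance(residuals1[, cols, drop = FALSE])
    n2 <- if (is.null(residuals2)) "identity"
          else estimate_noise_covariance(residuals2[, cols, drop = FALSE])
    rdm <- compute_rdm(P1[, cols, drop = FALSE], P2[, cols, drop = FALSE],
                       noise1 = n1, noise2 = n2, normalize = TRUE)
    rdm$conditions <- model$conditions
    fit <- fit_decomposition(rdm, model)
    for (nm in coef_names)
      maps[[nm]][nb$centers_linear[i]] <- fit$coefficients[[nm]]
  }
  maps
}

#' Gaussian smoothing of a coefficient map
#'
#' Separable Gaussian filter with sigma = fwhm / (2 sqrt(2 ln 2)) per
#' axis in mm, converted to voxels through the affine. Missing values are
#' excluded by renormalizing the kernel weights over observed voxels;
#' voxels that were missing stay missing.
#'
#' @param vol Numeric 3D array (may contain NA).
#' @param fwhm_mm Full width at half maximum in mm (0 = identity).
#' @param affine Voxel-to-mm transform; default isotropic
#'   \code{voxel_size_mm}.
#' @param voxel_size_mm Isotropic voxel size used when \code{affine} is
#'   missing.
#' @return Smoothed array, same shape.
#' @export
smooth_volume <- function(vol, fwhm_mm = 10, affine = NULL,
                          voxel_size_mm = 2) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(vol)
  if (is.null(affine)) affine <- diag(c(rep(voxel_size_mm, 3), 1))
  vox_mm <- sqrt(colSums(affine[1:3, 1:3]^2))
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox_mm

  na_mask <- is.na(vol)
  w <- array(as.numeric(!na_mask), dim(vol))
  v <- vol; v[na_mask] <- 0

  smooth_axis <- function(x, axis, sigma) {
    if (sigma <= 0) return(x)
    r <- max(1L, ceiling(4 * sigma))
    k <- stats::dnorm(-r:r, sd = sigma)
    k <- k / sum(k)
    d <- dim(x)
    perm <- c(axis, setdiff(1:3, axis))
    xp <- aperm(x, perm)
    m <- matrix(xp, nrow = d[axis])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      sh <- j - r - 1L
      src <- seq_len(n) + sh
      # half-sample reflection at the boundaries: preserves constants
      # and, for all-finite maps, total mass
      while (any(src < 1L | src > n)) {
        src[src < 1L] <- 1L - src[src < 1L]
        src[src > n] <- 2L * n + 1L - src[src > n]
      }
      out <- out + k[j] * m[src, , drop = FALSE]
    }
    aperm(array(out, d[perm]), order(perm))
  }
  for (ax in 1:3) {
    v <- smooth_axis(v, ax, sigma_vox[ax])
    w <- smooth_axis(w, ax, sigma_vox[ax])
  }
  out <- v / w
  out[na_mask] <- NA_real_
  out[w == 0] <- NA_real_
  out
}
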