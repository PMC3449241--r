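# Conductivity assignment: isotropic table values, or effective-medium
# rescaling of diffusion-like tensors for anisotropic white matter.

#' Rescale a diffusion-like tensor to a conductivity tensor
#'
#' Effective-medium conversion with a per-tensor volume constraint: the
#' output shares the input's eigenvectors, and all eigenvalues are scaled
#' by one positive factor chosen so that the geometric mean of the output
#' eigenvalues (equivalently `det(sigma)^(1/3)`) equals the tissue's target
#' isotropic conductivity. Eigenvalue ratios, and hence the anisotropy
#' ratio, are preserved exactly.
#'
#' @param tensor 3x3 symmetric positive-definite matrix (diffusion-like,
#'   arbitrary units).
#' @param sigma_iso_target Target isotropic conductivity in S/m.
#' @return 3x3 SPD conductivity tensor in S/m.
#' @examples
#' effective_medium_scale(diag(c(4, 1, 1)), 0.19)
#' @export
effective_medium_scale <- function(tensor, sigma_iso_target) {
  stopifnot(is.matrix(tensor), all(dim(tensor) == 3))
  if (sigma_iso_target <= 0) stop("sigma_iso_target must be > 0")
  if (max(abs(tensor - t(tensor))) > 1e-10 * max(abs(tensor)))
    stop("tensor must be symmetric")
  d <- det(tensor)
  if (d <= 0 || any(eigen(tensor, symmetric = TRUE,
                          only.values = TRUE)$values <= 0))
    stop("tensor must be positive definite")
  tensor * (sigma_iso_target / d^(1 / 3))
}

# vectorized volume-constraint scaling on n x 6 compact tensors
scale_tensors_6 <- function(t6, targets) {
  d <- t6[, 1] * (t6[, 2] * t6[, 3] - t6[, 6]^2) -
       t6[, 4] * (t6[, 4] * t6[, 3] - t6[, 6] * t6[, 5]) +
       t6[, 5] * (t6[, 4] * t6[, 6] - t6[, 2] * t6[, 5])
  if (any(d <= 0)) stop("non-positive-definite tensor in field")
  t6 * (targets / d^(1 / 3))
}

#' Assign conductivity tensors to a mesh
#'
#' Elements of tissues without a supplied tensor receive the isotropic
#' table value times the identity. Where a diffusion-like tensor field is
#' supplied (white matter, optionally gray matter), each element's tensor
#' is rescaled by the effective-medium volume constraint to the tissue's
#' target isotropic conductivity (see [effective_medium_scale()]).
#'
#' @param mesh A `hex_mesh` from [voxels_to_hex_mesh()] (optionally
#'   geometry-adapted).
#' @param table Named conductivity table from [tissue_table()].
#' @param tensors Optional `tensor_field` from
#'   [generate_wm_tensor_field()]; must cover every element of the tensor
#'   tissues it defines.
#' @return The mesh with `tensors` assigned (compact 6-column SPD storage)
#'   and `tensors_assigned = TRUE`. Idempotent for identical inputs.
#' @export
assign_conductivity <- function(mesh, table = tissue_table(),
                                tensors = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"))
  nm <- tissue_name(mesh$labels)
  missing_tab <- setdiff(unique(nm), names(table))
  if (length(missing_tab))
    stop("tissue(s) missing from conductivity table: ",
         paste(missing_tab, collapse = ", "))
  sig <- unname(table[nm])
  t6 <- cbind(xx = sig, yy = sig, zz = sig, xy = 0, xz = 0, yz = 0)

  if (!is.null(tensors)) {
    if (is.null(mesh$voxel_index))
      stop("mesh lacks voxel provenance; cannot map a voxel tensor field")
    pos <- match(mesh$voxel_index, tensors$index)
    has <- !is.na(pos)
    # every element of a tensor-bearing tissue must have a defined tensor
    tensor_tissues <- unique(nm[has])
    uncovered <- nm %in% tensor_tissues & !has
    if (any(uncovered))
      stop("tensor field does not cover all elements of: ",
           paste(unique(nm[uncovered]), collapse = ", "))
    if (any(has))
      t6[has, ] <- scale_tensors_6(tensors$tensors[pos[has], , drop = FALSE],
                                   sig[has])
  }
  mesh$tensors <- t6
  mesh$tensors_assigned <- TRUE
  mesh
}
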