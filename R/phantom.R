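#' Voxelized label volume
#'
#' Container for a voxelized tissue segmentation on a regular grid. Labels
#' follow the [TISSUES] encoding. `voxel_size` is in mm; `origin` is the
#' physical mm coordinate of the centre of the first voxel (index 1,1,1).
#'
#' @param labels 3-D integer array of tissue codes.
#' @param voxel_size Voxel edge length in mm (scalar, isotropic).
#' @param origin Numeric length-3, mm coordinate of the first voxel centre.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size, origin) {
  stopifnot(length(dim(labels)) == 3, voxel_size > 0, length(origin) == 3)
  if (!all(labels %in% TISSUES))
    stop("labels contain codes outside the tissue enumeration")
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "label_volume"
  )
}

#' @exportS3Method base::print
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat("label_volume:", paste(d, collapse = " x "), "voxels @",
      x$voxel_size, "mm\n")
  tab <- table(factor(tissue_name(x$labels), levels = names(TISSUES)))
  tab <- tab[tab > 0]
  for (nm in names(tab)) cat(sprintf("  %-17s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Default layered-sphere specification
#'
#' Outer radii (mm) of the nested tissue shells of the default head phantom:
#' WM 64, GM 71, CSF 74, then a skull compacta / spongiosa / compacta
#' sandwich at 76 / 79 / 81, and skin out to 86 mm. Approximates an adult
#' head; all radii are configurable.
#'
#' @return Data frame with columns `tissue` (name), `code`, `radius` (mm),
#'   ordered innermost first with strictly increasing radii.
#' @export
default_layer_spec <- function() {
  data.frame(
    tissue = c("wm", "gm", "csf", "skull_compacta", "skull_spongiosa",
               "skull_compacta", "skin"),
    code   = TISSUES[c("wm", "gm", "csf", "skull_compacta", "skull_spongiosa",
                       "skull_compacta", "skin")],
    radius = c(64, 71, 74, 76, 79, 81, 86),
    row.names = NULL
  )
}

#' Generate a voxelized layered-sphere head phantom
#'
#' Builds a label volume of nested concentric tissue shells centred at the
#' physical origin. Each voxel takes the code of the innermost layer whose
#' outer radius is at least the voxel-centre distance from the phantom
#' centre; voxels outside the outermost radius are background. Optional
#' gyral ridges relabel radial CSF sectors as gray matter so that GM locally
#' protrudes into the CSF shell, emulating gyri.
#'
#' @param layer_spec Data frame with columns `code` and `radius` (mm),
#'   innermost layer first, radii strictly increasing. Default
#'   [default_layer_spec()].
#' @param resolution Voxel edge length in mm. The default 2 mm keeps desk
#'   scale meshes tractable; 1 mm reproduces finer geometry.
#' @param gyrus Optional list describing schematic gyral ridges:
#'   `n` meridional ridges (default 8), `amplitude` as a fraction of the
#'   CSF shell thickness (default 1 = full thickness), `width_deg` angular
#'   half-width in azimuth (default 6), `incl_range` inclination band in
#'   degrees (default c(25, 155)), and `azim_range` to keep only ridges
#'   whose azimuth falls in a window (e.g. `c(135, 225)` for posterior
#'   gyri near the occipital midline). `NULL` disables ridges.
#' @param margin_mm Background padding outside the outer shell, in mm
#'   (room for electrode patches). Default 8.
#' @return A [label_volume]. Attribute `layer_spec` records the geometry.
#' @examples
#' ph <- generate_sphere_phantom(resolution = 4)
#' table(ph$labels)
#' @export
generate_sphere_phantom <- function(layer_spec = default_layer_spec(),
                                    resolution = 2,
                                    gyrus = NULL,
                                    margin_mm = 8) {
  stopifnot(resolution > 0, is.data.frame(layer_spec),
            all(c("code", "radius") %in% names(layer_spec)))
  radii <- layer_spec$radius
  if (any(radii < 0)) stop("layer radii must be non-negative")
  if (length(radii) > 1 && any(diff(radii) <= 0) && any(radii > 0))
    stop("layer radii must be strictly increasing from innermost to outermost")
  thinnest <- min(diff(c(0, radii)))
  if (all(radii == 0)) thinnest <- Inf
  if (resolution > thinnest)
    warning("resolution (", resolution,
            " mm) exceeds the thinnest shell (", thinnest,
            " mm); that shell may vanish")

  rmax <- max(radii)
  half <- ceiling((rmax + margin_mm) / resolution)
  n <- 2L * half + 1L                    # odd: centre voxel exactly at 0
  coord <- (seq_len(n) - (half + 1L)) * resolution
  origin <- rep(coord[1], 3)

  r2 <- outer(outer(coord^2, coord^2, `+`), coord^2, `+`)
  r <- sqrt(r2)
  labels <- array(0L, dim = c(n, n, n))
  # paint outermost first so inner layers overwrite: innermost wins
  for (k in rev(seq_len(nrow(layer_spec)))) {
    if (layer_spec$radius[k] > 0)
      labels[r <= layer_spec$radius[k]] <- as.integer(layer_spec$code[k])
  }

  if (!is.null(gyrus)) {
    gy <- utils::modifyList(
      list(n = 8L, amplitude = 1, width_deg = 6, incl_range = c(25, 155),
           azim_range = NULL),
      gyrus)
    csf_code <- TISSUES[["csf"]]
    gm_code <- TISSUES[["gm"]]
    ord <- match(c(gm_code, csf_code), layer_spec$code)
    if (any(is.na(ord)))
      stop("gyral ridges require GM and CSF layers in layer_spec")
    r_gm <- layer_spec$radius[ord[1]]
    r_csf <- layer_spec$radius[ord[2]]
    r_ridge <- r_gm + gy$amplitude * (r_csf - r_gm)

    idx <- which(labels == csf_code & r <= r_ridge)
    if (length(idx)) {
      ijk <- arrayInd(idx, dim(labels))
      x <- coord[ijk[, 1]]; y <- coord[ijk[, 2]]; z <- coord[ijk[, 3]]
      rr <- r[idx]
      incl <- acos(pmin(1, pmax(-1, z / rr))) * 180 / pi
      azim <- atan2(y, x) * 180 / pi
      ridge_az <- seq(0, 360, length.out = gy$n + 1)[seq_len(gy$n)]
      if (!is.null(gy$azim_range))
        ridge_az <- ridge_az[ridge_az >= gy$azim_range[1] &
                             ridge_az <= gy$azim_range[2]]
      daz <- vapply(ridge_az, function(a) {
        d <- abs(((azim - a + 180) %% 360) - 180)
        d
      }, numeric(length(azim)))
      on_ridge <- apply(daz <= gy$width_deg, 1, any) &
        incl >= gy$incl_range[1] & incl <= gy$incl_range[2]
      labels[idx[on_ridge]] <- gm_code
    }
  }

  vol <- label_volume(labels, resolution, origin)
  attr(vol, "layer_spec") <- layer_spec
  attr(vol, "gyrus") <- gyrus
  vol
}

# 6-neighborhood binary dilation of a 3-D logical array
dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

# voxel-centre coordinates (mm) of linear voxel indices
voxel_centers <- function(vol, idx) {
  ijk <- arrayInd(idx, dim(vol$labels))
  cbind(vol$origin[1] + (ijk[, 1] - 1) * vol$voxel_size,
        vol$origin[2] + (ijk[, 2] - 1) * vol$voxel_size,
        vol$origin[3] + (ijk[, 3] - 1) * vol$voxel_size)
}

#' White-matter diffusion-like tensor field
#'
#' Generates a per-voxel symmetric positive-definite tensor field over the
#' white-matter compartment of a phantom, standing in for a registered
#' diffusion-tensor image. The principal eigenvalue exceeds the two
#' transverse eigenvalues by `anisotropy_ratio`; the principal eigenvector
#' points radially from the phantom centre (`"radial"`) or along the local
#' azimuthal direction (`"tangential"`). Tensor units are arbitrary
#' (diffusion-like); only eigenvector structure and eigenvalue ratios carry
#' information, since conductivity scaling renormalizes magnitudes.
#'
#' @param vol A [label_volume] containing WM voxels.
#' @param anisotropy_ratio Longitudinal:transverse eigenvalue ratio, >= 1.
#'   1 yields isotropic tensors.
#' @param fiber_pattern `"radial"` or `"tangential"`.
#' @return Object of class `tensor_field`: list with `index` (linear voxel
#'   indices where tensors are defined), `tensors` (n x 6 matrix, columns
#'   xx, yy, zz, xy, xz, yz), and `dim`.
#' @export
generate_wm_tensor_field <- function(vol, anisotropy_ratio = 10,
                                     fiber_pattern = c("radial", "tangential")) {
  fiber_pattern <- match.arg(fiber_pattern)
  if (anisotropy_ratio < 1)
    stop("anisotropy_ratio must be >= 1")
  idx <- which(vol$labels == TISSUES[["wm"]])
  if (!length(idx)) stop("volume contains no WM voxels")
  p <- voxel_centers(vol, idx)
  rr <- sqrt(rowSums(p^2))

  if (fiber_pattern == "radial") {
    v <- p / pmax(rr, .Machine$double.eps)
    v[rr == 0, ] <- rep(c(1, 0, 0), each = sum(rr == 0))
  } else {
    s <- sqrt(p[, 1]^2 + p[, 2]^2)
    v <- cbind(-p[, 2], p[, 1], 0) / pmax(s, .Machine$double.eps)
    v[s == 0, ] <- rep(c(1, 0, 0), each = sum(s == 0))
  }
  # d0 * (I + (ratio-1) v v^T): eigenvalues d0*ratio along v, d0 transverse
  d0 <- 1
  a <- d0 * (anisotropy_ratio - 1)
  tens <- cbind(
    xx = d0 + a * v[, 1]^2,
    yy = d0 + a * v[, 2]^2,
    zz = d0 + a * v[, 3]^2,
    xy = a * v[, 1] * v[, 2],
    xz = a * v[, 1] * v[, 3],
    yz = a * v[, 2] * v[, 3]
  )
  structure(list(index = idx, tensors = tens, dim = dim(vol$labels)),
            class = "tensor_field")
}

# expand n x 6 compact symmetric storage to a 3x3 matrix for row i
tensor_matrix <- function(tens, i) {
  t6 <- tens[i, ]
  matrix(c(t6[1], t6[4], t6[5],
           t6[4], t6[2], t6[6],
           t6[5], t6[6], t6[3]), 3, 3)
}

#' Angular coordinates of supported 10-20 electrode positions
#'
#' Spherical coordinates of a 10-20-analog layout on the phantom sphere:
#' the vertex Cz is at inclination 0; the outer ring (FPz, Oz, F7, F8, P7,
#' P8) lies at inclination 90 degrees; azimuth is measured from the nasion
#' (0 degrees), positive to the subject's right, with ring positions at
#' equal-arc spacing.
#'
#' @param label Position name, one of `"FPz"`, `"Oz"`, `"Cz"`, `"F7"`,
#'   `"F8"`, `"P7"`, `"P8"`.
#' @return Numeric length-2: `c(inclination, azimuth)` in degrees.
#' @examples
#' ten_twenty_direction("Oz")   # c(90, 180)
#' @export
ten_twenty_direction <- function(label) {
  tab <- list(
    Cz  = c(0, 0),
    FPz = c(90, 0),
    Oz  = c(90, 180),
    F7  = c(90, -54),
    F8  = c(90, 54),
    P7  = c(90, -126),
    P8  = c(90, 126)
  )
  if (!label %in% names(tab))
    stop("unknown 10-20 position: ", label,
         " (supported: ", paste(names(tab), collapse = ", "), ")")
  stats::setNames(tab[[label]], c("inclination", "azimuth"))
}

# unit direction vector for (inclination, azimuth) in degrees;
# +z = vertex, +x = nasion, +y = subject's right
angles_to_direction <- function(angles) {
  th <- angles[1] * pi / 180
  ph <- angles[2] * pi / 180
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

#' Electrode patch description
#'
#' @param position Either a 10-20 position name (see
#'   [ten_twenty_direction()]) or numeric `c(inclination, azimuth)` degrees.
#' @param polarity `"anode"` or `"cathode"`.
#' @param width,height Patch dimensions in mm (default 70 x 50, the
#'   7 cm x 5 cm patch). The long axis lies along the local azimuthal
#'   direction.
#' @param thickness Patch thickness in mm (default 4).
#' @param conductivity Saline conductivity in S/m (default 1.4).
#' @return Object of class `electrode_patch`.
#' @export
electrode_patch <- function(position, polarity = c("anode", "cathode"),
                            width = 70, height = 50, thickness = 4,
                            conductivity = 1.4) {
  polarity <- match.arg(polarity)
  if (is.character(position)) position <- ten_twenty_direction(position)
  stopifnot(length(position) == 2, width > 0, height > 0, thickness > 0,
            conductivity > 0)
  structure(list(position = as.numeric(position), polarity = polarity,
                 width = width, height = height, thickness = thickness,
                 conductivity = conductivity),
            class = "electrode_patch")
}

#' Electrode montage
#'
#' A set of electrode patches plus the total injected current. At least one
#' anode and one cathode are required; the default total current is 1 mA.
#'
#' @param ... [electrode_patch] objects (or a single list of them).
#' @param total_current Total injected current in amperes (default 1e-3).
#' @return Object of class `montage`.
#' @examples
#' m <- montage(electrode_patch("FPz", "anode"),
#'              electrode_patch("Oz", "cathode"))
#' @export
montage <- function(..., total_current = 1e-3) {
  patches <- list(...)
  if (length(patches) == 1 && !inherits(patches[[1]], "electrode_patch"))
    patches <- patches[[1]]
  if (!all(vapply(patches, inherits, TRUE, "electrode_patch")))
    stop("montage() takes electrode_patch objects")
  if (total_current <= 0) stop("total_current must be > 0")
  pol <- vapply(patches, `[[`, "", "polarity")
  if (length(patches) && (!any(pol == "anode") || !any(pol == "cathode")))
    stop("montage needs at least one anode and one cathode")
  structure(list(patches = patches, total_current = total_current),
            class = "montage")
}

#' Standard two-patch montages
#'
#' The four montage configurations compared in the package's analyses,
#' named by their 10-20-analog positions: midline FPz/Oz, lateral-frontal
#' F7/F8, midline Cz/Oz, and lateral-posterior P7/P8. The first position is
#' the anode.
#'
#' @param total_current Total current in amperes (default 1 mA).
#' @param ... Passed to [electrode_patch()] (e.g. patch dimensions).
#' @return Named list of [montage] objects.
#' @export
standard_montages <- function(total_current = 1e-3, ...) {
  mk <- function(a, c.) montage(electrode_patch(a, "anode", ...),
                                electrode_patch(c., "cathode", ...),
                                total_current = total_current)
  list(
    "FPz-Oz" = mk("FPz", "Oz"),
    "F7-F8"  = mk("F7", "F8"),
    "Cz-Oz"  = mk("Cz", "Oz"),
    "P7-P8"  = mk("P7", "P8")
  )
}

#' Place electrode patches onto a phantom
#'
#' Relabels background voxels just above the skin surface to electrode
#' codes. Each patch covers the geodesic rectangle of its width x height
#' footprint centred at its angular position (long axis along the local
#' azimuthal direction) and extends radially from the skin surface outward
#' by the patch thickness.
#'
#' @param vol A [label_volume] with a closed skin surface.
#' @param montage A [montage].
#' @return New [label_volume] with electrode voxels added.
#' @export
place_electrode_patches <- function(vol, montage) {
  stopifnot(inherits(vol, "label_volume"), inherits(montage, "montage"))
  if (!length(montage$patches)) return(vol)
  skin <- TISSUES[["skin"]]
  skin_mask <- vol$labels == skin
  if (!any(skin_mask))
    stop("volume has no skin surface to place patches on")
  r_skin <- sqrt(max(rowSums(voxel_centers(vol, which(skin_mask))^2)))
  r_surf <- r_skin + vol$voxel_size / 2        # staircase surface estimate

  labels <- vol$labels
  dm <- dim(labels)
  idx_bg <- which(labels == TISSUES[["background"]])
  p <- voxel_centers(vol, idx_bg)
  rr <- pmax(sqrt(rowSums(p^2)), .Machine$double.eps)

  sel_by_patch <- vector("list", length(montage$patches))
  for (k in seq_along(montage$patches)) {
    pa <- montage$patches[[k]]
    d <- angles_to_direction(pa$position)
    th <- pa$position[1] * pi / 180; ph <- pa$position[2] * pi / 180
    e_th <- c(cos(th) * cos(ph), cos(th) * sin(ph), -sin(th))
    e_ph <- c(-sin(ph), cos(ph), 0)

    # geodesic-rectangle footprint test on voxel directions
    t <- p / rr
    cosg <- pmin(1, pmax(-1, t %*% d))
    g <- acos(cosg)
    tang <- t - cosg %*% t(d)
    nt <- sqrt(rowSums(tang^2))
    u_dir <- tang / pmax(nt, .Machine$double.eps)
    u <- r_surf * g * (u_dir %*% e_ph)     # along azimuth: patch width
    v <- r_surf * g * (u_dir %*% e_th)     # along inclination: patch height
    u[nt == 0] <- 0; v[nt == 0] <- 0
    foot <- array(FALSE, dm)
    foot[idx_bg[abs(u) <= pa$width / 2 & abs(v) <= pa$height / 2]] <- TRUE

    # grow the patch outward from the skin staircase, one voxel layer per
    # pass, so the pad has uniform thickness above the local surface
    n_layers <- max(1L, as.integer(round(pa$thickness / vol$voxel_size)))
    support <- skin_mask
    sel <- array(FALSE, dm)
    for (l in seq_len(n_layers)) {
      new <- foot & !sel & dilate6(support)
      if (!any(new)) break
      sel <- sel | new
      support <- new
    }
    if (!any(sel))
      stop("patch ", k, " footprint misses the labeled skin surface")
    sel_by_patch[[k]] <- which(sel)
  }

  pol <- vapply(montage$patches, `[[`, "", "polarity")
  an <- unlist(sel_by_patch[pol == "anode"])
  ca <- unlist(sel_by_patch[pol == "cathode"])
  if (length(intersect(an, ca)))
    stop("anode and cathode patch footprints overlap")
  labels[an] <- TISSUES[["electrode_anode"]]
  labels[ca] <- TISSUES[["electrode_cathode"]]
  out <- label_volume(labels, vol$voxel_size, vol$origin)
  attributes(out)[c("layer_spec", "gyrus")] <-
    attributes(vol)[c("layer_spec", "gyrus")]
  attr(out, "montage") <- montage
  out
}

#' Read/write label volumes as NIfTI
#'
#' Label volumes are persisted as integer NIfTI with the voxel size in the
#' header pixdim and the origin in the affine translation.
#'
#' @param vol A [label_volume].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `write_label_volume` returns `path` invisibly;
#'   `read_label_volume` returns a [label_volume].
#' @export
write_label_volume <- function(vol, path) {
  img <- RNifti::asNifti(structure(vol$labels,
                                   pixdim = rep(vol$voxel_size, 3)),
                         datatype = "int16")
  aff <- diag(c(rep(vol$voxel_size, 3), 1))
  aff[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  vs <- sqrt(sum(aff[1:3, 1]^2))           # voxel size from the affine
  label_volume(array(as.integer(img), dim = dim(img)), vs, aff[1:3, 4])
}
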