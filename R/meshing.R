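# Hexahedral meshing of label volumes.
#
# Vertex ordering convention (trilinear hexahedron): local coordinates
# (xi, eta, zeta) in [-1,1]^3, nodes ordered bottom face counter-clockwise
# then top face:
#   1 (-,-,-)  2 (+,-,-)  3 (+,+,-)  4 (-,+,-)
#   5 (-,-,+)  6 (+,-,+)  7 (+,+,+)  8 (-,+,+)

# local node signs, one row per node
HEX_SIGNS <- matrix(c(
  -1, -1, -1,
   1, -1, -1,
   1,  1, -1,
  -1,  1, -1,
  -1, -1,  1,
   1, -1,  1,
   1,  1,  1,
  -1,  1,  1), ncol = 3, byrow = TRUE)

# local faces with outward orientation (counter-clockwise seen from outside)
HEX_FACES <- matrix(c(
  1, 4, 3, 2,   # zeta = -1
  5, 6, 7, 8,   # zeta = +1
  1, 2, 6, 5,   # eta  = -1
  4, 8, 7, 3,   # eta  = +1
  1, 5, 8, 4,   # xi   = -1
  2, 3, 7, 6),  # xi   = +1
  ncol = 4, byrow = TRUE)

# shape-function local gradients at points (n x 3 local coords) -> list of
# n matrices? return array n x 8 x 3
hex_shape_grad <- function(pts) {
  n <- nrow(pts)
  g <- array(0, c(n, 8, 3))
  for (i in 1:8) {
    s <- HEX_SIGNS[i, ]
    g[, i, 1] <- 0.125 * s[1] * (1 + pts[, 2] * s[2]) * (1 + pts[, 3] * s[3])
    g[, i, 2] <- 0.125 * s[2] * (1 + pts[, 1] * s[1]) * (1 + pts[, 3] * s[3])
    g[, i, 3] <- 0.125 * s[3] * (1 + pts[, 1] * s[1]) * (1 + pts[, 2] * s[2])
  }
  g
}

# 2x2x2 Gauss points (weights all 1), exact for trilinear elements
hex_gauss_points <- function() {
  a <- 1 / sqrt(3)
  as.matrix(expand.grid(xi = c(-a, a), eta = c(-a, a), zeta = c(-a, a)))
}

#' Hexahedral finite-element mesh
#'
#' Mesh container produced by [voxels_to_hex_mesh()]. Node coordinates are
#' in meters; elements are rows of 8 node indices in the package's fixed
#' trilinear vertex ordering (bottom face counter-clockwise, then top
#' face). `tensors` holds one 3x3 symmetric conductivity tensor per element
#' in compact 6-column form (xx, yy, zz, xy, xz, yz) and is flagged
#' unassigned until [assign_conductivity()] is applied.
#'
#' @name hex_mesh
NULL

new_hex_mesh <- function(nodes, elems, labels, voxel_size_m,
                         voxel_index = NULL, vol_dim = NULL) {
  structure(list(
    nodes = nodes, elems = elems, labels = as.integer(labels),
    tensors = matrix(rep(c(1, 1, 1, 0, 0, 0), each = nrow(elems)),
                     nrow(elems), 6,
                     dimnames = list(NULL, c("xx","yy","zz","xy","xz","yz"))),
    tensors_assigned = FALSE,
    voxel_size_m = voxel_size_m,
    voxel_index = voxel_index, vol_dim = vol_dim
  ), class = "hex_mesh")
}

#' @exportS3Method base::print
print.hex_mesh <- function(x, ...) {
  cat("hex_mesh:", nrow(x$nodes), "nodes,", nrow(x$elems), "elements,",
      "tensors", if (x$tensors_assigned) "assigned" else "unassigned", "\n")
  invisible(x)
}

#' Convert a label volume to a hexahedral mesh
#'
#' Creates one hexahedral element per non-background voxel, with nodes
#' shared between adjacent voxels and coordinates converted from mm to
#' meters. Element labels are copied from voxel labels; conductivity
#' tensors are left unassigned. Node and element ordering is a
#' deterministic function of the input (elements in voxel linear-index
#' order, nodes in corner-grid order).
#'
#' @param vol A [label_volume].
#' @return A `hex_mesh`.
#' @examples
#' v <- label_volume(array(TISSUES[["gm"]], c(2, 2, 2)), 1, c(0, 0, 0))
#' m <- voxels_to_hex_mesh(v)  # 27 nodes, 8 elements
#' @export
voxels_to_hex_mesh <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  dm <- dim(vol$labels)
  vox <- which(vol$labels != TISSUES[["background"]])
  if (!length(vox)) stop("volume contains no non-background voxels")
  ijk <- arrayInd(vox, dm)

  # corner grid is (nx+1) x (ny+1) x (nz+1); voxel (i,j,k) owns corners
  # (i..i+1, j..j+1, k..k+1); map local node ordering to corner offsets
  off <- (HEX_SIGNS + 1L) / 2L
  gx <- dm[1] + 1L; gy <- dm[2] + 1L
  corner <- matrix(0L, length(vox), 8)
  for (i in 1:8) {
    corner[, i] <- (ijk[, 1] + off[i, 1]) +
      (ijk[, 2] + off[i, 2] - 1L) * gx +
      (ijk[, 3] + off[i, 3] - 1L) * gx * gy
  }
  node_ids <- sort(unique(as.vector(corner)))
  elems <- matrix(match(corner, node_ids), length(vox), 8)

  cijk <- arrayInd(node_ids, c(gx, gy, dm[3] + 1L))
  vs <- vol$voxel_size
  nodes <- cbind(vol$origin[1] + (cijk[, 1] - 1.5) * vs,
                 vol$origin[2] + (cijk[, 2] - 1.5) * vs,
                 vol$origin[3] + (cijk[, 3] - 1.5) * vs) / 1000
  new_hex_mesh(nodes, elems, vol$labels[vox], vs / 1000,
               voxel_index = vox, vol_dim = dm)
}

# Jacobian determinants at the 2x2x2 Gauss points for all elements.
# Returns n_elem x 8 matrix. Also used to validate adapted meshes.
element_jacobians <- function(mesh) {
  gp <- hex_gauss_points()
  dN <- hex_shape_grad(gp)
  M <- nrow(mesh$elems)
  X <- lapply(1:3, function(a) {
    matrix(mesh$nodes[mesh$elems, a], M, 8)
  })
  detJ <- matrix(0, M, nrow(gp))
  for (q in seq_len(nrow(gp))) {
    J <- array(0, c(M, 3, 3))        # J[,a,b] = d x_b / d xi_a
    for (a in 1:3) for (b in 1:3)
      J[, a, b] <- X[[b]] %*% dN[q, , a]
    detJ[, q] <-
      J[,1,1] * (J[,2,2] * J[,3,3] - J[,2,3] * J[,3,2]) -
      J[,1,2] * (J[,2,1] * J[,3,3] - J[,2,3] * J[,3,1]) +
      J[,1,3] * (J[,2,1] * J[,3,2] - J[,2,2] * J[,3,1])
  }
  detJ
}

#' Element volumes
#'
#' Volume of every element in m^3, by 2x2x2 Gauss quadrature (exact for
#' trilinear hexahedra).
#'
#' @param mesh A `hex_mesh`.
#' @return Numeric vector, one volume per element.
#' @export
element_volumes <- function(mesh) {
  rowSums(element_jacobians(mesh))
}

# All element faces with exact voxel-grid identity keys. A face
# perpendicular to axis a is identified by (corner-grid index of its
# minimum corner, a); two voxels sharing a face produce the same key.
# Returns list(elem, local_face, nodes (nf x 4), key).
all_faces <- function(mesh) {
  if (is.null(mesh$voxel_index))
    stop("mesh lacks voxel provenance; faces cannot be enumerated")
  M <- nrow(mesh$elems)
  dm <- mesh$vol_dim
  gx <- dm[1] + 1L; gy <- dm[2] + 1L; gz <- dm[3] + 1L
  ijk <- arrayInd(mesh$voxel_index, dm)
  cidx <- function(di, dj, dk) {
    (ijk[, 1] + di) + (ijk[, 2] + dj - 1) * gx +
      (ijk[, 3] + dk - 1) * gx * gy
  }
  # local faces in HEX_FACES order: zeta-, zeta+, eta-, eta+, xi-, xi+
  min_corner <- cbind(cidx(0, 0, 0), cidx(0, 0, 1),
                      cidx(0, 0, 0), cidx(0, 1, 0),
                      cidx(0, 0, 0), cidx(1, 0, 0))
  axis <- c(3, 3, 2, 2, 1, 1)
  el <- rep(seq_len(M), times = 6)
  lf <- rep(1:6, each = M)
  nodes <- matrix(0L, M * 6, 4)
  key <- numeric(M * 6)
  for (f in 1:6) {
    rows <- (f - 1) * M + seq_len(M)
    nodes[rows, ] <- mesh$elems[, HEX_FACES[f, ]]
    key[rows] <- min_corner[, f] * 3 + axis[f]
  }
  list(elem = el, local_face = lf, nodes = nodes, key = key)
}

# faces on the mesh boundary (owned by exactly one element)
boundary_faces <- function(mesh) {
  fc <- all_faces(mesh)
  dup <- duplicated(fc$key) | duplicated(fc$key, fromLast = TRUE)
  keep <- !dup
  list(elem = fc$elem[keep], local_face = fc$local_face[keep],
       nodes = fc$nodes[keep, , drop = FALSE])
}

# area and outward unit normal of quad faces given node coordinate matrix;
# faces as nf x 4 node-index matrix ordered counter-clockwise from outside
face_area_normal <- function(nodes_xyz, faces) {
  p1 <- nodes_xyz[faces[, 1], , drop = FALSE]
  p2 <- nodes_xyz[faces[, 2], , drop = FALSE]
  p3 <- nodes_xyz[faces[, 3], , drop = FALSE]
  p4 <- nodes_xyz[faces[, 4], , drop = FALSE]
  d1 <- p3 - p1; d2 <- p4 - p2
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  a2 <- sqrt(rowSums(cr^2))
  list(area = a2 / 2, normal = cr / pmax(a2, .Machine$double.eps))
}

#' Geometry-adapt a voxel mesh to smoothed tissue interfaces
#'
#' Shifts mesh nodes that lie on material interfaces (shared by elements of
#' differing labels, or on the outer mesh boundary) toward the centroid of
#' the centres of their incident interface faces, by at most `shift_factor`
#' times the voxel size. Interior nodes are left untouched. One smoothing
#' pass is applied; all element Jacobians are verified positive afterwards.
#'
#' @param mesh A `hex_mesh` from [voxels_to_hex_mesh()].
#' @param shift_factor Maximum node displacement as a fraction of the voxel
#'   size, in `[0, 0.49]`. The default 0.33 is a safe bound against element
#'   degeneration.
#' @return Adapted `hex_mesh`. Attribute `interface_nodes` lists the node
#'   indices eligible to move (all others are bit-identical to the input).
#' @export
geometry_adapt <- function(mesh, shift_factor = 0.33) {
  stopifnot(inherits(mesh, "hex_mesh"))
  if (shift_factor < 0 || shift_factor > 0.49)
    stop("shift_factor must be in [0, 0.49]")
  if (shift_factor == 0) {
    attr(mesh, "interface_nodes") <- integer(0)
    return(mesh)
  }
  fc <- all_faces(mesh)
  o <- order(fc$key)
  key_s <- fc$key[o]
  first <- !duplicated(key_s)
  runlen <- tabulate(cumsum(first))
  # pair up shared faces
  pos_first <- which(first)
  is_shared <- runlen == 2
  e1 <- fc$elem[o][pos_first]
  e2 <- rep(NA_integer_, length(pos_first))
  e2[is_shared] <- fc$elem[o][pos_first[is_shared] + 1L]
  lab1 <- mesh$labels[e1]
  lab2 <- ifelse(is.na(e2), -1L, mesh$labels[e2])   # -1: exterior
  iface <- lab1 != lab2
  f_nodes <- fc$nodes[o, , drop = FALSE][pos_first[iface], , drop = FALSE]

  # face centres
  ctr <- (mesh$nodes[f_nodes[, 1], ] + mesh$nodes[f_nodes[, 2], ] +
          mesh$nodes[f_nodes[, 3], ] + mesh$nodes[f_nodes[, 4], ]) / 4

  nn <- nrow(mesh$nodes)
  acc <- matrix(0, nn, 3)
  cnt <- numeric(nn)
  for (c. in 1:4) {
    id <- f_nodes[, c.]
    for (a in 1:3) acc[, a] <- acc[, a] +
      unname(tapply2(ctr[, a], id, nn))
    cnt <- cnt + tabulate(id, nn)
  }
  movers <- which(cnt > 0)
  target <- acc[movers, , drop = FALSE] / cnt[movers]
  disp <- target - mesh$nodes[movers, , drop = FALSE]
  dlen <- sqrt(rowSums(disp^2))
  cap <- shift_factor * mesh$voxel_size_m
  scl <- pmin(1, cap / pmax(dlen, .Machine$double.eps))
  nodes2 <- mesh$nodes
  nodes2[movers, ] <- mesh$nodes[movers, , drop = FALSE] + disp * scl

  out <- mesh
  out$nodes <- nodes2
  detJ <- element_jacobians(out)
  bad <- which(apply(detJ <= 0, 1, any))
  if (length(bad))
    stop("geometry adaptation produced non-positive Jacobians in element(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  attr(out, "interface_nodes") <- movers
  out
}

# sum x by integer group id into a length-n vector (fast tapply)
tapply2 <- function(x, id, n) {
  out <- numeric(n)
  s <- rowsum(x, id)
  out[as.integer(rownames(s))] <- s
  out
}

#' Export a mesh to legacy ASCII VTK
#'
#' Writes an unstructured-grid file (VTK cell type 12, hexahedron) with the
#' element tissue label, and optionally a per-element vector field, as cell
#' data. Intended for external viewers.
#'
#' @param mesh A `hex_mesh`.
#' @param path Output `.vtk` path.
#' @param cell_vectors Optional n_elem x 3 matrix written as a vector field
#'   named `J`.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, cell_vectors = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0", "hexstim mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nn, "double")), con)
  utils::write.table(mesh$nodes, con, row.names = FALSE, col.names = FALSE)
  writeLines(paste("CELLS", ne, ne * 9), con)
  utils::write.table(cbind(8L, mesh$elems - 1L), con,
                     row.names = FALSE, col.names = FALSE)
  writeLines(paste("CELL_TYPES", ne), con)
  writeLines(as.character(rep(12L, ne)), con)
  writeLines(c(paste("CELL_DATA", ne), "SCALARS tissue int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$labels), con)
  if (!is.null(cell_vectors)) {
    writeLines("VECTORS J double", con)
    utils::write.table(cell_vectors, con, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
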