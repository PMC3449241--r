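# Quasistatic potential problem: assemble the FE stiffness matrix for
# div(sigma grad Phi) = 0 with inhomogeneous Neumann current injection,
# solve the resulting singular-consistent sparse system, and derive the
# current density J = -sigma grad Phi.

#' Assemble the FE stiffness matrix
#'
#' Isoparametric trilinear hexahedral stiffness matrix
#' `K[i,j] = sum_elements integral grad(N_i) . sigma grad(N_j) dV`,
#' evaluated by 2x2x2 Gauss quadrature (exact for trilinear elements with
#' constant per-element sigma). The matrix is symmetric positive
#' semidefinite with the constant vector in its null space (pure-Neumann
#' problem); assembly order is deterministic (element index order).
#'
#' @param mesh A `hex_mesh` with assigned conductivity tensors.
#' @return Sparse symmetric matrix (`Matrix::dsCMatrix`), nodes x nodes.
#' @export
assemble_stiffness <- function(mesh) {
  stopifnot(inherits(mesh, "hex_mesh"))
  if (!isTRUE(mesh$tensors_assigned))
    stop("conductivity tensors are unassigned; run assign_conductivity()")
  gp <- hex_gauss_points()
  dN <- hex_shape_grad(gp)
  M <- nrow(mesh$elems)
  X <- lapply(1:3, function(a) matrix(mesh$nodes[mesh$elems, a], M, 8))
  t6 <- mesh$tensors
  S <- list(c(1, 4, 5), c(4, 2, 6), c(5, 6, 3))  # sigma[b,c] column in t6

  Ke <- array(0, c(M, 8, 8))
  for (q in seq_len(nrow(gp))) {
    J <- array(0, c(M, 3, 3))                    # J[,a,b] = dx_b/dxi_a
    for (a in 1:3) for (b in 1:3) J[, a, b] <- X[[b]] %*% dN[q, , a]
    co <- array(0, c(M, 3, 3))                   # cofactors -> inverse
    co[, 1, 1] <- J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]
    co[, 1, 2] <- J[, 2, 3] * J[, 3, 1] - J[, 2, 1] * J[, 3, 3]
    co[, 1, 3] <- J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1]
    co[, 2, 1] <- J[, 1, 3] * J[, 3, 2] - J[, 1, 2] * J[, 3, 3]
    co[, 2, 2] <- J[, 1, 1] * J[, 3, 3] - J[, 1, 3] * J[, 3, 1]
    co[, 2, 3] <- J[, 1, 2] * J[, 3, 1] - J[, 1, 1] * J[, 3, 2]
    co[, 3, 1] <- J[, 1, 2] * J[, 2, 3] - J[, 1, 3] * J[, 2, 2]
    co[, 3, 2] <- J[, 1, 3] * J[, 2, 1] - J[, 1, 1] * J[, 2, 3]
    co[, 3, 3] <- J[, 1, 1] * J[, 2, 2] - J[, 1, 2] * J[, 2, 1]
    detJ <- J[, 1, 1] * co[, 1, 1] + J[, 1, 2] * co[, 1, 2] +
      J[, 1, 3] * co[, 1, 3]
    if (any(detJ <= 0))
      stop("non-positive Jacobian at quadrature point; invalid mesh")
    # physical gradients g[,i,b] = sum_a inv(J)[b,a] dN[q,i,a],
    # inv(J)[b,a] = co[,a,b]/detJ
    g <- array(0, c(M, 8, 3))
    for (i in 1:8) for (b in 1:3)
      g[, i, b] <- (co[, 1, b] * dN[q, i, 1] + co[, 2, b] * dN[q, i, 2] +
                    co[, 3, b] * dN[q, i, 3]) / detJ
    # h[,i,c] = sum_b g[,i,b] sigma[,b,c]
    h <- array(0, c(M, 8, 3))
    for (i in 1:8) for (c. in 1:3)
      h[, i, c.] <- g[, i, 1] * t6[, S[[1]][c.]] +
        g[, i, 2] * t6[, S[[2]][c.]] + g[, i, 3] * t6[, S[[3]][c.]]
    for (i in 1:8) for (j in i:8) {
      v <- (h[, i, 1] * g[, j, 1] + h[, i, 2] * g[, j, 2] +
            h[, i, 3] * g[, j, 3]) * detJ
      Ke[, i, j] <- Ke[, i, j] + v
      if (j > i) Ke[, j, i] <- Ke[, j, i] + v
    }
  }
  ii <- mesh$elems[, rep(1:8, times = 8)]
  jj <- mesh$elems[, rep(1:8, each = 8)]
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(Ke),
                            dims = rep(nrow(mesh$nodes), 2))
  Matrix::forceSymmetric(K)
}

#' Electrode Neumann load vector
#'
#' Converts the montage's total current into nodal loads: a uniform normal
#' current density is applied over the exposed (mesh-boundary) faces of
#' each polarity's electrode elements and converted to nodal values by
#' face-area weighting (a quarter of each face's area per corner node).
#' Anode loads sum to `+total_current`, cathode loads to `-total_current`,
#' so the load is compatible with the pure-Neumann operator.
#'
#' @param mesh A `hex_mesh` containing electrode-labeled elements.
#' @param montage A [montage] (only `total_current` is read; patch geometry
#'   is already in the mesh labels).
#' @return Numeric load vector over nodes, in amperes.
#' @export
electrode_load_vector <- function(mesh, montage) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(montage, "montage"))
  bf <- boundary_faces(mesh)
  load <- numeric(nrow(mesh$nodes))
  for (pol in c("electrode_anode", "electrode_cathode")) {
    code <- TISSUES[[pol]]
    if (!any(mesh$labels == code))
      stop("mesh has no elements for ", pol)
    sel <- mesh$labels[bf$elem] == code
    if (!any(sel))
      stop(pol, " has no exposed outer faces")
    faces <- bf$nodes[sel, , drop = FALSE]
    area <- face_area_normal(mesh$nodes, faces)$area
    sign <- if (pol == "electrode_anode") 1 else -1
    w <- rep(area / 4, 4)                      # quarter of face area per node
    contrib <- tapply2(w, as.vector(faces), nrow(mesh$nodes))
    load <- load + sign * montage$total_current * contrib / sum(area)
  }
  load
}

#' Solve the quasistatic potential problem
#'
#' Solves `K phi = b` for the electric potential on the pure-Neumann
#' (singular, consistent) stiffness matrix and projects the result to the
#' zero-mean gauge. Two methods are available: `"direct"` factorizes the
#' grounded system with a sparse Cholesky decomposition and re-gauges the
#' solution; `"cg"` runs Jacobi-preconditioned conjugate gradients on the
#' semidefinite operator to a relative preconditioned-residual tolerance.
#'
#' @param system List with `stiffness` (sparse symmetric matrix) and
#'   `load` (numeric vector summing to zero), e.g. from
#'   [assemble_stiffness()] and [electrode_load_vector()].
#' @param rel_tol Relative residual tolerance (default 1e-9).
#' @param method `"cg"` (default) or `"direct"`.
#' @param max_iter CG iteration cap (default 10000).
#' @return Numeric potential per node (volts, zero mean), with attribute
#'   `solver_info`: list(`method`, `iterations`, `rel_residual`,
#'   `n_unknowns`).
#' @export
solve_potential <- function(system, rel_tol = 1e-9,
                            method = c("cg", "direct"), max_iter = 10000) {
  method <- match.arg(method)
  K <- system$stiffness
  b <- system$load
  stopifnot(nrow(K) == length(b))
  bn <- max(abs(b))
  if (bn == 0) {
    phi <- numeric(length(b))
    attr(phi, "solver_info") <- list(method = method, iterations = 0L,
                                     rel_residual = 0,
                                     n_unknowns = length(b))
    return(phi)
  }
  if (abs(sum(b)) > 1e-8 * sum(abs(b)))
    stop("incompatible load: entries do not sum to zero")

  if (method == "direct") {
    # Ground node 1 by adding a conductance to its diagonal: because the
    # load sums to zero, the augmented SPD system has the exact solution of
    # the singular one with phi[1] = 0. Then re-gauge to zero mean.
    K1 <- K
    K1[1, 1] <- K1[1, 1] * 2
    ch <- Matrix::Cholesky(K1, LDL = FALSE, super = TRUE)
    phi <- as.numeric(Matrix::solve(ch, b))
    phi <- phi - mean(phi)
    r <- as.numeric(b - K %*% phi)
    info <- list(method = "direct", iterations = 1L,
                 rel_residual = sqrt(sum(r^2) / sum(b^2)),
                 n_unknowns = length(b))
  } else {
    d <- Matrix::diag(K)
    if (any(d <= 0)) stop("non-positive diagonal; invalid stiffness matrix")
    x <- numeric(length(b))
    r <- b
    z <- r / d
    p <- z
    rz <- sum(r * z)
    b2 <- sqrt(sum(b^2))
    it <- 0L
    repeat {
      it <- it + 1L
      Ap <- as.numeric(K %*% p)
      alpha <- rz / sum(p * Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      rel <- sqrt(sum(r^2)) / b2
      if (rel <= rel_tol) break
      if (it >= max_iter)
        stop("CG did not converge in ", max_iter,
             " iterations (relative residual ", signif(rel, 3), ")")
      z <- r / d
      rz_new <- sum(r * z)
      beta <- rz_new / rz
      rz <- rz_new
      p <- z + beta * p
      if (it %% 50 == 0) x <- x - mean(x)   # keep the constant mode out
    }
    phi <- x - mean(x)
    info <- list(method = "cg", iterations = it, rel_residual = rel,
                 n_unknowns = length(b))
  }
  attr(phi, "solver_info") <- info
  phi
}

#' Current density from the potential
#'
#' Evaluates `J = -sigma grad Phi` at each element centroid using the
#' isoparametric shape-function gradients. With the physical sign
#' convention used here, current flows from the anode to the cathode;
#' swapping the electrodes negates every `J` exactly.
#'
#' @param mesh A `hex_mesh` with assigned tensors.
#' @param potential Nodal potential in volts (from [solve_potential()]).
#' @return n_elem x 3 matrix of current densities in A/m^2.
#' @export
compute_current_density <- function(mesh, potential) {
  stopifnot(length(potential) == nrow(mesh$nodes))
  M <- nrow(mesh$elems)
  dN <- hex_shape_grad(matrix(0, 1, 3))[1, , ]   # 8 x 3 at centroid
  X <- lapply(1:3, function(a) matrix(mesh$nodes[mesh$elems, a], M, 8))
  Phi <- matrix(potential[mesh$elems], M, 8)
  J <- array(0, c(M, 3, 3))
  for (a in 1:3) for (b in 1:3) J[, a, b] <- X[[b]] %*% dN[, a]
  # grad_xi Phi
  gx <- Phi %*% dN                                # M x 3
  # solve J^T ... grad_x Phi = inv(J) grad_xi Phi, via cofactors
  co <- array(0, c(M, 3, 3))
  co[, 1, 1] <- J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]
  co[, 1, 2] <- J[, 2, 3] * J[, 3, 1] - J[, 2, 1] * J[, 3, 3]
  co[, 1, 3] <- J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1]
  co[, 2, 1] <- J[, 1, 3] * J[, 3, 2] - J[, 1, 2] * J[, 3, 3]
  co[, 2, 2] <- J[, 1, 1] * J[, 3, 3] - J[, 1, 3] * J[, 3, 1]
  co[, 2, 3] <- J[, 1, 2] * J[, 3, 1] - J[, 1, 1] * J[, 3, 2]
  co[, 3, 1] <- J[, 1, 2] * J[, 2, 3] - J[, 1, 3] * J[, 2, 2]
  co[, 3, 2] <- J[, 1, 3] * J[, 2, 1] - J[, 1, 1] * J[, 2, 3]
  co[, 3, 3] <- J[, 1, 1] * J[, 2, 2] - J[, 1, 2] * J[, 2, 1]
  detJ <- J[, 1, 1] * co[, 1, 1] + J[, 1, 2] * co[, 1, 2] +
    J[, 1, 3] * co[, 1, 3]
  grad <- sapply(1:3, function(b)
    (co[, 1, b] * gx[, 1] + co[, 2, b] * gx[, 2] + co[, 3, b] * gx[, 3]) /
      detJ)
  if (M == 1) grad <- matrix(grad, 1, 3)
  t6 <- mesh$tensors
  cbind(
    -(t6[, 1] * grad[, 1] + t6[, 4] * grad[, 2] + t6[, 5] * grad[, 3]),
    -(t6[, 4] * grad[, 1] + t6[, 2] * grad[, 2] + t6[, 6] * grad[, 3]),
    -(t6[, 5] * grad[, 1] + t6[, 6] * grad[, 2] + t6[, 3] * grad[, 3])
  )
}

#' Solve a montage on a conductive mesh
#'
#' Convenience wrapper: assembles the stiffness matrix and electrode load,
#' solves for the potential, and computes the element current densities.
#'
#' @param mesh A `hex_mesh` with assigned conductivity tensors and
#'   electrode elements.
#' @param montage A [montage].
#' @param rel_tol,method,max_iter Passed to [solve_potential()].
#' @param system Optional precomputed list(stiffness, load) to reuse.
#' @return Object of class `stim_solution`: list with `potential` (V,
#'   zero-mean), `current_density` (n_elem x 3, A/m^2), `solver_info`.
#' @export
solve_montage <- function(mesh, montage, rel_tol = 1e-9,
                          method = "cg", max_iter = 10000,
                          system = NULL) {
  if (is.null(system))
    system <- list(stiffness = assemble_stiffness(mesh),
                   load = electrode_load_vector(mesh, montage))
  phi <- solve_potential(system, rel_tol = rel_tol, method = method,
                         max_iter = max_iter)
  structure(list(potential = as.numeric(phi),
                 current_density = compute_current_density(mesh, phi),
                 solver_info = attr(phi, "solver_info")),
            class = "stim_solution")
}

#' @exportS3Method base::print
print.stim_solution <- function(x, ...) {
  si <- x$solver_info
  cat("stim_solution:", si$n_unknowns, "unknowns,", si$method,
      "solver,", si$iterations, "iteration(s), rel. residual",
      signif(si$rel_residual, 3), "\n")
  jm <- sqrt(rowSums(x$current_density^2))
  cat("  |J| range:", signif(min(jm), 3), "-", signif(max(jm), 3),
      "A/m^2\n")
  invisible(x)
}

#' Net current flux through a closed element-set boundary
#'
#' Sums `J . n dA` over the interior faces separating a chosen element set
#' from its complement (normal oriented out of the set, `J` averaged
#' across the face). For a set containing exactly one electrode of a
#' two-patch montage, the result approximates the total injected current
#' (discrete conservation).
#'
#' @param mesh A `hex_mesh`.
#' @param current_density n_elem x 3 matrix from
#'   [compute_current_density()].
#' @param inside Logical vector over elements defining the enclosed set.
#' @return Net outward current in amperes.
#' @export
flux_through_surface <- function(mesh, current_density, inside) {
  stopifnot(length(inside) == nrow(mesh$elems))
  fc <- all_faces(mesh)
  o <- order(fc$key)
  ks <- fc$key[o]
  first <- !duplicated(ks)
  grp <- cumsum(first)
  n2 <- tabulate(grp) == 2
  pos1 <- which(first)[n2]
  e1 <- fc$elem[o][pos1]
  e2 <- fc$elem[o][pos1 + 1L]
  lf1 <- fc$local_face[o][pos1]
  cross <- xor(inside[e1], inside[e2])
  if (!any(cross)) return(0)
  e1 <- e1[cross]; e2 <- e2[cross]; lf1 <- lf1[cross]
  faces <- matrix(0L, length(e1), 4)
  for (f in 1:6) {
    sel <- lf1 == f
    if (any(sel)) faces[sel, ] <- mesh$elems[e1[sel], HEX_FACES[f, ],
                                             drop = FALSE]
  }
  an <- face_area_normal(mesh$nodes, faces)   # outward w.r.t. e1
  Jbar <- (current_density[e1, , drop = FALSE] +
           current_density[e2, , drop = FALSE]) / 2
  flux <- rowSums(Jbar * an$normal) * an$area
  # orient out of the 'inside' set
  sum(ifelse(inside[e1], flux, -flux))
}
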