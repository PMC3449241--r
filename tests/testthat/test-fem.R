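# independent brute-force element stiffness for the unit cube with
# sigma = identity: trilinear basis written directly in x, y, z and
# integrated on a dense midpoint grid (no isoparametric machinery)
brute_unit_cube_Ke <- function(n_grid = 40) {
  h <- 1 / n_grid
  xs <- (seq_len(n_grid) - 0.5) * h
  g <- expand.grid(x = xs, y = xs, z = xs)
  # node i at corner (a,b,c) in {0,1}^3 matching the package ordering
  corners <- (hexstim:::HEX_SIGNS + 1) / 2
  Ke <- matrix(0, 8, 8)
  gradN <- function(i) {
    a <- corners[i, 1]; b <- corners[i, 2]; c. <- corners[i, 3]
    fx <- if (a == 1) g$x else 1 - g$x; dfx <- if (a == 1) 1 else -1
    fy <- if (b == 1) g$y else 1 - g$y; dfy <- if (b == 1) 1 else -1
    fz <- if (c. == 1) g$z else 1 - g$z; dfz <- if (c. == 1) 1 else -1
    cbind(dfx * fy * fz, fx * dfy * fz, fx * fy * dfz)
  }
  G <- lapply(1:8, gradN)
  for (i in 1:8) for (j in 1:8)
    Ke[i, j] <- sum(G[[i]] * G[[j]]) * h^3
  Ke
}

unit_cube_mesh <- function(sigma = 1) {
  v <- box_volume(1, 1, 1, voxel_size = 1000)   # 1 m voxel
  assign_conductivity(voxels_to_hex_mesh(v), table = c(gm = sigma))
}

test_that("element stiffness matches a brute-force quadrature oracle", {
  mesh <- unit_cube_mesh()
  Kg <- as.matrix(assemble_stiffness(mesh))
  # reorder global node numbering to the element's local vertex order
  perm <- mesh$elems[1, ]
  K <- Kg[perm, perm]
  Ke <- brute_unit_cube_Ke()
  expect_lt(max(abs(K - Ke)), 2e-4)
  expect_equal(K, t(K))
  expect_lt(max(abs(rowSums(K))), 1e-14)
})

test_that("stiffness has nullity one on a connected mesh", {
  v <- box_volume(2, 1, 1)
  mesh <- assign_conductivity(voxels_to_hex_mesh(v))
  K <- as.matrix(assemble_stiffness(mesh))
  expect_lt(max(abs(rowSums(K))), 1e-16)
  expect_equal(qr(K)$rank, nrow(K) - 1)
})

test_that("anisotropic tensors enter the weak form correctly", {
  # bar with conductivity sigma_x along x: end-to-end resistance scales
  # with 1/sigma_x regardless of transverse components
  v <- box_volume(4, 1, 1, voxel_size = 1000)
  mesh <- voxels_to_hex_mesh(v)
  mesh$tensors <- matrix(rep(c(2, 5, 9, 0, 0, 0), each = 4), 4, 6)
  mesh$tensors_assigned <- TRUE
  K <- assemble_stiffness(mesh)
  x <- mesh$nodes[, 1]
  ends <- abs(x - min(x)) < 1e-9
  far <- abs(x - max(x)) < 1e-9
  b <- numeric(nrow(mesh$nodes))
  b[ends] <- 1 / 4
  b[far] <- -1 / 4
  phi <- solve_potential(list(stiffness = K, load = b), method = "cg",
                         rel_tol = 1e-12)
  drop_ <- mean(phi[ends]) - mean(phi[far])
  expect_equal(drop_, 1 * 4 / (2 * 1), tolerance = 1e-9)  # I*L/(sigma_x*A)
})

test_that("electrode loads carry the montage current and face-area weights", {
  # skin slab with a single-voxel electrode pad on top of each end
  lab <- array(TISSUES[["skin"]], c(5, 3, 1))
  lab <- array(c(lab), c(5, 3, 2))
  lab[, , 2] <- TISSUES[["background"]]
  lab[1, 2, 2] <- TISSUES[["electrode_anode"]]
  lab[5, 2, 2] <- TISSUES[["electrode_cathode"]]
  v <- label_volume(lab, 10, c(0, 0, 0))
  mesh <- assign_conductivity(voxels_to_hex_mesh(v))
  mo <- montage(electrode_patch("Cz", "anode"),
                electrode_patch("Oz", "cathode"), total_current = 1e-3)
  b <- electrode_load_vector(mesh, mo)
  an_nodes <- unique(as.vector(
    mesh$elems[mesh$labels == TISSUES[["electrode_anode"]], ]))
  expect_equal(sum(b[an_nodes][b[an_nodes] > 0]), 1e-3, tolerance = 1e-12)
  expect_lt(abs(sum(b)), 1e-15)

  # weight oracle: each node's load is proportional to the total exposed
  # electrode face area attached to it (faces counted independently)
  bf <- hexstim:::boundary_faces(mesh)
  an_faces <- bf$nodes[mesh$labels[bf$elem] ==
                         TISSUES[["electrode_anode"]], , drop = FALSE]
  counts <- table(factor(as.vector(an_faces),
                         levels = seq_len(nrow(mesh$nodes))))
  w <- as.numeric(counts)
  w <- w / sum(w) * 1e-3
  pos <- b > 0
  expect_equal(b[pos], w[pos], tolerance = 1e-12)
})

test_that("zero load gives zero potential and constant potential zero J", {
  mesh <- unit_cube_mesh()
  K <- assemble_stiffness(mesh)
  phi <- solve_potential(list(stiffness = K,
                              load = numeric(nrow(mesh$nodes))))
  expect_identical(as.numeric(phi), numeric(8))
  J <- compute_current_density(mesh, rep(3.7, 8))
  expect_equal(max(abs(J)), 0)
})

test_that("incompatible loads are rejected", {
  mesh <- unit_cube_mesh()
  K <- assemble_stiffness(mesh)
  expect_error(solve_potential(list(stiffness = K, load = rep(1, 8))),
               "incompatible")
})

test_that("bar solve reproduces Ohm's law to trilinear exactness", {
  n <- 10; sig <- 0.43; I <- 2e-3; h <- 0.004
  v <- box_volume(n, 1, 1, code = TISSUES[["skin"]], voxel_size = h * 1000)
  mesh <- assign_conductivity(voxels_to_hex_mesh(v))
  K <- assemble_stiffness(mesh)
  left <- abs(mesh$nodes[, 1] - min(mesh$nodes[, 1])) < 1e-12
  right <- abs(mesh$nodes[, 1] - max(mesh$nodes[, 1])) < 1e-12
  b <- numeric(nrow(mesh$nodes))
  b[left] <- I / 4; b[right] <- -I / 4
  for (method in c("cg", "direct")) {
    phi <- solve_potential(list(stiffness = K, load = b), method = method,
                           rel_tol = 1e-12)
    drop_ <- mean(phi[left]) - mean(phi[right])
    expect_equal(drop_, I * (n * h) / (sig * h^2), tolerance = 1e-8)
    si <- attr(phi, "solver_info")
    expect_lte(si$rel_residual, 1e-10)
    expect_equal(si$n_unknowns, nrow(mesh$nodes))
    # linear-in-x potential: every element J = (-sigma * g, 0, 0) with the
    # uniform density I/A
    J <- compute_current_density(mesh, phi)
    expect_equal(J[, 1], rep(I / h^2, n), tolerance = 1e-8)
    expect_lt(max(abs(J[, 2:3])), 1e-8 * I / h^2)
  }
})

test_that("exactly linear potentials reproduce exact uniform J", {
  ph <- generate_sphere_phantom(three_layer_spec(), resolution = 8)
  mesh <- voxels_to_hex_mesh(ph)
  mesh <- geometry_adapt(mesh, 0.3)
  mesh$tensors <- matrix(rep(c(2, 2, 2, 0, 0, 0), each = nrow(mesh$elems)),
                         ncol = 6)
  mesh$tensors_assigned <- TRUE
  g <- 5
  phi <- g * mesh$nodes[, 1]
  J <- compute_current_density(mesh, phi)
  expect_equal(J[, 1], rep(-2 * g, nrow(mesh$elems)), tolerance = 1e-12)
  expect_lt(max(abs(J[, 2:3])), 1e-10)
})

test_that("potential is antisymmetric for antipodal patches on a sphere", {
  spec <- data.frame(code = TISSUES[["skin"]], radius = 40)
  ph <- generate_sphere_phantom(spec, resolution = 4)
  mo <- montage(electrode_patch(c(90, 0), "anode", width = 12, height = 12),
                electrode_patch(c(90, 180), "cathode", width = 12,
                                height = 12))
  vol <- place_electrode_patches(ph, mo)
  mesh <- assign_conductivity(voxels_to_hex_mesh(vol))
  sol <- solve_montage(mesh, mo, method = "direct", rel_tol = 1e-9)
  # pair nodes with their point reflections through the centre
  keyof <- function(x) paste(round(x[, 1] * 1e7), round(x[, 2] * 1e7),
                             round(x[, 3] * 1e7))
  mirror <- match(keyof(-mesh$nodes), keyof(mesh$nodes))
  ok <- !is.na(mirror)
  asym <- max(abs(sol$potential[ok] + sol$potential[mirror[ok]]))
  expect_lt(asym, 10 * 1e-9 * max(abs(sol$potential)))
})

test_that("negating the load negates potential and current density", {
  mesh <- solve_three_layer(4)$mesh
  mo <- solve_three_layer(4)$montage
  K <- assemble_stiffness(mesh)
  b <- electrode_load_vector(mesh, mo)
  p1 <- solve_potential(list(stiffness = K, load = b))
  p2 <- solve_potential(list(stiffness = K, load = -b))
  expect_identical(as.numeric(p1), -as.numeric(p2))
  expect_identical(compute_current_density(mesh, p1),
                   -compute_current_density(mesh, p2))
})

test_that("solutions scale linearly with total current", {
  fix <- solve_three_layer(4)
  K <- assemble_stiffness(fix$mesh)
  b <- electrode_load_vector(fix$mesh, fix$montage)
  p1 <- solve_potential(list(stiffness = K, load = b))
  p3 <- solve_potential(list(stiffness = K, load = 3 * b))
  expect_equal(3 * as.numeric(p1), as.numeric(p3), tolerance = 1e-12)
})
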