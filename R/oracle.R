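# Analytic zonal-harmonic series for current injection on concentric
# multi-layer spheres: the independent correctness standard for the FE
# solver.

#' Concentric-layer sphere model
#'
#' @param layer_radii Outer radii of the layers in meters, innermost first,
#'   strictly increasing.
#' @param layer_conductivities Conductivity of each layer in S/m.
#' @param source_dir,sink_dir Unit direction vectors of the point current
#'   source (+I) and sink (-I) on the outer surface.
#' @param total_current Injected current in amperes.
#' @return Object of class `sphere_model`.
#' @export
sphere_model <- function(layer_radii, layer_conductivities,
                         source_dir, sink_dir, total_current = 1e-3) {
  stopifnot(length(layer_radii) == length(layer_conductivities),
            all(diff(layer_radii) > 0), all(layer_radii > 0),
            all(layer_conductivities > 0), total_current > 0)
  nrm <- function(v) v / sqrt(sum(v^2))
  structure(list(radii = as.numeric(layer_radii),
                 sigma = as.numeric(layer_conductivities),
                 source_dir = nrm(as.numeric(source_dir)),
                 sink_dir = nrm(as.numeric(sink_dir)),
                 total_current = total_current),
            class = "sphere_model")
}

# per-degree radial coefficients (A_k, B_k per layer) for the layered
# sphere, normalized so the outer Neumann condition carries the point
# source of strength I; returns list(A = L x N, B = L x N) for degrees 1..N
layered_sphere_coeffs <- function(model, n_terms) {
  L <- length(model$radii)
  R <- model$radii[L]
  A <- matrix(0, L, n_terms)
  B <- matrix(0, L, n_terms)
  for (n in seq_len(n_terms)) {
    a <- numeric(L); b <- numeric(L)
    a[1] <- 1; b[1] <- 0
    if (L > 1) for (k in seq_len(L - 1)) {
      x <- model$radii[k] / R
      xn <- x^n; xm <- x^(-(n + 1))
      av <- a[k] * xn; bv <- b[k] * xm          # value split
      P <- av + bv
      Fv <- model$sigma[k] * (n * av - (n + 1) * bv)
      a2 <- ((n + 1) * P + Fv / model$sigma[k + 1]) / (2 * n + 1)
      b2 <- (n * P - Fv / model$sigma[k + 1]) / (2 * n + 1)
      a[k + 1] <- a2 / xn
      b[k + 1] <- b2 / xm
    }
    denom <- model$sigma[L] * (n * a[L] - (n + 1) * b[L]) / R
    if (denom == 0 || !is.finite(denom))
      stop("layered-sphere series ill-conditioned at degree ", n)
    cn <- model$total_current * (2 * n + 1) / (4 * pi * R^2) / denom
    A[, n] <- a * cn
    B[, n] <- b * cn
  }
  list(A = A, B = B)
}

#' Analytic potential of a layered sphere under point-current injection
#'
#' Evaluates the zonal-harmonic series for the potential generated by a
#' point current source (+I) and sink (-I) on the outer surface of a
#' concentric multi-layer conductor. Degrees n = 1..`n_terms` are summed;
#' the n = 0 mode vanishes in the zero-mean gauge on the outer surface.
#'
#' @param model A [sphere_model].
#' @param points n x 3 matrix (or length-3 vector) of evaluation positions
#'   in meters; all must lie inside or on the outer sphere.
#' @param n_terms Number of series terms (default 200).
#' @return Potential in volts at each point. Attribute `tail_ratio` gives
#'   the magnitude of the last term relative to the accumulated sum (a
#'   convergence diagnostic).
#' @export
layered_sphere_potential <- function(model, points, n_terms = 200) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(n_terms >= 1)
  r <- sqrt(rowSums(points^2))
  R <- model$radii[length(model$radii)]
  if (any(r > R * (1 + 1e-12)))
    stop("evaluation point(s) outside the outer sphere")
  layer <- findInterval(pmin(r, R), model$radii, left.open = TRUE) + 1L
  co <- layered_sphere_coeffs(model, n_terms)

  rt <- pmin(r / R, 1)
  safe_r <- pmax(r, .Machine$double.eps)
  u1 <- pmin(1, pmax(-1, (points %*% model$source_dir) / safe_r))
  u2 <- pmin(1, pmax(-1, (points %*% model$sink_dir) / safe_r))
  # Legendre recurrences for both angles, accumulated degree by degree
  P1a <- rep(1, nrow(points)); P1b <- as.numeric(u1)
  P2a <- rep(1, nrow(points)); P2b <- as.numeric(u2)
  phi <- numeric(nrow(points))
  last_term <- numeric(nrow(points))
  rt_pow <- rt                       # rt^n
  for (n in seq_len(n_terms)) {
    aco <- co$A[cbind(layer, n)]
    bco <- co$B[cbind(layer, n)]
    # B is exactly 0 in the innermost layer; skip the (possibly
    # overflowing) negative power there
    rad <- aco * rt_pow
    nz <- bco != 0
    if (any(nz)) rad[nz] <- rad[nz] + bco[nz] * rt[nz]^(-(n + 1))
    term <- rad * (P1b - P2b)
    term[r == 0] <- 0
    phi <- phi + term
    last_term <- term
    # advance recurrences: P_{n+1} = ((2n+1) u P_n - n P_{n-1})/(n+1)
    tmp <- ((2 * n + 1) * u1 * P1b - n * P1a) / (n + 1)
    P1a <- P1b; P1b <- as.numeric(tmp)
    tmp <- ((2 * n + 1) * u2 * P2b - n * P2a) / (n + 1)
    P2a <- P2b; P2b <- as.numeric(tmp)
    rt_pow <- rt_pow * rt
  }
  attr(phi, "tail_ratio") <- max(abs(last_term)) /
    max(max(abs(phi)), .Machine$double.eps)
  phi
}

# closed-form potential of a homogeneous sphere with surface point
# source/sink (used as an independent check of the series)
homogeneous_sphere_potential <- function(R, sigma, source_dir, sink_dir,
                                         total_current, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  r <- sqrt(rowSums(points^2))
  t <- pmin(r / R, 1)
  term <- function(udir) {
    u <- ifelse(r > 0, (points %*% udir) / pmax(r, .Machine$double.eps), 1)
    u <- pmin(1, pmax(-1, u))
    d <- sqrt(pmax(1 - 2 * t * u + t^2, 0))
    d <- pmax(d, .Machine$double.eps)
    2 / d + log(2 / (1 - t * u + d))
  }
  total_current / (4 * pi * sigma * R) *
    (term(source_dir) - term(sink_dir))
}

#' Compare an FE solution against the analytic sphere series
#'
#' Samples FE nodal potentials on a spherical shell away from the
#' electrodes (a polar cap around each electrode direction is excluded,
#' where the point-source oracle and the patch-electrode FE model
#' legitimately differ), re-gauges both solutions to zero mean over the
#' sample, and reports relative L2 and maximum errors. Optionally compares
#' |J| at interior element centroids against a finite-difference gradient
#' of the series.
#'
#' @param solution A `stim_solution` computed on `mesh`.
#' @param mesh The sphere-phantom `hex_mesh` the solution was computed on.
#' @param model The matching [sphere_model].
#' @param shell_radius Sampling shell radius in meters (default: 60% of
#'   the innermost layer radius boundary, a mid-depth shell).
#' @param exclude_cap_deg Polar-cap half-angle around each electrode to
#'   exclude, degrees (default 20).
#' @param compare_j If `TRUE`, also report the relative L2 error of |J|
#'   over sampled interior elements (slower).
#' @param n_terms Series length for the oracle.
#' @return List: `rel_l2`, `max_rel` (potential errors on the shell),
#'   `n_points`, and optionally `rel_l2_jmag`.
#' @export
compare_to_oracle <- function(solution, mesh, model,
                              shell_radius = NULL, exclude_cap_deg = 20,
                              compare_j = FALSE, n_terms = 200) {
  stopifnot(inherits(solution, "stim_solution"), inherits(mesh, "hex_mesh"),
            inherits(model, "sphere_model"))
  R <- model$radii[length(model$radii)]
  non_el <- mesh$labels < TISSUES[["electrode_anode"]]
  rmax_mesh <- sqrt(max(rowSums(
    mesh$nodes[unique(as.vector(mesh$elems[non_el, ])), ]^2)))
  if (abs(rmax_mesh - R) > 0.05 * R)
    stop("mesh outer radius does not match the sphere model")
  if (is.null(shell_radius)) shell_radius <- 0.6 * model$radii[1]
  r <- sqrt(rowSums(mesh$nodes^2))
  vs <- mesh$voxel_size_m
  on_shell <- abs(r - shell_radius) <= vs / 2
  t <- mesh$nodes[on_shell, , drop = FALSE] / r[on_shell]
  cap <- cos(exclude_cap_deg * pi / 180)
  keep <- (t %*% model$source_dir) < cap & (t %*% model$sink_dir) < cap
  idx <- which(on_shell)[keep]
  if (length(idx) < 10)
    stop("too few shell sample points; check shell_radius")
  fe <- solution$potential[idx]
  an <- layered_sphere_potential(model, mesh$nodes[idx, , drop = FALSE],
                                 n_terms = n_terms)
  fe <- fe - mean(fe)
  an <- an - mean(an)
  out <- list(
    rel_l2 = sqrt(sum((fe - an)^2) / sum(an^2)),
    max_rel = max(abs(fe - an)) / max(abs(an)),
    n_points = length(idx)
  )
  if (compare_j) {
    cent <- element_centroids(mesh)
    rc <- sqrt(rowSums(cent^2))
    ec <- abs(rc - shell_radius) <= vs / 2
    tc <- cent[ec, , drop = FALSE] / rc[ec]
    keepc <- (tc %*% model$source_dir) < cap & (tc %*% model$sink_dir) < cap
    eidx <- which(ec)[keepc]
    h <- vs / 20
    grad <- sapply(1:3, function(a) {
      dp <- cent[eidx, , drop = FALSE]; dm <- dp
      dp[, a] <- dp[, a] + h; dm[, a] <- dm[, a] - h
      (layered_sphere_potential(model, dp, n_terms) -
         layered_sphere_potential(model, dm, n_terms)) / (2 * h)
    })
    lay <- findInterval(rc[eidx], model$radii, left.open = TRUE) + 1L
    jan <- sqrt(rowSums(grad^2)) * model$sigma[lay]
    jfe <- sqrt(rowSums(solution$current_density[eidx, , drop = FALSE]^2))
    out$rel_l2_jmag <- sqrt(sum((jfe - jan)^2) / sum(jan^2))
    out$n_elements_j <- length(eidx)
  }
  out
}

# element centroid coordinates (mean of the 8 node positions)
element_centroids <- function(mesh) {
  M <- nrow(mesh$elems)
  sapply(1:3, function(a)
    rowMeans(matrix(mesh$nodes[mesh$elems, a], M, 8)))
}
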