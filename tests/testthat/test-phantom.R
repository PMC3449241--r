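test_that("default 6-tissue phantom contains exactly the head tissue codes", {
  ph <- generate_sphere_phantom(resolution = 2)
  expect_setequal(unique(as.vector(ph$labels)), 0:6)
})

test_that("degenerate and invalid layer specs are handled", {
  spec0 <- data.frame(code = TISSUES[["gm"]], radius = 0)
  ph <- generate_sphere_phantom(spec0, resolution = 1)
  expect_true(all(ph$labels == 0L))

  bad <- data.frame(code = TISSUES[c("wm", "gm")], radius = c(10, 10))
  expect_error(generate_sphere_phantom(bad, resolution = 1),
               "strictly increasing")
  expect_warning(
    generate_sphere_phantom(
      data.frame(code = TISSUES[c("wm", "gm")], radius = c(10, 10.5)),
      resolution = 2),
    "thinnest shell")
})

test_that("voxelization matches a brute-force lattice enumeration", {
  spec <- data.frame(code = TISSUES[["gm"]], radius = 5)
  ph <- generate_sphere_phantom(spec, resolution = 1, margin_mm = 2)
  # independent oracle: triple loop over integer lattice points
  count <- 0L
  for (x in -7:7) for (y in -7:7) for (z in -7:7)
    if (x^2 + y^2 + z^2 <= 25) count <- count + 1L
  expect_identical(sum(ph$labels != 0L), count)
})

test_that("tissue shells are nested per the layer ordering", {
  ph <- generate_sphere_phantom(resolution = 2)
  spec <- attr(ph, "layer_spec")
  idx <- which(ph$labels != 0L)
  r <- sqrt(rowSums(hexstim:::voxel_centers(ph, idx)^2))
  lab <- ph$labels[idx]
  # every voxel lies within the outer radius of its own layer, and outside
  # the preceding layer's radius
  for (k in seq_len(nrow(spec))) {
    in_layer <- lab == spec$code[k] &
      (k == 1 | r > c(0, spec$radius)[k])
    sel <- lab == spec$code[k]
    expect_true(all(r[sel] <= spec$radius[max(which(spec$code ==
      spec$code[k]))] + 1e-9))
  }
  # WM strictly inside the GM outer radius, GM inside CSF, CSF inside skull
  expect_lt(max(r[lab == TISSUES[["wm"]]]), spec$radius[spec$tissue == "gm"])
  expect_lt(max(r[lab == TISSUES[["gm"]]]), spec$radius[spec$tissue == "csf"])
  expect_lt(max(r[lab == TISSUES[["csf"]]]),
            min(spec$radius[spec$tissue == "skull_compacta"]))
})

test_that("gyral ridges convert CSF to GM and touch nothing else", {
  plain <- generate_sphere_phantom(resolution = 2)
  ridged <- generate_sphere_phantom(resolution = 2,
                                    gyrus = list(n = 8, amplitude = 1))
  n_plain <- table(factor(plain$labels, levels = 0:8))
  n_ridge <- table(factor(ridged$labels, levels = 0:8))
  gm <- as.character(TISSUES[["gm"]]); csf <- as.character(TISSUES[["csf"]])
  expect_gt(n_ridge[[gm]], n_plain[[gm]])
  expect_lt(n_ridge[[csf]], n_plain[[csf]])
  moved <- n_ridge[[gm]] - n_plain[[gm]]
  expect_equal(n_plain[[csf]] - n_ridge[[csf]], moved)
  others <- setdiff(names(n_plain), c(gm, csf))
  expect_identical(as.vector(n_plain[others]), as.vector(n_ridge[others]))
})

test_that("WM tensor field is SPD, WM-only, and follows the fiber pattern", {
  ph <- suppressWarnings(generate_sphere_phantom(resolution = 4))
  expect_error(generate_wm_tensor_field(ph, anisotropy_ratio = 0.5),
               ">= 1")

  tf <- generate_wm_tensor_field(ph, anisotropy_ratio = 1)
  expect_true(all(abs(tf$tensors[, 1:3] - tf$tensors[1, 1]) < 1e-14))
  expect_true(all(abs(tf$tensors[, 4:6]) < 1e-14))

  # tensors exist exactly on WM voxels
  expect_setequal(tf$index, which(ph$labels == TISSUES[["wm"]]))

  # radial pattern: principal eigenvector on the +x axis is (1,0,0)
  tf10 <- generate_wm_tensor_field(ph, 10, "radial")
  centers <- hexstim:::voxel_centers(ph, tf10$index)
  on_x <- which(centers[, 2] == 0 & centers[, 3] == 0 & centers[, 1] > 0)
  expect_gt(length(on_x), 0)
  ev <- eigen(hexstim:::tensor_matrix(tf10$tensors, on_x[1]),
              symmetric = TRUE)
  expect_equal(abs(ev$vectors[, 1]), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(ev$values[1] / ev$values[3], 10, tolerance = 1e-12)

  # SPD across a range of anisotropy ratios
  for (ratio in c(1, 2, 10, 100)) {
    tfr <- generate_wm_tensor_field(ph, ratio, "tangential")
    some <- seq(1, length(tfr$index), length.out = 25)
    for (i in some) {
      lam <- eigen(hexstim:::tensor_matrix(tfr$tensors, i),
                   symmetric = TRUE, only.values = TRUE)$values
      expect_true(all(lam > 0))
    }
  }
})

test_that("10-20 analog directions follow the standard construction", {
  expect_equal(ten_twenty_direction("Cz")[["inclination"]], 0)
  expect_equal(unname(ten_twenty_direction("Oz")), c(90, 180))
  f7 <- ten_twenty_direction("F7"); f8 <- ten_twenty_direction("F8")
  expect_equal(f7[["inclination"]], f8[["inclination"]])
  expect_equal(f7[["azimuth"]], -f8[["azimuth"]])
  expect_error(ten_twenty_direction("T3"), "unknown")
})

test_that("label volumes survive a NIfTI round trip", {
  ph <- generate_sphere_phantom(
    data.frame(code = TISSUES[c("gm", "skin")], radius = c(6, 10)),
    resolution = 2, margin_mm = 2)
  f <- tempfile(fileext = ".nii.gz")
  write_label_volume(ph, f)
  back <- read_label_volume(f)
  expect_identical(back$labels, ph$labels)
  expect_equal(back$voxel_size, ph$voxel_size)
  expect_equal(back$origin, ph$origin, tolerance = 1e-6)
  unlink(f)
})
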