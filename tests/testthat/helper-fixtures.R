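# Shared fixtures, built lazily and cached for the duration of a test run.
# Heavy solves (the 2 mm default-phantom solutions used by the acceptance
# checks) are computed once and reused across test blocks.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small uniform box label volume (nx x ny x nz of one tissue)
box_volume <- function(nx = 2, ny = 2, nz = 2, code = TISSUES[["gm"]],
                       voxel_size = 1) {
  label_volume(array(as.integer(code), c(nx, ny, nz)), voxel_size,
               c(0, 0, 0))
}

# 3-layer isotropic sphere phantom spec used against the analytic oracle:
# brain-like core, resistive shell, conductive outer shell
three_layer_spec <- function() {
  data.frame(tissue = c("gm", "skull_compacta", "skin"),
             code = TISSUES[c("gm", "skull_compacta", "skin")],
             radius = c(70, 78, 86), row.names = NULL)
}

three_layer_sigma <- function() {
  unname(tissue_table()[c("gm", "skull_compacta", "skin")])
}

# small-patch antipodal montage for oracle comparisons
small_patch_montage <- function() {
  montage(electrode_patch(c(90, 0), "anode", width = 10, height = 10),
          electrode_patch(c(90, 180), "cathode", width = 10, height = 10))
}

# FE solve of the 3-layer sphere at a given resolution, vs-oracle ready
solve_three_layer <- function(resolution) {
  cached(paste0("sphere3_", resolution), {
    ph <- generate_sphere_phantom(three_layer_spec(),
                                  resolution = resolution)
    mo <- small_patch_montage()
    vol <- place_electrode_patches(ph, mo)
    mesh <- assign_conductivity(geometry_adapt(voxels_to_hex_mesh(vol)))
    list(mesh = mesh, montage = mo,
         solution = solve_montage(mesh, mo),
         model = sphere_model(c(70, 78, 86) / 1000, three_layer_sigma(),
                              angles_to_direction(c(90, 0)),
                              angles_to_direction(c(90, 180)), 1e-3))
  })
}

# default 2 mm head phantom with the FPz-Oz montage: mesh, system, solution
default_head_case <- function() {
  cached("head2mm", {
    mo <- standard_montages()[["FPz-Oz"]]
    vol <- place_electrode_patches(generate_sphere_phantom(resolution = 2),
                                   mo)
    mesh <- assign_conductivity(geometry_adapt(voxels_to_hex_mesh(vol)))
    system <- list(stiffness = assemble_stiffness(mesh),
                   load = electrode_load_vector(mesh, mo))
    list(vol = vol, mesh = mesh, montage = mo, system = system,
         solution = solve_montage(mesh, mo, system = system))
  })
}

# four-montage comparison at 2 mm (shared by the montage-ordering checks)
four_montage_comparison <- function() {
  cached("cmp4", run_pipeline(pipeline_config(resolution = 2)))
}

angles_to_direction <- hexstim:::angles_to_direction
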