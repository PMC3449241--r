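#' Tissue label codes
#'
#' Integer codes used throughout the package for the six head-tissue
#' compartments, background, and the two electrode patches. The encoding is
#' fixed so that label volumes written to NIfTI form a stable file contract.
#'
#' @format Named integer vector with entries `background` (0), `skin` (1),
#'   `skull_compacta` (2), `skull_spongiosa` (3), `csf` (4), `gm` (5),
#'   `wm` (6), `electrode_anode` (7), `electrode_cathode` (8).
#' @export
TISSUES <- c(
  background       = 0L,
  skin             = 1L,
  skull_compacta   = 2L,
  skull_spongiosa  = 3L,
  csf              = 4L,
  gm               = 5L,
  wm               = 6L,
  electrode_anode  = 7L,
  electrode_cathode = 8L
)

#' Tissue conductivity table
#'
#' Isotropic conductivities in S/m assigned to each tissue compartment.
#' Skin, skull compacta, skull spongiosa and CSF use literature values of
#' 0.43, 0.007, 0.025 and 1.79 S/m; gray and white matter default to the
#' effective-medium target means of 0.24 and 0.19 S/m; electrode patches are
#' saline-like at 1.4 S/m.
#'
#' @param ... Named overrides, e.g. `tissue_table(gm = 0.3)`. Names must be
#'   tissue names from [TISSUES] (other than `background`).
#' @return Named numeric vector mapping tissue name to conductivity in S/m.
#' @examples
#' tissue_table()
#' tissue_table(skull_compacta = 0.01)
#' @export
tissue_table <- function(...) {
  tab <- c(
    skin            = 0.43,
    skull_compacta  = 0.007,
    skull_spongiosa = 0.025,
    csf             = 1.79,
    gm              = 0.24,
    wm              = 0.19,
    electrode_anode = 1.4,
    electrode_cathode = 1.4
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(tab))
    if (length(bad)) stop("unknown tissue(s): ", paste(bad, collapse = ", "))
    tab[names(over)] <- as.numeric(unlist(over))
  }
  if (any(tab <= 0)) stop("all conductivities must be > 0")
  tab
}

# tissue name for a code (vectorized)
tissue_name <- function(code) {
  names(TISSUES)[match(code, TISSUES)]
}
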