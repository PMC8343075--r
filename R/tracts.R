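#' Canonical white-matter tracts and diffusion properties
#'
#' The 20 major white-matter tracts delineated by AFQ-style tractography,
#' and the four tensor-derived diffusion properties quantified along them.
#' Tract identifiers are snake_case; properties are FA (fractional
#' anisotropy, dimensionless), MD (mean), RD (radial) and AxD (axial)
#' diffusivity, the latter three in units of 1e-3 mm^2/s.
#'
#' @return `canonical_tracts()` returns a character vector of the 20 tract
#'   identifiers; `diffusion_properties()` the four property codes.
#' @export
#' @examples
#' canonical_tracts()
canonical_tracts <- function() {
  c("left_thalamic_radiation", "right_thalamic_radiation",
    "left_corticospinal", "right_corticospinal",
    "left_cingulum_cingulate", "right_cingulum_cingulate",
    "left_cingulum_hippocampus", "right_cingulum_hippocampus",
    "callosum_forceps_major", "callosum_forceps_minor",
    "left_ifof", "right_ifof",
    "left_ilf", "right_ilf",
    "left_slf", "right_slf",
    "left_uncinate", "right_uncinate",
    "left_arcuate", "right_arcuate")
}

#' @rdname canonical_tracts
#' @export
diffusion_properties <- function() c("FA", "MD", "RD", "AxD")

# property units, for reports
property_units <- function(property) {
  ifelse(property == "FA", "dimensionless", "1e-3 mm^2/s")
}
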