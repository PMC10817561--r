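# Shared fixture builders; everything is generated in code at test time.

img_const <- function(value, shape = c(1, 1), bit_depth = 8L,
                      wavelength_nm = 808) {
  intensity_image(matrix(value, shape[1], shape[2]), bit_depth = bit_depth,
                  wavelength_nm = wavelength_nm)
}

# The packaged chicken-tissue NIR matrix (rows 780/808/980 nm,
# cols meat/bone/skin).
chicken_mat <- function() chicken_attenuation_matrix()

# Small noise-free, unquantized phantom for exact round-trip checks.
exact_phantom <- function(preset = "side_by_side", shape = c(32L, 32L),
                          seed = 1L) {
  phantom_preset(preset, frame_shape = shape, seed = seed,
                 noise = list(speckle_sigma = 0, read_sigma = 0),
                 quantize = FALSE)
}

# A homogeneous-specimen characterization sample with exact transmittance
# exp(-mu * d) against a flat reference beam.
homogeneous_sample <- function(mu, d, tissue = "meat", wavelength = 808,
                               shape = c(8, 8), ref_counts = 40000) {
  ref <- intensity_image(matrix(ref_counts, shape[1], shape[2]), 16L, wavelength)
  obj <- intensity_image(matrix(ref_counts * exp(-mu * d), shape[1], shape[2]),
                         16L, wavelength)
  characterization_sample(tissue, wavelength, d, obj, ref)
}

random_mask <- function(shape, p = 0.4) {
  matrix(stats::runif(prod(shape)) < p, shape[1], shape[2])
}
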