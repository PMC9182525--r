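# Shared fixtures built in code.

# Noise-free configuration used by deterministic round-trip tests.
noise_free_config <- function(seed = 42) {
  sim_config(seed = seed, noise_scale = 0, spike_rate = 0)
}

# Single Gaussian band spectrum on a given grid.
gaussian_spectrum <- function(axis, amplitude, center, fwhm,
                              modality = "FTIR", offset = 0) {
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  new_spectrum(axis, offset + amplitude * exp(-(axis - center)^2 / (2 * sig^2)),
               modality)
}

# Closed-form area of a Gaussian band.
gaussian_area <- function(amplitude, fwhm) {
  amplitude * fwhm / (2 * sqrt(2 * log(2))) * sqrt(2 * pi)
}

# Published sensitivity ratios of the thirteen network inputs, used as input
# data for the pruning arithmetic.
published_sensitivity <- function() {
  data.frame(
    feature = c("DMTII", "CaP", "FWHM002", "DMTI", "a_lattice",
                "CP_FTIR", "CP_Raman", "Fe", "P", "CI_FTIR", "C", "Ca",
                "CI_Raman"),
    ratio = c(7.22, 5.46, 2.63, 1.76, 1.57, 1.53, 1.49, 1.35, 1.31,
              1.07, 1.06, 0.996, 0.994))
}

# Standard Raman preprocessing chain.
raman_preprocess <- function(s) {
  rubber_band(subtract_fluorescence(despike(s)))
}
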