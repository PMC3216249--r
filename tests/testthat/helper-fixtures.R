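# Shared fixtures: everything is generated in code, nothing on disk.

noiseless_blot <- function(...) blot_config(noise_sd = 0, ...)

# Fig-1A-style control panel: a line with both proteins, one MSH2-only,
# one MLH1-only.
control_panel <- function() {
  list(subject_spec("SW480", cell_type = "cell_line"),
       subject_spec("HCT116", cell_type = "cell_line",
                    base_abundance_mlh1 = 0),
       subject_spec("LoVo", cell_type = "cell_line",
                    base_abundance_msh2 = 0))
}

# closed-form Gaussian band area restricted to a window (the independent
# densitometry oracle)
gaussian_area <- function(A, mu, sigma, lo, hi) {
  A * sigma * sqrt(2 * pi) *
    (stats::pnorm(hi, mu, sigma) - stats::pnorm(lo, mu, sigma))
}

# net band integrals of a noiseless lane, by direct summation against the
# known background (independent of measure_band)
net_integral_direct <- function(profile, blot, protein) {
  ctr <- if (protein == "MLH1") blot$band_center_mlh1 else
    blot$band_center_msh2
  w <- ceiling(3 * blot$band_sigma)
  idx <- profile$positions >= ctr - w & profile$positions <= ctr + w
  bg <- blot$background_level +
    blot$background_slope * (profile$positions[idx] - 1)
  sum(profile$intensities[idx] - bg)
}
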