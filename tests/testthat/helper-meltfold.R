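# shared fixtures for the test suite -- everything is generated in code

# hairpin parameters of the 16-mer segment as determined by NMR
# (Tm = 60.8 degC, dH = -137 kJ/mol; dS follows as dH/Tm)
hairpin_nmr <- function() thermo_params_from_tm(60.8, -137000, "hairpin")

# hairpin parameters as determined by UV at 3.08 uM
hairpin_uv <- function() thermo_params_from_tm(57.4, -137000, "hairpin")

# UV-regime generator config (5-85 degC, 4 degC step, 1e-3 AU noise)
uv_cfg16 <- function(seed = 1L, noise_sigma = 0.001, model = "hairpin",
                     duplex = NULL) {
  synth_config(seed = seed, model = model, hairpin = hairpin_uv(),
               duplex = duplex, c = 3.08e-6, noise_sigma = noise_sigma,
               T_grid = seq(5, 85, by = 4))
}

# NMR-regime generator config (5-75 degC, 2 degC step, ppm noise)
nmr_cfg16 <- function(seed = 1L, noise_sigma = 0.002, model = "hairpin",
                      duplex = NULL) {
  synth_config(seed = seed, model = model, hairpin = hairpin_nmr(),
               duplex = duplex, c = 1.14e-3, noise_sigma = noise_sigma,
               T_grid = seq(5, 75, by = 2))
}

# small resonance subset for fast fitting loops: the n resonances with
# the largest folded/unfolded shift difference (the informative ones)
small_resonances <- function(n = 8) {
  tab <- default_resonance_table()
  tab[order(-abs(tab$delta_u0 - tab$delta_f0))[seq_len(n)], ]
}

# a tiny proton geometry including the calibration pair
tiny_geometry <- function() {
  data.frame(atom_a = c("C-4 H5", "C-5 H5", "A6 H8", "T1 H1'", "T2 M7"),
             atom_b = c("C-4 H6", "C-5 H6", "A6 H1'", "T2 H6", "A3 H2"),
             d = c(2.9, 2.9, 3.6, 3.1, 4.0),
             stringsAsFactors = FALSE)
}
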