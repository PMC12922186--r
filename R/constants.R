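# CODATA 2018 values, >= 8 significant digits, hard-coded for reproducibility
.const <- list(
  N_A = 6.02214076e23,   # mol^-1 (exact, SI 2019)
  k_B = 1.380649e-23     # J K^-1 (exact, SI 2019)
)

# internal length unit is Angstrom; conversions live here
A_PER_NM <- 10
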