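example_canopy_spectrum.csv
  A simulated 203-band top-of-canopy reflectance spectrum on the camera
  grid (397-1006 nm), produced by the package's own forward model for a
  typical mid-season rice parameter set (synthetic; no field data).
  Format: the two-column CSV (wavelength_nm, reflectance) accepted by
  read_spectrum_csv() and the command-line `invert` subcommand.
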