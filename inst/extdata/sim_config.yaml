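# Default single-dipole group-simulation settings.
# Any field omitted here falls back to the package default.
seed_mni_mm: [52, -29, 13]   # centre of the source-location distribution
jitter_sd_mm: 5              # per-participant location scatter
moment_nAm: 20               # dipole moment; swept by the hit/miss runner
freq_hz: 40
duration_s: 0.2
fs_hz: 200
n_epochs: 60
n_active: 30
noise_density_fT: 10         # white-noise density, fT/sqrt(Hz)
bandwidth_hz: 80
sensors:
  n_channels: 275
  array_radius_m: 0.12
  sphere_radius_m: 0.09
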