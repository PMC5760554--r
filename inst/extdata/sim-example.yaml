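# Example acquisition config for `helixsheet.R simulate`.
# A small two-slice run over a mitochondrial-membrane phantom.
grid:
  n_side: 128
  aperture_radius: 32
phantom:
  kind: mito_cylinder
  center_um: [0.0, 0.0, 1.8]
  radius_um: 0.15
  length_um: 3.0
  axis: [1.0, 0.3, 0.0]
  thickness_nm: 40.0
  density_um2: 400.0
  seed: 7
scan:
  start_um: 1.5
  stop_um: 2.5
  step_um: 1.0
frames_per_slice: 40
fiducial_period: 20
illumination:
  mode: sheet
# keep the bead at least half a template (41 px) from the field edge
fiducials:
  x_nm: [1600.0]
  y_nm: [-1600.0]
  z_nm: [0.0]
  photons: [50000.0]   # keeps peak counts below the 16-bit A/D ceiling
blink:
  k_off: 10.0
  k_on: 0.01
  k_bleach: 0.2
  initial_dark: 0.995
drift:
  kind: linear
  rate_nm: 1.0
camera:
  exposure_ms: 50.0
  em_gain: 186.0
fov:
  nx: 64
  ny: 64
  pixel_nm: 160.0
photon_rate: 60000.0
background: 8.0
seed: 11
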