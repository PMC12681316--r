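# Example run configuration for the wire-current workflow.
# Unspecified values fall back to package defaults (the nominal da-hdrAFI
# protocol, 12x12 voxels of 2x2 mm, 3x3 sub-voxel oversampling).

sequence:
  alpha_a1: 45.2        # degrees
  alpha_a2: 69.3
  tr_a1: 23.7           # ms
  tr_a2: 61.5
  alpha_b1: 21.9
  alpha_b2: 39.0
  tr_b1: 26.5
  tr_b2: 188.5
  b1_rms_seq: 0.84      # uT; fitted currents are referenced to this

geometry:
  n_voxels: 12
  voxel_size: 2         # mm
  slice_thickness: 2    # mm
  subdivision: 3
  exclusion_radius: 2   # mm

dictionary:
  t1: 1000              # ms, gel/tissue T1 (fixed input, not fitted)
  lambda_max: 30
  lambda_step: 0.01
  n_positions: 201
  z_extent: 2           # slice thicknesses each side

pulse:
  shape: hann_sinc
  tbw: 4

# for `simulate`: the ground-truth scene
truth:
  i_rms: 0.12           # A
  phi_j_prime: 0.7      # rad
  xi: 0.35              # rad, wire angle to B0
  theta: 0.4            # rad, in-plane azimuth
  x0: 0.6               # mm
  y0: -0.8
  lambda_b: 1.05
# noise_sigma: 0        # omit for the default body-coil noise level

# for `fit`: either a simulated patch prefix or 4 NIfTI images
# patch_prefix: out/patch
# images: [sa1.nii.gz, sa2.nii.gz, sb1.nii.gz, sb2.nii.gz]
# center_hint: [64, 71]  # 1-based voxel indices of the wire in the images
# position_hint: [0, 0]  # mm, in-patch coordinates, centers the x0/y0 bounds
fit:
  population_size: 61
  n_iterations: 122
  mask_radius: 4        # mm

# for `calibrate`: CSV with columns i_mri (A), dt_thermo (K)
# observations: observations.csv
# slice_distance: 33    # mm, tip-to-slice distance of the calibration
# for `predict` / `limit`:
# calibration: calibration.json
# i_mri: 0.12
# dt_thresh: 2          # K

seed: 1
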