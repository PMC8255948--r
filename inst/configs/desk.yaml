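# Desk-scale comparison profile: finishes in minutes on one CPU while
# preserving the full-scale method ordering experiment layout.
n_rows: 64
n_cols: 64
pixel_size: 0.35
n_angles: 60
n_radial: 96
n_tof: 5
tof_fwhm: 8.25
total_events: 200000
background_fraction: 0.4
methods: [mlaa, kernel, red-kernel, unet-kernel]
n_outer: 200
record_every: 50
report_iter: 200
k: 50
sigma: 1
patch_side: 3
ae_epochs: 300
n_realizations: 3
master_seed: 1
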