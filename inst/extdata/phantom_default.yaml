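# Default synthetic head phantom: 4-shell sphere with bilateral vestibular
# ROIs. All fields optional; these are the package defaults.
layer_radii_mm: [92, 86, 80, 78, 55]
layer_tissues: [skin, skull, CSF, gray matter, white matter]
voxel_mm: 2
asymmetry_factor: 1
include_cochlea: false
grid_margin_mm: 9
seed: 42
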