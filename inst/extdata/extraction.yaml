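# Pinned feature-extraction configuration.
# Fixed-bin-width discretization in Hounsfield units; all five texture
# families at distance 1 over the full 3D neighbourhood.
bin_width: 0.5
enabled_classes:
  - shape-size
  - first-order
  - textural
glcm_directions: 13
glrlm_directions: 13
glszm_connectivity: 26
gldm_alpha: 0
neighbourhood_distance: 1
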