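# Custom montage: anode on the left mastoid site, cathode by explicit
# direction (vertex), smaller pads.
name: mastoid_vertex
pads:
  - {site: 1, polarity: anode, diameter_mm: 20}
  - {direction: [0, 0, 1], polarity: cathode, diameter_mm: 20}
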