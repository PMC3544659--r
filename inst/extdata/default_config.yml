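# ihcscore configuration (all fields optional; these are the defaults)
zones: [60, 120, 170, 230]   # upper bounds of zones 3+/2+/1+/0; >230 excluded
dominance: 0.66              # strict majority-zone threshold
rounding: half_up            # grade rounding of the weighted score
stains: hdab                 # stain-vector preset or path to a 3x3 text file
background: [255, 255, 255]  # per-channel white level, or "estimate"
epsilon: 1                   # intensity floor in the OD transform
area_threshold: 170          # "stained" cutoff for area categories
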