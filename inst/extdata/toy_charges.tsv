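# Toy partial-charge table (synthetic; NOT force-field charges).
# Columns: resname atom charge (elementary-charge units).
# GCS = idealized neutral glucosamine residue, HOH = 3-site water.
GCS N   -0.90
GCS HN   0.40
GCS O3  -0.65
GCS HO3  0.40
GCS O4  -0.40
GCS O5  -0.40
GCS O6  -0.65
GCS HO6  0.40
GCS C1   0.50
GCS C2   0.25
GCS C3   0.25
GCS C4   0.30
GCS C5   0.25
GCS C6   0.25
HOH O   -0.834
HOH H1   0.417
HOH H2   0.417
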