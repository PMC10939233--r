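# Example Prox-seq simulation configuration.
# All count parameters are mean UMIs per cell; lengths are in nm.

protein_names: [CD3, CD28, IgG1]   # panel; names must not contain ":"

# mean non-interacting probe counts per protein (probe A and probe B)
probe_a_means: [20, 15, 2]
probe_b_means: [20, 15, 2]

# mean complex counts, keyed "<proteinA>:<proteinB>"; homodimers i:i
complex_means:
  "CD3:CD3": 50
  "CD3:CD28": 30
  "CD28:CD3": 30
  "CD28:CD28": 50

nb_dispersion: 1.5          # negative binomial size parameter n_NB
radius: 5000                # cell radius (5 um)
ligation_distance: 50       # ligation distance (50 nm)
nonspecific_prob: [0, 0, 0.05]  # per-antibody nonspecific binding
n_cells: 100
seed: 1
variance_mode: negative_binomial   # or "none"
output_nonproximal: true    # write the free-oligo (non-proximal) table
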