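# Default modification registry: the tagged H3 tail search space.
# delta = monoisotopic Da; max_count is per peptide (omit for fixed mods).
- name: Methyl
  delta: 14.015650
  targets: [K, R]
  mod_class: common
  max_count: 3
- name: Dimethyl
  delta: 28.031300
  targets: [K, R]
  mod_class: common
  max_count: 3
- name: Trimethyl
  delta: 42.046950
  targets: [K]
  mod_class: common
  max_count: 3
- name: Phospho
  delta: 79.966331
  targets: [S, T]
  mod_class: common
  max_count: 2
- name: Acetyl
  delta: 42.010565
  targets: [K]
  mod_class: common
  max_count: 5
- name: Propionyl
  delta: 56.026215
  targets: [K]
  mod_class: rare
  max_count: 1
- name: TMT6plex
  delta: 229.162932
  targets: [H]
  mod_class: fixed
- name: CtermLigationOffset
  delta: 76.1001
  targets: [Cterm]
  mod_class: fixed
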