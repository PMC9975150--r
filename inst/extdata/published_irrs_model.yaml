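format: irrs_model
version: published
pairs:
- Effector memory CD8 T cell|CD56dim natural killer cell
- Type 2 T helper cell|Effector memory CD8 T cell
- Immature B cell|Effector memory CD4 T cell
- Natural killer T cell|Immature B cell
- MDSC|Monocyte
- Natural killer cell|Central memory CD8 T cell
coefficients:
- -0.201895537
- 0.162775185
- -0.167620476
- 0.376203094
- -0.146018787
- -0.32046159
training_median: NA
ssgsea:
  alpha: 0.25
  normalize: none
filter_threshold: 0.8
p_cut: 0.05
seed: NA
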