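# Preset three-genotype mutation-selection experiment.
# Genotype 3 carries a reproductive advantage (lambda 1.5 vs 1.05) but can
# only be reached by the very rare 2 -> 3 mutation (probability 1e-14).
# Null diagonal entries of the mutation matrix are completed so each row
# sums to 1.
model: multitype
lambdas: [1.05, 1.05, 1.5]
alphas: [2, 2, 2]
betas: [1.0e-6, 1.0e-6, 1.0e-6]
mutation:
- [~, 1.0e-6, 0.0]
- [1.0e-12, ~, 1.0e-14]
- [1.0e-15, 1.0e-17, ~]
x0: [10000, 0, 0]
nGenerations: 300
nReplicates: 100
masterSeed: 101
quantileLevels: [0.05, 0.25, 0.5, 0.75, 0.95]
includeExtinct: true
deterministicOnly: false
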