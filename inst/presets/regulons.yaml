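# TF-driven co-expression: 3 regulons, one active type each
nGenes: 600
nTypes: 3
cellsPerType: 120
markersPerType: 10
markerFold: 6
baseMean: 4.5

dispersion: 2
libSizeSd: 0.2
mitoGeneCount: 5
stressGeneCount: 5
mitoFrac: 0.02
stressFrac: 0.02
regulons:
  nTFs: 3
  targetsPerTF: 10
  couplingStrength: 0.8
seed: 1
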