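# P7-like cochlear duct: 12 discrete cell-type programs, ~1,200 cells
nGenes: 2000
nTypes: 12
cellsPerType: 100
markersPerType: 25
exclusivesPerType: 5
markerFold: 6
baseMean: 1.5
dispersion: 2
libSizeSd: 0.2
mitoGeneCount: 10
stressGeneCount: 10
mitoFrac: 0.02
stressFrac: 0.02
qcOutlierFractions:
  low_complexity: 0.02
  high_complexity: 0.01
  high_mito: 0.02
  high_stress: 0.01
seed: 1
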