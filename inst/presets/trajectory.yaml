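# Differentiation continuum with 4 temporal phase modules (OHC-style)
nGenes: 1000
nTypes: 1
cellsPerType: 400
markersPerType: 0
markerFold: 5
baseMean: 2.5
dispersion: 2
libSizeSd: 0.2
mitoGeneCount: 10
stressGeneCount: 10
mitoFrac: 0.02
stressFrac: 0.02
trajectory:
  nCells: 400
  nModules: 4
  genesPerModule: 50
seed: 1
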