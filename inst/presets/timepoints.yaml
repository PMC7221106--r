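# Two-time-point pair with planted per-pathway up/down shifts (2-fold)
nGenes: 1200
nTypes: 3
cellsPerType: 150
markersPerType: 0
markerFold: 6
baseMean: 2.5
dispersion: 2
libSizeSd: 0.2
mitoGeneCount: 10
stressGeneCount: 10
mitoFrac: 0.02
stressFrac: 0.02
pathways:
  nPathways: 6
  genesPerPathway: 16
  upFrac: [0.75, 0.25, 1.0, 0.0, 0.5, 0.625]
  downFrac: [0.25, 0.75, 0.0, 1.0, 0.25, 0.125]
seed: 1
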