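{
  "seed": 42,
  "outdir": "darkbin-out",
  "simulation": {
    "genomeLength": 40000,
    "knownDivergence": 0.005,
    "novelDivergence": 0.12,
    "contigsPerGenome": 8,
    "minContigLen": 2000,
    "coverageKnown": 30,
    "coverageNovel1": 10,
    "coverageNovel2": 100,
    "coverageCv": 0.05,
    "nGenes": 15,
    "geneLength": 800,
    "mlst": { "nLoci": 8, "readLen": 100, "coverage": 20,
              "errorRate": 0.01 },
    "cohort": { "nPatients": 10, "effectMultiplier": 2,
                "depthPerSample": 20000 }
  },
  "thresholds": {
    "minBinTotalLen": 20000,
    "rarefactionDepth": 20000
  }
}
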