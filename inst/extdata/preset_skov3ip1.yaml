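# Synthetic preset emulating the SKOV3IP1 combination experiment:
# single-agent IC50s cisplatin 22 uM, paclitaxel 0.38 uM, DSF 20 uM,
# constant-ratio two- and three-drug mixtures with synergistic true CI.
seed: 20220101
fa_levels: [0.5, 0.75, 0.9]
drugs:
  - name: cisplatin
    simulate: {m: 2.0, dm: 22, noise_sd: 0.02}
  - name: paclitaxel
    simulate: {m: 1.5, dm: 0.38, noise_sd: 0.02}
  - name: disulfiram
    simulate: {m: 2.5, dm: 20, noise_sd: 0.02}
combinations:
  - name: Cis + Pac
    drugs: [cisplatin, paclitaxel]
    simulate: {ci: 0.5, noise_sd: 0.02}
  - name: Cis + DSF
    drugs: [cisplatin, disulfiram]
    simulate: {ci: 0.3, noise_sd: 0.02}
  - name: Cis + Pac + DSF
    drugs: [cisplatin, paclitaxel, disulfiram]
    simulate: {ci: 0.3, noise_sd: 0.02}
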