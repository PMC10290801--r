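# Rasfonin chain specification: two acetate-derived polyketide chains
# joined by an ester bond. Unit indices count from the starter unit.
name: rasfonin
formula: C25H38O6
chains:
  - name: hexaketide
    release: pyrone_cyclization
    units:
      - {alpha_methyl: false, beta_state: starter}
      - {alpha_methyl: true,  beta_state: reduced}
      - {alpha_methyl: true,  beta_state: reduced}
      - {alpha_methyl: true,  beta_state: enoyl}
      - {alpha_methyl: false, beta_state: hydroxyl}
      - {alpha_methyl: false, beta_state: ketone}
  - name: tetraketide
    release: ester_transfer
    units:
      - {alpha_methyl: false, beta_state: starter}
      - {alpha_methyl: true,  beta_state: reduced}
      - {alpha_methyl: true,  beta_state: enoyl}
      - {alpha_methyl: false, beta_state: reduced}
ester_links:
  - {chain: tetraketide, position: C4}
post_pks_hydroxylations: ["C4", "C8'", "C10'"]
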