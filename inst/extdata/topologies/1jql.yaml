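# Monomeric (mutant) E. coli beta clamp from the beta/delta complex
# (PDB 1JQL).  Sub-assembly topology: three domains, no opening interface.
# Residue ranges are the same reconstruction used for 1OK7; edit the chain
# identifier if your copy of the entry labels the beta subunit differently.
clamp_name: pol3_beta_monomer_1jql
domains:
- label: A1
  chain: A
  start: 1
  end: 125
- label: A2
  chain: A
  start: 126
  end: 252
- label: A3
  chain: A
  start: 253
  end: 366
ring_order: [A1, A2, A3]
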