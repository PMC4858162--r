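# E. coli Pol III beta sliding clamp homodimer (PDB 1OK7, chains A and B).
# Three DNA-clamp domains per protomer.  The source publications do not
# tabulate domain residue boundaries; the ranges below are a reconstruction
# from the standard three-domain decomposition of the beta fold
# (~1-125 / 126-252 / 253-366) and may be edited.
clamp_name: pol3_beta_1ok7
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
- label: B1
  chain: B
  start: 1
  end: 125
- label: B2
  chain: B
  start: 126
  end: 252
- label: B3
  chain: B
  start: 253
  end: 366
ring_order: [A1, A2, A3, B1, B2, B3]
open_interface: [A3, B1]
torsion_quadruples:
- [B1, B2, B3, A1]
- [B2, B3, A1, A2]
- [B3, A1, A2, A3]
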