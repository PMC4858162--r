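# S. cerevisiae PCNA homotrimer (PDB 1PLQ, biological assembly with chains
# A, B, C).  Two DNA-clamp domains per protomer; ranges are a reconstruction
# from the standard PCNA decomposition (N-domain ~1-117, C-domain 118-258
# including the interdomain connecting loop) and may be edited.
clamp_name: pcna_1plq
domains:
- label: A1
  chain: A
  start: 1
  end: 117
- label: A2
  chain: A
  start: 118
  end: 258
- label: B1
  chain: B
  start: 1
  end: 117
- label: B2
  chain: B
  start: 118
  end: 258
- label: C1
  chain: C
  start: 1
  end: 117
- label: C2
  chain: C
  start: 118
  end: 258
ring_order: [A1, A2, B1, B2, C1, C2]
open_interface: [A2, B1]
torsion_quadruples:
- [B1, B2, C1, C2]
- [B2, C1, C2, A1]
- [C1, C2, A1, A2]
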