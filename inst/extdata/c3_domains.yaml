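# Complement C3 domain annotation, mature-protein numbering.
# Boundaries are RECONSTRUCTED from figure-level information and the
# crystallographic literature on C3/C3b; they are approximate and editable.
# The beta chain spans residues 1-645, the alpha chain 650-1641.
protein_id: C3
chains:
  - chain_id: beta
    first_residue: 1
    last_residue: 645
  - chain_id: alpha
    first_residue: 650
    last_residue: 1641
domains:
  - name: MG1
    segments: [[1, 104]]
  - name: MG2
    segments: [[105, 209]]
  - name: MG3
    segments: [[210, 329]]
  - name: MG4
    segments: [[330, 434]]
  - name: MG5
    segments: [[435, 534]]
  - name: MG6
    segments: [[535, 577], [746, 806]]
  - name: LNK
    segments: [[578, 645]]
  - name: ANA
    segments: [[650, 726]]
  - name: a-NT
    segments: [[727, 745]]
  - name: MG7
    segments: [[807, 911]]
  - name: CUB
    segments: [[912, 962], [1269, 1330]]
  - name: TED
    segments: [[963, 1268]]
  - name: MG8
    segments: [[1331, 1474]]
  - name: anchor
    segments: [[1475, 1495]]
  - name: C345C
    segments: [[1496, 1641]]
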