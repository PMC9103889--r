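# Alignment-atom designations and symmetry-equivalent atom mappings for the
# reference probes.  Benzamidine is aligned on all carbon atoms; catechol and
# benzene on all heavy atoms.  Each mapping is a permutation of the alignment
# atoms: the atom listed at position i may play the role of reference atom i.
benzene:
  resname: BNZ
  alignment_atoms: [C1, C2, C3, C4, C5, C6]
  # D6 automorphisms of the labeled ring: 6 rotations + 6 reflections
  symmetry_mappings:
    - [C1, C2, C3, C4, C5, C6]
    - [C2, C3, C4, C5, C6, C1]
    - [C3, C4, C5, C6, C1, C2]
    - [C4, C5, C6, C1, C2, C3]
    - [C5, C6, C1, C2, C3, C4]
    - [C6, C1, C2, C3, C4, C5]
    - [C1, C6, C5, C4, C3, C2]
    - [C2, C1, C6, C5, C4, C3]
    - [C3, C2, C1, C6, C5, C4]
    - [C4, C3, C2, C1, C6, C5]
    - [C5, C4, C3, C2, C1, C6]
    - [C6, C5, C4, C3, C2, C1]
  # idealized ring, C-C 1.39 A, in the xy plane
  coords:
    - {name: C1, element: C, xyz: [1.390, 0.000, 0.000]}
    - {name: C2, element: C, xyz: [0.695, 1.203738, 0.000]}
    - {name: C3, element: C, xyz: [-0.695, 1.203738, 0.000]}
    - {name: C4, element: C, xyz: [-1.390, 0.000, 0.000]}
    - {name: C5, element: C, xyz: [-0.695, -1.203738, 0.000]}
    - {name: C6, element: C, xyz: [0.695, -1.203738, 0.000]}
catechol:
  resname: CAT
  alignment_atoms: [C1, C2, C3, C4, C5, C6, O1, O2]
  # C2 axis through the midpoint of the C1-C2 bond swaps the two hydroxyls
  symmetry_mappings:
    - [C1, C2, C3, C4, C5, C6, O1, O2]
    - [C2, C1, C6, C5, C4, C3, O2, O1]
benzamidine:
  resname: BAM
  # aligned on all carbon atoms; C7 is the amidino carbon bonded to C1
  alignment_atoms: [C1, C2, C3, C4, C5, C6, C7]
  # mirror through the C1-C4 axis
  symmetry_mappings:
    - [C1, C2, C3, C4, C5, C6, C7]
    - [C1, C6, C5, C4, C3, C2, C7]
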