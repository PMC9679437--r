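; Curvature-model user-parameter block (published values for the 5 nm case)
user1-grps = NANO ; Index group for the atoms that are to experience the attractive potential, in our case the N-terminal nitrogen atoms of the peptides. These must be placed within the center of the box.
user2-grps = PEPTIDE ; Group containing all peptide atoms, they experience repulsive interactions.
userint1 = 1 ; on switch of the module
userint2 = 0 ; Center of nanoparticle is 0.5*BOX X - Radius,0.5*BOX Y,0.5*BOX Z.
userint3 = 0
userint4 = 0
userreal1 = 2.5 ; Radius of Nanoparticle in nm
userreal2 = 500 ; Force constant in kJ nm-2 mol-1
userreal3 = 0
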