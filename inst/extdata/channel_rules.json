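{
  "comment": "Pharmacophore typing rules for protein heavy atoms, keyed by residue and PDB atom name. Approximates AutoDock-style typing: side-chain carbons not bonded to heteroatoms are hydrophobic; ring systems aromatic; N/O/S donors and acceptors by residue chemistry; Asp/Glu carboxylates negative ionizable; Arg/Lys amines positive ionizable; metal ions metallic. The excluded-volume channel is implicit: every heavy atom carries it. Editable; pass a modified copy to assignChannels(rules=).",
  "metal_elements": ["NA", "MG", "K", "CA", "MN", "FE", "CO", "NI", "CU", "ZN"],
  "backbone": {
    "hbond_acceptor": ["O", "OXT"],
    "hbond_donor": ["N"]
  },
  "residues": {
    "ALA": { "hydrophobic": ["CB"] },
    "VAL": { "hydrophobic": ["CB", "CG1", "CG2"] },
    "LEU": { "hydrophobic": ["CB", "CG", "CD1", "CD2"] },
    "ILE": { "hydrophobic": ["CB", "CG1", "CG2", "CD1"] },
    "MET": { "hydrophobic": ["CB", "CG", "CE"], "hbond_acceptor": ["SD"] },
    "PRO": { "hydrophobic": ["CB", "CG", "CD"] },
    "GLY": { },
    "SER": { "hbond_acceptor": ["OG"], "hbond_donor": ["OG"] },
    "THR": { "hydrophobic": ["CG2"], "hbond_acceptor": ["OG1"], "hbond_donor": ["OG1"] },
    "CYS": { "hbond_donor": ["SG"] },
    "PHE": { "hydrophobic": ["CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"],
             "aromatic": ["CG", "CD1", "CD2", "CE1", "CE2", "CZ"] },
    "TYR": { "hydrophobic": ["CB", "CG", "CD1", "CD2", "CE1", "CE2"],
             "aromatic": ["CG", "CD1", "CD2", "CE1", "CE2", "CZ"],
             "hbond_acceptor": ["OH"], "hbond_donor": ["OH"] },
    "TRP": { "hydrophobic": ["CB", "CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"],
             "aromatic": ["CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"],
             "hbond_donor": ["NE1"] },
    "HIS": { "hydrophobic": ["CB"],
             "aromatic": ["CG", "ND1", "CD2", "CE1", "NE2"],
             "hbond_acceptor": ["ND1"], "hbond_donor": ["NE2"] },
    "ASP": { "hydrophobic": ["CB"],
             "hbond_acceptor": ["OD1", "OD2"],
             "negative_ionizable": ["CG", "OD1", "OD2"] },
    "GLU": { "hydrophobic": ["CB", "CG"],
             "hbond_acceptor": ["OE1", "OE2"],
             "negative_ionizable": ["CD", "OE1", "OE2"] },
    "ASN": { "hydrophobic": ["CB"], "hbond_acceptor": ["OD1"], "hbond_donor": ["ND2"] },
    "GLN": { "hydrophobic": ["CB", "CG"], "hbond_acceptor": ["OE1"], "hbond_donor": ["NE2"] },
    "LYS": { "hydrophobic": ["CB", "CG", "CD"], "hbond_donor": ["NZ"],
             "positive_ionizable": ["NZ"] },
    "ARG": { "hydrophobic": ["CB", "CG"], "hbond_donor": ["NE", "NH1", "NH2"],
             "positive_ionizable": ["CZ", "NE", "NH1", "NH2"] }
  }
}
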