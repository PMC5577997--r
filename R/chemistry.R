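# Amino-acid chemistry tables shared by the detectors: standard residues,
# charged side-chain atoms, hydrogen-bond donors/acceptors, and the
# heavy-atom covalent topology used for 1-2/1-3 exclusion.

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

ACIDIC_RESIDUES <- c("ASP", "GLU")
BASIC_RESIDUES <- c("LYS", "ARG", "HIS")

# Charged side-chain atoms per residue (carboxylate O, amino/guanidinium/
# imidazolium N). His nitrogens are conditional on the criteria flag.
CHARGED_ATOMS <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"),
  LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"),
  HIS = c("ND1", "NE2")
)

# Side-chain heavy-atom bonds per residue type; backbone bonds
# (N-CA, CA-C, C-O, C-OXT, CA-CB) are added programmatically.
SIDECHAIN_BONDS <- list(
  ALA = NULL,
  ARG = list(c("CB", "CG"), c("CG", "CD"), c("CD", "NE"), c("NE", "CZ"),
             c("CZ", "NH1"), c("CZ", "NH2")),
  ASN = list(c("CB", "CG"), c("CG", "OD1"), c("CG", "ND2")),
  ASP = list(c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2")),
  CYS = list(c("CB", "SG")),
  GLN = list(c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"), c("CD", "NE2")),
  GLU = list(c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"), c("CD", "OE2")),
  GLY = NULL,
  HIS = list(c("CB", "CG"), c("CG", "ND1"), c("CG", "CD2"), c("ND1", "CE1"),
             c("CD2", "NE2"), c("CE1", "NE2")),
  ILE = list(c("CB", "CG1"), c("CB", "CG2"), c("CG1", "CD1")),
  LEU = list(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2")),
  LYS = list(c("CB", "CG"), c("CG", "CD"), c("CD", "CE"), c("CE", "NZ")),
  MET = list(c("CB", "CG"), c("CG", "SD"), c("SD", "CE")),
  PHE = list(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"), c("CD1", "CE1"),
             c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ")),
  PRO = list(c("CB", "CG"), c("CG", "CD"), c("CD", "N")),
  SER = list(c("CB", "OG")),
  THR = list(c("CB", "OG1"), c("CB", "CG2")),
  TRP = list(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"), c("CD1", "NE1"),
             c("NE1", "CE2"), c("CD2", "CE2"), c("CD2", "CE3"),
             c("CE2", "CZ2"), c("CE3", "CZ3"), c("CZ2", "CH2"),
             c("CZ3", "CH2")),
  TYR = list(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"), c("CD1", "CE1"),
             c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ"), c("CZ", "OH")),
  VAL = list(c("CB", "CG1"), c("CB", "CG2"))
)

# Hydrogen-bond donor heavy atoms. "placed" donors have unambiguous sp2
# geometry so an explicit hydrogen can be constructed from the antecedent
# atoms; "rotatable" donors (hydroxyls, lysine ammonium) cannot and fall
# back to heavy-atom-only criteria. The backbone amide N is handled
# separately (it needs the preceding residue's carbonyl C).
DONOR_ATOMS <- list(
  ARG = list(
    NE  = list(kind = "placed", antecedents = c("CD", "CZ")),
    NH1 = list(kind = "placed_sp2pair", stem = "CZ", plane = "NE"),
    NH2 = list(kind = "placed_sp2pair", stem = "CZ", plane = "NE")
  ),
  ASN = list(ND2 = list(kind = "placed_sp2pair", stem = "CG", plane = "OD1")),
  GLN = list(NE2 = list(kind = "placed_sp2pair", stem = "CD", plane = "OE1")),
  TRP = list(NE1 = list(kind = "placed", antecedents = c("CD1", "CE2"))),
  HIS = list(
    ND1 = list(kind = "placed", antecedents = c("CG", "CE1")),
    NE2 = list(kind = "placed", antecedents = c("CD2", "CE1"))
  ),
  SER = list(OG  = list(kind = "rotatable")),
  THR = list(OG1 = list(kind = "rotatable")),
  TYR = list(OH  = list(kind = "rotatable")),
  LYS = list(NZ  = list(kind = "rotatable")),
  CYS = list(SG  = list(kind = "rotatable"))
)

# Hydrogen-bond acceptor heavy atoms with the covalent antecedent used for
# the donor-acceptor-antecedent angle. Backbone carbonyl O and terminal OXT
# are added programmatically. His ring nitrogens are treated as protonated
# (donors), matching their classification as basic in salt-bridge chemistry,
# and are therefore not acceptors by default.
ACCEPTOR_ATOMS <- list(
  ASP = list(OD1 = "CG", OD2 = "CG"),
  GLU = list(OE1 = "CD", OE2 = "CD"),
  ASN = list(OD1 = "CG"),
  GLN = list(OE1 = "CD"),
  SER = list(OG = "CB"),
  THR = list(OG1 = "CB"),
  TYR = list(OH = "CZ"),
  MET = list()
)

is_standard_aa <- function(resid) resid %in% STANDARD_AA
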