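# Frozen per-atom oracle attributes (symbol, heavy-atom degree, total
# hydrogens, implicit valence, aromatic flag) and bond counts for the
# fixture panel, computed once with an independent cheminformatics
# toolkit and frozen here. Atom order follows the SMILES atom order.
# bracket_h marks atoms whose hydrogens are written explicitly in the
# SMILES brackets; for those the reference toolkit reports implicit
# valence 0 while this package's valence-model convention counts the
# hydrogen (the total hydrogen count agrees either way).
rdkit_oracle <- list(
  ethane = list(smiles = "CC",
    symbol = c("C","C"),
    degree = c(1,1),
    num_hs = c(3,3),
    implicit_valence = c(3,3),
    aromatic = c(FALSE,FALSE),
    bracket_h = c(FALSE,FALSE),
    n_bonds = 1L),
  benzene = list(smiles = "c1ccccc1",
    symbol = c("C","C","C","C","C","C"),
    degree = c(2,2,2,2,2,2),
    num_hs = c(1,1,1,1,1,1),
    implicit_valence = c(1,1,1,1,1,1),
    aromatic = c(TRUE,TRUE,TRUE,TRUE,TRUE,TRUE),
    bracket_h = c(FALSE,FALSE,FALSE,FALSE,FALSE,FALSE),
    n_bonds = 6L),
  phenol = list(smiles = "c1ccccc1O",
    symbol = c("C","C","C","C","C","C","O"),
    degree = c(2,2,2,2,2,3,1),
    num_hs = c(1,1,1,1,1,0,1),
    implicit_valence = c(1,1,1,1,1,0,1),
    aromatic = c(TRUE,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE),
    bracket_h = c(FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE),
    n_bonds = 7L),
  pyridine = list(smiles = "c1ccncc1",
    symbol = c("C","C","C","N","C","C"),
    degree = c(2,2,2,2,2,2),
    num_hs = c(1,1,1,0,1,1),
    implicit_valence = c(1,1,1,0,1,1),
    aromatic = c(TRUE,TRUE,TRUE,TRUE,TRUE,TRUE),
    bracket_h = c(FALSE,FALSE,FALSE,FALSE,FALSE,FALSE),
    n_bonds = 6L),
  pyrrole = list(smiles = "c1cc[nH]c1",
    symbol = c("C","C","C","N","C"),
    degree = c(2,2,2,2,2),
    num_hs = c(1,1,1,1,1),
    implicit_valence = c(1,1,1,0,1),
    aromatic = c(TRUE,TRUE,TRUE,TRUE,TRUE),
    bracket_h = c(FALSE,FALSE,FALSE,TRUE,FALSE),
    n_bonds = 5L),
  isopropanol = list(smiles = "CC(C)O",
    symbol = c("C","C","C","O"),
    degree = c(1,3,1,1),
    num_hs = c(3,1,3,1),
    implicit_valence = c(3,1,3,1),
    aromatic = c(FALSE,FALSE,FALSE,FALSE),
    bracket_h = c(FALSE,FALSE,FALSE,FALSE),
    n_bonds = 3L),
  acetanilide = list(smiles = "CC(=O)Nc1ccccc1",
    symbol = c("C","C","O","N","C","C","C","C","C","C"),
    degree = c(1,3,1,2,3,2,2,2,2,2),
    num_hs = c(3,0,0,1,0,1,1,1,1,1),
    implicit_valence = c(3,0,0,1,0,1,1,1,1,1),
    aromatic = c(FALSE,FALSE,FALSE,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE),
    bracket_h = c(FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE),
    n_bonds = 10L),
  aspirin = list(smiles = "CC(=O)Oc1ccccc1C(=O)O",
    symbol = c("C","C","O","O","C","C","C","C","C","C","C","O","O"),
    degree = c(1,3,1,2,3,2,2,2,2,3,3,1,1),
    num_hs = c(3,0,0,0,0,1,1,1,1,0,0,0,1),
    implicit_valence = c(3,0,0,0,0,1,1,1,1,0,0,0,1),
    aromatic = c(FALSE,FALSE,FALSE,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE),
    bracket_h = c(FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE),
    n_bonds = 13L),
  caffeine = list(smiles = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    symbol = c("C","N","C","N","C","C","C","O","N","C","C","O","N","C"),
    degree = c(1,3,2,2,3,3,3,1,3,1,3,1,3,1),
    num_hs = c(3,0,1,0,0,0,0,0,0,3,0,0,0,3),
    implicit_valence = c(3,0,1,0,0,0,0,0,0,3,0,0,0,3),
    aromatic = c(FALSE,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE,TRUE,FALSE,TRUE,FALSE,TRUE,FALSE),
    bracket_h = c(FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE),
    n_bonds = 15L),
  nitromethane = list(smiles = "C[N+](=O)[O-]",
    symbol = c("C","N","O","O"),
    degree = c(1,3,1,1),
    num_hs = c(3,0,0,0),
    implicit_valence = c(3,0,0,0),
    aromatic = c(FALSE,FALSE,FALSE,FALSE),
    bracket_h = c(FALSE,FALSE,FALSE,FALSE),
    n_bonds = 3L)
)
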