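## Shared fixtures built in code.

extfile <- function(name) system.file("extdata", name, package = "HSAbind")

## Reference logP values for the packaged SDF panel, computed once with an
## independent implementation of the same published atomic-contribution
## scheme (RDKit Chem.Crippen.MolLogP, rdkit 2024.09.2) and frozen.
RDKIT_LOGP_SDF <- c(
  benzene = 1.6866, pentane = 2.1965, decane = 4.147, aspirin = 1.3101,
  ibuprofen = 3.0732, ethanol = -0.0014, pyridine = 1.0816,
  naphthalene = 2.8398, acetaminophen = 1.3506, salicylic_acid = 1.0904,
  chlorobenzene = 2.34, nicotine = 1.8483, acetone = 0.5953,
  ethanolamine = -1.0626, methanesulfonamide = -1.0953, thiophene = 1.7481,
  pyrrole = 1.0147, furan = 1.2796, `acetamide-n-methyl` = -0.2477,
  urea = -0.9762)

## Same oracle, harder chemistry (fused heteroaromatics, charge-separated
## groups, halogen-rich rings), keyed by SMILES.
RDKIT_LOGP_SMILES <- c(
  "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O" = 3.6096,   # warfarin
  "CC(C)NCC(O)c1ccc(NS(C)(=O)=O)cc1" = 1.0895,        # sotalol
  "CC1(C)SC2C(NC(=O)COc3ccccc3)C(=O)N2C1C(=O)O" = 0.6971, # penicillin V
  "CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc21" = 3.1538,     # diazepam
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C" = -1.0293,             # caffeine
  "OC(=O)Cc1c[nH]c2ccccc12" = 1.795,                  # indole-3-acetic acid
  "CCCCCCCCCCCCCC(=O)O" = 4.7721,                     # myristic acid
  "OC(=O)c1cc(I)c(O)c(I)c1I" = 2.9042,                # triiodophenol acid
  "[O-][N+](=O)c1ccccc1" = 1.5948,                    # nitrobenzene
  "[O-]C(=O)c1ccccc1" = 0.0501,                       # benzoate
  "O=c1cccc[nH]1" = 0.3749,                           # 2-pyridone
  "OCC(O)CO" = -1.6681)                               # glycerol

## A long-format docking result table for aggregation tests: one ligand,
## ten structures x two sites.
fullGridResults <- function(ligand = "L1", score = -8) {
  ens <- as.data.frame(ensembleEntries(buildEnsemble()))
  grid <- expand.grid(pdb_id = ens$pdb_id, site = c("site_I", "site_II"),
                      stringsAsFactors = FALSE)
  data.frame(ligand_id = ligand, pdb_id = grid$pdb_id, site = grid$site,
             score = score, stringsAsFactors = FALSE)
}

## Write a tiny SMILES file, optionally with an unparsable line.
writeSmilesFixture <- function(path, withBad = FALSE) {
  lines <- c("c1ccccc1\tbenzene", "CCO\tethanol", "CCCCC\tpentane",
             "CC(=O)O\tacetic", "c1ccncc1\tpyridine")
  if (withBad) lines <- append(lines, "notasmiles(((\tbroken", after = 2)
  writeLines(lines, path)
  path
}
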