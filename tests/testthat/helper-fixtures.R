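# Small fixture builders shared across the test files. Everything is
# generated in code; no binary data.

toy_peaks <- function(resnum = 1:5, height = 100, chain = ".",
                      shift_H = 8.2, shift_N = 118, shift_C = NA,
                      label = "toy") {
  peak_table(data.frame(chain = chain, resnum = resnum, resname = "ALA",
                        shift_H = shift_H, shift_N = shift_N,
                        shift_C = shift_C, height = height),
             label = label)
}

# minimal single-residue-per-atom model builder
toy_model <- function(chain, resnum, atom, x, y, z, resname = "ALA") {
  data.frame(chain = chain, resnum = resnum, resname = resname,
             atom = atom, x = x, y = y, z = z, stringsAsFactors = FALSE)
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_r <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_r)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# hand-written NMR-STAR fragment with an assigned chemical shift loop
star_fixture <- function(path) {
  writeLines(c(
    "data_toy_shifts",
    "save_assigned_chemical_shifts",
    "   _Assigned_chem_shift_list.Sf_category assigned_chemical_shifts",
    "   loop_",
    "      _Atom_chem_shift.ID",
    "      _Atom_chem_shift.Comp_index_ID",
    "      _Atom_chem_shift.Comp_ID",
    "      _Atom_chem_shift.Atom_ID",
    "      _Atom_chem_shift.Val",
    "      _Atom_chem_shift.Auth_seq_ID",
    "      1 5 GLY H 8.21 5",
    "      2 5 GLY N 109.8 5",
    "      3 5 GLY C 174.1 5",
    "      4 6 ALA H 8.05 6",
    "      5 6 ALA N 122.4 6",
    "   stop_",
    "save_"), path)
  path
}

cif_fixture <- function(path) {
  writeLines(c(
    "data_toy",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 0.00 ? 7 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.000 2.500 3.200 1.00 0.00 ? 7 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 3.000 2.100 3.100 1.00 0.00 ? 7 ALA A C 1",
    "#"), path)
  path
}
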