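# Shared fixtures built in code.

small_bundle <- function(seed = 1, n_helices = 2, residues_per_helix = 12) {
  generate_helix_bundle(bundle_spec(n_helices = n_helices,
                                    residues_per_helix = residues_per_helix,
                                    loop_length = 3, seed = seed))
}

# a minimal hand-written PDB with two residues (GLY, ALA)
minimal_pdb_lines <- c(
  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      4  O   GLY A   1       1.251   2.390   0.000  1.00  0.00           O",
  "ATOM      5  N   ALA A   2       3.332   1.536   0.000  1.00  0.00           N",
  "ATOM      6  CA  ALA A   2       4.023   2.813   0.000  1.00  0.00           C",
  "ATOM      7  C   ALA A   2       5.531   2.613   0.000  1.00  0.00           C",
  "ATOM      8  O   ALA A   2       6.021   1.480   0.000  1.00  0.00           O",
  "END")

write_minimal_pdb <- function(path, lines = minimal_pdb_lines) {
  writeLines(lines, path)
  path
}

# two full-backbone residues with CA atoms ca_sep apart on x
two_residue_model <- function(ca_sep) {
  res <- function(i, x0) data.frame(
    serial = 4 * (i - 1) + 1:4,
    atom_name = c("N", "CA", "C", "O"),
    residue_name = "ALA", chain_id = "A",
    residue_index = i, orig_residue_index = i,
    x = c(x0 - 1.3, x0, x0 + 1.4, x0 + 1.4),
    y = c(0.4, 0, 0.5, 1.73), z = 0,
    element = c("N", "C", "C", "O"))
  structure_model("pair", rbind(res(1, 0), res(2, ca_sep)))
}
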