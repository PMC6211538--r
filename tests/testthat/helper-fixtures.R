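# Shared fixtures, built once per test run and memoized.

.fx <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

# extended q grid for form-factor tables (covers smearing margins)
q_table_grid <- function() c(0, exp(seq(log(1e-4), log(0.35), length.out = 160)))

# data-like q grid (instrument range)
q_data_grid <- function(n = 120) exp(seq(log(0.006), log(0.2), length.out = n))

mock_build <- function(n_res, seed, open_state = FALSE, hydrate = TRUE) {
  pdb <- make_mock_structure(n_res, seed = seed, open_state = open_state)
  atoms <- load_structure(paste(pdb, collapse = "\n"))
  ps <- assign_scattering(atoms)
  pts <- if (hydrate)
    add_hydration_shell(ps, atoms, slab = membrane_slab(-40, 0)) else ps
  list(pdb = pdb, atoms = atoms, points = pts,
       ff = form_factor(pts, q_table_grid()),
       r_sub = subunit_radius_from_volume(atoms))
}

mock_closed <- function() memo("mock_closed", function() mock_build(220, 3))
mock_open <- function() memo("mock_open", function()
  mock_build(220, 4, open_state = TRUE))
# smaller, bare (no shell) pair for the many-replicate studies
mock_small_closed <- function() memo("mock_small_closed", function()
  mock_build(120, 3, hydrate = FALSE))
mock_small_open <- function() memo("mock_small_open", function()
  mock_build(120, 4, open_state = TRUE, hydrate = FALSE))

# a formfactor_table for a pre-mixed 50:50 composite of two states (model-1
# carrier of the F-test null truth)
composite_ff <- function(ffa, ffb, frac = 0.5) {
  structure(data.frame(q = ffa$q, P = (1 - frac) * ffa$P + frac * ffb$P,
                       A00 = (1 - frac) * ffa$A00 + frac * ffb$A00,
                       beta = 1),
            total_b = attr(ffa, "total_b"), rg = attr(ffa, "rg"),
            class = c("formfactor_table", "data.frame"))
}

# minimal hand-written PDB fixtures
pdb_single_ala_ca <- function() {
  c("ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END")
}

# 10 atoms: 8 plain + one atom in two altlocs (A occ 0.6, B occ 0.4)
pdb_altloc <- function(occ_a = 0.6, occ_b = 0.4) {
  plain <- vapply(1:8, function(i) sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    i, i, i * 3.8, 0, 0, 1.0, 0.0), "")
  alt <- c(sprintf(
    "ATOM      9  CB AALA A   9      10.000   1.000   0.000%6.2f  0.00           C",
    occ_a), sprintf(
    "ATOM     10  CB BALA A   9      10.000   1.500   0.000%6.2f  0.00           C",
    occ_b))
  c(plain, alt, "END")
}

pdb_waters_only <- function() {
  c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    2  O   HOH A   2       3.000   0.000   0.000  1.00  0.00           O",
    "END")
}

# bare atoms data.frame for direct assign_scattering tests
bare_atoms <- function(elements, x = seq_along(elements), resname = "UNK",
                       atomname = paste0(elements, seq_along(elements))) {
  data.frame(element = elements, x = x, y = 0, z = 0,
             residue_name = resname, atom_name = atomname,
             chain_id = "A", residue_number = seq_along(elements),
             is_hetero = FALSE, occupancy = 1)
}

fm <- function(x) x * 1e-13  # fm -> cm
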