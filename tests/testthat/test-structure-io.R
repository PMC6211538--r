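# PDB parsing dialect, scattering-length assignment and hydration shell.

test_that("single-record parse yields one carbon at the stated position", {
  atoms <- load_structure(paste(pdb_single_ala_ca(), collapse = "\n"))
  expect_equal(nrow(atoms), 1)
  expect_equal(atoms$element, "C")
  expect_equal(unlist(atoms[1, c("x", "y", "z")], use.names = FALSE),
               c(1, 2, 3))
  expect_equal(atoms$residue_name, "ALA")
  expect_false(atoms$is_hetero)
})

test_that("altloc rule keeps the highest occupancy, ties prefer A", {
  atoms <- load_structure(paste(pdb_altloc(0.6, 0.4), collapse = "\n"))
  expect_equal(nrow(atoms), 9)          # 8 plain + one of the two altlocs
  expect_equal(atoms$y[9], 1.0)         # altloc A position
  # higher occupancy on B wins
  atoms_b <- load_structure(paste(pdb_altloc(0.4, 0.6), collapse = "\n"))
  expect_equal(atoms_b$y[9], 1.5)
  # exact tie falls back to altloc A
  atoms_t <- load_structure(paste(pdb_altloc(0.5, 0.5), collapse = "\n"))
  expect_equal(atoms_t$y[9], 1.0)
})

test_that("water-only and malformed input raise informative errors", {
  expect_error(load_structure(paste(pdb_waters_only(), collapse = "\n")),
               "empty")
  bad <- pdb_single_ala_ca()
  substr(bad[1], 33, 38) <- "xx.yyy"
  expect_error(load_structure(paste(bad, collapse = "\n")), "line 1")
  expect_error(load_structure("REMARK nothing here\nEND"), "no ATOM")
})

test_that("excess scattering lengths obey the exchange limits", {
  b <- neutron_b_table()
  # single carbon, pure D2O, zero excluded volume -> bare coherent b of C
  vol0 <- vdw_volume_table(); vol0[] <- 0
  ps <- assign_scattering(bare_atoms("C"), solvent_spec(d2o_fraction = 1),
                          volume_table = vol0, on_unknown = "bare")
  expect_equal(ps$b, fm(b[["C"]]), tolerance = 1e-12)

  # a serine hydroxyl carries one labile H: full exchange turns it into D
  ser <- data.frame(element = "O", x = 0, y = 0, z = 0,
                    residue_name = "SER", atom_name = "OG", chain_id = "A",
                    residue_number = 1, is_hetero = FALSE, occupancy = 1)
  no_ex <- assign_scattering(ser, solvent_spec(d2o_fraction = 0,
                                               exchange_fraction = 1,
                                               solvent_sld = 0))
  full_ex <- assign_scattering(ser, solvent_spec(d2o_fraction = 1,
                                                 exchange_fraction = 1,
                                                 solvent_sld = 0))
  expect_equal(no_ex$b, fm(b[["O"]] + b[["H"]]), tolerance = 1e-12)
  expect_equal(full_ex$b, fm(b[["O"]] + b[["D"]]), tolerance = 1e-12)
})

test_that("unknown elements and residues are reported by name", {
  bad <- bare_atoms("XX")
  expect_error(assign_scattering(bad, on_unknown = "bare"), "XX")
  unk <- bare_atoms("C", resname = "XYZ", atomname = "C9")
  expect_error(assign_scattering(unk), "XYZ")
})

test_that("total_b is affine in the D2O fraction", {
  atoms <- mock_small_closed()$atoms[1:50, ]
  tb <- vapply(c(0, 0.5, 1), function(f)
    attr(assign_scattering(atoms, solvent_spec(d2o_fraction = f)), "total_b"),
    0)
  expect_equal(tb[2], (tb[1] + tb[3]) / 2, tolerance = 1e-10)
})

test_that("hydration beads follow the closed-form single-atom count", {
  atoms <- bare_atoms("C")
  solv <- solvent_spec()
  ps <- assign_scattering(atoms, solv, on_unknown = "bare")
  hyd <- add_hydration_shell(ps, atoms, solv)
  r_c <- (3 * vdw_volume_table()[["C"]] / (4 * pi))^(1 / 3) + 1.4
  n_expect <- max(1, round(4 * pi * r_c^2 / (4.13 * 30 / 3)))
  expect_equal(attr(hyd, "n_beads"), n_expect)
  added <- attr(hyd, "total_b") - attr(ps, "total_b")
  expect_equal(added, n_expect * 0.10 * 4.13 * b_water(1), tolerance = 1e-12)
})

test_that("per-bead excess scales as the solvent water scattering length", {
  atoms <- bare_atoms("C")
  ps <- assign_scattering(atoms, solvent_spec(), on_unknown = "bare")
  bead_b <- function(f) {
    solv <- solvent_spec(d2o_fraction = f)
    h <- add_hydration_shell(ps, atoms, solv)
    (attr(h, "total_b") - attr(ps, "total_b")) / attr(h, "n_beads")
  }
  expect_equal(bead_b(1) / bead_b(0), b_water(1) / b_water(0),
               tolerance = 1e-12)
})

test_that("a slab covering the whole structure leaves the shell empty", {
  atoms <- bare_atoms("C")
  ps <- assign_scattering(atoms, on_unknown = "bare")
  expect_warning(
    hyd <- add_hydration_shell(ps, atoms, slab = membrane_slab(-100, 100)),
    "empty")
  expect_equal(attr(hyd, "n_beads"), 0L)
  expect_equal(nrow(hyd), nrow(ps))
})

test_that("the shell only appends points and placement is deterministic", {
  mc <- mock_small_closed()
  atoms <- mc$atoms[1:60, ]
  ps <- assign_scattering(atoms)
  h1 <- add_hydration_shell(ps, atoms, slab = membrane_slab(-40, 0))
  h2 <- add_hydration_shell(ps, atoms, slab = membrane_slab(-40, 0))
  expect_identical(as.data.frame(h1), as.data.frame(h2))
  expect_gt(nrow(h1), nrow(ps))
  expect_equal(h1$b[seq_len(nrow(ps))], ps$b)
  expect_equal(h1$x[seq_len(nrow(ps))], ps$x)
  # membrane exclusion: no bead center inside the slab
  beads_z <- h1$z[-seq_len(nrow(ps))]
  expect_true(all(beads_z < -40 | beads_z > 0))
})

test_that("point sets export and read back through the text format", {
  ps <- make_assembly(synthetic_spec("two_points", distance = 50))
  f <- withr::local_tempfile(fileext = ".txt")
  write_point_set(ps, f)
  m <- read.table(f)
  expect_equal(nrow(m), 2)
  expect_equal(m$V4, ps$b)
})
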