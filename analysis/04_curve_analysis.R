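#!/usr/bin/env Rscript
# Model-free curve analyses of the simulated samples: Guinier, indirect
# Fourier transform p(r), Kratky table, Porod background, scattering
# invariant and the three molecular-weight estimators; plus the low-q
# truncation treatment of the aggregated sample.

library(sansmix)

seed <- 1
sim_dir <- "results/sim"
out <- "results/curves"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
if (!file.exists(file.path(sim_dir, "manifest.json"))) corpus(seed, sim_dir)
man <- jsonlite::read_json(file.path(sim_dir, "manifest.json"),
                           simplifyVector = TRUE)

# Composition of the mock, for context. Note the mock is a *sparse* point
# assembly: its van der Waals volume is far below the envelope its points
# span, so volume-based MW estimators report the scattering (correlation)
# volume of the envelope, not the composition mass. Their absolute accuracy
# is established on homogeneous analytic spheres in the test suite and the
# acceptance script; here they serve to compare samples against each other.
atoms <- load_structure(file.path(sim_dir, "mock_receptor_closed.pdb"))
cat(sprintf("mock composition: %d atoms, %.0f A^3 van der Waals volume\n\n",
            nrow(atoms), protein_volume(atoms)))

rows <- list()
for (nm in c("model1_single.dat", "model2_oligomer.dat",
             "noguinier_aggregated.dat")) {
  cur <- read_sans(file.path(sim_dir, nm))
  g <- guinier(cur)
  used <- cur
  n_cut <- 0
  if (!g$valid) {
    # aggregation tail: truncate low q until a valid Guinier region appears
    while (!g$valid && n_cut < 30) {
      n_cut <- n_cut + 4
      used <- truncate_low_q(cur, n_cut)
      g <- guinier(used)
    }
    cat(sprintf("%s: no valid Guinier region; truncated %d points (qmin %.4f)\n",
                nm, n_cut, min(used$q)))
  }
  pr <- ift_pr(used)
  write_pr(pr, file.path(out, paste0(sub(".dat", "", nm, fixed = TRUE),
                                     "_pr.txt")))
  kt <- kratky(used)
  write.csv(kt, file.path(out, paste0(sub(".dat", "", nm, fixed = TRUE),
                                      "_kratky.csv")), row.names = FALSE)
  B <- porod_background(used)
  Q <- invariant_q(used, background = as.numeric(B), extrapolation = pr,
                   high_q_tail = "porod")
  i0 <- attr(pr, "i0")
  mwf <- mw_fischer(used, i0 = i0, background = as.numeric(B),
                    rg = attr(pr, "rg"), qmax = 0.2)
  mwp <- mw_porod_petoukhov(used, i0 = i0, background = as.numeric(B),
                            rg = attr(pr, "rg"))
  rows[[nm]] <- data.frame(
    curve = nm, n_truncated = n_cut, guinier_rg = g$rg, guinier_i0 = g$i0,
    guinier_valid = g$valid, pr_rg = attr(pr, "rg"),
    pr_dmax = attr(pr, "dmax"), pr_i0 = i0,
    background = as.numeric(B), invariant = as.numeric(Q),
    mw_truncated_invariant_kda = as.numeric(mwf),
    mw_porod_kda = as.numeric(mwp))
  cat(sprintf(
    "%-26s Rg(Guinier) %5.1f | Rg(pr) %5.1f | Dmax %5.1f | MW %5.1f kDa\n",
    nm, g$rg, attr(pr, "rg"), attr(pr, "dmax"), as.numeric(mwf)))
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out, "curve_analysis.csv"), row.names = FALSE)
jsonlite::write_json(tab, file.path(out, "curve_analysis.json"),
                     auto_unbox = TRUE, digits = NA, dataframe = "rows")

cat("\nGuinier and p(r) radii agree for the clean single-state sample.\n")
cat("The oligomer-bearing samples show\n")
cat("how sensitive the model-free sizes are to even percent-level\n")
cat("aggregation: the mock subunit is small, so the same oligomer fraction\n")
cat("and size carry a larger intensity share than for a full-size receptor\n")
cat("and the apparent Rg/Dmax stay inflated even after low-q truncation.\n")
cat("Recovering single-particle information there is the job of the\n")
cat("model-based fractal filtering in analysis/03_fit_models.R.\n")
cat("Tables written under", out, "\n")
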