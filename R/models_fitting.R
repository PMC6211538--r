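# Mixture models 1-4 for detergent-solubilized receptor SANS data,
# resolution smearing, weighted least-squares fitting and F-test model
# comparison.
#
# Model 1: I = C P(q) + B                      (single state)
# Model 2: I = C [(1-g) P + g P S'(q)] + B     (state + fractal oligomers)
# Model 3: I = C [(1-a) P_atm + a P_alt] + B   (two-state mixture)
# Model 4: models 2 and 3 combined, oligomers formed from both states.
# C = K * n, with the squared excess scattering length absorbed in the
# unnormalized P(q) (cm^2), n a number density (cm^-3), so I is in cm^-1.
# Oligomers mix on a per-tetramer basis: gamma is the number fraction of
# protein in oligomeric form and S'(q) the per-subunit effective structure
# factor, so gamma -> 0 and S' -> 1 both collapse to the single-state model.

MODEL_PARAM_NAMES <- list(`1` = c("K", "B"),
                          `2` = c("K", "B", "rg_olig", "gamma"),
                          `3` = c("K", "B", "alpha"),
                          `4` = c("K", "B", "rg_olig", "gamma", "alpha"))

#' Convert a molar concentration to a number density
#' @param molar concentration in mol/L.
#' @return particles per cm^3.
#' @export
molar_to_numdens <- function(molar) molar * AVOGADRO / 1000

#' Specify a mixture model
#'
#' @param model_id 1, 2, 3 or 4.
#' @param components named list of one or two `formfactor_table` objects
#'   (from [form_factor()]); the first is the primary atomic state, the
#'   second the alternate (open/EM-class) state required by models 3 and 4.
#'   Tables must cover the q range to be fitted, including the smearing
#'   margin.
#' @param subunit_r mean fractal subunit distance, A (see
#'   [subunit_radius_from_volume()]); required by models 2 and 4.
#' @param D,k fractal dimension and structural coefficient. Both are fixed
#'   (D = 2, k = 1) in the intended use: the data rarely constrain them.
#' @param conc_n particle number density, cm^-3 ([molar_to_numdens()]).
#' @param label free text.
#' @return Object of class `sans_model_spec`.
#' @export
model_spec <- function(model_id, components, subunit_r = NULL, D = 2, k = 1,
                       conc_n, label = "") {
  model_id <- as.integer(model_id)
  stopifnot(model_id %in% 1:4, is.list(components), length(components) >= 1,
            conc_n > 0)
  if (model_id %in% c(3, 4) && length(components) < 2)
    stop("models 3 and 4 need two components (atomic + alternate state)")
  if (model_id %in% c(2, 4)) {
    if (is.null(subunit_r) || subunit_r <= 0)
      stop("models 2 and 4 need a positive subunit_r")
    .check_fractal_dim(D)
  }
  comp <- lapply(components, function(ff) {
    stopifnot(inherits(ff, "formfactor_table"))
    list(q_range = range(ff$q),
         P = stats::splinefun(ff$q, ff$P, method = "natural"),
         A00 = stats::splinefun(ff$q, ff$A00, method = "natural"),
         rg = attr(ff, "rg"), total_b = attr(ff, "total_b"))
  })
  structure(list(model_id = model_id, components = comp,
                 subunit_r = subunit_r, D = D, k = k, conc_n = conc_n,
                 label = label),
            class = "sans_model_spec")
}

.check_q_range <- function(spec, q) {
  for (nm in names(spec$components)) {
    rng <- spec$components[[nm]]$q_range
    if (min(q) < rng[1] - 1e-12 || max(q) > rng[2] + 1e-12)
      stop(sprintf("q outside tabulated range [%.4g, %.4g] of component '%s'",
                   rng[1], rng[2], nm))
  }
}

# per-component oligomer intensity P(q) * S'(q)
.olig_intensity <- function(comp, spec, params, q) {
  xi <- xi_from_rg(params[["rg_olig"]], spec$D)
  S <- teixeira_sq(q, spec$D, spec$subunit_r, xi)
  P <- comp$P(q)
  Sp <- effective_sq(P, comp$A00(q), S)
  P * Sp
}

#' Evaluate a mixture model intensity (unsmeared)
#'
#' @param spec a [model_spec()].
#' @param params named list/vector with the parameters the model uses:
#'   `K` (concentration correction), `B` (background, cm^-1), `rg_olig`
#'   (oligomer radius of gyration, A; models 2, 4), `gamma` (oligomeric
#'   number fraction; models 2, 4), `alpha` (alternate-state intensity
#'   fraction; models 3, 4).
#' @param q q grid, A^-1, inside the tabulated component range.
#' @return Intensities, cm^-1.
#' @export
model_intensity <- function(spec, params, q) {
  stopifnot(inherits(spec, "sans_model_spec"))
  params <- as.list(params)
  need <- MODEL_PARAM_NAMES[[as.character(spec$model_id)]]
  miss <- setdiff(need, names(params))
  if (length(miss) > 0)
    stop("missing parameter(s) for model ", spec$model_id, ": ",
         paste(miss, collapse = ", "))
  .check_q_range(spec, q)
  ca <- spec$components[[1]]
  mono <- switch(as.character(spec$model_id),
    `1` = ca$P(q),
    `2` = ca$P(q),
    `3` = ,
    `4` = {
      a <- params[["alpha"]]
      (1 - a) * ca$P(q) + a * spec$components[[2]]$P(q)
    })
  I <- switch(as.character(spec$model_id),
    `1` = mono,
    `2` = {
      g <- params[["gamma"]]
      (1 - g) * mono + g * .olig_intensity(ca, spec, params, q)
    },
    `3` = mono,
    `4` = {
      g <- params[["gamma"]]
      a <- params[["alpha"]]
      olig <- (1 - a) * .olig_intensity(ca, spec, params, q) +
        a * .olig_intensity(spec$components[[2]], spec, params, q)
      (1 - g) * mono + g * olig
    })
  params[["K"]] * spec$conc_n * I + params[["B"]]
}

# Gauss-Legendre nodes/weights for Gaussian smearing over +-width sigma;
# weights are GL weight * normal density, normalized to sum 1
.smear_nodes <- function(n_nodes = 21, width = 3) {
  gl <- pracma::gaussLegendre(n_nodes, -width, width)
  w <- gl$w * stats::dnorm(gl$x)
  list(x = gl$x, w = w / sum(w))
}

#' Apply Gaussian q-resolution smearing to tabulated intensities
#'
#' Convolves I(q) with a Gaussian of width `sigma_q(q)` per point, using a
#' fixed Gauss-Legendre quadrature over +-3 sigma. Off-grid nodes are linearly
#' interpolated; outside the grid the curve is extended flat, which preserves
#' constants exactly. Points with `sigma_q = 0` are returned unchanged.
#'
#' @param values intensities on `q`.
#' @param q q grid, A^-1.
#' @param sigma_q Gaussian resolution widths, A^-1 (same length).
#' @param n_nodes,width quadrature size and half-width in sigma units.
#' @return Smeared intensities.
#' @export
smear <- function(values, q, sigma_q, n_nodes = 21, width = 3) {
  stopifnot(length(values) == length(q), length(sigma_q) == length(q),
            all(sigma_q >= 0))
  nd <- .smear_nodes(n_nodes, width)
  qn <- outer(q, rep(1, n_nodes)) + outer(sigma_q, nd$x)
  In <- matrix(stats::approx(q, values, xout = abs(as.vector(qn)),
                             rule = 2)$y, nrow = length(q))
  out <- as.vector(In %*% nd$w)
  ifelse(sigma_q == 0, values, out)
}

# smeared model evaluation by direct model calls at the quadrature nodes
# (no interpolation error; used by the fitter)
.smeared_model <- function(spec, params, q, sigma_q, nodes) {
  if (is.null(sigma_q) || all(sigma_q == 0))
    return(model_intensity(spec, params, q))
  qn <- abs(outer(q, rep(1, length(nodes$x))) + outer(sigma_q, nodes$x))
  qv <- as.vector(qn)
  Iv <- model_intensity(spec, params, qv)
  as.vector(matrix(Iv, nrow = length(q)) %*% nodes$w)
}

# shape basis of a model: the intensity with K = 1 and B = 0 (everything the
# linear prefactor multiplies, conc_n included), smeared
.smeared_basis <- function(spec, nl_params, q, sigma_q, nodes) {
  p <- c(as.list(nl_params), list(K = 1, B = 0))
  .smeared_model(spec, p, q, sigma_q, nodes)
}

# weighted box-constrained solve of I ~ K * m + B: unconstrained normal
# equations first, then the edge candidates when a bound is hit (exact for
# a 2-parameter box)
.solve_linear <- function(m, y, w, loK, upK, loB, upB) {
  wm <- w * m; wy <- w * y
  a11 <- sum(wm^2); a12 <- sum(wm * w); a22 <- sum(w^2)
  b1 <- sum(wm * wy); b2 <- sum(w * wy)
  det <- a11 * a22 - a12^2
  cand <- list()
  if (det > 0) {
    K <- (b1 * a22 - b2 * a12) / det
    B <- (a11 * b2 - a12 * b1) / det
    if (K >= loK && K <= upK && B >= loB && B <= upB)
      return(c(K = K, B = B))
  }
  solveK <- function(B) min(max((b1 - B * a12) / a11, loK), upK)
  solveB <- function(K) min(max((b2 - K * a12) / a22, loB), upB)
  for (Kfix in c(loK, upK)) cand <- c(cand, list(c(K = Kfix, B = solveB(Kfix))))
  for (Bfix in c(loB, upB)) cand <- c(cand, list(c(K = solveK(Bfix), B = Bfix)))
  chi2 <- vapply(cand, function(p)
    sum((w * (p[["K"]] * m + p[["B"]] - y))^2), 0)
  cand[[which.min(chi2)]]
}

#' Chi-square of model values against a curve
#'
#' @param data a [sans_curve()].
#' @param model_values fitted intensities on the curve's q grid.
#' @param n_params number of fitted parameters (for the reduced value).
#' @return List `chi2`, `chi2_reduced`, `dof`, `residuals` (the normalized
#'   residuals `(I_fit - I_exp)/sigma`).
#' @export
chi_square <- function(data, model_values, n_params = 0) {
  stopifnot(inherits(data, "sans_curve"),
            length(model_values) == nrow(data))
  res <- (model_values - data$I) / data$sigma
  chi2 <- sum(res^2)
  dof <- nrow(data) - n_params
  list(chi2 = chi2,
       chi2_reduced = if (dof > 0) chi2 / dof else NA_real_,
       dof = dof, residuals = res)
}

.default_bounds <- function(spec) {
  rg_min <- max(spec$components[[1]]$rg, spec$subunit_r %||% 0, 1)
  list(start = c(K = 1, B = 0, rg_olig = 300, gamma = 0.01, alpha = 0.1),
       lower = c(K = 1e-8, B = -0.1, rg_olig = rg_min, gamma = 0, alpha = 0),
       upper = c(K = 10, B = 0.1, rg_olig = 2000, gamma = 1, alpha = 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a mixture model to a SANS curve
#'
#' Weighted least squares minimizing `sum ((I_fit - I_exp)/sigma)^2`, with
#' resolution smearing applied when the curve carries a `sigma_q` column.
#' The model is linear in the scale `K` and background `B` for any values of
#' the shape parameters, so those two are profiled out exactly (variable
#' projection, box-constrained) and a bounded Levenberg-Marquardt search
#' runs only over the shape parameters (`rg_olig`, `gamma`, `alpha`); model
#' 1 reduces to a single constrained linear solve. Parameter uncertainties
#' come from the local curvature, `cov = (J^T J)^{-1}` of the normalized
#' residuals over all parameters. Deterministic given `start` (and `seed`
#' when `n_starts > 1`: multi-starts draw shape starts uniformly between
#' the bounds).
#'
#' @param spec a [model_spec()].
#' @param data a [sans_curve()].
#' @param start,lower,upper named overrides of the default start values and
#'   box bounds.
#' @param n_starts number of starts; the best converged fit is returned.
#' @param seed RNG seed for the extra starts.
#' @param max_iter Levenberg-Marquardt iteration budget; exhausting it flags
#'   the result as not converged rather than raising an error.
#' @return Object of class `sans_fit`: parameter estimates, standard
#'   uncertainties, covariance/correlation matrices, chi2, reduced chi2,
#'   degrees of freedom, fitted curve and normalized residuals.
#' @export
fit_model <- function(spec, data, start = NULL, lower = NULL, upper = NULL,
                      n_starts = 1, seed = NULL, max_iter = 200) {
  stopifnot(inherits(spec, "sans_model_spec"), inherits(data, "sans_curve"))
  pn <- MODEL_PARAM_NAMES[[as.character(spec$model_id)]]
  nl <- setdiff(pn, c("K", "B"))  # shape parameters; K, B are projected out
  db <- .default_bounds(spec)
  p0 <- db$start[pn]; lo <- db$lower[pn]; up <- db$upper[pn]
  for (nm in names(start)) p0[nm] <- start[[nm]]
  for (nm in names(lower)) lo[nm] <- lower[[nm]]
  for (nm in names(upper)) up[nm] <- upper[[nm]]
  p0 <- pmin(pmax(p0, lo), up)
  if (nrow(data) <= length(pn))
    stop("no degrees of freedom: ", nrow(data), " points, ",
         length(pn), " parameters")
  sq <- if (has_resolution(data)) data$sigma_q else NULL
  nodes <- .smear_nodes()
  w <- 1 / data$sigma

  # variable projection: for any shape parameters the model is linear in
  # C = K*n and B, so the inner weighted least squares is exact and the
  # outer optimizer only sees the (well-conditioned) shape parameters
  inner <- function(th) {
    m <- .smeared_basis(spec, th, data$q, sq, nodes)
    kb <- .solve_linear(m, data$I, w, lo[["K"]], up[["K"]], lo[["B"]],
                        up[["B"]])
    list(K = kb[["K"]], B = kb[["B"]], m = m,
         resid = w * (kb[["K"]] * m + kb[["B"]] - data$I))
  }

  # shape parameters in scaled units for the outer optimizer
  sc <- c(rg_olig = 300, gamma = 0.05, alpha = 0.2)[nl]
  info <- 1L
  message <- "linear solve"
  if (length(nl) == 0) {
    sol <- inner(stats::setNames(numeric(0), character(0)))
    p <- c(K = sol$K, B = sol$B)
  } else {
    resid_fn <- function(ths) {
      th <- ths * sc
      names(th) <- nl
      inner(th)$resid
    }
    starts <- list(p0[nl])
    if (n_starts > 1) {
      if (!is.null(seed)) set.seed(seed)
      for (s in seq_len(n_starts - 1))
        starts[[s + 1]] <- lo[nl] + stats::runif(length(nl)) *
          (up[nl] - lo[nl])
    }
    best <- NULL
    for (st in starts) {
      res <- minpack.lm::nls.lm(par = st / sc, lower = lo[nl] / sc,
                                upper = up[nl] / sc, fn = resid_fn,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = max_iter,
                                  maxfev = 100 * max_iter))
      if (is.null(best) || res$deviance < best$deviance) best <- res
    }
    th <- best$par * sc
    names(th) <- nl
    sol <- inner(th)
    p <- c(c(K = sol$K, B = sol$B), th)[pn]
    info <- best$info
    message <- best$message
  }
  names(p) <- pn
  converged <- info %in% c(1, 2, 3, 4)

  # local-curvature covariance of ALL parameters: central-difference
  # Jacobian of the weighted residuals, eigenvalue-floored inverse so flat
  # ridge directions surface as large, not spurious, uncertainties
  full_resid <- function(pv) {
    pl <- as.list(pv)
    names(pl) <- pn
    w * (.smeared_model(spec, pl, data$q, sq, nodes) - data$I)
  }
  # Jacobian in scaled units (d residual / d (p_i / sc_i)): parameter
  # magnitudes span ~7 decades (B in cm^-1 vs rg in A), and the inverse must
  # be formed where the conditioning reflects the science, not the units,
  # or flat ridge directions get clamped into spuriously small uncertainties
  sc_all <- c(K = 1, B = 0.01, rg_olig = 300, gamma = 0.05, alpha = 0.2)[pn]
  J <- vapply(seq_along(pn), function(i) {
    h <- 1e-5 * sc_all[i]
    pp <- p; pm <- p
    pp[i] <- p[i] + h; pm[i] <- p[i] - h
    (full_resid(pp) - full_resid(pm)) / (2 * h) * sc_all[i]
  }, numeric(nrow(data)))
  ev <- eigen(crossprod(J), symmetric = TRUE)
  lam <- pmax(ev$values, max(ev$values, 1e-300) * 1e-12)
  vcov_sc <- ev$vectors %*% diag(1 / lam, length(lam)) %*% t(ev$vectors)
  vcov <- vcov_sc * outer(sc_all, sc_all)
  dimnames(vcov) <- list(pn, pn)
  se <- sqrt(pmax(diag(vcov), 0))
  cor <- vcov / outer(se, se)
  fitted <- as.vector(p[["K"]] * sol$m + p[["B"]])
  cs <- chi_square(data, fitted, n_params = length(pn))
  structure(list(model_id = spec$model_id, params = p, se = se, vcov = vcov,
                 cor = cor, chi2 = cs$chi2, chi2_reduced = cs$chi2_reduced,
                 dof = cs$dof, n_points = nrow(data), n_params = length(pn),
                 converged = converged, info = info,
                 message = message, fitted = fitted,
                 residuals = cs$residuals, data_label = attr(data, "label"),
                 at_bounds = pn[p <= lo + 1e-12 | p >= up - 1e-12]),
            class = "sans_fit")
}

#' @export
print.sans_fit <- function(x, ...) {
  cat(sprintf("model %d fit to '%s': chi2r = %.3f (dof %d)%s\n",
              x$model_id, x$data_label, x$chi2_reduced, x$dof,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- data.frame(estimate = x$params, se = x$se)
  print(est)
  invisible(x)
}

#' F-test between two fits of the same curve
#'
#' Two modes, both one-sided (upper tail):
#' * `nested`: the fits differ in parameter count;
#'   `F = [(chi2_s - chi2_c)/(f_s - f_c)] / [chi2_c/f_c]` on
#'   `(f_s - f_c, f_c)` degrees of freedom. No improvement (or a worse
#'   complex fit) gives P = 1.
#' * `variance`: equal parameter counts (e.g. the same model with two
#'   different structures); the variance ratio
#'   `F = chi2r_worse / chi2r_better` on `(f, f)` degrees of freedom.
#'
#' `auto` picks `nested` when the parameter counts differ.
#'
#' @param fit_simple,fit_complex `sans_fit` objects on the same data. In
#'   `variance` mode the order is irrelevant.
#' @param mode `"auto"`, `"nested"` or `"variance"`.
#' @param level significance level for the `significant` flag.
#' @return List `F`, `p`, `df1`, `df2`, `mode`, `significant`.
#' @export
f_test <- function(fit_simple, fit_complex, mode = c("auto", "nested", "variance"),
                   level = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit_simple, "sans_fit"), inherits(fit_complex, "sans_fit"))
  if (fit_simple$n_points != fit_complex$n_points)
    stop("fits are not on the same data")
  if (mode == "auto")
    mode <- if (fit_simple$n_params != fit_complex$n_params) "nested" else "variance"
  if (mode == "nested") {
    if (fit_complex$n_params < fit_simple$n_params) {
      tmp <- fit_simple; fit_simple <- fit_complex; fit_complex <- tmp
    }
    df1 <- fit_simple$dof - fit_complex$dof
    df2 <- fit_complex$dof
    if (df1 <= 0) stop("nested mode needs different parameter counts")
    dchi <- fit_simple$chi2 - fit_complex$chi2
    if (dchi <= 0) {
      F <- 0; p <- 1
    } else {
      F <- (dchi / df1) / (fit_complex$chi2 / df2)
      p <- stats::pf(F, df1, df2, lower.tail = FALSE)
    }
  } else {
    worse <- if (fit_simple$chi2_reduced >= fit_complex$chi2_reduced)
      fit_simple else fit_complex
    better <- if (identical(worse, fit_simple)) fit_complex else fit_simple
    F <- worse$chi2_reduced / better$chi2_reduced
    df1 <- worse$dof; df2 <- better$dof
    p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  }
  list(F = F, p = p, df1 = df1, df2 = df2, mode = mode,
       significant = p < level)
}

#' Write a fit report as JSON plus a flat residual table
#'
#' @param fit a `sans_fit`. @param data the fitted [sans_curve()].
#' @param json_file,table_file output paths (either may be `NULL`).
#' @export
write_fit_report <- function(fit, data, json_file = NULL, table_file = NULL) {
  if (!is.null(json_file)) {
    rep <- list(model_id = fit$model_id, data = fit$data_label,
                params = as.list(fit$params), se = as.list(fit$se),
                chi2 = fit$chi2, chi2_reduced = fit$chi2_reduced,
                dof = fit$dof, converged = fit$converged,
                correlation = fit$cor)
    jsonlite::write_json(rep, json_file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(table_file)) {
    con <- file(table_file, "w")
    writeLines("# q[1/A] I_exp[1/cm] sigma[1/cm] I_fit[1/cm] residual[-]", con)
    writeLines(sprintf("%.6e %.6e %.6e %.6e %.4f",
                       data$q, data$I, data$sigma, fit$fitted, fit$residuals),
               con)
    close(con)
  }
  invisible(fit)
}
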