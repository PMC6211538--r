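# Experimental-curve toolbox: Guinier and Kratky analyses, Porod-plot
# background, the scattering invariant, molecular-weight estimators, a
# regularized indirect Fourier transform for p(r), and inter-setting overlap
# scaling.

#' Guinier analysis with automatic range selection
#'
#' Iteratively fits `ln I = ln I0 - q^2 Rg^2 / 3` on the widest low-q window
#' satisfying `q_max * Rg <= qrg_max`: starting from the first `min_points`
#' points, the window is re-derived from the current Rg estimate until it is
#' self-consistent. Curves with a low-q upturn (aggregation) drive Rg up and
#' the window below `min_points`, in which case no valid Guinier region
#' exists and `valid` is `FALSE`.
#'
#' @param data a [sans_curve()].
#' @param qrg_max the validity limit on `q * Rg` (1.3 for globular
#'   particles).
#' @param min_points smallest acceptable window.
#' @return Object of class `guinier_result`: list `rg`, `i0`, `q_range_used`,
#'   `qrg_max` (realized `q_max * rg`), `n_used`, `valid`.
#' @export
guinier <- function(data, qrg_max = 1.3, min_points = 5) {
  stopifnot(inherits(data, "sans_curve"))
  pos <- data$I > 0
  q <- data$q[pos]; I <- data$I[pos]; s <- data$sigma[pos]
  out <- list(rg = NA_real_, i0 = NA_real_, q_range_used = c(NA, NA),
              qrg_max = NA_real_, n_used = 0L, valid = FALSE)
  class(out) <- "guinier_result"
  if (length(q) < min_points) return(out)
  fit_window <- function(n) {
    w <- (I[1:n] / s[1:n])^2   # weights for ln I: sigma_lnI = sigma/I
    co <- stats::lm.wfit(cbind(1, q[1:n]^2), log(I[1:n]), w)$coefficients
    c(i0 = exp(co[[1]]), rg = sqrt(max(0, -3 * co[[2]])))
  }
  n <- min_points
  est <- fit_window(n)
  for (it in 1:50) {
    if (est[["rg"]] <= 0) break
    n_new <- sum(q * est[["rg"]] <= qrg_max)
    n_new <- min(n_new, length(q))
    if (n_new < min_points) break
    est_new <- fit_window(n_new)
    if (n_new == n) { est <- est_new; n <- n_new
      out$valid <- TRUE; break }
    n <- n_new
    est <- est_new
  }
  if (out$valid && q[n] * est[["rg"]] > qrg_max * (1 + 1e-9))
    out$valid <- FALSE
  out$rg <- est[["rg"]]; out$i0 <- est[["i0"]]
  out$q_range_used <- c(q[1], q[n]); out$qrg_max <- q[n] * est[["rg"]]
  out$n_used <- n
  out
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("Guinier: rg = %.2f A, i0 = %.4g, %d points, qmax*rg = %.2f%s\n",
              x$rg, x$i0, x$n_used, x$qrg_max,
              if (x$valid) "" else "  [NO VALID REGION]"))
  invisible(x)
}

#' Kratky representation
#'
#' @param data a [sans_curve()].
#' @return data.frame `q`, `q2I` (= q^2 I(q)); the plot that distinguishes
#'   folded (bell-shaped) from unfolded (plateauing) particles.
#' @export
kratky <- function(data) {
  stopifnot(inherits(data, "sans_curve"))
  if (nrow(data) == 0) stop("empty curve")
  data.frame(q = data$q, q2I = data$q^2 * data$I)
}

#' Constant background from a Porod plot
#'
#' For a particle with a sharp interface, `I(q) = A q^-4 + B` at high q, so
#' `q^4 I(q)` is linear in `q^4` with slope `B`. Returns the fitted slope over
#' the stated window.
#'
#' @param data a [sans_curve()].
#' @param q_window high-q window `(q_lo, q_hi)`, A^-1. The default uses the
#'   upper part of the measured range, 0.15 A^-1 to q_max.
#' @return Background estimate, cm^-1, with attribute `porod_constant` (A,
#'   cm^-1 A^-4) and `n_used`.
#' @export
porod_background <- function(data, q_window = NULL) {
  stopifnot(inherits(data, "sans_curve"))
  if (is.null(q_window)) q_window <- c(0.15, max(data$q))
  sel <- data$q >= q_window[1] & data$q <= q_window[2]
  if (sum(sel) < 5)
    stop("fewer than 5 points in the Porod window [",
         q_window[1], ", ", q_window[2], "]")
  x <- data$q[sel]^4
  y <- data$q[sel]^4 * data$I[sel]
  co <- stats::lm.fit(cbind(1, x), y)$coefficients
  structure(co[[2]], porod_constant = co[[1]], n_used = sum(sel))
}

#' Scattering invariant Q
#'
#' `Q = integral q^2 [I(q) - B] dq`, trapezoid on the measured grid, with the
#' low-q gap [0, q_min] filled from the Guinier form of the supplied
#' extrapolation model (a [guinier()] or p(r) result providing `i0` and `rg`)
#' and an optional `q^-4` tail extension beyond q_max (Porod constant
#' estimated from the last points).
#'
#' @param data a [sans_curve()].
#' @param background constant background B, cm^-1.
#' @param extrapolation object with `i0`/`rg` (a `guinier_result` or
#'   `pr_result`), or `NULL` to extend the first intensity flat to q = 0.
#' @param high_q_tail `"none"` or `"porod"`.
#' @return Q, cm^-1 A^-3, with attribute `parts` (low/measured/tail).
#' @export
invariant_q <- function(data, background = 0, extrapolation = NULL,
                        high_q_tail = c("none", "porod")) {
  stopifnot(inherits(data, "sans_curve"))
  high_q_tail <- match.arg(high_q_tail)
  q <- data$q
  Ib <- data$I - background
  mid <- pracma::trapz(q, q^2 * Ib)
  if (!is.null(extrapolation)) {
    i0 <- if (inherits(extrapolation, "pr_result"))
      attr(extrapolation, "i0") else extrapolation$i0
    rg <- if (inherits(extrapolation, "pr_result"))
      attr(extrapolation, "rg") else extrapolation$rg
    low <- stats::integrate(function(x) x^2 * i0 * exp(-x^2 * rg^2 / 3),
                            0, q[1])$value
  } else {
    low <- Ib[1] * q[1]^3 / 3
  }
  tail <- 0
  if (high_q_tail == "porod") {
    ntail <- max(5, round(0.1 * length(q)))
    A <- mean(utils::tail(q, ntail)^4 * utils::tail(Ib, ntail))
    tail <- max(0, A / max(q))
  }
  structure(low + mid + tail,
            parts = c(low = low, measured = mid, tail = tail))
}

#' Molecular weight from forward scattering and concentration
#'
#' `MW = [I(0)/c] * N_A * rho_p^2 / delta_rho^2`, the standard
#' absolute-scale estimator given the protein concentration, the average
#' excess scattering length density and the average protein mass density.
#'
#' @param i0 forward scattering, cm^-1.
#' @param c_mg_ml concentration in g/cm^3 (= mg/ml * 1e-3; pass g/cm^3).
#' @param delta_rho average excess scattering length density, cm^-2.
#' @param rho_p average protein mass density, g/cm^3.
#' @return MW in kDa.
#' @export
mw_from_i0 <- function(i0, c_mg_ml, delta_rho, rho_p = 1.37) {
  stopifnot(i0 > 0, c_mg_ml > 0)
  if (!is.finite(delta_rho) || delta_rho == 0)
    stop("delta_rho must be nonzero")
  (i0 / c_mg_ml) * AVOGADRO * rho_p^2 / delta_rho^2 / 1000
}

.fischer_constants <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- mw_constants()
    cached
  }
})

#' Concentration-independent molecular weight, truncated-invariant method
#'
#' Computes the apparent Porod volume `V' = 2 pi^2 I(0) / Q'` with the
#' invariant integrated only up to a truncation `qmax` (no tail
#' extrapolation), corrects it to a true volume with a per-qmax power-law
#' calibration, and converts volume to mass with the average protein density
#' (1.37 g/cm^3). Following Fischer et al. (2010), the truncation makes the
#' estimate robust to the high-q background; the correction coefficients
#' shipped in [mw_constants()] were recalibrated on simulated homogeneous
#' spheres.
#'
#' @param data a [sans_curve()] (background-subtracted via `background`).
#' @param i0 forward scattering, cm^-1 (from Guinier or p(r)).
#' @param background constant background, cm^-1.
#' @param rg radius of gyration, A, for the low-q Guinier fill-in.
#' @param qmax truncation, A^-1; snapped to the nearest calibrated value
#'   covered by the data.
#' @return MW in kDa, with attributes `volume` (corrected, A^3),
#'   `apparent_volume`, `qmax_used`, `reliable` (FALSE when the invariant or
#'   volume is non-positive).
#' @export
mw_fischer <- function(data, i0, background = 0, rg = NULL, qmax = 0.3) {
  stopifnot(inherits(data, "sans_curve"), i0 > 0)
  cst <- .fischer_constants()$fischer
  avail <- cst$qmax[cst$qmax <= max(data$q) + 1e-9]
  if (length(avail) == 0) {
    warning("curve too short for any calibrated truncation; using full range")
    avail <- min(cst$qmax)
  }
  qm <- avail[which.min(abs(avail - qmax))]
  ci <- which(cst$qmax == qm)
  trunc <- data[data$q <= qm + 1e-12, , drop = FALSE]
  tc <- sans_curve(trunc$q, trunc$I, trunc$sigma, label = "truncated")
  extra <- if (!is.null(rg)) list(i0 = i0, rg = rg) else NULL
  Q <- as.numeric(invariant_q(tc, background = background,
                              extrapolation = extra, high_q_tail = "none"))
  vap <- 2 * pi^2 * i0 / Q
  reliable <- is.finite(Q) && Q > 0 && vap > 0
  vol <- if (reliable) exp(cst$log_a[ci]) * vap^cst$beta[ci] else NA_real_
  mw <- vol * cst$rho_da_per_a3 / 1000
  if (!reliable || !is.finite(mw) || mw <= 0) {
    warning("truncated-invariant MW estimate unreliable (degenerate invariant)")
    reliable <- FALSE
  }
  structure(mw, volume = vol, apparent_volume = vap, qmax_used = qm,
            invariant = as.numeric(Q), reliable = reliable)
}

#' Concentration-independent molecular weight, Porod-volume rule of thumb
#'
#' Porod volume `V = 2 pi^2 I(0) / Q` with the invariant extended by the
#' `q^-4` tail, divided by the empirical volume-to-mass factor of
#' Petoukhov et al. (2012) shipped in [mw_constants()].
#'
#' @inheritParams mw_fischer
#' @return MW in kDa, with attributes `volume` (A^3) and `reliable`.
#' @export
mw_porod_petoukhov <- function(data, i0, background = 0, rg = NULL) {
  stopifnot(inherits(data, "sans_curve"), i0 > 0)
  extra <- if (!is.null(rg)) list(i0 = i0, rg = rg) else NULL
  Q <- as.numeric(invariant_q(data, background = background,
                              extrapolation = extra, high_q_tail = "porod"))
  vol <- 2 * pi^2 * i0 / Q
  reliable <- is.finite(Q) && Q > 0 && vol > 0
  mw <- vol / .fischer_constants()$petoukhov$vol_per_da / 1000
  if (!reliable || !is.finite(mw) || mw <= 0) {
    warning("Porod-volume MW estimate unreliable (degenerate invariant)")
    reliable <- FALSE
  }
  structure(mw, volume = vol, invariant = as.numeric(Q), reliable = reliable)
}
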