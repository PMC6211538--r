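# Synthetic inputs: toy point-scatterer assemblies, mock multi-domain
# receptor structures in PDB format, simulated mixture curves with realistic
# noise and a resolution column, and a reproducible fixture corpus. Every
# object the pipeline consumes can be generated here, seeded, with no
# downloads.

#' Specify a synthetic point assembly
#'
#' @param shape `"sphere"` (uniform ball), `"shell"` (spherical surface),
#'   `"two_points"`, `"mock_receptor"` (three stacked cylindrical layers:
#'   two wide extracellular layers on a narrow membrane-embedded stem), or
#'   `"custom"` (pass `points`, a data.frame x/y/z).
#' @param radius sphere/shell radius, A.
#' @param distance two-point separation, A.
#' @param layers mock-receptor geometry: data.frame `z0`, `z1`, `radius`
#'   (A). The default stacks a narrow stem (the detergent-embedded part,
#'   z in [-40, 0]) under two wide layers, receptor-like proportions.
#' @param n_points number of points (ignored for `two_points`/`custom`).
#' @param b_per_point excess scattering length per point, cm.
#' @param seed RNG seed; the assembly is fully determined by spec + seed.
#' @param points data.frame for `shape = "custom"`.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c("sphere", "shell", "two_points",
                                     "mock_receptor", "custom"),
                           radius = 50, distance = 50,
                           layers = NULL, n_points = 1000,
                           b_per_point = 1e-12, seed = 1, points = NULL) {
  shape <- match.arg(shape)
  if (shape == "mock_receptor" && is.null(layers))
    layers <- data.frame(z0 = c(-40, 0, 45), z1 = c(0, 45, 100),
                         radius = c(17, 38, 44))
  if (shape == "custom" && is.null(points))
    stop("custom shape needs points")
  stopifnot(n_points >= 1)
  structure(list(shape = shape, radius = radius, distance = distance,
                 layers = layers, n_points = as.integer(n_points),
                 b_per_point = b_per_point, seed = as.integer(seed),
                 points = points),
            class = "synthetic_spec")
}

#' Generate a point assembly from a synthetic spec
#'
#' @param spec a [synthetic_spec()].
#' @return A [point_set()], deterministic given the spec (seed included).
#' @export
make_assembly <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  b <- spec$b_per_point
  ps <- switch(spec$shape,
    two_points = {
      d <- spec$distance
      point_set(c(0, 0), c(0, 0), c(-d / 2, d / 2), rep(b, 2),
                label = "two points")
    },
    sphere = {
      set.seed(spec$seed)
      n <- spec$n_points
      u <- stats::runif(n)^(1 / 3) * spec$radius
      dirs <- .random_directions(n)
      point_set(u * dirs[, 1], u * dirs[, 2], u * dirs[, 3], rep(b, n),
                label = sprintf("ball R=%g", spec$radius))
    },
    shell = {
      set.seed(spec$seed)
      dirs <- .random_directions(spec$n_points) * spec$radius
      point_set(dirs[, 1], dirs[, 2], dirs[, 3], rep(b, spec$n_points),
                label = sprintf("shell R=%g", spec$radius))
    },
    mock_receptor = {
      set.seed(spec$seed)
      ly <- spec$layers
      vol <- pi * ly$radius^2 * (ly$z1 - ly$z0)
      n_l <- pmax(1L, round(spec$n_points * vol / sum(vol)))
      pts <- do.call(rbind, lapply(seq_len(nrow(ly)), function(i) {
        n <- n_l[i]
        rad <- ly$radius[i] * sqrt(stats::runif(n))
        th <- stats::runif(n, 0, 2 * pi)
        cbind(rad * cos(th), rad * sin(th),
              stats::runif(n, ly$z0[i], ly$z1[i]))
      }))
      point_set(pts[, 1], pts[, 2], pts[, 3], rep(b, nrow(pts)),
                label = "mock receptor")
    },
    custom = point_set(spec$points$x, spec$points$y, spec$points$z,
                       rep(b, nrow(spec$points)), label = "custom"))
  ps
}

.random_directions <- function(n) {
  z <- stats::runif(n, -1, 1)
  th <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(th), s * sin(th), z)
}

#' Noise and resolution model for simulated curves
#'
#' Additive Gaussian noise with intensity-dependent width
#' `sigma_i = relative_floor * max(I) + i_dependent_coeff * I_i`, and a
#' resolution column `sigma_q = sigma_q_model * q / 2.355`: a fractional
#' FWHM wavelength spread (10% is typical of a velocity-selector SANS
#' instrument) converted to a Gaussian sigma.
#'
#' @param relative_floor floor of the noise, as a fraction of the peak
#'   intensity.
#' @param i_dependent_coeff fractional noise on each intensity.
#' @param sigma_q_model fractional FWHM of the q resolution.
#' @param seed RNG seed.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(relative_floor = 0.002, i_dependent_coeff = 0.03,
                       sigma_q_model = 0.10, seed = 1) {
  stopifnot(relative_floor >= 0, i_dependent_coeff >= 0, sigma_q_model >= 0)
  structure(list(relative_floor = relative_floor,
                 i_dependent_coeff = i_dependent_coeff,
                 sigma_q_model = sigma_q_model, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Simulate a reduced SANS curve from a mixture model
#'
#' Evaluates [model_intensity()], applies Gaussian resolution smearing with
#' the same `sigma_q` column it emits, and adds seeded Gaussian noise per
#' [noise_spec()]. With both noise coefficients zero the curve equals the
#' smeared model exactly.
#'
#' @param spec a [model_spec()]. @param params model parameters (see
#'   [model_intensity()]). @param q q grid, A^-1. @param noise a
#'   [noise_spec()].
#' @return A 4-column [sans_curve()] with attribute `true_params`.
#' @export
simulate_curve <- function(spec, params, q, noise = noise_spec()) {
  stopifnot(inherits(spec, "sans_model_spec"), inherits(noise, "noise_spec"))
  sigma_q <- noise$sigma_q_model * q / 2.355
  nodes <- .smear_nodes()
  I <- .smeared_model(spec, as.list(params), q, sigma_q, nodes)
  sigma <- noise$relative_floor * max(I) + noise$i_dependent_coeff * I
  if (all(sigma == 0)) {
    sigma_rep <- pmax(1e-12, 0.01 * abs(I))  # positive column, zero noise
    return(sans_curve(q, I, sigma_rep, sigma_q = sigma_q,
                      label = "simulated (noise-free)"))
  }
  set.seed(noise$seed)
  I_noisy <- I + stats::rnorm(length(q), 0, sigma)
  out <- sans_curve(q, I_noisy, sigma, sigma_q = sigma_q, label = "simulated")
  attr(out, "true_params") <- as.list(params)
  out
}

# ---- mock atomic structures ------------------------------------------------

#' Write-ready mock receptor structure in PDB format
#'
#' Builds a synthetic poly-alanine structure with receptor-like proportions:
#' residues scattered through three stacked cylindrical layers (narrow
#' membrane stem + two wide extracellular layers), each residue carrying
#' N, CA, C, O, CB at fixed local offsets. `open_state = TRUE` widens and
#' lifts the top layers, mimicking an open extracellular conformation of the
#' same mass. Entirely synthetic; deterministic given the seed.
#'
#' @param n_res number of residues.
#' @param seed RNG seed.
#' @param open_state widen the extracellular layers.
#' @return Character vector of PDB lines (with attribute `layers`).
#' @export
make_mock_structure <- function(n_res = 220, seed = 1, open_state = FALSE) {
  layers <- if (open_state)
    data.frame(z0 = c(-40, 0, 50), z1 = c(0, 50, 112), radius = c(17, 46, 56))
  else
    data.frame(z0 = c(-40, 0, 45), z1 = c(0, 45, 100), radius = c(17, 38, 44))
  set.seed(seed)
  # residue allocation by (receptor-like) mass fraction, not layer volume:
  # the membrane stem is narrow but densely packed protein
  mass_frac <- c(0.18, 0.36, 0.46)
  n_l <- round(n_res * mass_frac)
  n_l[1] <- n_res - sum(n_l[-1])
  centers <- do.call(rbind, lapply(seq_len(nrow(layers)), function(i) {
    n <- n_l[i]
    rad <- layers$radius[i] * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    cbind(rad * cos(th), rad * sin(th),
          stats::runif(n, layers$z0[i], layers$z1[i]))
  }))
  offs <- rbind(N = c(-1.20, 0.40, 0.00), CA = c(0, 0, 0),
                C = c(1.20, 0.45, 0.00), O = c(1.90, 1.40, 0.30),
                CB = c(-0.35, -1.30, 0.95))
  el <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(centers))) {
    for (a in rownames(offs)) {
      serial <- serial + 1L
      xyz <- centers[i, ] + offs[a, ]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, a, i, xyz[1], xyz[2], xyz[3], 1.0, 0.0, el[[a]]))
    }
  }
  structure(c(lines, "END"), layers = layers)
}

# ---- fixture corpus --------------------------------------------------------

#' Write a reproducible synthetic fixture corpus
#'
#' Generates mock structures (closed and open states), simulated curves for
#' models 1-4 — including a 1-2% oligomer case and a heavily aggregated
#' curve with no valid Guinier region — and a JSON manifest of every file's
#' generating parameters. Regenerating with the same seed is byte-identical.
#'
#' @param seed integer seed; sub-seeds are derived from it.
#' @param out_dir output directory (created if missing).
#' @param n_res mock structure size (residues).
#' @param conc_molar nominal molar protein concentration of the simulated
#'   sample.
#' @return The manifest, invisibly (list; also written as `manifest.json`).
#' @export
corpus <- function(seed, out_dir, n_res = 220, conc_molar = 0.54e-6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  q <- exp(seq(log(0.006), log(0.2), length.out = 120))

  pdb_closed <- make_mock_structure(n_res, seed = seed, open_state = FALSE)
  pdb_open <- make_mock_structure(n_res, seed = seed + 1L, open_state = TRUE)
  writeLines(pdb_closed, file.path(out_dir, "mock_receptor_closed.pdb"))
  writeLines(pdb_open, file.path(out_dir, "mock_receptor_open.pdb"))

  slab <- membrane_slab(-40, 0)
  build <- function(pdb_lines) {
    atoms <- load_structure(paste(pdb_lines, collapse = "\n"))
    ps <- assign_scattering(atoms)
    hyd <- add_hydration_shell(ps, atoms, slab = slab)
    q_ext <- c(0, exp(seq(log(1e-4), log(0.35), length.out = 160)))
    list(atoms = atoms, points = hyd, ff = form_factor(hyd, q_ext))
  }
  closed <- build(pdb_closed)
  open <- build(pdb_open)
  r_sub <- subunit_radius_from_volume(closed$atoms)
  n_dens <- molar_to_numdens(conc_molar)

  specs <- list(
    model1_single = list(
      spec = model_spec(1, list(closed = closed$ff), conc_n = n_dens),
      params = list(K = 1.05, B = 2e-7)),
    model2_oligomer = list(
      spec = model_spec(2, list(closed = closed$ff), subunit_r = r_sub,
                        conc_n = n_dens),
      params = list(K = 1.05, B = 2e-7, rg_olig = 300, gamma = 0.015)),
    model3_twostate = list(
      spec = model_spec(3, list(closed = closed$ff, open = open$ff),
                        conc_n = n_dens),
      params = list(K = 1.05, B = 2e-7, alpha = 0.3)),
    model4_combined = list(
      spec = model_spec(4, list(closed = closed$ff, open = open$ff),
                        subunit_r = r_sub, conc_n = n_dens),
      params = list(K = 1.05, B = 2e-7, rg_olig = 300, gamma = 0.015,
                    alpha = 0.3)),
    noguinier_aggregated = list(
      spec = model_spec(2, list(closed = closed$ff), subunit_r = r_sub,
                        conc_n = n_dens),
      params = list(K = 1.05, B = 2e-7, rg_olig = 800, gamma = 0.25))
  )
  manifest <- list(seed = seed, n_res = n_res, conc_molar = conc_molar,
                   subunit_r = r_sub,
                   structures = list(
                     mock_receptor_closed.pdb = list(seed = seed,
                                                     open_state = FALSE),
                     mock_receptor_open.pdb = list(seed = seed + 1L,
                                                   open_state = TRUE)),
                   curves = list())
  for (i in seq_along(specs)) {
    nm <- names(specs)[i]
    sp <- specs[[i]]
    cur <- simulate_curve(sp$spec, sp$params, q,
                          noise = noise_spec(seed = seed + 10L + i))
    fn <- paste0(nm, ".dat")
    write_sans(cur, file.path(out_dir, fn))
    manifest$curves[[fn]] <- c(list(model_id = sp$spec$model_id,
                                    noise_seed = seed + 10L + i),
                               sp$params)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# ---- analytic references ---------------------------------------------------

#' Analytic sphere scattering references
#'
#' `sphere_intensity()` is the exact orientationally averaged intensity of a
#' homogeneous sphere, `i0 * [3 (sin x - x cos x)/x^3]^2` with `x = qR`;
#' `sphere_pr()` the matching pair distance density
#' `p(r) proportional to r^2 (1 - 3u/2 + u^3/2)`, `u = r/(2R)`. Used as
#' independent oracles for the Guinier, p(r) and IFT machinery.
#'
#' @param q q grid, A^-1. @param R sphere radius, A. @param i0 forward
#'   intensity.
#' @return Intensities.
#' @export
sphere_intensity <- function(q, R, i0 = 1) {
  x <- q * R
  amp <- ifelse(x == 0, 1, 3 * (sin(x) - x * cos(x)) / x^3)
  i0 * amp^2
}

#' @rdname sphere_intensity
#' @param r distance grid, A.
#' @param norm normalization of the density: `"i0"` scales so that
#'   `integral p dr = i0`.
#' @export
sphere_pr <- function(r, R, i0 = 1, norm = c("i0", "peak")) {
  norm <- match.arg(norm)
  u <- r / (2 * R)
  p <- ifelse(u <= 1, r^2 * (1 - 1.5 * u + 0.5 * u^3), 0)
  if (norm == "i0") {
    p <- p * i0 / pracma::trapz(r, p)
  } else {
    p <- p / max(p)
  }
  p
}
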