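# Mass-fractal description of random oligomers: Teixeira structure factor,
# the correlation-length <-> radius-of-gyration relation, the fractal scaling
# law for the subunit count, and the decoupling approximation that corrects
# the structure factor for non-spherical subunits.

.check_fractal_dim <- function(D) {
  if (!is.numeric(D) || length(D) != 1 || D <= 1 || D >= 3)
    stop("fractal dimension D must lie in (1, 3), got ", D)
}

#' Teixeira mass-fractal structure factor
#'
#' Structure factor of a fractal aggregate of spherical subunits of mean
#' distance `r`, fractal dimension `D` and correlation length `xi`
#' (Teixeira 1988):
#' \deqn{S(q) = 1 + \frac{D\,\Gamma(D-1)}{(qr)^D}
#'   \frac{\sin[(D-1)\arctan(q\xi)]}{(D-1)\,[1 + 1/(q\xi)^2]^{(D-1)/2}}}
#' The raw expression is 0/0 at q = 0; there the analytic limit
#' `1 + Gamma(D+1)/(D-1) * (xi/r)^D ... ` reduces (via
#' `D*Gamma(D-1) = Gamma(D+1)/(D-1)`) to
#' `S(0) = 1 + D*Gamma(D-1)*(xi/r)^D`, which is returned instead.
#'
#' @param q q grid, A^-1 (q = 0 allowed, handled by the limit).
#' @param D fractal dimension, 1 < D < 3 (D = 2 is regular, Gamma(1) = 1).
#' @param r mean subunit distance, A.
#' @param xi correlation length, A.
#' @return S(q), dimensionless, > 0.
#' @export
teixeira_sq <- function(q, D = 2, r, xi) {
  .check_fractal_dim(D)
  stopifnot(r > 0, xi > 0, all(q >= 0))
  s <- numeric(length(q))
  z <- q == 0
  s[z] <- 1 + D * gamma(D - 1) * (xi / r)^D
  qq <- q[!z]
  s[!z] <- 1 + D * gamma(D - 1) / (qq * r)^D *
    sin((D - 1) * atan(qq * xi)) /
    ((D - 1) * (1 + 1 / (qq * xi)^2)^((D - 1) / 2))
  s
}

#' Correlation length from the oligomer radius of gyration
#'
#' `xi = rg * sqrt(2 / (D (D + 1)))`; at D = 2 this is `rg / sqrt(3)`.
#'
#' @param rg_olig oligomer radius of gyration, A.
#' @param D fractal dimension.
#' @return xi, A.
#' @export
xi_from_rg <- function(rg_olig, D = 2) {
  .check_fractal_dim(D)
  rg_olig * sqrt(2 / (D * (D + 1)))
}

#' Oligomer radius of gyration from the correlation length
#' @param xi correlation length, A. @param D fractal dimension.
#' @return rg, A.
#' @export
rg_from_xi <- function(xi, D = 2) {
  .check_fractal_dim(D)
  xi / sqrt(2 / (D * (D + 1)))
}

#' Subunits per oligomer from the fractal scaling law
#'
#' `N = k (rg_olig / r)^D`, kept real-valued: N enters the mixture model as
#' a derived scale factor, not a particle count.
#'
#' @param rg_olig oligomer radius of gyration, A.
#' @param r mean subunit distance, A.
#' @param D fractal dimension. @param k structural coefficient (k ~ 1 at
#'   D ~ 2).
#' @return N, real.
#' @export
oligomer_count <- function(rg_olig, r, D = 2, k = 1) {
  .check_fractal_dim(D)
  stopifnot(r > 0, k > 0)
  k * (rg_olig / r)^D
}

#' Mean subunit distance from the protein volume
#'
#' The fractal subunit distance is fixed to the radius of the sphere whose
#' volume equals the protein's total van der Waals volume (implicit
#' hydrogens included).
#'
#' @inheritParams protein_volume
#' @return r = (3V / 4 pi)^(1/3), A.
#' @export
subunit_radius_from_volume <- function(atoms,
                                       volume_table = vdw_volume_table(),
                                       residue_h = residue_hydrogen_table(),
                                       on_unknown = "error") {
  v <- protein_volume(atoms, volume_table, residue_h, on_unknown)
  (3 * v / (4 * pi))^(1 / 3)
}

#' Effective structure factor under the decoupling approximation
#'
#' Randomly oriented anisotropic subunits damp the interference term:
#' `S'(q) = 1 + beta(q) (S(q) - 1)` with `beta = A00^2 / P` in [0, 1]. The
#' intensity of one oligomer (per subunit) is then `P(q) S'(q)`.
#'
#' @param P unnormalized form factor values.
#' @param A00 zeroth-order amplitude values (same grid).
#' @param S Teixeira structure factor values (same grid).
#' @return S'(q).
#' @export
effective_sq <- function(P, A00, S) {
  stopifnot(length(P) == length(A00), length(P) == length(S))
  beta <- ifelse(P > 0, A00^2 / P, 1)
  1 + beta * (S - 1)
}
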