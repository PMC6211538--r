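#' Construct a point-scatterer set
#'
#' A `point_set` is the common currency of the pipeline: a cloud of point
#' scatterers (atom centers, with implicit hydrogens folded in, plus optional
#' hydration beads), each carrying an excess scattering length. Form factors,
#' amplitudes and pair distance distributions are computed from it.
#'
#' @param x,y,z coordinates in Angstrom.
#' @param b excess scattering lengths in cm.
#' @param label free-text label.
#' @return Object of class `point_set`: data.frame with columns `x`, `y`,
#'   `z`, `b`, attributes `label` and `total_b` (sum of `b`, cm).
#' @export
point_set <- function(x, y, z, b, label = "") {
  stopifnot(length(x) == length(y), length(x) == length(z),
            length(x) == length(b))
  if (length(x) == 0) stop("empty point set")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("non-finite coordinates in point set")
  if (!all(is.finite(b))) stop("non-finite excess scattering lengths")
  ps <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   b = as.numeric(b))
  structure(ps, label = label, total_b = sum(ps$b),
            class = c("point_set", "data.frame"))
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("point_set '%s': %d points, total_b = %.4g cm\n",
              attr(x, "label"), nrow(x), attr(x, "total_b")))
  invisible(x)
}

n_points <- function(ps) nrow(ps)

total_b <- function(ps) attr(ps, "total_b")

coords_matrix <- function(ps) cbind(ps$x, ps$y, ps$z)

#' Concatenate point sets
#' @param ... `point_set` objects.
#' @param label label for the result.
#' @return A `point_set` with all points.
#' @export
bind_point_sets <- function(..., label = NULL) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, TRUE, "point_set")))
  if (is.null(label)) label <- attr(sets[[1]], "label")
  df <- do.call(rbind, lapply(sets, function(s) as.data.frame(s)[c("x", "y", "z", "b")]))
  point_set(df$x, df$y, df$z, df$b, label = label)
}

#' Write a point set as whitespace-separated text
#'
#' Four columns `x y z b_excess` (A, A, A, cm) with a comment header; the
#' debug/export format of the structure module.
#'
#' @param ps a `point_set`.
#' @param file output path.
#' @export
write_point_set <- function(ps, file) {
  stopifnot(inherits(ps, "point_set"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# point_set '%s'  columns: x[A] y[A] z[A] b_excess[cm]",
                     attr(ps, "label")), con)
  writeLines(sprintf("% .6f % .6f % .6f % .6e", ps$x, ps$y, ps$z, ps$b), con)
  invisible(file)
}
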