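# Reduced scattering curves: container, reader and writer for the 3/4-column
# ASCII format used by the scattering data banks (q, I, sigma[, sigma_q])
# with "#" comment headers.

#' Construct a reduced SANS curve
#'
#' @param q momentum transfer, A^-1, strictly increasing.
#' @param I intensity, cm^-1 (absolute units).
#' @param sigma intensity uncertainties, cm^-1, > 0.
#' @param sigma_q optional Gaussian q-resolution widths, A^-1, >= 0.
#' @param label free-text label.
#' @return Object of class `sans_curve` (a data.frame).
#' @export
sans_curve <- function(q, I, sigma, sigma_q = NULL, label = "") {
  stopifnot(length(q) == length(I), length(q) == length(sigma))
  if (length(q) == 0) stop("empty curve")
  if (is.unsorted(q, strictly = TRUE)) stop("q must be strictly increasing")
  if (any(!is.finite(q)) || any(!is.finite(I)) || any(!is.finite(sigma)))
    stop("non-finite values in curve")
  if (any(sigma <= 0)) stop("sigma must be positive")
  df <- data.frame(q = q, I = I, sigma = sigma)
  if (!is.null(sigma_q)) {
    stopifnot(length(sigma_q) == length(q), all(sigma_q >= 0))
    df$sigma_q <- sigma_q
  }
  structure(df, label = label, class = c("sans_curve", "data.frame"))
}

#' @export
print.sans_curve <- function(x, ...) {
  cat(sprintf("sans_curve '%s': %d points, q in [%.4g, %.4g] 1/A%s\n",
              attr(x, "label"), nrow(x), min(x$q), max(x$q),
              if (!is.null(x$sigma_q)) ", with resolution column" else ""))
  invisible(x)
}

has_resolution <- function(curve) !is.null(curve$sigma_q)

#' Read a reduced scattering curve from ASCII
#'
#' Accepts whitespace- or comma-separated files with 3 or 4 numeric columns
#' (q, I, sigma, optionally sigma_q) and `#` comment headers; lines that do
#' not parse as numbers (textual preambles) are skipped.
#'
#' @param file path.
#' @param label label; defaults to the file name.
#' @return A [sans_curve()].
#' @export
read_sans <- function(file, label = basename(file)) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  lines <- gsub(",", " ", lines)
  fields <- strsplit(trimws(lines), "\\s+")
  nums <- lapply(fields, function(f) suppressWarnings(as.numeric(f)))
  ok <- vapply(nums, function(v) length(v) >= 3 && !anyNA(v[1:3]), TRUE)
  nums <- nums[ok]
  if (length(nums) == 0) stop("no numeric data rows in ", file)
  ncol4 <- all(vapply(nums, length, 0L) >= 4)
  m <- do.call(rbind, lapply(nums, function(v) v[1:(if (ncol4) 4 else 3)]))
  m <- m[order(m[, 1]), , drop = FALSE]
  sans_curve(m[, 1], m[, 2], m[, 3],
             sigma_q = if (ncol4) m[, 4] else NULL, label = label)
}

#' Write a reduced scattering curve as 4- (or 3-) column ASCII
#' @param curve a [sans_curve()]. @param file path.
#' @export
write_sans <- function(curve, file) {
  stopifnot(inherits(curve, "sans_curve"))
  con <- file(file, "w")
  on.exit(close(con))
  hdr <- "# q[1/A] I[1/cm] sigma[1/cm]"
  if (has_resolution(curve)) hdr <- paste(hdr, "sigma_q[1/A]")
  writeLines(c(sprintf("# sans_curve '%s'", attr(curve, "label")), hdr), con)
  if (has_resolution(curve)) {
    writeLines(sprintf("%.6e %.6e %.6e %.6e",
                       curve$q, curve$I, curve$sigma, curve$sigma_q), con)
  } else {
    writeLines(sprintf("%.6e %.6e %.6e", curve$q, curve$I, curve$sigma), con)
  }
  invisible(file)
}

#' Drop the first points of a curve
#'
#' Low-q truncation limits the influence of a small aggregation 'tail' on
#' p(r) and size parameters.
#'
#' @param curve a [sans_curve()]. @param n_points number of leading points to
#'   remove (0 allowed).
#' @return The truncated [sans_curve()]; the label records the truncation.
#' @export
truncate_low_q <- function(curve, n_points) {
  stopifnot(inherits(curve, "sans_curve"), n_points >= 0)
  if (n_points >= nrow(curve))
    stop("cannot remove ", n_points, " of ", nrow(curve), " points")
  if (n_points == 0) return(curve)
  out <- curve[-seq_len(n_points), , drop = FALSE]
  sans_curve(out$q, out$I, out$sigma, sigma_q = out$sigma_q,
             label = sprintf("%s [first %d points removed]",
                             attr(curve, "label"), n_points))
}
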