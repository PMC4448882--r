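#' Unit cell
#'
#' Construct a unit cell from the six standard cell parameters.
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees; must lie in (0, 180).
#' @return An object of class `unit_cell`.
#' @examples
#' cell <- unit_cell(10, 10, 10, 90, 90, 90)
#' metric_tensors(cell)$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("invalid cell: lengths must be positive and finite", call. = FALSE)
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("invalid cell: angles must lie in (0, 180) degrees", call. = FALSE)
  cell <- structure(list(a = a, b = b, c = c,
                         alpha = alpha, beta = beta, gamma = gamma),
                    class = "unit_cell")
  # volume check catches angle combinations with no metric embedding
  G <- direct_metric(cell)
  if (det(G) <= 0)
    stop("invalid cell: degenerate metric (volume <= 0)", call. = FALSE)
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.3f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, metric_tensors(x)$volume))
  invisible(x)
}

direct_metric <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  with(cell, matrix(c(a * a,      a * b * cg, a * c * cb,
                      a * b * cg, b * b,      b * c * ca,
                      a * c * cb, b * c * ca, c * c), 3, 3))
}

#' Direct and reciprocal metric tensors
#'
#' @param cell A [unit_cell()].
#' @return List with `G` (direct metric, A^2), `Gstar` (reciprocal metric,
#'   A^-2, the inverse of `G`) and `volume` (A^3, `sqrt(det(G))`).
#' @export
metric_tensors <- function(cell) {
  G <- direct_metric(cell)
  dG <- det(G)
  if (dG <= 0) stop("invalid cell: degenerate metric (volume <= 0)", call. = FALSE)
  list(G = G, Gstar = solve(G), volume = sqrt(dG))
}

#' Resolution of a reflection
#'
#' d-spacing of Miller index hkl, `1/sqrt(h' G* h)`.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer triple, or an n x 3 matrix of triples.
#' @return d in Angstrom (vector for matrix input).
#' @export
d_spacing <- function(cell, hkl) {
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, 1, 3)
  if (any(rowSums(h != 0) == 0))
    stop("undefined reflection: (0,0,0) has no d-spacing", call. = FALSE)
  Gs <- metric_tensors(cell)$Gstar
  q2 <- rowSums((h %*% Gs) * h)
  d <- 1 / sqrt(q2)
  if (!is.matrix(hkl)) d[1] else d
}

#' Fractional-to-Cartesian orthogonalization matrix
#'
#' Returns the 3x3 matrix M such that `r_cart = M %*% x_frac` (Angstrom).
#' Convention: Cartesian x along the a axis, y in the a-b plane, z
#' completing the right-handed set.  Shape orientations (declination from
#' z, azimuth from x in the x-y plane) refer to this frame.
#'
#' @param cell A [unit_cell()].
#' @return 3x3 numeric matrix with `t(M) %*% M == G`.
#' @export
orthogonalization_matrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           cell$c * v / sg),
         3, 3, byrow = TRUE)
}

#' Cartesian distance between two fractional positions
#'
#' @param cell A [unit_cell()].
#' @param x1,x2 Fractional coordinate triples.
#' @return Distance in Angstrom (no periodic imaging; fixtures keep bonded
#'   atoms within one cell).
#' @export
frac_distance <- function(cell, x1, x2) {
  d <- as.numeric(x1) - as.numeric(x2)
  sqrt(drop(t(d) %*% direct_metric(cell) %*% d))
}
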