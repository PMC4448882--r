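#' Atom site
#'
#' @param label Unique site label (e.g. `"C1"`).
#' @param element Element symbol; must have a scattering-factor entry.
#' @param xyz Fractional coordinates (length 3).
#' @param occ Occupancy in (0, 1].
#' @param uiso Isotropic displacement parameter in A^2 (ignored if `uaniso`
#'   given).
#' @param uaniso Optional length-6 anisotropic ADP `(U11,U22,U33,U12,U13,U23)`
#'   in the CIF U convention, A^2.
#' @return Object of class `atom_site`.
#' @export
atom_site <- function(label, element, xyz, occ = 1, uiso = 0.03, uaniso = NULL) {
  stopifnot(length(xyz) == 3)
  if (!is.null(uaniso) && length(uaniso) != 6)
    stop("uaniso must have 6 components (U11,U22,U33,U12,U13,U23)", call. = FALSE)
  if (occ <= 0 || occ > 1)
    stop("occupancy must lie in (0, 1]: ", label, call. = FALSE)
  if (is.null(uaniso) && uiso < 0)
    stop("u_iso must be >= 0: ", label, call. = FALSE)
  structure(list(label = as.character(label), element = as.character(element),
                 xyz = as.numeric(xyz), occ = occ,
                 adp_type = if (is.null(uaniso)) "iso" else "aniso",
                 uiso = uiso, uaniso = if (is.null(uaniso)) NULL else as.numeric(uaniso)),
            class = "atom_site")
}

#' Special-shape site
#'
#' A non-atomic scattering density modelling a severely disordered group:
#' a spherical shell (e.g. PF6 fluorines), a line (solvent in a channel)
#' or a torus (librating CF3, Cp or benzene rings).
#'
#' @param label Unique site label.
#' @param kind One of `"shell"`, `"line"`, `"torus"`.
#' @param xyz Fractional coordinates of the centroid.
#' @param element Element symbol of the smeared scatterer.
#' @param multiplicity Number of atoms smeared onto the shape (>= 1).
#' @param magnitude Radius in A (shell, torus) or full length in A (line).
#' @param declination Angle in degrees between the line axis / torus normal
#'   and the Cartesian z axis (see [orthogonalization_matrix()]); ignored
#'   for shells.
#' @param azimuth Angle in degrees between the projection of the axis onto
#'   the x-y plane and the x axis; ignored for shells.
#' @param uiso Isotropic displacement parameter of the smeared density, A^2.
#' @param occ Occupancy.
#' @return Object of class `shape_site`.
#' @export
shape_site <- function(label, kind, xyz, element, multiplicity, magnitude,
                       declination = 0, azimuth = 0, uiso = 0.05, occ = 1) {
  kind <- match.arg(kind, c("shell", "line", "torus"))
  if (magnitude <= 0) stop("shape magnitude must be > 0: ", label, call. = FALSE)
  if (declination < 0 || declination > 180)
    stop("declination must lie in [0, 180]: ", label, call. = FALSE)
  azimuth <- azimuth %% 360
  if (multiplicity < 1) stop("multiplicity must be >= 1: ", label, call. = FALSE)
  structure(list(label = as.character(label), kind = kind, xyz = as.numeric(xyz),
                 element = as.character(element), multiplicity = multiplicity,
                 magnitude = magnitude, declination = declination,
                 azimuth = azimuth, uiso = uiso, occ = occ),
            class = "shape_site")
}

#' Crystal model
#'
#' Container for a unit cell, an explicit symmetry-operator list, atom
#' sites, optional special-shape sites and the overall scale factor.
#'
#' @param cell A [unit_cell()].
#' @param symops List of [symop()] (default: P1 identity only).
#' @param atoms List of [atom_site()].
#' @param shapes List of [shape_site()].
#' @param scale Overall scale applied to calculated structure factors.
#' @return Object of class `crystal_model`.
#' @export
crystal_model <- function(cell, symops = spacegroup_symops("P1"),
                          atoms = list(), shapes = list(), scale = 1) {
  labels <- c(vapply(atoms, `[[`, "", "label"), vapply(shapes, `[[`, "", "label"))
  if (anyDuplicated(labels))
    stop("duplicate site labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "), call. = FALSE)
  structure(list(cell = cell, symops = symops, atoms = atoms, shapes = shapes,
                 scale = scale), class = "crystal_model")
}

#' @export
print.crystal_model <- function(x, ...) {
  cat(sprintf("crystal model: %d atom sites, %d shape sites, %d symmetry ops, scale %.4g\n",
              length(x$atoms), length(x$shapes), length(x$symops), x$scale))
  print(x$cell)
  invisible(x)
}

#' Labels of all sites in a model
#' @param model A [crystal_model()].
#' @return Character vector (atoms first, then shapes).
#' @export
site_labels <- function(model) {
  c(vapply(model$atoms, `[[`, "", "label"),
    vapply(model$shapes, `[[`, "", "label"))
}

#' Index of an atom site by label
#' @param model A [crystal_model()].
#' @param label Site label.
#' @return Integer index into `model$atoms`; error if absent.
#' @export
find_atom <- function(model, label) {
  i <- match(label, vapply(model$atoms, `[[`, "", "label"))
  if (is.na(i)) stop("no atom site labelled '", label, "'", call. = FALSE)
  i
}

# ---- ADP conversions ------------------------------------------------------

# CIF Uij (vector U11,U22,U33,U12,U13,U23) -> symmetric 3x3 matrix
uij_to_matrix <- function(u) {
  matrix(c(u[1], u[4], u[5],
           u[4], u[2], u[6],
           u[5], u[6], u[3]), 3, 3)
}

matrix_to_uij <- function(U) c(U[1, 1], U[2, 2], U[3, 3], U[1, 2], U[1, 3], U[2, 3])

# reciprocal cell lengths a*, b*, c*
recip_lengths <- function(cell) sqrt(diag(metric_tensors(cell)$Gstar))

#' Cartesian ADP tensor of a site
#'
#' Converts a site's displacement parameters to a Cartesian 3x3 tensor
#' (A^2).  Isotropic sites give `uiso * I`.  The CIF U convention is
#' `U_cart = M N U_cif N t(M)` with `N = diag(a*, b*, c*)` and `M` the
#' orthogonalization matrix.
#'
#' @param site An [atom_site()].
#' @param cell The [unit_cell()].
#' @return 3x3 symmetric matrix.
#' @export
u_cartesian <- function(site, cell) {
  if (site$adp_type == "iso") return(diag(site$uiso, 3))
  M <- orthogonalization_matrix(cell)
  N <- diag(recip_lengths(cell))
  M %*% N %*% uij_to_matrix(site$uaniso) %*% N %*% t(M)
}

#' Equivalent isotropic displacement parameter
#'
#' `U_eq = trace(U_cart) / 3`; equals `u_iso` for isotropic sites.
#'
#' @inheritParams u_cartesian
#' @return U_eq in A^2.
#' @export
u_equiv <- function(site, cell) {
  if (site$adp_type == "iso") site$uiso else sum(diag(u_cartesian(site, cell))) / 3
}

# express an isotropic u as a CIF Uij vector with U_cart = u * I
iso_as_uij <- function(u, cell) {
  M <- orthogonalization_matrix(cell)
  N <- diag(recip_lengths(cell))
  A <- solve(N) %*% solve(M)
  matrix_to_uij(u * A %*% t(A))
}

# ---- connectivity ---------------------------------------------------------

#' Bond list container
#'
#' A connectivity is a two-column character matrix of bonded label pairs.
#'
#' @param pairs Character vector of length 2*k, or a k x 2 matrix.
#' @return k x 2 character matrix of class `connectivity`.
#' @export
connectivity <- function(pairs) {
  m <- if (is.matrix(pairs)) pairs else matrix(pairs, ncol = 2, byrow = TRUE)
  structure(m, class = c("connectivity", class(m)))
}

bonded_neighbors <- function(conn, label) {
  unique(c(conn[conn[, 1] == label, 2], conn[conn[, 2] == label, 1]))
}
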