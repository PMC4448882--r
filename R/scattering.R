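#' Debye-Waller attenuation factor
#'
#' Isotropic: `exp(-8 pi^2 u_iso s^2)`.  Anisotropic (CIF U convention):
#' `exp(-2 pi^2 sum_ij U_ij h_i h_j a*_i a*_j)`.
#'
#' @param site An [atom_site()] (isotropic or anisotropic).
#' @param hkl Integer triple or n x 3 matrix.
#' @param cell The [unit_cell()].
#' @return Attenuation in (0, 1] (vector for matrix input).
#' @export
debye_waller <- function(site, hkl, cell) {
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, 1, 3)
  if (site$adp_type == "iso") {
    d <- d_spacing(cell, h)
    out <- exp(-2 * pi^2 * site$uiso / d^2)
  } else {
    ev <- eigen(u_cartesian(site, cell), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10)
      warning("anisotropic ADP of ", site$label,
              " is not positive semi-definite (non-physical)", call. = FALSE)
    hs <- h * matrix(recip_lengths(cell), nrow(h), 3, byrow = TRUE)
    u <- site$uaniso
    quad <- hs[, 1]^2 * u[1] + hs[, 2]^2 * u[2] + hs[, 3]^2 * u[3] +
      2 * (hs[, 1] * hs[, 2] * u[4] + hs[, 1] * hs[, 3] * u[5] +
           hs[, 2] * hs[, 3] * u[6])
    out <- exp(-2 * pi^2 * quad)
  }
  if (!is.matrix(hkl)) out[1] else out
}

# shape axis (unit Cartesian) from declination/azimuth in degrees
shape_axis <- function(declination, azimuth) {
  d <- declination * pi / 180
  a <- azimuth * pi / 180
  c(sin(d) * cos(a), sin(d) * sin(a), cos(d))
}

# sin(x)/x with series fallback near 0
.sinc <- function(x) ifelse(abs(x) < 1e-6, 1 - x^2 / 6, sin(x) / x)

#' Special-shape smearing factor
#'
#' The Fourier transform of the idealized uniform density of a special
#' shape, evaluated at the Cartesian scattering vector `q` (`|q| = 2 pi/d`):
#' spherical shell of radius R, `sin(qR)/(qR)`; line of full length L and
#' axis n, `sin(q.n L/2)/(q.n L/2)`; ideal ring torus of radius R and
#' normal n, `J0(R |q_perp|)`.  All are 1 at `q = 0`.
#'
#' @param shape A [shape_site()].
#' @param q_cart Cartesian scattering vector(s) in 1/A: length-3 vector or
#'   n x 3 matrix.
#' @param axis Optional unit axis overriding the shape's
#'   declination/azimuth (used after symmetry rotation).
#' @return Smearing factor in `[-1, 1]`.
#' @export
shape_form_factor <- function(shape, q_cart, axis = NULL) {
  q <- if (is.matrix(q_cart)) q_cart else matrix(q_cart, 1, 3)
  if (is.null(axis)) axis <- shape_axis(shape$declination, shape$azimuth)
  out <- switch(shape$kind,
    shell = .sinc(sqrt(rowSums(q^2)) * shape$magnitude),
    line = .sinc(drop(q %*% axis) * shape$magnitude / 2),
    torus = {
      qpar <- drop(q %*% axis)
      qperp2 <- pmax(rowSums(q^2) - qpar^2, 0)
      besselJ(sqrt(qperp2) * shape$magnitude, 0)
    },
    stop("unknown shape kind: ", shape$kind, call. = FALSE))
  if (!is.matrix(q_cart)) out[1] else out
}

# ---- precomputed reflection geometry --------------------------------------

# everything about the hkl list that does not depend on model parameters
reflection_geometry <- function(model, hkl) {
  hkl <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  cell <- model$cell
  M <- orthogonalization_matrix(cell)
  Minv <- solve(M)
  d <- d_spacing(cell, hkl)
  sym <- lapply(model$symops, function(op) {
    Rc <- M %*% op$R %*% Minv  # Cartesian rotation for shape axes
    list(hR = hkl %*% op$R, pht = drop(hkl %*% op$t), Rc = Rc)
  })
  list(hkl = hkl, n = nrow(hkl), d = d, s = 1 / (2 * d),
       astar = recip_lengths(cell), qmat = 2 * pi * hkl %*% Minv, sym = sym)
}

# complex contribution of one atom site (and optionally its derivatives
# with respect to that site's quantities, in quantity_table order)
.atom_contrib <- function(site, geom, derivs = FALSE) {
  f <- atomic_form_factor(site$element, geom$s)
  n <- geom$n
  F <- complex(real = numeric(n))
  adp_names <- if (site$adp_type == "iso") "uiso" else
    c("u11", "u22", "u33", "u12", "u13", "u23")
  pn <- c("x", "y", "z", adp_names, "occ")
  dF <- if (derivs) matrix(0i, n, length(pn), dimnames = list(NULL, pn))
  for (sy in geom$sym) {
    phase <- 2 * pi * (drop(sy$hR %*% site$xyz) + sy$pht)
    e <- complex(argument = phase)
    if (site$adp_type == "iso") {
      dw <- exp(-2 * pi^2 * site$uiso / geom$d^2)
    } else {
      hs <- sy$hR * matrix(geom$astar, n, 3, byrow = TRUE)
      u <- site$uaniso
      quad <- hs[, 1]^2 * u[1] + hs[, 2]^2 * u[2] + hs[, 3]^2 * u[3] +
        2 * (hs[, 1] * hs[, 2] * u[4] + hs[, 1] * hs[, 3] * u[5] +
             hs[, 2] * hs[, 3] * u[6])
      dw <- exp(-2 * pi^2 * quad)
    }
    g <- site$occ * f * dw * e
    F <- F + g
    if (derivs) {
      tw0pi <- 2i * pi
      dF[, "x"] <- dF[, "x"] + tw0pi * sy$hR[, 1] * g
      dF[, "y"] <- dF[, "y"] + tw0pi * sy$hR[, 2] * g
      dF[, "z"] <- dF[, "z"] + tw0pi * sy$hR[, 3] * g
      if (site$adp_type == "iso") {
        dF[, "uiso"] <- dF[, "uiso"] - 2 * pi^2 / geom$d^2 * g
      } else {
        cfac <- c(1, 1, 1, 2, 2, 2)
        idx <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
        for (j in 1:6) {
          ii <- idx[[j]]
          dF[, adp_names[j]] <- dF[, adp_names[j]] -
            2 * pi^2 * cfac[j] * hs[, ii[1]] * hs[, ii[2]] * g
        }
      }
      dF[, "occ"] <- dF[, "occ"] + g / site$occ
    }
  }
  list(F = F, dF = dF)
}

# complex contribution of one shape site; the smeared density carries
# multiplicity * occ * f(s) * isotropic DW * shape transform
.shape_contrib_value <- function(shape, geom) {
  f <- atomic_form_factor(shape$element, geom$s)
  dw <- exp(-2 * pi^2 * shape$uiso / geom$d^2)
  F <- complex(real = numeric(geom$n))
  axis0 <- shape_axis(shape$declination, shape$azimuth)
  for (sy in geom$sym) {
    phase <- 2 * pi * (drop(sy$hR %*% shape$xyz) + sy$pht)
    ax <- drop(sy$Rc %*% axis0)
    ax <- ax / sqrt(sum(ax^2))
    sf <- shape_form_factor(shape, geom$qmat, axis = ax)
    F <- F + shape$occ * shape$multiplicity * f * dw * sf *
      complex(argument = phase)
  }
  F
}

.shape_contrib <- function(shape, geom, derivs = FALSE) {
  F <- .shape_contrib_value(shape, geom)
  if (!derivs) return(list(F = F, dF = NULL))
  pn <- c("x", "y", "z", "uiso", "magnitude", "declination", "azimuth", "occ")
  dF <- matrix(0i, geom$n, length(pn), dimnames = list(NULL, pn))
  # analytic: position, uiso, occ (shape transform independent of them)
  for (sy in geom$sym) {
    phase <- 2 * pi * (drop(sy$hR %*% shape$xyz) + sy$pht)
    ax <- drop(sy$Rc %*% shape_axis(shape$declination, shape$azimuth))
    ax <- ax / sqrt(sum(ax^2))
    g <- shape$occ * shape$multiplicity *
      atomic_form_factor(shape$element, geom$s) *
      exp(-2 * pi^2 * shape$uiso / geom$d^2) *
      shape_form_factor(shape, geom$qmat, axis = ax) *
      complex(argument = phase)
    dF[, "x"] <- dF[, "x"] + 2i * pi * sy$hR[, 1] * g
    dF[, "y"] <- dF[, "y"] + 2i * pi * sy$hR[, 2] * g
    dF[, "z"] <- dF[, "z"] + 2i * pi * sy$hR[, 3] * g
    dF[, "uiso"] <- dF[, "uiso"] - 2 * pi^2 / geom$d^2 * g
    dF[, "occ"] <- dF[, "occ"] + g / shape$occ
  }
  # magnitude / declination / azimuth: five-point central differences of the
  # shape contribution (avoids error-prone hand derivatives of Bessel terms)
  for (p in c("magnitude", "declination", "azimuth")) {
    h <- 1e-5
    vals <- lapply(c(-2, -1, 1, 2), function(k) {
      sh <- shape
      sh[[p]] <- sh[[p]] + k * h
      .shape_contrib_value(sh, geom)
    })
    dF[, p] <- (vals[[1]] - 8 * vals[[2]] + 8 * vals[[3]] - vals[[4]]) / (12 * h)
  }
  list(F = F, dF = dF)
}

#' Calculated structure factors
#'
#' Complex molecular structure factors
#' `Fc_mol(h) = scale * sum_sym sum_sites occ f(s) DW shape exp(2 pi i h.(Rx+t))`,
#' with an optional per-reflection complex disordered-solvent contribution
#' added before taking the modulus: `|Fc| = |Fc_mol + Fc_solvent|`.
#'
#' @param model A [crystal_model()].
#' @param hkl n x 3 integer matrix of Miller indices.
#' @param solvent Optional complex vector of length n (the solvent
#'   contribution, e.g. from [read_fab()]).
#' @return List of class `structure_factor_set`: `hkl`, `d`, `Fc_mol`,
#'   `Fc_solvent`, `Fc` (total complex), `Fabs` (`|Fc|`), `phase` (degrees).
#' @export
calc_structure_factors <- function(model, hkl, solvent = NULL) {
  geom <- reflection_geometry(model, hkl)
  if (is.null(solvent)) solvent <- complex(real = numeric(geom$n))
  if (length(solvent) != geom$n)
    stop("solvent contribution length (", length(solvent),
         ") does not match reflection count (", geom$n, ")", call. = FALSE)
  F <- complex(real = numeric(geom$n))
  for (a in model$atoms) F <- F + .atom_contrib(a, geom)$F
  for (s in model$shapes) F <- F + .shape_contrib(s, geom)$F
  Fmol <- model$scale * F
  Ftot <- Fmol + solvent
  structure(list(hkl = geom$hkl, d = geom$d, Fc_mol = Fmol,
                 Fc_solvent = solvent, Fc = Ftot, Fabs = Mod(Ftot),
                 phase = (Arg(Ftot) * 180 / pi) %% 360),
            class = "structure_factor_set")
}

#' Design matrix of the least-squares problem
#'
#' Computes `Yc` (either `|Fc|` or `|Fc|^2` per the refinement target) and
#' the n_reflections x n_free matrix of analytic derivatives
#' `dYc/dp`, folded through the parameter-map constraint chain (riding
#' hydrogens accumulate onto their parent's indices, shared ADPs onto the
#' leader's, and so on).
#'
#' @param model A [crystal_model()].
#' @param hkl n x 3 Miller index matrix.
#' @param pmap A [build_parameter_map()] result.
#' @param mode Refinement target: `"F2"` (default) or `"F"`.
#' @param solvent Optional complex solvent contribution (length n).
#' @return List with `Yc`, `A` (design matrix), `sf` (the
#'   `structure_factor_set`).
#' @export
design_matrix <- function(model, hkl, pmap, mode = c("F2", "F"),
                          solvent = NULL) {
  mode <- match.arg(mode)
  geom <- reflection_geometry(model, hkl)
  n <- geom$n
  if (is.null(solvent)) solvent <- complex(real = numeric(n))
  qt <- pmap$qtab
  dFq <- matrix(0i, n, nrow(qt))
  F <- complex(real = numeric(n))
  for (i in seq_along(model$atoms)) {
    ct <- .atom_contrib(model$atoms[[i]], geom, derivs = TRUE)
    F <- F + ct$F
    cols <- which(qt$site_type == "atom" & qt$site == i)
    dFq[, cols] <- ct$dF[, qt$param[cols], drop = FALSE]
  }
  for (i in seq_along(model$shapes)) {
    ct <- .shape_contrib(model$shapes[[i]], geom, derivs = TRUE)
    F <- F + ct$F
    cols <- which(qt$site_type == "shape" & qt$site == i)
    dFq[, cols] <- ct$dF[, qt$param[cols], drop = FALSE]
  }
  scale_col <- which(qt$param == "scale")
  dFq <- dFq * model$scale
  dFq[, scale_col] <- F
  Fmol <- model$scale * F
  Ftot <- Fmol + solvent
  # chain to the real-valued target
  if (mode == "F2") {
    dY <- 2 * (Re(Ftot) * Re(dFq) + Im(Ftot) * Im(dFq))
    Yc <- Mod(Ftot)^2
  } else {
    am <- Mod(Ftot)
    safe <- ifelse(am > 0, am, 1)
    dY <- (Re(Ftot) * Re(dFq) + Im(Ftot) * Im(dFq)) / safe
    dY[am == 0, ] <- 0
    Yc <- am
  }
  A <- dY %*% pmap$T
  colnames(A) <- pmap$free_names
  sf <- structure(list(hkl = geom$hkl, d = geom$d, Fc_mol = Fmol,
                       Fc_solvent = solvent, Fc = Ftot, Fabs = Mod(Ftot),
                       phase = (Arg(Ftot) * 180 / pi) %% 360),
                  class = "structure_factor_set")
  list(Yc = Yc, A = A, sf = sf)
}

#' Single design row
#'
#' Derivatives of one reflection's calculated quantity with respect to the
#' free parameters.
#'
#' @inheritParams design_matrix
#' @param hkl A single Miller index triple.
#' @return Named numeric vector of length `pmap$n_free`.
#' @export
design_row <- function(model, hkl, pmap, mode = c("F2", "F"), solvent = NULL) {
  dm <- design_matrix(model, matrix(hkl, 1, 3), pmap, mode, solvent)
  drop(dm$A)
}

#' Agreement statistics
#'
#' The minimisation function is `M = sum w (Yo - Yc)^2` where Y is either
#' F or F^2.  Also reports `R1 = sum ||Fo| - |Fc|| / sum |Fo|`, the
#' weighted R factor and the goodness of fit
#' `GoF = sqrt(M / (n_obs - n_params))`.
#'
#' @param Yo,Yc Observed and calculated quantities (F or F^2 per `mode`).
#' @param sigma Standard uncertainties of `Yo`.
#' @param weights Weights (default `1/sigma^2`).
#' @param n_params Number of refined parameters (for GoF).
#' @param mode `"F2"` or `"F"` (how to obtain |F| for R1).
#' @return List with `M`, `R1`, `wR`, `GoF` (NA when `n_obs <= n_params`),
#'   `n_obs`.
#' @export
agreement_statistics <- function(Yo, sigma, Yc, weights = NULL, n_params = 0,
                                 mode = c("F2", "F")) {
  mode <- match.arg(mode)
  if (is.null(weights)) weights <- 1 / sigma^2
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  r <- Yo - Yc
  M <- sum(weights * r^2)
  if (mode == "F2") {
    Fo <- sqrt(pmax(Yo, 0)); Fc <- sqrt(pmax(Yc, 0))
  } else {
    Fo <- abs(Yo); Fc <- abs(Yc)
  }
  R1 <- sum(abs(Fo - Fc)) / sum(Fo)
  wR <- sqrt(M / sum(weights * Yo^2))
  n <- length(Yo)
  GoF <- if (n > n_params) sqrt(M / (n - n_params)) else NA_real_
  list(M = M, R1 = R1, wR = wR, GoF = GoF, n_obs = n)
}
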