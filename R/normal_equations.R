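#' Accumulate the normal equations from reflection data
#'
#' Builds `N = A' W A` and `g = A' W (Yo - Yc)` by loading reflections in
#' batches: derivatives are computed into a partial design-matrix block and
#' the block is accumulated with one symmetric product per batch.  All
#' accumulation is in double precision; the result is independent of the
#' batch size.
#'
#' @param model A [crystal_model()].
#' @param reflections A `reflection_set` (see [reflection_set()]).
#' @param pmap A [build_parameter_map()] result (must have free parameters).
#' @param batch_size Reflections per block (>= 1).
#' @param mode Refinement target, `"F2"` or `"F"`.
#' @param weights `"sigma"` for `1/sigma^2`, `"unit"`, or a numeric vector.
#' @return Object of class `normal_equations`: `N`, `g`, `n_obs`,
#'   `n_restraints`, `Yc`, `Yo`, `sigma`, `w`, plus the free-parameter
#'   names.
#' @export
accumulate_normal_matrix <- function(model, reflections, pmap,
                                     batch_size = 64,
                                     mode = c("F2", "F"),
                                     weights = "sigma") {
  mode <- match.arg(mode)
  if (pmap$n_free == 0)
    stop("no free parameters: nothing to refine", call. = FALSE)
  stopifnot(batch_size >= 1)
  obs <- reflection_target(reflections, mode)
  n <- nrow(reflections$hkl)
  w <- if (is.numeric(weights)) weights
       else if (weights == "unit") rep(1, n)
       else 1 / obs$sigma^2
  solv <- reflections$solvent
  np <- pmap$n_free
  N <- matrix(0, np, np)
  g <- numeric(np)
  Yc <- numeric(n)
  starts <- seq(1, n, by = batch_size)
  for (s0 in starts) {
    ii <- s0:min(s0 + batch_size - 1, n)
    dm <- design_matrix(model, reflections$hkl[ii, , drop = FALSE], pmap,
                        mode = mode,
                        solvent = if (is.null(solv)) NULL else solv[ii])
    B <- dm$A
    wB <- B * w[ii]
    N <- N + crossprod(B, wB)
    g <- g + drop(crossprod(wB, obs$Yo[ii] - dm$Yc))
    Yc[ii] <- dm$Yc
  }
  dimnames(N) <- list(pmap$free_names, pmap$free_names)
  names(g) <- pmap$free_names
  structure(list(N = N, g = g, n_obs = n, n_restraints = 0,
                 Yo = obs$Yo, Yc = Yc, sigma = obs$sigma, w = w,
                 free_names = pmap$free_names, mode = mode),
            class = "normal_equations")
}

#' Accumulate restraint equations into the normal matrix
#'
#' Restraint design rows are very sparse (a distance restraint involves at
#' most six parameters), so each row is added one by one as a rank-one
#' update touching only its nonzero index pairs.
#'
#' @param ne A `normal_equations` object.
#' @param rows List of equation rows from [restraint_equations()].
#' @return Updated `normal_equations` with `restraint_ssq` (sum of squared
#'   weighted residuals) attached.
#' @export
accumulate_restraints <- function(ne, rows) {
  ssq <- if (is.null(ne$restraint_ssq)) 0 else ne$restraint_ssq
  np <- nrow(ne$N)
  for (row in rows) {
    if (length(row$idx) == 0) { ne$n_restraints <- ne$n_restraints + 1; next }
    if (any(row$idx < 1 | row$idx > np))
      stop("restraint row index out of range", call. = FALSE)
    ne$N[row$idx, row$idx] <- ne$N[row$idx, row$idx] +
      outer(row$vals, row$vals)
    ne$g[row$idx] <- ne$g[row$idx] - row$vals * row$residual
    ne$n_restraints <- ne$n_restraints + 1
    ssq <- ssq + row$residual^2
  }
  ne$restraint_ssq <- ssq
  ne
}

#' Diagonal preconditioning of the normal matrix
#'
#' Chooses the diagonal matrix `C` with `C_ii = 1/sqrt(N_ii)` so that
#' `N' = C N C` has all its diagonal elements equal to one, reducing the
#' loss of floating-point precision during the solve.  The inverse is
#' recovered as `N^-1 = C N'^-1 C`.  Parameters with a zero diagonal are
#' flagged undetermined and excluded (their row/column is replaced by the
#' identity and their gradient zeroed).
#'
#' @param ne A `normal_equations` object (or a bare symmetric matrix).
#' @return List with `Nprime`, `C` (diagonal vector), `gprime` (`C g`, if a
#'   gradient is present), `undetermined` (labels).
#' @export
precondition <- function(ne) {
  N <- if (inherits(ne, "normal_equations")) ne$N else ne
  g <- if (inherits(ne, "normal_equations")) ne$g else NULL
  d <- diag(N)
  active <- d > 0
  if (!any(active))
    stop("nothing to refine: all normal-matrix diagonal elements are zero",
         call. = FALSE)
  C <- ifelse(active, 1 / sqrt(d), 0)
  Np <- N * outer(C, C)
  und <- which(!active)
  for (i in und) { Np[i, ] <- 0; Np[, i] <- 0; Np[i, i] <- 1 }
  gp <- if (!is.null(g)) { gp <- C * g; gp[und] <- 0; gp }
  list(Nprime = Np, C = C, gprime = gp,
       undetermined = if (length(und)) colnames(N)[und] else character())
}

#' Condition object for a singular normal matrix
#' @noRd
.singular_error <- function(pivot, label, value) {
  stop(structure(class = c("microrefine_singular", "error", "condition"),
                 list(message = sprintf(
                   "singular normal matrix: pivot %d (%s) = %.3e; remove or constrain the degenerate parameter(s), or retry with method='eigen_filter'",
                   pivot, label, value),
                   call = NULL, pivot = pivot, label = label)))
}

# LDL' factorisation of a symmetric matrix (no pivoting; intended for the
# preconditioned unit-diagonal system).  Errors on a vanishing pivot.
.ldlt <- function(A, labels = NULL, tol = 1e-10) {
  n <- nrow(A)
  L <- diag(1, n)
  d <- numeric(n)
  scale <- max(abs(diag(A)), 1)
  for (j in seq_len(n)) {
    if (j > 1) {
      lj <- L[j, 1:(j - 1), drop = FALSE]
      d[j] <- A[j, j] - sum(lj^2 * d[1:(j - 1)])
    } else d[j] <- A[j, j]
    if (abs(d[j]) < tol * scale)
      .singular_error(j, if (is.null(labels)) sprintf("p%d", j) else labels[j],
                      d[j])
    if (j < n) {
      jj <- (j + 1):n
      if (j > 1) {
        L[jj, j] <- (A[jj, j] -
          (L[jj, 1:(j - 1), drop = FALSE] %*%
             (L[j, 1:(j - 1)] * d[1:(j - 1)]))) / d[j]
      } else L[jj, j] <- A[jj, j] / d[j]
    }
  }
  list(L = L, d = d)
}

.ldlt_solve <- function(fac, b) {
  y <- forwardsolve(fac$L, b)
  backsolve(t(fac$L), y / fac$d)
}

#' Solve the preconditioned normal equations
#'
#' `ldlt`: an LDL' factorisation solve that fails with a singular-matrix
#' error naming the offending pivot when the matrix is numerically rank
#' deficient.  `eigen_filter`: symmetric eigendecomposition in which
#' contributions from eigenvalues below `filter_tol * lambda_max` are
#' discarded (a pseudo-inverse), always returning finite shifts; the
#' degenerate parameter combinations simply receive no shift.
#'
#' @param Nprime Preconditioned symmetric matrix (unit diagonal).
#' @param gprime Preconditioned gradient.
#' @param method `"ldlt"` or `"eigen_filter"`.
#' @param filter_tol Relative eigenvalue cutoff for `eigen_filter`.
#' @param labels Parameter labels for error messages.
#' @return List with `shifts` (in the preconditioned space), `Ninv`
#'   (inverse of `Nprime`, pseudo-inverse for `eigen_filter`), `method`,
#'   `n_filtered`.
#' @export
solve_normal_equations <- function(Nprime, gprime,
                                   method = c("ldlt", "eigen_filter"),
                                   filter_tol = 1e-8, labels = NULL) {
  method <- match.arg(method)
  if (max(abs(Nprime - t(Nprime))) > 1e-8 * max(abs(Nprime)))
    stop("normal matrix is not symmetric", call. = FALSE)
  if (is.null(labels)) labels <- colnames(Nprime)
  if (method == "ldlt") {
    fac <- .ldlt(Nprime, labels = labels)
    shifts <- .ldlt_solve(fac, gprime)
    Ninv <- apply(diag(1, nrow(Nprime)), 2, function(e) .ldlt_solve(fac, e))
    list(shifts = drop(shifts), Ninv = (Ninv + t(Ninv)) / 2,
         method = method, n_filtered = 0L)
  } else {
    e <- eigen(Nprime, symmetric = TRUE)
    keep <- e$values > filter_tol * max(e$values)
    Vk <- e$vectors[, keep, drop = FALSE]
    inv_l <- 1 / e$values[keep]
    Ninv <- Vk %*% (inv_l * t(Vk))
    list(shifts = drop(Ninv %*% gprime), Ninv = Ninv, method = method,
         n_filtered = sum(!keep))
  }
}

#' Multicollinearity diagnostics of the normal matrix
#'
#' Reports the condition number `lambda_max/lambda_min` (infinite when the
#' smallest eigenvalue is non-positive) and, for each of the `k` smallest
#' eigenpairs, the parameter labels with the largest eigenvector
#' components: these name the near-collinear parameter combination (e.g.
#' two unconstrained occupancies of scatterers sharing a site).
#'
#' @param Nprime Preconditioned symmetric normal matrix.
#' @param k Number of small eigenpairs to report.
#' @param labels Parameter labels (default: column names).
#' @param n_top Labels reported per eigenvector.
#' @return List with `condition_number`, `eigenvalues`, `small_modes`
#'   (each: `eigenvalue`, `labels`, `loadings`).
#' @export
condition_diagnostics <- function(Nprime, k = 3, labels = NULL, n_top = 4) {
  if (is.null(labels)) labels <- colnames(Nprime)
  if (is.null(labels)) labels <- sprintf("p%d", seq_len(nrow(Nprime)))
  e <- eigen(Nprime, symmetric = TRUE)
  lmin <- min(e$values); lmax <- max(e$values)
  cond <- if (lmin <= 0) Inf else lmax / lmin
  nk <- min(k, length(e$values))
  modes <- lapply(seq_len(nk), function(j) {
    col <- length(e$values) - j + 1  # eigen() sorts decreasing
    v <- e$vectors[, col]
    ord <- order(abs(v), decreasing = TRUE)[seq_len(min(n_top, length(v)))]
    list(eigenvalue = e$values[col], labels = labels[ord], loadings = v[ord])
  })
  list(condition_number = cond, eigenvalues = e$values, small_modes = modes)
}
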