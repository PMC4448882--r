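#' Refinement configuration
#'
#' @param mode Refinement target: `"F2"` (default) or `"F"`.
#' @param weights `"sigma"` (`1/sigma^2`, default) or `"unit"`.
#' @param batch_size Reflections per design-matrix block.
#' @param max_cycles Maximum least-squares cycles.
#' @param tol Convergence: stop when `max |shift|/esd < tol`.
#' @param solver `"ldlt"` or `"eigen_filter"`.
#' @param filter_tol Relative eigenvalue cutoff for the filtering solver.
#' @param shift_limit Optional sigma of shift-limiting restraints applied
#'   to every parameter each cycle (`NULL` = no damping).
#' @param fix_origin Add [floating_origin_rows()] automatically in polar
#'   space groups (default `TRUE`).
#' @return List of class `refine_config`.
#' @export
refine_config <- function(mode = c("F2", "F"), weights = "sigma",
                          batch_size = 64, max_cycles = 20, tol = 0.01,
                          solver = c("ldlt", "eigen_filter"),
                          filter_tol = 1e-8, shift_limit = NULL,
                          fix_origin = TRUE) {
  structure(list(mode = match.arg(mode), weights = weights,
                 batch_size = batch_size, max_cycles = max_cycles, tol = tol,
                 solver = match.arg(solver), filter_tol = filter_tol,
                 shift_limit = shift_limit, fix_origin = fix_origin),
            class = "refine_config")
}

#' Floating-origin restraint rows
#'
#' In polar space groups the structure can translate along one or more
#' lattice directions without changing any `|Fc|` (in P1 all three), which
#' makes the normal matrix exactly rank deficient.  The floating
#' directions are the common fixed subspace of the symmetry rotations
#' (`R v = v` for every operator).  One restraint row per floating
#' direction pins the scattering-power-weighted collective shift: residual
#' zero, so relative geometry is never biased, only the origin drift is
#' removed.
#'
#' @param model A [crystal_model()].
#' @param pmap A [build_parameter_map()] result.
#' @param sigma Restraint sigma (dimensionless shift scale).
#' @return List of equation rows (possibly empty), as for
#'   [restraint_equations()].
#' @export
floating_origin_rows <- function(model, pmap, sigma = 0.005) {
  stack <- do.call(rbind, lapply(model$symops, function(op) op$R - diag(3)))
  sv <- svd(stack)
  float <- sv$v[, sv$d < 1e-9, drop = FALSE]
  if (ncol(float) == 0) return(list())
  qt <- pmap$qtab
  rows <- list()
  for (j in seq_len(ncol(float))) {
    v <- float[, j]
    qids <- integer(); qvals <- numeric()
    for (i in seq_along(model$atoms)) {
      z <- atomic_form_factor(model$atoms[[i]]$element, 0)
      for (ax in 1:3) {
        if (abs(v[ax]) < 1e-12) next
        qids <- c(qids, which(qt$site_type == "atom" & qt$site == i &
                                qt$param == c("x", "y", "z")[ax]))
        qvals <- c(qvals, z * v[ax])
      }
    }
    for (i in seq_along(model$shapes)) {
      s <- model$shapes[[i]]
      z <- s$multiplicity * atomic_form_factor(s$element, 0)
      for (ax in 1:3) {
        if (abs(v[ax]) < 1e-12) next
        qids <- c(qids, which(qt$site_type == "shape" & qt$site == i &
                                qt$param == c("x", "y", "z")[ax]))
        qvals <- c(qvals, z * v[ax])
      }
    }
    fr <- .fold_row(pmap, qids, qvals / sigma)
    if (length(fr$idx))
      rows[[length(rows) + 1]] <- list(residual = 0, idx = fr$idx,
                                       vals = fr$vals, value = 0)
  }
  rows
}

#' Least-squares structure refinement
#'
#' Minimises `M = sum w (Yo - Yc)^2` (Y either F or F^2), with restraints
#' sharing the objective on the `1/sigma^2` weight scale.  Each cycle:
#' structure factors and design rows are accumulated batch-wise into the
#' normal equations, restraints are accumulated one by one, the matrix is
#' preconditioned to unit diagonal, solved (LDL' or eigenvalue filtering),
#' and the shifts are applied through the constraint chain (riding
#' hydrogens follow their parents, shared ADPs their leader).
#'
#' Parameter esds are `GoF * sqrt(diag(N^-1))` with the inverse recovered
#' through the preconditioner (`N^-1 = C N'^-1 C`); the GoF here uses the
#' restraint-augmented residual and observation count.
#'
#' @param model A [crystal_model()] starting model.
#' @param reflections A [reflection_set()].
#' @param restraints An expanded [restraint_set()], or `NULL`.
#' @param config A [refine_config()].
#' @param pmap Optional pre-built [build_parameter_map()]; otherwise built
#'   with `constraints`.
#' @param constraints Constraint list for [build_parameter_map()].
#' @return Object of class `refinement_result`: `model`, `history` (per
#'   cycle: M, R1, GoF, max shift/esd), `converged`, `status`
#'   (`"converged"`, `"max_cycles"`, `"diverged"`, `"no_cycles"`), `esd`
#'   (named, free parameters), `esd_quantities` (per model quantity),
#'   `stats` (final agreement statistics), `diagnostics` (condition
#'   report), `pmap`.
#' @export
refine <- function(model, reflections, restraints = NULL,
                   config = refine_config(), pmap = NULL,
                   constraints = list()) {
  if (is.null(pmap)) pmap <- build_parameter_map(model, constraints)
  if (pmap$n_free == 0) stop("no free parameters", call. = FALSE)
  n_restr <- if (is.null(restraints)) 0 else length(restraints)
  if (nrow(reflections$hkl) < pmap$n_free && n_restr == 0)
    warning("fewer observations than parameters and no restraints: ",
            "the normal matrix is rank deficient", call. = FALSE)
  model <- refresh_riders(model, pmap)

  history <- data.frame()
  status <- "no_cycles"
  rising <- 0L
  prev_M <- Inf
  esd_free <- rep(NA_real_, pmap$n_free)
  diag_report <- NULL
  Ninv <- NULL

  for (cycle in seq_len(max(config$max_cycles, 0))) {
    ne <- accumulate_normal_matrix(model, reflections, pmap,
                                   batch_size = config$batch_size,
                                   mode = config$mode,
                                   weights = config$weights)
    rows <- if (n_restr > 0) restraint_equations(restraints, model, pmap)
            else list()
    if (!is.null(config$shift_limit))
      rows <- c(rows, shift_limit_equations(pmap, config$shift_limit))
    if (isTRUE(config$fix_origin))
      rows <- c(rows, floating_origin_rows(model, pmap))
    ne <- accumulate_restraints(ne, rows)

    st <- agreement_statistics(ne$Yo, ne$sigma, ne$Yc, weights = ne$w,
                               n_params = pmap$n_free, mode = config$mode)
    M_aug <- st$M + if (is.null(ne$restraint_ssq)) 0 else ne$restraint_ssq
    dof <- ne$n_obs + ne$n_restraints - pmap$n_free
    gof_aug <- if (dof > 0) sqrt(M_aug / dof) else 1

    pc <- precondition(ne)
    sol <- solve_normal_equations(pc$Nprime, pc$gprime,
                                  method = config$solver,
                                  filter_tol = config$filter_tol,
                                  labels = pmap$free_names)
    shifts <- pc$C * sol$shifts
    Ninv <- outer(pc$C, pc$C) * sol$Ninv     # N^-1 = C N'^-1 C
    esd_free <- gof_aug * sqrt(pmax(diag(Ninv), 0))
    shift_esd <- abs(shifts) / pmax(esd_free, 1e-12)
    max_se <- max(shift_esd)
    diag_report <- condition_diagnostics(pc$Nprime, labels = pmap$free_names)

    history <- rbind(history, data.frame(
      cycle = cycle, M = M_aug, M_data = st$M, R1 = st$R1, GoF = gof_aug,
      max_shift_esd = max_se))

    if (M_aug > prev_M * (1 + 1e-6)) rising <- rising + 1L else rising <- 0L
    if (rising >= 3L) {
      status <- "diverged"
      warning(sprintf(
        "refinement diverging: objective rose for 3 consecutive cycles (M = %.6g)",
        M_aug), call. = FALSE)
      break
    }
    prev_M <- M_aug

    model <- apply_shifts(model, pmap, shifts)

    if (max_se < config$tol) { status <- "converged"; break }
    # perfect-fit guard: at M ~ 0 the esds collapse and shift/esd becomes
    # ill-defined, but vanishing absolute shifts mean convergence
    qv <- get_quantities(model)[pmap$free_qids]
    if (max(abs(shifts) / pmax(abs(qv), 1)) < 1e-9) {
      status <- "converged"; break
    }
    status <- "max_cycles"
  }

  # final statistics on the updated model
  sf_args <- list(model = model, hkl = reflections$hkl,
                  solvent = reflections$solvent)
  sf <- do.call(calc_structure_factors, sf_args)
  obs <- reflection_target(reflections, config$mode)
  Yc <- if (config$mode == "F2") sf$Fabs^2 else sf$Fabs
  w <- if (is.numeric(config$weights)) config$weights
       else if (identical(config$weights, "unit")) rep(1, length(Yc))
       else 1 / obs$sigma^2
  stats <- agreement_statistics(obs$Yo, obs$sigma, Yc, weights = w,
                                n_params = pmap$n_free, mode = config$mode)

  names(esd_free) <- pmap$free_names
  esd_q <- if (!is.null(Ninv)) {
    g <- sqrt(pmax(rowSums((pmap$T %*% Ninv) * pmap$T), 0))
    stats_gof <- if (nrow(history)) history$GoF[nrow(history)] else 1
    v <- stats_gof * g
    names(v) <- pmap$qtab$qname
    v
  } else NULL

  structure(list(model = model, history = history,
                 converged = identical(status, "converged"), status = status,
                 esd = esd_free, esd_quantities = esd_q, stats = stats,
                 structure_factors = sf, diagnostics = diag_report,
                 pmap = pmap, n_obs = nrow(reflections$hkl),
                 n_restraints = n_restr),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("refinement: %s after %d cycle(s)\n", x$status,
              nrow(x$history)))
  cat(sprintf("  %d observations, %d restraints, %d free parameters\n",
              x$n_obs, x$n_restraints, x$pmap$n_free))
  cat(sprintf("  final R1 = %.6g, wR = %.6g, GoF(data) = %.4g\n",
              x$stats$R1, x$stats$wR, x$stats$GoF))
  if (nrow(x$history)) {
    cat("  cycle log:\n")
    print(x$history, row.names = FALSE)
  }
  invisible(x)
}
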