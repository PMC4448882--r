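make_engine_fixture <- function() {
  fx <- make_fixture("random_structure", seed = 3, n_atoms = 5, n_aniso = 2,
                     sg = "P-1")
  rs <- simulate_observations(fx$model, d_min = 1.6, noise_frac = 0.02,
                              seed = 4)
  list(m = fx$model, rs = rs, pm = build_parameter_map(fx$model))
}

test_that("normal-matrix accumulation is exact and batch-invariant", {
  fx <- make_engine_fixture()
  # single reflection: rank-one outer product
  one <- reflection_set(matrix(c(2, 1, 3), 1), 40, 2)
  ne1 <- accumulate_normal_matrix(fx$m, one, fx$pm, batch_size = 1)
  a <- design_row(fx$m, c(2, 1, 3), fx$pm)
  w <- 1 / 4
  expect_equal(ne1$N, w * outer(a, a), tolerance = 1e-12, ignore_attr = TRUE)

  sub <- reflection_set(fx$rs$hkl[1:200, ], fx$rs$Fsq[1:200],
                        fx$rs$sigma[1:200])
  neA <- accumulate_normal_matrix(fx$m, sub, fx$pm, batch_size = 1)
  neB <- accumulate_normal_matrix(fx$m, sub, fx$pm, batch_size = 64)
  expect_lt(max(abs(neA$N - neB$N)) / max(abs(neA$N)), 1e-10)
  expect_lt(max(abs(neA$g - neB$g)) / max(abs(neA$g)), 1e-10)
  expect_lt(max(abs(neA$N - t(neA$N))), 1e-12 * max(abs(neA$N)))

  # dense-product oracle: naive A' W A on 200 reflections
  dm <- design_matrix(fx$m, sub$hkl, fx$pm)
  W <- diag(1 / sub$sigma^2)
  No <- t(dm$A) %*% W %*% dm$A
  go <- drop(t(dm$A) %*% W %*% (sub$Fsq - dm$Yc))
  expect_lt(max(abs(neA$N - No)) / max(abs(No)), 1e-10)
  expect_lt(max(abs(neA$g - go)) / max(abs(go)), 1e-10)

  empty_pm <- build_parameter_map(fx$m, refine = character())
  expect_error(accumulate_normal_matrix(fx$m, sub, empty_pm), "no free")
})

test_that("restraints accumulate sparsely, one by one", {
  fx <- make_engine_fixture()
  sub <- reflection_set(fx$rs$hkl[1:100, ], fx$rs$Fsq[1:100],
                        fx$rs$sigma[1:100])
  ne <- accumulate_normal_matrix(fx$m, sub, fx$pm)
  ne_same <- accumulate_restraints(ne, list())
  expect_equal(ne_same$N, ne$N)

  # a distance-restraint row touches at most a 6x6 sub-block
  r <- restraint("DISTANCE",
                 c(fx$m$atoms[[1]]$label, fx$m$atoms[[2]]$label), 2, 0.05)
  eq <- restraint_equation(r, fx$m, fx$pm)
  ne_r <- accumulate_restraints(ne, list(eq))
  changed <- which(abs(ne_r$N - ne$N) > 0, arr.ind = TRUE)
  expect_lte(length(unique(changed[, 1])), 6)
  expect_equal(ne_r$n_restraints, 1)

  # sparse accumulation equals the dense outer-product oracle on 50 rows
  set.seed(7)
  rows <- lapply(1:50, function(i) {
    idx <- sort(sample(fx$pm$n_free, sample(2:6, 1)))
    list(residual = rnorm(1), idx = idx, vals = rnorm(length(idx)))
  })
  ne_s <- accumulate_restraints(ne, rows)
  Nd <- ne$N; gd <- ne$g
  for (row in rows) {
    dense <- numeric(fx$pm$n_free); dense[row$idx] <- row$vals
    Nd <- Nd + outer(dense, dense)
    gd <- gd - dense * row$residual
  }
  expect_equal(ne_s$N, Nd, tolerance = 1e-12)
  expect_equal(ne_s$g, gd, tolerance = 1e-12)
  bad <- list(list(residual = 0, idx = fx$pm$n_free + 1, vals = 1))
  expect_error(accumulate_restraints(ne, bad), "out of range")

  # order invariance
  ne_p <- accumulate_restraints(ne, rev(rows))
  expect_lt(max(abs(ne_p$N - ne_s$N)) / max(abs(ne_s$N)), 1e-10)
})

test_that("preconditioning gives unit diagonal and recovers the inverse", {
  expect_equal(precondition(diag(3))$Nprime, diag(3))
  pc <- precondition(diag(c(4, 25)))
  expect_equal(pc$C, c(0.5, 0.2))
  expect_equal(pc$Nprime, diag(2))

  set.seed(11)
  A <- crossprod(matrix(rnorm(1600), 40)) + diag(40)
  pc <- precondition(A)
  expect_lt(max(abs(diag(pc$Nprime) - 1)), 1e-12)
  sol <- solve_normal_equations(pc$Nprime, rep(0, 40))
  Ninv <- outer(pc$C, pc$C) * sol$Ninv
  expect_lt(max(abs(Ninv - solve(A))) / max(abs(solve(A))), 1e-8)

  # zero-diagonal parameter flagged undetermined, not fatal
  Az <- A; Az[5, ] <- 0; Az[, 5] <- 0
  colnames(Az) <- paste0("p", 1:40)
  pz <- precondition(Az)
  expect_equal(pz$undetermined, "p5")
  expect_error(precondition(matrix(0, 2, 2)), "nothing to refine")
})

test_that("solvers honor their contracts", {
  b <- c(1, -2, 0.5)
  expect_equal(solve_normal_equations(diag(3), b)$shifts, b)
  set.seed(13)
  A <- crossprod(matrix(rnorm(900), 30)) + diag(30)
  pc <- precondition(A)
  g <- rnorm(30)
  sol <- solve_normal_equations(pc$Nprime, pc$C * g)
  x <- pc$C * sol$shifts
  expect_lt(max(abs(x - solve(A, g))) / max(abs(x)), 1e-8)

  # constructed degeneracy: two perfectly collinear parameters
  B <- matrix(rnorm(100), 20, 5); B[, 5] <- B[, 4]
  Nd <- crossprod(B)
  pcd <- precondition(Nd)
  err <- tryCatch(solve_normal_equations(pcd$Nprime, rep(0.1, 5),
                                         labels = paste0("p", 1:5)),
                  error = function(e) e)
  expect_s3_class(err, "microrefine_singular")
  expect_match(conditionMessage(err), "p[45]")
  ef <- solve_normal_equations(pcd$Nprime, rep(0.1, 5),
                               method = "eigen_filter")
  expect_true(all(is.finite(ef$shifts)))
  expect_equal(ef$n_filtered, 1L)
  # the collinear combination (p4 - p5 direction) receives no shift
  null_dir <- c(0, 0, 0, 1, -1) / sqrt(2)
  expect_lt(abs(sum(ef$shifts * null_dir)), 1e-10)
  expect_error(solve_normal_equations(matrix(c(1, 2, 0, 1), 2), c(1, 1)),
               "symmetric")
})

test_that("refinement recovers a perturbed structure from noiseless data", {
  fx <- make_fixture("random_structure", seed = 3, n_atoms = 5, n_aniso = 2,
                     sg = "P-1")
  rs <- simulate_observations(fx$model, d_min = 1.3, noise_frac = 0, seed = 1)
  start <- perturb_model(fx$model, 0.02, seed = 9)
  res <- refine(start, rs, config = refine_config(max_cycles = 15))
  expect_equal(res$status, "converged")
  expect_lt(res$stats$R1, 1e-6)
  pm <- res$pmap
  dev <- abs(get_quantities(res$model) - get_quantities(fx$model))
  expect_lt(max(dev[pm$qtab$param %in% c("x", "y", "z")]), 1e-5)
  # objective non-increasing on this well-posed noiseless run
  expect_true(all(diff(res$history$M) <= 1e-8 * res$history$M[1]))
})

test_that("zero cycles returns the model unchanged with statistics", {
  fx <- make_engine_fixture()
  res <- refine(fx$m, fx$rs, config = refine_config(max_cycles = 0))
  expect_equal(res$status, "no_cycles")
  expect_equal(get_quantities(res$model), get_quantities(fx$m))
  expect_true(is.finite(res$stats$R1))
})

test_that("the preconditioner identity C N'^-1 C N = I holds on a solve", {
  fx <- make_engine_fixture()
  ne <- accumulate_normal_matrix(fx$m, fx$rs, fx$pm)
  pc <- precondition(ne)
  sol <- solve_normal_equations(pc$Nprime, pc$gprime)
  Ninv <- outer(pc$C, pc$C) * sol$Ninv
  expect_lt(max(abs(Ninv %*% ne$N - diag(fx$pm$n_free))), 1e-6)
})

test_that("refining on F and on F-squared find the same noiseless minimum", {
  fx <- make_fixture("random_structure", seed = 14, n_atoms = 3, sg = "P-1")
  rs <- simulate_observations(fx$model, d_min = 1.5, noise_frac = 0, seed = 2)
  start <- perturb_model(fx$model, 0.01, seed = 5)
  r2 <- refine(start, rs, config = refine_config(mode = "F2", max_cycles = 12))
  rf <- refine(start, rs, config = refine_config(mode = "F", max_cycles = 12))
  expect_lt(r2$stats$R1, 1e-6)
  expect_lt(rf$stats$R1, 1e-6)
  expect_equal(get_quantities(r2$model), get_quantities(rf$model),
               tolerance = 1e-6)
})

test_that("condition diagnostics report the collinear combination", {
  expect_equal(condition_diagnostics(diag(3))$condition_number, 1)
  expect_equal(condition_diagnostics(diag(c(100, 1)))$condition_number, 100)

  fx <- make_fixture("collinear_occupancy")
  rs <- simulate_observations(fx$model, d_min = 0.9, noise_frac = 0.02,
                              seed = 2)
  pm <- build_parameter_map(fx$model, fx$constraints)
  ne <- accumulate_normal_matrix(fx$model, rs, pm)
  dg <- condition_diagnostics(precondition(ne)$Nprime,
                              labels = pm$free_names)
  expect_setequal(dg$small_modes[[1]]$labels[1:2], c("CL1.occ", "K1.occ"))
  # occupancy-sum constraint removes the degeneracy
  pm2 <- build_parameter_map(fx$model,
                             c(fx$constraints, list(fx$occ_sum_constraint)))
  ne2 <- accumulate_normal_matrix(fx$model, rs, pm2)
  dg2 <- condition_diagnostics(precondition(ne2)$Nprime,
                               labels = pm2$free_names)
  expect_gt(dg$condition_number / dg2$condition_number, 10)
})
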