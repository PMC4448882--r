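test_that("restraint grammar parses and rejects malformed lines", {
  rs <- parse_restraints("DISTANCE 1.39, 0.01 = C1 TO C2")
  expect_equal(length(rs), 1)
  r <- rs$restraints[[1]]
  expect_equal(r$kind, "DISTANCE")
  expect_equal(r$target, 1.39)
  expect_equal(r$sigma, 0.01)
  expect_equal(r$atoms, c("C1", "C2"))

  expect_equal(length(parse_restraints("")), 0)
  expect_equal(length(parse_restraints("# only a comment\n! and another")), 0)
  expect_error(parse_restraints("DISTANCE 1.39, -0.01 = C1 TO C2"),
               "line 1.*sigma")
  expect_error(parse_restraints("WOBBLE 1, 1 = C1 TO C2"),
               "line 1.*unknown keyword")
  expect_error(parse_restraints("\nDISTANCE 1.39 = C1 TO C2"), "line 2")
  expect_error(parse_restraints("DISTANCE 1.39, 0.01 = C1 TO C9",
                                labels = c("C1", "C2")),
               "unknown atom label.*C9")
  multi <- parse_restraints(paste(
    "ANGLE 120, 0.5 = C1 TO C2 TO C3",
    "SIMU 0.04 = C1 C2",
    "DELU 0.01 = C1 TO C2, C2 TO C3",
    "LIMIT 0.05", sep = "\n"))
  kinds <- vapply(multi$restraints, `[[`, "", "kind")
  expect_equal(kinds, c("ANGLE", "SIMU_GROUP", "RIGID_BOND", "RIGID_BOND",
                        "LIMIT"))
})

test_that("SAME decomposition counts follow the target connectivity", {
  # two 2-atom groups, one bond: a single distance equivalence
  conn2 <- connectivity(c("A1", "A2"))
  ex2 <- expand_same(c("A1", "A2"), list(c("B1", "B2")), conn2)
  expect_equal(vapply(ex2$restraints, `[[`, "", "kind"), "EQUIV_DISTANCE")
  # 3-atom chain: two bonds and one 1-3 (angle-type) pair
  conn3 <- connectivity(c("A1", "A2", "A2", "A3"))
  ex3 <- expand_same(c("A1", "A2", "A3"), list(c("B1", "B2", "B3")), conn3)
  kinds <- vapply(ex3$restraints, `[[`, "", "kind")
  expect_equal(sum(kinds == "EQUIV_DISTANCE"), 2)
  expect_equal(sum(kinds == "EQUIV_ANGLE"), 1)
  expect_error(expand_same(c("A1", "A2"), list("B1"), conn2), "equal length")
  expect_error(expand_same(c("X1", "X2"), list(c("B1", "B2")), conn2),
               "connectivity")
})

test_that("the two-pyridine four-line SAME scheme expands to 48 restraints", {
  fx <- make_fixture("pyridine_pair")
  rset <- parse_restraints(fx$restraints_text,
                           labels = site_labels(fx$model))
  expect_equal(length(rset), 4)          # four SAME directives
  ex <- expand_restraint_set(rset, fx$model, fx$conn)
  expect_equal(length(ex), 48)
  kinds <- vapply(ex$restraints, `[[`, "", "kind")
  expect_equal(sum(kinds == "EQUIV_DISTANCE"), 24)
  expect_equal(sum(kinds == "EQUIV_ANGLE"), 24)
  # expanded restraints remember their generating line
  expect_true(all(grepl("^line", vapply(ex$restraints, `[[`, "", "provenance"))))
})

test_that("SAME expansion is invariant under relabeling", {
  fx <- make_fixture("pyridine_pair")
  relab <- setNames(paste0("Q", seq_len(12)), site_labels(fx$model))
  txt2 <- fx$restraints_text
  for (old in names(relab))
    txt2 <- gsub(paste0("\\b", old, "\\b"), relab[old], txt2)
  conn2 <- connectivity(matrix(relab[fx$conn], ncol = 2))
  m2 <- fx$model
  for (i in seq_along(m2$atoms)) m2$atoms[[i]]$label <- relab[[m2$atoms[[i]]$label]]
  ex1 <- expand_restraint_set(parse_restraints(fx$restraints_text),
                              fx$model, fx$conn)
  ex2 <- expand_restraint_set(parse_restraints(txt2), m2, conn2)
  pair_key <- function(ex, inv = identity) sort(vapply(ex$restraints,
    function(r) paste(inv(c(r$atoms, r$atoms2)), collapse = "-"), ""))
  inv_map <- setNames(names(relab), relab)
  expect_equal(pair_key(ex1), pair_key(ex2, function(x) inv_map[x]),
               ignore_attr = TRUE)
})

test_that("SIMU expands to per-component difference equations", {
  cell <- unit_cell(8, 8, 8)
  u <- uij_from_cart(diag(0.03, 3), cell)
  m <- crystal_model(cell, atoms = list(
    atom_site("A1", "C", c(0.1, 0.1, 0.1), uaniso = u),
    atom_site("A2", "C", c(0.3, 0.1, 0.1), uaniso = u),
    atom_site("B1", "C", c(0.5, 0.5, 0.5), uiso = 0.03),
    atom_site("B2", "C", c(0.7, 0.5, 0.5), uiso = 0.04)))
  expect_equal(length(expand_simu(list(c("A1", "A2")), m)), 6)
  expect_equal(length(expand_simu(list("A1"), m)), 0)
  expect_equal(length(expand_simu(list(c("B1", "B2")), m)), 1)
  expect_error(expand_simu(list(c("A1", "B1")), m), "promote")
  expect_equal(expand_simu(list(c("A1", "B1")), m,
                           promote = TRUE)$restraints[[1]]$component, "ueq")
  expect_equal(length(expand_delu(rbind(c("A1", "A2"), c("A2", "B1"),
                                        c("B1", "B2")))), 3)
})

test_that("Hirshfeld rigid-bond difference matches the projection oracle", {
  cell <- unit_cell(10, 10, 10)
  a <- atom_site("A", "C", c(0, 0, 0), uiso = 0.04)
  b <- atom_site("B", "C", c(0.15, 0, 0), uiso = 0.04)
  expect_equal(hirshfeld_delta(a, b, cell), 0)
  ua <- uij_from_cart(diag(c(0.05, 0.02, 0.02)), cell)
  ub <- uij_from_cart(diag(c(0.02, 0.02, 0.02)), cell)
  aa <- atom_site("A", "C", c(0, 0, 0), uaniso = ua)
  bb <- atom_site("B", "C", c(0.15, 0, 0), uaniso = ub)   # bond along x
  expect_equal(hirshfeld_delta(aa, bb, cell), 0.03, tolerance = 1e-10)
  # triclinic oracle: explicit orthogonalization and projection
  tric <- unit_cell(5.1, 7.2, 9.3, 91, 95, 102)
  set.seed(12)
  Ua <- crossprod(matrix(rnorm(9, sd = 0.1), 3)) + diag(0.02, 3)
  Ub <- crossprod(matrix(rnorm(9, sd = 0.1), 3)) + diag(0.02, 3)
  at <- atom_site("A", "C", c(0.1, 0.2, 0.3), uaniso = uij_from_cart(Ua, tric))
  bt <- atom_site("B", "C", c(0.25, 0.1, 0.4), uaniso = uij_from_cart(Ub, tric))
  M <- orthogonalization_matrix(tric)
  z <- drop(M %*% (at$xyz - bt$xyz)); z <- z / sqrt(sum(z^2))
  expect_equal(hirshfeld_delta(at, bt, tric),
               drop(t(z) %*% (Ua - Ub) %*% z), tolerance = 1e-8)
  expect_error(hirshfeld_delta(at, at, tric), "coincident")
})

test_that("restraint equations: residuals, sparsity and asymmetric masking", {
  cell <- unit_cell(10, 10, 10)
  m <- crystal_model(cell, atoms = list(
    atom_site("A", "C", c(0, 0, 0), uiso = 0.03),
    atom_site("B", "C", c(0.14, 0, 0), uiso = 0.03),  # 1.4 A along x
    atom_site("C", "C", c(0.5, 0.5, 0.5), uiso = 0.03)))
  pm <- build_parameter_map(m)
  eq <- restraint_equation(restraint("DISTANCE", c("A", "B"), 1.5, 0.01),
                           m, pm)
  expect_equal(eq$residual, -10, tolerance = 1e-10)
  expect_equal(length(eq$idx), 6)    # up to six parameters, all present here
  # asymmetric SIMU: zero entries on the reference atom
  u <- uij_from_cart(diag(0.03, 3), cell)
  ma <- crystal_model(cell, atoms = list(
    atom_site("R1", "C", c(0.1, 0.1, 0.1), uaniso = u),
    atom_site("D1", "C", c(0.3, 0.1, 0.1),
              uaniso = uij_from_cart(diag(0.05, 3), cell))))
  pma <- build_parameter_map(ma)
  sim <- expand_simu(list("R1", "D1"), ma, asym = TRUE)
  for (r in sim$restraints) {
    eqa <- restraint_equation(r, ma, pma)
    expect_false(any(grepl("^R1\\.", pma$free_names[eqa$idx])))
  }
})

test_that("restraint Jacobians match finite differences of their residuals", {
  fx <- make_fixture("pyridine_pair")
  m <- fx$model
  pm <- build_parameter_map(m)
  q0 <- get_quantities(m)
  cases <- list(
    restraint("DISTANCE", c("N1", "C3"), 2.2, 0.01),
    restraint("ANGLE", c("N1", "C2", "C3"), 118, 0.5),
    restraint("EQUIV_DISTANCE", c("N1", "C2"), sigma = 0.01,
              atoms2 = c("N11", "C12")),
    restraint("EQUIV_ANGLE", c("N1", "C3"), sigma = 0.02,
              atoms2 = c("N11", "C13")),
    restraint("RIGID_BOND", c("N1", "C2"), 0, 0.01))
  for (r in cases) {
    eq <- restraint_equation(r, m, pm)
    fd <- vapply(eq$idx, function(j) {
      qid <- pm$free_qids[j]; h <- 1e-6
      qp <- q0; qp[qid] <- qp[qid] + h
      qm <- q0; qm[qid] <- qm[qid] - h
      (restraint_equation(r, set_quantities(m, qp), pm)$residual -
         restraint_equation(r, set_quantities(m, qm), pm)$residual) / (2 * h)
    }, 0)
    expect_lt(max(abs(eq$vals - fd)) / max(abs(fd)), 1e-6)
  }
})

test_that("a model satisfying its restraints contributes no gradient", {
  fx <- make_fixture("pyridine_pair")
  ex <- expand_restraint_set(parse_restraints(fx$restraints_text),
                             fx$model, fx$conn)
  pm <- build_parameter_map(fx$model)
  g <- numeric(pm$n_free)
  res <- numeric(0)
  for (r in ex$restraints) {
    eq <- restraint_equation(r, fx$model, pm)
    g[eq$idx] <- g[eq$idx] - eq$vals * eq$residual
    res <- c(res, eq$residual)
  }
  # both rings are ideal and identical: every equivalence is satisfied
  expect_lt(max(abs(res)), 1e-8)
  expect_lt(max(abs(g)), 1e-6)
})

test_that("shift-limiting equations damp shifts and equal diagonal loading", {
  fx <- make_fixture("pyridine_pair")
  m <- perturb_model(fx$model, 0.01, seed = 2)
  # noisy data give order-one weights, so the damping term can dominate
  rs <- simulate_observations(fx$model, d_min = 1.6, noise_frac = 0.02,
                              seed = 1)
  pm <- build_parameter_map(m)
  ne <- accumulate_normal_matrix(m, rs, pm)
  ne_d <- accumulate_restraints(ne, shift_limit_equations(pm, 0.05))
  expect_equal(ne_d$N, ne$N + diag(1 / 0.05^2, pm$n_free),
               tolerance = 1e-12)
  expect_error(shift_limit_equations(pm, -1), "sigma")

  one_cycle <- function(sl) {
    cfg <- refine_config(max_cycles = 1, shift_limit = sl, fix_origin = TRUE)
    r <- refine(m, rs, config = cfg)
    q1 <- get_quantities(r$model)
    max(abs(q1 - get_quantities(m)))
  }
  free_shift <- one_cycle(NULL)
  weak <- one_cycle(1e6)
  strong <- one_cycle(0.001)
  expect_equal(weak, free_shift, tolerance = 1e-6)
  expect_lt(strong, free_shift)
})
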