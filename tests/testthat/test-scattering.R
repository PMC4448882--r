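test_that("atomic form factors approximate electron counts and decrease", {
  for (el in c("H", "C", "N", "O", "Ni", "I")) {
    z <- c(H = 1, C = 6, N = 7, O = 8, Ni = 28, I = 53)[el]
    expect_lt(abs(atomic_form_factor(el, 0) - z) / z, 0.02)
    expect_lt(atomic_form_factor(el, 0.5), atomic_form_factor(el, 0))
  }
  expect_error(atomic_form_factor("Xx", 0.1), "missing scatterer")
  register_form_factor("Q1", a = c(1, 1, 1, 1), b = c(1, 2, 3, 4), c = 0.5)
  expect_equal(atomic_form_factor("Q1", 0), 4.5, ignore_attr = TRUE)
})

test_that("Debye-Waller factors: closed forms and representation equivalence", {
  cell <- unit_cell(10, 10, 10)
  a0 <- atom_site("C1", "C", c(0, 0, 0), uiso = 0)
  expect_equal(debye_waller(a0, c(3, -2, 5), cell), 1)
  a <- atom_site("C1", "C", c(0, 0, 0), uiso = 0.05)
  expect_equal(debye_waller(a, c(1, 0, 0), cell),
               exp(-8 * pi^2 * 0.05 * 0.05^2))
  # isotropic ADP written as the equivalent aniso tensor: same factor
  tric <- unit_cell(5.1, 7.2, 9.3, 91, 95, 102)
  u6 <- uij_from_cart(diag(0.04, 3), tric)
  ai <- atom_site("C1", "C", c(0, 0, 0), uiso = 0.04)
  aa <- atom_site("C1", "C", c(0, 0, 0), uaniso = u6)
  hkl <- rbind(c(1, 2, 3), c(-2, 0, 4), c(3, -1, -2))
  expect_equal(debye_waller(aa, hkl, tric), debye_waller(ai, hkl, tric),
               tolerance = 1e-10)
  bad <- atom_site("C1", "C", c(0, 0, 0),
                   uaniso = c(0.01, 0.01, 0.01, 0.05, 0, 0))
  expect_warning(debye_waller(bad, c(1, 1, 0), cell), "semi-definite")
})

test_that("shape form factors match deterministic point-scatterer oracles", {
  shell <- shape_site("S", "shell", c(0, 0, 0), "F", 6, 1.58)
  line <- shape_site("L", "line", c(0, 0, 0), "O", 2, 4.2, 35, 70)
  torus <- shape_site("T", "torus", c(0, 0, 0), "C", 6, 1.4, 35, 70)
  # in-phase limit and special geometries
  expect_equal(shape_form_factor(shell, c(0, 0, 0)), 1)
  expect_equal(shape_form_factor(line, c(0, 0, 0)), 1)
  expect_equal(shape_form_factor(torus, c(0, 0, 0)), 1)
  qpi <- c(pi / 1.58, 0, 0)           # |q| R = pi
  expect_equal(shape_form_factor(shell, qpi), 0, tolerance = 1e-12)
  ax <- c(sin(35 * pi / 180) * cos(70 * pi / 180),
          sin(35 * pi / 180) * sin(70 * pi / 180), cos(35 * pi / 180))
  expect_equal(shape_form_factor(torus, 3.7 * ax), 1, tolerance = 1e-10)

  set.seed(42)
  q <- matrix(rnorm(300, sd = 2), 100, 3)
  vs <- shape_form_factor(shell, q)
  vl <- shape_form_factor(line, q)
  vt <- shape_form_factor(torus, q)
  os <- apply(q, 1, function(qi) point_average_shell(1.58, qi))
  ol <- apply(q, 1, function(qi) point_average_line(4.2, ax, qi))
  ot <- apply(q, 1, function(qi) point_average_torus(1.4, ax, qi))
  expect_lt(max(abs(vs - os)), 1e-4)
  expect_lt(max(abs(vl - ol)), 1e-4)
  expect_lt(max(abs(vt - ot)), 1e-4)
  expect_true(all(abs(c(vs, vl, vt)) <= 1 + 1e-12))
  expect_error(shape_site("X", "blob", c(0, 0, 0), "C", 1, 1), "arg")
})

test_that("structure factors: point-scatterer limits and interference", {
  cell <- unit_cell(10, 10, 10)
  hkl <- rbind(c(1, 0, 0), c(2, 1, 0), c(1, 1, 1))
  register_form_factor("QU", a = c(0.25, 0.25, 0.25, 0.25),
                       b = c(0, 0, 0, 0), c = 0)   # f == 1 at all s
  m1 <- crystal_model(cell, atoms = list(
    atom_site("A1", "QU", c(0, 0, 0), uiso = 0)))
  sf <- calc_structure_factors(m1, hkl)
  expect_equal(sf$Fc, rep(1 + 0i, 3))
  m2 <- crystal_model(cell, atoms = list(
    atom_site("A1", "QU", c(0, 0, 0), uiso = 0),
    atom_site("A2", "QU", c(0.5, 0, 0), uiso = 0)))
  expect_equal(calc_structure_factors(m2, matrix(c(1, 0, 0), 1))$Fabs, 0,
               tolerance = 1e-12)
})

test_that("symmetry summation agrees with the explicit P1 expansion", {
  fx <- make_fixture("random_structure", seed = 6, n_atoms = 3, sg = "P21/c")
  m <- fx$model
  # oracle: expand every atom over the symmetry operators into a P1 model
  atoms <- list()
  k <- 0
  for (a in m$atoms) for (op in m$symops) {
    k <- k + 1
    atoms[[k]] <- atom_site(paste0(a$label, "_", k), a$element,
                            apply_symmetry(op, a$xyz), occ = a$occ,
                            uiso = a$uiso)
  }
  p1 <- crystal_model(m$cell, atoms = atoms)
  hkl <- as.matrix(expand.grid(h = -2:2, k = -2:2, l = 0:2))
  hkl <- hkl[rowSums(hkl != 0) > 0, ]
  expect_equal(calc_structure_factors(m, hkl)$Fc,
               calc_structure_factors(p1, hkl)$Fc, tolerance = 1e-10)
})

test_that("torus with matching radius reproduces a discrete carbon ring at low resolution", {
  cell <- unit_cell(10, 10, 10)
  ctr <- c(0.5, 0.5, 0.5)
  M <- orthogonalization_matrix(cell); Minv <- solve(M)
  disc <- lapply(0:5, function(j) {
    th <- j * pi / 3
    atom_site(paste0("C", j + 1), "C",
              drop(Minv %*% (drop(M %*% ctr) + 1.39 * c(cos(th), sin(th), 0))),
              uiso = 0.05)
  })
  md <- crystal_model(cell, atoms = disc)
  mt <- crystal_model(cell, shapes = list(
    shape_site("TOR", "torus", ctr, "C", 6, 1.39, 0, 0, uiso = 0.05)))
  rs <- simulate_observations(md, d_min = 2.5, noise_frac = 0, seed = 1)
  fd <- calc_structure_factors(md, rs$hkl)$Fabs
  ft <- calc_structure_factors(mt, rs$hkl)$Fabs
  ragg <- sum(abs(ft - fd)) / sum(fd)
  # near-1% agreement; the residual is the 6-fold Bessel harmonic (J6) of
  # a six-point ring at qR ~ 3.5, not an error in the smeared transform
  expect_lt(ragg, 0.02)
  expect_gt(ragg, 0.005)
})

test_that("solvent contribution enters the calculated structure factors", {
  fx <- make_fixture("pyridine_pair")
  hkl <- rbind(c(1, 0, 0), c(0, 2, 1), c(3, 1, 2))
  sf0 <- calc_structure_factors(fx$model, hkl)
  sfz <- calc_structure_factors(fx$model, hkl, solvent = complex(real = rep(0, 3)))
  expect_equal(sfz$Fabs, sf0$Fabs, tolerance = 1e-14)
  solv <- complex(real = c(3, 1, -2), imaginary = c(4, 0, 1))
  sfs <- calc_structure_factors(fx$model, hkl, solvent = solv)
  expect_equal(sfs$Fc, sf0$Fc_mol + solv)
  expect_equal(sfs$Fabs, Mod(sf0$Fc_mol + solv))
  expect_error(calc_structure_factors(fx$model, hkl, solvent = complex(1)),
               "length")
})

test_that("structure-factor invariances: Friedel, translation, occupancy linearity", {
  fx <- make_fixture("random_structure", seed = 5, n_atoms = 4, n_aniso = 1)
  m <- fx$model
  set.seed(8)
  hkl <- matrix(sample(-4:4, 60, replace = TRUE), 20, 3)
  hkl <- hkl[rowSums(hkl != 0) > 0, , drop = FALSE]
  sf <- calc_structure_factors(m, hkl)
  expect_equal(calc_structure_factors(m, -hkl)$Fc, Conj(sf$Fc),
               tolerance = 1e-12)
  tshift <- c(0.11, -0.23, 0.37)
  m2 <- m
  for (i in seq_along(m2$atoms)) m2$atoms[[i]]$xyz <- m2$atoms[[i]]$xyz + tshift
  sf2 <- calc_structure_factors(m2, hkl)
  expect_equal(sf2$Fabs, sf$Fabs, tolerance = 1e-10)
  expect_equal(Arg(sf2$Fc / sf$Fc) %% (2 * pi),
               (2 * pi * drop(hkl %*% tshift)) %% (2 * pi), tolerance = 1e-8)
  m3 <- m
  for (i in seq_along(m3$atoms)) m3$atoms[[i]]$occ <- m3$atoms[[i]]$occ / 2
  expect_equal(2 * calc_structure_factors(m3, hkl)$Fc_mol, sf$Fc_mol,
               tolerance = 1e-12)
})

test_that("design rows match finite differences, honor fixes, and are linear in scale", {
  fx <- make_fixture("random_structure", seed = 3, n_atoms = 5, n_aniso = 2)
  m <- fx$model
  pm <- build_parameter_map(m)
  set.seed(21)
  hkl <- matrix(sample(-5:5, 24, replace = TRUE), 8, 3)
  hkl <- hkl[rowSums(hkl != 0) > 0, , drop = FALSE]
  for (mode in c("F2", "F")) {
    A <- design_matrix(m, hkl, pm, mode = mode)$A
    fd <- fd_design_row(m, hkl, pm, mode = mode)
    expect_lt(max(abs(A - fd)) / max(abs(fd)), 1e-7)
  }
  # fixed parameter leaves no entry
  pmf <- build_parameter_map(m, list(
    list(type = "fix", labels = m$atoms[[1]]$label)))
  expect_false(any(grepl(paste0("^", m$atoms[[1]]$label, "\\."),
                         pmf$free_names)))
  # dYc/dscale at scale 1, mode F, is |Fc| itself
  row <- design_matrix(m, hkl, pm, mode = "F")
  expect_equal(row$A[, match("scale", pm$free_names)], row$sf$Fabs,
               tolerance = 1e-12)
})

test_that("design rows cover special-shape parameters", {
  fx <- make_fixture("benzene_torus")
  m <- fx$model
  pm <- build_parameter_map(m)
  # tilt the torus so declination/azimuth derivatives are generic
  m$shapes[[1]]$declination <- 25; m$shapes[[1]]$azimuth <- 40
  m$shapes[[2]]$declination <- 25; m$shapes[[2]]$azimuth <- 40
  hkl <- rbind(c(2, 1, 1), c(3, -1, 2), c(1, 4, -2))
  A <- design_matrix(m, hkl, pm)$A
  fd <- fd_design_row(m, hkl, pm)
  expect_lt(max(abs(A - fd)) / max(abs(fd)), 1e-6)
})

test_that("agreement statistics implement the minimisation function", {
  expect_equal(agreement_statistics(c(2, 2), c(1, 1), c(2, 2))$M, 0)
  expect_equal(agreement_statistics(c(2, 2), c(1, 1), c(2, 2))$R1, 0)
  st <- agreement_statistics(c(2, 2), c(1, 1), c(1, 1), weights = c(1, 1),
                             n_params = 0)
  expect_equal(st$M, 2)
  expect_true(is.na(agreement_statistics(c(2, 2), c(1, 1), c(1, 1),
                                         n_params = 5)$GoF))
  expect_error(agreement_statistics(1, 1, 1, weights = -1), "weights")
  # chi-square sampling: unit-variance residuals give GoF ~ 1
  set.seed(31)
  n <- 2000; p <- 50
  sig <- runif(n, 0.5, 2)
  Yo <- 100 + sig * rnorm(n)
  st <- agreement_statistics(Yo, sig, rep(100, n), n_params = p)
  expect_lt(abs(st$GoF - 1), 3 / sqrt(2 * (n - p)) * 3)
})
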