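# deterministic brute-force point-scatterer averages over the ideal shape
# densities; independent of the closed forms in the package

point_average_shell <- function(R, q, n = 4000) {
  qn <- sqrt(sum(q^2))
  # uniform over the sphere = uniform in cos(theta); midpoint rule
  ct <- (seq_len(n) - 0.5) / n * 2 - 1
  mean(cos(qn * R * ct))
}

point_average_line <- function(L, axis, q, n = 10000) {
  t <- (seq_len(n) - 0.5) / n - 0.5   # uniform points along the segment
  mean(cos(sum(q * axis) * L * t))
}

point_average_torus <- function(R, axis, q, n = 10000) {
  th <- (seq_len(n) - 1) / n * 2 * pi # periodic trapezoid = spectral
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  pts <- R * (outer(cos(th), e1) + outer(sin(th), e2))
  mean(cos(drop(pts %*% q)))
}

# CIF Uij vector whose Cartesian tensor is U (3x3)
uij_from_cart <- function(U, cell) {
  M <- orthogonalization_matrix(cell)
  N <- diag(sqrt(diag(metric_tensors(cell)$Gstar)))
  A <- solve(N) %*% solve(M)
  u <- A %*% U %*% t(A)
  c(u[1, 1], u[2, 2], u[3, 3], u[1, 2], u[1, 3], u[2, 3])
}

# finite-difference design row oracle (central differences on the target)
fd_design_row <- function(model, hkl, pmap, mode = "F2") {
  q0 <- get_quantities(model)
  sapply(seq_len(pmap$n_free), function(j) {
    qid <- pmap$free_qids[j]
    p <- pmap$qtab$param[qid]
    h <- if (p %in% c("x", "y", "z")) 1e-6 else 1e-5
    qp <- q0; qp[qid] <- qp[qid] + h
    qm <- q0; qm[qid] <- qm[qid] - h
    Yp <- calc_structure_factors(set_quantities(model, qp), hkl)$Fabs
    Ym <- calc_structure_factors(set_quantities(model, qm), hkl)$Fabs
    if (mode == "F2") (Yp^2 - Ym^2) / (2 * h) else (Yp - Ym) / (2 * h)
  })
}

expect_rel_equal <- function(a, b, tol, scale = NULL) {
  if (is.null(scale)) scale <- max(abs(a), abs(b))
  expect_lt(max(abs(a - b)), tol * scale)
}
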