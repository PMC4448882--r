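# ---- idealized pyridine ring geometry -------------------------------------

# mirror-symmetric planar ring, C-N 1.34 A, C-C 1.39 A, built by walking
# the bond chain N -> C2 -> C3 -> C4 with fixed angles at N and C2 and the
# angle at C3 solved so that C4 lands on the mirror axis; mirroring gives
# C5, C6 and the remaining bonds exactly
pyridine_ring_xy <- function(cn = 1.34, cc = 1.39,
                             angle_n = 117, angle_c2 = 123.8) {
  walk <- function(a3) {
    psi <- pi / 2 - (angle_n / 2) * pi / 180  # heading of N -> C2, from +x
    p <- matrix(0, 4, 2)                       # N, C2, C3, C4
    lens <- c(cn, cc, cc)
    angs <- c(angle_c2, a3)
    for (k in 1:3) {
      p[k + 1, ] <- p[k, ] + lens[k] * c(cos(psi), sin(psi))
      if (k < 3) psi <- psi + (180 - angs[k]) * pi / 180
    }
    p
  }
  a3 <- uniroot(function(a) walk(a)[4, 1], c(100, 140), tol = 1e-13)$root
  p <- walk(a3)
  ring <- rbind(p,                      # N1 C2 C3 C4
                c(-p[3, 1], p[3, 2]),   # C5 = mirror of C3
                c(-p[2, 1], p[2, 2]))   # C6 = mirror of C2
  sweep(ring, 2, colMeans(ring))        # centre on the ring centroid
}

# simple 3D rotation from Euler-like angles (degrees, about z then x then z)
.rot3 <- function(a, b, g) {
  ra <- a * pi / 180; rb <- b * pi / 180; rg <- g * pi / 180
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  Rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
  Rz(ra) %*% Rx(rb) %*% Rz(rg)
}

.place_ring <- function(ring_xy, cell, centre_frac, rot = diag(3)) {
  M <- orthogonalization_matrix(cell)
  Minv <- solve(M)
  centre <- drop(M %*% centre_frac)
  t(apply(cbind(ring_xy, 0), 1, function(r)
    drop(Minv %*% (centre + drop(rot %*% r)))))
}

#' Generate a ground-truth fixture
#'
#' Built-in synthetic structures exercising the refinement machinery:
#' \describe{
#'   \item{`pyridine_pair`}{two idealized pyridine rings (C-C 1.39, C-N
#'     1.34 A) in P1, with the four-line SAME restraint scheme (second
#'     ring onto the first, plus mirrored first and second rings mapped
#'     back, exploiting the ring's mirror symmetry).}
#'   \item{`benzene_torus`}{a librationally disordered benzene modelled as
#'     a pair of concentric tori (6 C, 6 H); the equivalent discrete
#'     12-atom model is returned alongside for comparison.}
#'   \item{`cf3_disorder`}{a CF3 group disordered over two components
#'     rotated by 60 degrees (occupancies 0.7/0.3) with the asymmetric
#'     ADP restraint pairing atoms related by the 180-degree rotation.}
#'   \item{`collinear_occupancy`}{two scatterers of similar form factor
#'     (Cl, K) sharing one site with both occupancies nominally free: the
#'     classic occupancy multicollinearity.}
#'   \item{`random_structure`}{a seeded random light-atom structure
#'     (options `n_atoms`, `sg`, `n_aniso`).}
#' }
#'
#' @param name Fixture name (above).
#' @param seed Random seed (used by `random_structure`).
#' @param ... Fixture-specific options.
#' @return List with `model` (ground truth), `conn` ([connectivity()]),
#'   `restraints_text` (restraint file content, possibly empty), plus
#'   fixture-specific extras (`model_discrete`, `constraints`).
#' @export
make_fixture <- function(name, seed = 1, ...) {
  opts <- list(...)
  switch(name,
    pyridine_pair = {
      cell <- unit_cell(9, 10, 11)
      ring <- pyridine_ring_xy()
      f1 <- .place_ring(ring, cell, c(0.28, 0.25, 0.27))
      f2 <- .place_ring(ring, cell, c(0.70, 0.68, 0.72), .rot3(40, 55, 10))
      lab1 <- c("N1", "C2", "C3", "C4", "C5", "C6")
      lab2 <- c("N11", "C12", "C13", "C14", "C15", "C16")
      el <- c("N", "C", "C", "C", "C", "C")
      us <- c(0.025, 0.030, 0.035, 0.032, 0.028, 0.033)
      atoms <- c(
        lapply(1:6, function(i) atom_site(lab1[i], el[i], f1[i, ], uiso = us[i])),
        lapply(1:6, function(i) atom_site(lab2[i], el[i], f2[i, ], uiso = us[i] + 0.005)))
      ringbond <- function(l) cbind(l, l[c(2:6, 1)])
      conn <- connectivity(rbind(ringbond(lab1), ringbond(lab2)))
      g1 <- paste(lab1, collapse = " ")
      g2 <- paste(lab2, collapse = " ")
      m1 <- paste(lab1[c(1, 6, 5, 4, 3, 2)], collapse = " ")  # mirrored ring 1
      m2 <- paste(lab2[c(1, 6, 5, 4, 3, 2)], collapse = " ")  # mirrored ring 2
      txt <- paste(
        paste0("SAME 0.01, 0.02 = ", g1, " AND ", g2),
        paste0("SAME 0.01, 0.02 = ", g1, " AND ", m1),
        paste0("SAME 0.01, 0.02 = ", g1, " AND ", m2),
        paste0("SAME 0.01, 0.02 = ", g2, " AND ", m2),
        sep = "\n")
      list(model = crystal_model(cell, atoms = atoms), conn = conn,
           restraints_text = txt)
    },
    benzene_torus = {
      cell <- unit_cell(10, 10, 10)
      ctr <- c(0.5, 0.5, 0.5)
      rc <- 1.39; rh <- rc + 1.08
      tor <- list(
        shape_site("TORC", "torus", ctr, "C", 6, rc, 0, 0, uiso = 0.05),
        shape_site("TORH", "torus", ctr, "H", 6, rh, 0, 0, uiso = 0.06))
      M <- orthogonalization_matrix(cell)
      Minv <- solve(M)
      disc <- list()
      for (j in 0:5) {
        th <- j * pi / 3
        pc <- drop(Minv %*% (drop(M %*% ctr) + rc * c(cos(th), sin(th), 0)))
        ph <- drop(Minv %*% (drop(M %*% ctr) + rh * c(cos(th), sin(th), 0)))
        disc[[length(disc) + 1]] <- atom_site(paste0("C", j + 1), "C", pc,
                                              uiso = 0.05)
        disc[[length(disc) + 1]] <- atom_site(paste0("H", j + 1), "H", ph,
                                              uiso = 0.06)
      }
      conn <- connectivity(rbind(
        cbind(paste0("C", 1:6), paste0("C", c(2:6, 1))),
        cbind(paste0("C", 1:6), paste0("H", 1:6))))
      list(model = crystal_model(cell, shapes = tor),
           model_discrete = crystal_model(cell, atoms = disc),
           conn = conn, restraints_text = "")
    },
    cf3_disorder = {
      cell <- unit_cell(8, 8, 8)
      M <- orthogonalization_matrix(cell)
      Minv <- solve(M)
      c1 <- c(4, 4, 4.4); c2 <- c(4, 4, 2.87)  # C-C 1.53 A along z
      dcf <- 1.33; pol <- (180 - 111.5) * pi / 180
      fpos <- function(tor_deg) {
        t <- tor_deg * pi / 180
        c1 + dcf * c(sin(pol) * cos(t), sin(pol) * sin(t), cos(pol))
      }
      # mildly anisotropic, tangentially elongated F tensors
      fadp <- function(tor_deg, scale) {
        t <- tor_deg * pi / 180
        tangent <- c(-sin(t), cos(t), 0)
        U <- 0.03 * diag(3) + scale * outer(tangent, tangent)
        N <- diag(recip_lengths(cell))
        matrix_to_uij(solve(N) %*% solve(M) %*% U %*% t(solve(M)) %*% solve(N))
      }
      atoms <- list(
        atom_site("C1", "C", drop(Minv %*% c1), uiso = 0.03),
        atom_site("C2", "C", drop(Minv %*% c2), uiso = 0.028))
      torA <- c(0, 120, 240); torB <- c(60, 180, 300)
      for (j in 1:3) {
        atoms[[length(atoms) + 1]] <- atom_site(paste0("F", j, "A"), "F",
          drop(Minv %*% fpos(torA[j])), occ = 0.7,
          uaniso = fadp(torA[j], 0.025))
        atoms[[length(atoms) + 1]] <- atom_site(paste0("F", j, "B"), "F",
          drop(Minv %*% fpos(torB[j])), occ = 0.3,
          uaniso = fadp(torB[j], 0.035))
      }
      conn <- connectivity(rbind(
        c("C1", "C2"),
        cbind("C1", paste0("F", 1:3, "A")),
        cbind("C1", paste0("F", 1:3, "B"))))
      # asymmetric ADP similarity pairing atoms related by the 180-degree
      # rotation: the major component is the reference
      txt <- "SIMU 0.04 = F1A F2A F3A AND F2B F3B F1B ASYM"
      list(model = crystal_model(cell, atoms = atoms), conn = conn,
           restraints_text = txt)
    },
    collinear_occupancy = {
      cell <- unit_cell(7, 7, 7)
      site <- c(0.30, 0.40, 0.45)
      atoms <- list(
        atom_site("CL1", "Cl", site, occ = 0.5, uiso = 0.03),
        atom_site("K1", "K", site, occ = 0.5, uiso = 0.03),
        atom_site("C1", "C", c(0.10, 0.80, 0.20), uiso = 0.035),
        atom_site("C2", "C", c(0.70, 0.15, 0.65), uiso = 0.040))
      constraints <- list(
        list(type = "fix", labels = c("CL1", "K1"),
             params = c("x", "y", "z", "uiso")),
        list(type = "free", labels = c("CL1", "K1"), params = "occ"))
      list(model = crystal_model(cell, atoms = atoms),
           conn = connectivity(matrix(character(), 0, 2)),
           restraints_text = "", constraints = constraints,
           occ_sum_constraint = list(type = "occ_sum",
                                     labels = c("CL1", "K1"), total = 1))
    },
    random_structure = {
      n_atoms <- opts$n_atoms %||% 6
      sg <- opts$sg %||% "P1"
      n_aniso <- opts$n_aniso %||% 0
      cell <- if (sg %in% c("P21", "P21/c"))
        unit_cell(9, 9.5, 10.5, 90, 101, 90)
      else unit_cell(9, 9.5, 10.5, 92, 101, 87)
      set.seed(seed)
      els <- sample(c("C", "N", "O"), n_atoms, replace = TRUE)
      atoms <- lapply(seq_len(n_atoms), function(i) {
        xyz <- runif(3, 0.05, 0.45)
        if (i <= n_aniso) {
          A <- matrix(rnorm(9, sd = 0.05), 3)
          Uc <- 0.03 * diag(3) + crossprod(A)   # SPD by construction
          M <- orthogonalization_matrix(cell)
          N <- diag(recip_lengths(cell))
          atom_site(paste0(els[i], i), els[i], xyz,
                    uaniso = matrix_to_uij(solve(N) %*% solve(M) %*% Uc %*%
                                             t(solve(M)) %*% solve(N)))
        } else {
          atom_site(paste0(els[i], i), els[i], xyz,
                    uiso = runif(1, 0.02, 0.05))
        }
      })
      list(model = crystal_model(cell, symops = spacegroup_symops(sg),
                                 atoms = atoms),
           conn = connectivity(matrix(character(), 0, 2)),
           restraints_text = "")
    },
    stop("unknown fixture name: ", name, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate observed reflection data
#'
#' Enumerates the full hkl sphere to the resolution limit, computes
#' `|Fc|^2` from the ground-truth model and applies multiplicative
#' Gaussian noise: `Yo = |Fc|^2 (1 + noise_frac * eps)`,
#' `sigma = noise_frac * |Fc|^2` floored at
#' `noise_frac * 0.05 * mean(|Fc|^2)`.  The floor emulates the additive
#' background/counting uncertainty of a real measurement; without it the
#' weakest reflections would receive unbounded `1/sigma^2` weights and
#' dominate (and roughen) the least-squares landscape.  `noise_frac = 0`
#' gives exact data with a uniform tiny sigma (uniform weights).
#'
#' @param model Ground-truth [crystal_model()].
#' @param d_min Resolution limit in A (> 0).
#' @param noise_frac Fractional Gaussian noise level (>= 0).
#' @param seed Random seed (recorded as an attribute).
#' @return A [reflection_set()]; attributes `seed` and `d` are attached.
#' @export
simulate_observations <- function(model, d_min, noise_frac = 0, seed = 1) {
  stopifnot(d_min > 0, noise_frac >= 0)
  astar <- recip_lengths(model$cell)
  hmax <- floor(1 / (d_min * astar))
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  grid <- grid[rowSums(grid != 0) > 0, , drop = FALSE]
  d <- d_spacing(model$cell, grid)
  keep <- d >= d_min
  hkl <- grid[keep, , drop = FALSE]
  d <- d[keep]
  ord <- order(hkl[, 1], hkl[, 2], hkl[, 3])
  hkl <- hkl[ord, , drop = FALSE]; d <- d[ord]
  sf <- calc_structure_factors(model, hkl)
  F2 <- sf$Fabs^2
  set.seed(seed)
  eps <- rnorm(length(F2))
  Yo <- F2 * (1 + noise_frac * eps)
  floor_sig <- if (noise_frac > 0) noise_frac * 0.05 * mean(F2)
               else 1e-8 * (1 + max(F2))
  sig <- pmax(noise_frac * F2, floor_sig)
  rs <- reflection_set(hkl, Yo, sig)
  attr(rs, "seed") <- seed
  attr(rs, "d") <- d
  rs
}

#' Randomly perturb model coordinates (and optionally ADPs)
#'
#' @param model A [crystal_model()].
#' @param amount Half-width of the uniform coordinate perturbation
#'   (fractional units).
#' @param seed Random seed.
#' @param adp_amount Optional half-width for u_iso perturbation (A^2).
#' @return Perturbed model.
#' @export
perturb_model <- function(model, amount = 0.02, seed = 1, adp_amount = 0) {
  set.seed(seed)
  for (i in seq_along(model$atoms)) {
    model$atoms[[i]]$xyz <- model$atoms[[i]]$xyz + runif(3, -amount, amount)
    if (adp_amount > 0 && model$atoms[[i]]$adp_type == "iso")
      model$atoms[[i]]$uiso <- abs(model$atoms[[i]]$uiso +
                                     runif(1, -adp_amount, adp_amount))
  }
  model
}

#' Infer heavy-atom connectivity from distances
#'
#' Bonds any pair closer than the sum of covalent radii plus a tolerance.
#'
#' @param model A [crystal_model()].
#' @param tol Slack added to the radius sum (A).
#' @return A [connectivity()].
#' @export
infer_connectivity <- function(model, tol = 0.45) {
  radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07,
             S = 1.05, Cl = 1.02, K = 2.03, Ni = 1.24, Br = 1.20, I = 1.39)
  labs <- vapply(model$atoms, `[[`, "", "label")
  els <- vapply(model$atoms, `[[`, "", "element")
  pairs <- matrix(character(), 0, 2)
  n <- length(labs)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    rmax <- sum(radii[c(els[i], els[j])], na.rm = TRUE) + tol
    dij <- frac_distance(model$cell, model$atoms[[i]]$xyz,
                         model$atoms[[j]]$xyz)
    if (dij > 1e-4 && dij < rmax) pairs <- rbind(pairs, c(labs[i], labs[j]))
  }
  connectivity(pairs)
}
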