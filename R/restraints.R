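#' Restraint observational equation
#'
#' @param kind One of `"DISTANCE"`, `"ANGLE"`, `"EQUIV_DISTANCE"`,
#'   `"EQUIV_ANGLE"`, `"SIMU"`, `"RIGID_BOND"`, `"SAME"` (unexpanded
#'   directive), `"SIMU_GROUP"` (unexpanded directive), `"LIMIT"`.
#' @param atoms Atom labels (for EQUIV kinds: the reference pair).
#' @param target Target value (A, degrees or A^2); `NA` for "match
#'   partner" equivalences.
#' @param sigma Standard deviation of the restraint, same units; must be
#'   positive.
#' @param atoms2 Mapped pair for EQUIV kinds.
#' @param component ADP component for SIMU equations (`"u11"`..`"u23"`,
#'   `"uiso"` or `"ueq"`).
#' @param asym If `TRUE` the restraint is one-sided: Jacobian entries of
#'   `ref_atoms` are zeroed so refinement pulls only the dependent group
#'   toward the reference, whose parameters are not influenced.
#' @param ref_atoms Labels of the reference group (asymmetric restraints).
#' @param provenance Free-text origin tag (e.g. the generating SAME line).
#' @return Object of class `restraint`.
#' @export
restraint <- function(kind, atoms = character(), target = NA_real_, sigma,
                      atoms2 = NULL, component = NULL, asym = FALSE,
                      ref_atoms = character(), provenance = "") {
  if (!is.numeric(sigma) || sigma <= 0)
    stop("restraint sigma must be > 0", call. = FALSE)
  if (!is.null(atoms2) && length(atoms2) != length(atoms))
    stop("equivalence restraints need tuples of equal arity", call. = FALSE)
  structure(list(kind = kind, atoms = atoms, target = target, sigma = sigma,
                 atoms2 = atoms2, component = component, asym = asym,
                 ref_atoms = ref_atoms, provenance = provenance),
            class = "restraint")
}

#' Bundle restraints into a set
#' @param restraints List of [restraint()] objects.
#' @return Object of class `restraint_set`.
#' @export
restraint_set <- function(restraints = list()) {
  structure(list(restraints = restraints), class = "restraint_set")
}

#' @export
length.restraint_set <- function(x) length(x$restraints)

#' @export
print.restraint_set <- function(x, ...) {
  kinds <- vapply(x$restraints, `[[`, "", "kind")
  cat("restraint set:", length(kinds), "entries\n")
  if (length(kinds)) print(table(kinds))
  invisible(x)
}

#' Tabular audit report of a restraint set
#' @param x A `restraint_set`.
#' @param ... Unused.
#' @return data.frame with one row per restraint.
#' @export
as.data.frame.restraint_set <- function(x, ...) {
  do.call(rbind, lapply(x$restraints, function(r) data.frame(
    kind = r$kind,
    atoms = paste(r$atoms, collapse = "-"),
    atoms2 = if (is.null(r$atoms2)) "" else paste(r$atoms2, collapse = "-"),
    component = if (is.null(r$component)) "" else r$component,
    target = r$target, sigma = r$sigma, asym = r$asym,
    provenance = r$provenance, stringsAsFactors = FALSE)))
}

# ---- parser ---------------------------------------------------------------

.parse_fail <- function(lineno, msg) {
  stop(sprintf("restraint parse error at line %d: %s", lineno, msg),
       call. = FALSE)
}

.check_labels <- function(atoms, labels, lineno) {
  if (is.null(labels)) return(invisible())
  bad <- setdiff(atoms, labels)
  if (length(bad))
    .parse_fail(lineno, paste0("unknown atom label(s): ",
                               paste(bad, collapse = ", ")))
}

#' Parse a plain-text restraint file
#'
#' Grammar (one restraint or directive per line; `#` and `!` start
#' comments):
#' \preformatted{
#' DISTANCE <target>, <sigma> = A1 TO A2
#' ANGLE    <target>, <sigma> = A1 TO A2 TO A3
#' SAME <sigma_d>, <sigma_a> = A1 A2 ... AND B1 B2 ... [ASYM]
#' SIMU <sigma> = A1 A2 ... [AND B1 B2 ...] [ASYM]
#' DELU <sigma> = A1 TO A2 [, A3 TO A4 ...]
#' LIMIT <sigma>
#' }
#' SAME and SIMU lines are stored as directives; expand them against a
#' model/connectivity with [expand_restraint_set()] (or directly with
#' [expand_same()] / [expand_simu()]).
#'
#' @param text Character scalar (whole file) or vector of lines.
#' @param labels Optional known site labels for validation.
#' @return A [restraint_set()].
#' @export
parse_restraints <- function(text, labels = NULL) {
  lines <- if (length(text) == 1) strsplit(text, "\n")[[1]] else text
  out <- list()
  for (ln in seq_along(lines)) {
    raw <- sub("[#!].*$", "", lines[ln])
    raw <- trimws(raw)
    if (!nzchar(raw)) next
    toks <- strsplit(raw, "[[:space:]]+")[[1]]
    kw <- toupper(toks[1])
    rest <- sub("^[A-Za-z]+[[:space:]]*", "", raw)
    if (kw == "LIMIT") {
      s <- suppressWarnings(as.numeric(rest))
      if (is.na(s)) .parse_fail(ln, "LIMIT needs a numeric sigma")
      if (s <= 0) .parse_fail(ln, "sigma must be > 0")
      out[[length(out) + 1]] <- restraint("LIMIT", sigma = s,
                                          provenance = paste0("line ", ln))
      next
    }
    halves <- strsplit(rest, "=", fixed = TRUE)[[1]]
    if (length(halves) != 2) .parse_fail(ln, "expected '<numbers> = <atoms>'")
    nums <- suppressWarnings(as.numeric(trimws(strsplit(halves[1], ",")[[1]])))
    if (anyNA(nums)) .parse_fail(ln, "non-numeric target/sigma")
    body <- trimws(halves[2])
    asym <- grepl("[[:space:]]ASYM$", body, ignore.case = TRUE)
    if (asym) body <- trimws(sub("[[:space:]]+[Aa][Ss][Yy][Mm]$", "", body))
    prov <- paste0("line ", ln)

    if (kw == "DISTANCE" || kw == "ANGLE") {
      if (length(nums) != 2) .parse_fail(ln, paste(kw, "needs 'target, sigma'"))
      if (nums[2] <= 0) .parse_fail(ln, "sigma must be > 0")
      atoms <- trimws(strsplit(body, "[[:space:]]+TO[[:space:]]+")[[1]])
      need <- if (kw == "DISTANCE") 2 else 3
      if (length(atoms) != need || any(!nzchar(atoms)))
        .parse_fail(ln, paste(kw, "needs", need, "atoms joined by TO"))
      .check_labels(atoms, labels, ln)
      out[[length(out) + 1]] <- restraint(kw, atoms, nums[1], nums[2],
                                          provenance = prov)
    } else if (kw == "SAME") {
      if (length(nums) != 2) .parse_fail(ln, "SAME needs 'sigma_d, sigma_a'")
      if (any(nums <= 0)) .parse_fail(ln, "sigma must be > 0")
      groups <- lapply(strsplit(body, "[[:space:]]+AND[[:space:]]+")[[1]],
                       function(g) strsplit(trimws(g), "[[:space:]]+")[[1]])
      if (length(groups) < 2) .parse_fail(ln, "SAME needs target AND mapped group(s)")
      if (length(unique(lengths(groups))) != 1)
        .parse_fail(ln, "SAME groups must have equal length")
      for (g in groups) .check_labels(g, labels, ln)
      out[[length(out) + 1]] <- structure(
        list(kind = "SAME", groups = groups, sigma_d = nums[1],
             sigma_a = nums[2], asym = asym, provenance = prov),
        class = "restraint")
    } else if (kw == "SIMU") {
      if (length(nums) != 1) .parse_fail(ln, "SIMU needs one sigma")
      if (nums[1] <= 0) .parse_fail(ln, "sigma must be > 0")
      groups <- lapply(strsplit(body, "[[:space:]]+AND[[:space:]]+")[[1]],
                       function(g) strsplit(trimws(g), "[[:space:]]+")[[1]])
      if (length(groups) == 2 && length(groups[[1]]) != length(groups[[2]]))
        .parse_fail(ln, "SIMU paired groups must have equal length")
      if (length(groups) > 2) .parse_fail(ln, "SIMU takes at most two groups")
      for (g in groups) .check_labels(g, labels, ln)
      out[[length(out) + 1]] <- structure(
        list(kind = "SIMU_GROUP", groups = groups, sigma = nums[1],
             asym = asym, provenance = prov),
        class = "restraint")
    } else if (kw == "DELU") {
      if (length(nums) != 1) .parse_fail(ln, "DELU needs one sigma")
      if (nums[1] <= 0) .parse_fail(ln, "sigma must be > 0")
      pairs <- strsplit(body, ",")[[1]]
      for (p in pairs) {
        atoms <- trimws(strsplit(trimws(p), "[[:space:]]+TO[[:space:]]+")[[1]])
        if (length(atoms) != 2) .parse_fail(ln, "DELU pairs are 'A TO B'")
        .check_labels(atoms, labels, ln)
        out[[length(out) + 1]] <- restraint("RIGID_BOND", atoms, 0, nums[1],
                                            provenance = prov)
      }
    } else .parse_fail(ln, paste0("unknown keyword '", toks[1], "'"))
  }
  restraint_set(out)
}

# ---- SAME decomposition ---------------------------------------------------

# unique 1-2 (bonded) and 1-3 (angle-defining) index pairs of an ordered
# group under a connectivity
.group_pairs <- function(group, conn) {
  n <- length(group)
  adj <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(conn))) {
    i <- match(conn[r, 1], group); j <- match(conn[r, 2], group)
    if (!is.na(i) && !is.na(j)) adj[i, j] <- adj[j, i] <- TRUE
  }
  if (!any(adj))
    stop("connectivity does not cover the restrained group", call. = FALSE)
  bonds <- which(adj & upper.tri(adj), arr.ind = TRUE)
  onethree <- matrix(0L, 0, 2)
  for (j in seq_len(n)) {
    nb <- which(adj[j, ])
    if (length(nb) >= 2) {
      cmb <- t(combn(nb, 2))
      onethree <- rbind(onethree, cmb)
    }
  }
  if (nrow(onethree)) {
    onethree <- t(apply(onethree, 1, sort))
    onethree <- unique(onethree)
    # exclude pairs that are themselves bonded (small rings)
    keep <- !apply(onethree, 1, function(p) adj[p[1], p[2]])
    onethree <- onethree[keep, , drop = FALSE]
  }
  list(bonds = bonds, onethree = onethree)
}

#' Decompose a SAME directive into equivalence restraints
#'
#' The first group is the target; the connectivity of the target works out
#' which distances and angles are restrained.  Every bonded (1-2) pair and
#' every angle-defining (1-3) pair of the target generates, for each mapped
#' group, one equivalence tying the mapped group's value to the target's.
#' Angle equivalences are realised as 1-3 distance equivalences (uniquely
#' determined once the 1-2 restraints hold).  Mirrored mappings are
#' expressed by supplying the mirror-permuted atom order as a mapped group;
#' self-pairs arising from mirror self-maps are retained (they count, and
#' are trivially satisfied).
#'
#' @param target_group Ordered character vector of target atom labels.
#' @param mapped_groups List of equally long ordered label vectors.
#' @param conn A [connectivity()] covering the target group.
#' @param sigma_d,sigma_a Sigmas for 1-2 and 1-3 equivalences (A).
#' @param asym One-sided flag: the target group acts as a fixed reference.
#' @param provenance Origin tag recorded on every generated restraint.
#' @return A [restraint_set()] of `EQUIV_DISTANCE`/`EQUIV_ANGLE` restraints.
#' @export
expand_same <- function(target_group, mapped_groups, conn,
                        sigma_d = 0.01, sigma_a = 0.02, asym = FALSE,
                        provenance = "SAME") {
  if (!is.list(mapped_groups)) mapped_groups <- list(mapped_groups)
  for (g in mapped_groups)
    if (length(g) != length(target_group))
      stop("SAME groups must have equal length", call. = FALSE)
  pr <- .group_pairs(target_group, conn)
  out <- list()
  for (g in mapped_groups) {
    for (r in seq_len(nrow(pr$bonds))) {
      i <- pr$bonds[r, 1]; j <- pr$bonds[r, 2]
      out[[length(out) + 1]] <- restraint(
        "EQUIV_DISTANCE", atoms = target_group[c(i, j)],
        sigma = sigma_d, atoms2 = g[c(i, j)], asym = asym,
        ref_atoms = if (asym) target_group else character(),
        provenance = provenance)
    }
    for (r in seq_len(nrow(pr$onethree))) {
      i <- pr$onethree[r, 1]; j <- pr$onethree[r, 2]
      out[[length(out) + 1]] <- restraint(
        "EQUIV_ANGLE", atoms = target_group[c(i, j)],
        sigma = sigma_a, atoms2 = g[c(i, j)], asym = asym,
        ref_atoms = if (asym) target_group else character(),
        provenance = provenance)
    }
  }
  restraint_set(out)
}

# ---- SIMU / DELU ----------------------------------------------------------

.simu_components <- function(model, a, b, promote) {
  ta <- model$atoms[[find_atom(model, a)]]$adp_type
  tb <- model$atoms[[find_atom(model, b)]]$adp_type
  if (ta == "aniso" && tb == "aniso")
    return(c("u11", "u22", "u33", "u12", "u13", "u23"))
  if (ta == "iso" && tb == "iso") return("uiso")
  if (!promote)
    stop("SIMU pair ", a, "/", b, " mixes isotropic and anisotropic ADPs; ",
         "set promote=TRUE to compare equivalent isotropic values",
         call. = FALSE)
  "ueq"
}

#' Expand a thermal-similarity (SIMU) directive
#'
#' One group: similarity equations between successive members.  Two groups:
#' member-wise pairing (the asymmetric CF3/tert-butyl use case, pairing
#' atoms related by a 180 degree rotation).  Each pair contributes one
#' difference equation per ADP component.
#'
#' @param groups List of one or two character vectors of atom labels.
#' @param model The [crystal_model()] (ADP types decide the components).
#' @param sigma Sigma in A^2 (conventional default 0.04).
#' @param asym One-sided flag; the first group (or first member of each
#'   pair) is the reference.
#' @param promote Compare U_eq when a pair mixes iso and aniso ADPs
#'   (otherwise an error).
#' @param provenance Origin tag.
#' @return A [restraint_set()] of per-component SIMU equations.
#' @export
expand_simu <- function(groups, model, sigma = 0.04, asym = FALSE,
                        promote = FALSE, provenance = "SIMU") {
  if (!is.list(groups)) groups <- list(groups)
  pairs <- if (length(groups) == 1) {
    g <- groups[[1]]
    if (length(g) < 2) return(restraint_set())
    lapply(seq_len(length(g) - 1), function(i) c(g[i], g[i + 1]))
  } else {
    mapply(c, groups[[1]], groups[[2]], SIMPLIFY = FALSE, USE.NAMES = FALSE)
  }
  out <- list()
  for (p in pairs) {
    for (comp in .simu_components(model, p[1], p[2], promote)) {
      out[[length(out) + 1]] <- restraint(
        "SIMU", atoms = p, target = 0, sigma = sigma, component = comp,
        asym = asym, ref_atoms = if (asym) p[1] else character(),
        provenance = provenance)
    }
  }
  restraint_set(out)
}

#' Expand rigid-bond (DELU) restraints
#'
#' One Hirshfeld rigid-bond equation with target 0 per bonded pair.
#'
#' @param bonded_pairs k x 2 character matrix (or [connectivity()]) of
#'   bonded label pairs.
#' @param sigma Sigma in A^2 (conventional default 0.01).
#' @param provenance Origin tag.
#' @return A [restraint_set()] of `RIGID_BOND` restraints.
#' @export
expand_delu <- function(bonded_pairs, sigma = 0.01, provenance = "DELU") {
  m <- if (is.matrix(bonded_pairs)) bonded_pairs else
    matrix(bonded_pairs, ncol = 2, byrow = TRUE)
  restraint_set(lapply(seq_len(nrow(m)), function(r)
    restraint("RIGID_BOND", atoms = m[r, ], target = 0, sigma = sigma,
              provenance = provenance)))
}

#' Expand all directives in a restraint set
#'
#' Replaces SAME and grouped SIMU directives by their decomposed
#' equivalence/similarity equations, recording the generating line in each
#' restraint's provenance.
#'
#' @param rset A [restraint_set()] from [parse_restraints()].
#' @param model The [crystal_model()].
#' @param conn A [connectivity()] (required when SAME directives occur).
#' @param promote Passed to [expand_simu()].
#' @return An expanded [restraint_set()].
#' @export
expand_restraint_set <- function(rset, model, conn = NULL, promote = FALSE) {
  out <- list()
  for (r in rset$restraints) {
    if (r$kind == "SAME") {
      if (is.null(conn))
        stop("SAME directives need a connectivity to expand", call. = FALSE)
      ex <- expand_same(r$groups[[1]], r$groups[-1], conn,
                        sigma_d = r$sigma_d, sigma_a = r$sigma_a,
                        asym = r$asym, provenance = r$provenance)
      out <- c(out, ex$restraints)
    } else if (r$kind == "SIMU_GROUP") {
      ex <- expand_simu(r$groups, model, sigma = r$sigma, asym = r$asym,
                        promote = promote, provenance = r$provenance)
      out <- c(out, ex$restraints)
    } else out[[length(out) + 1]] <- r
  }
  restraint_set(out)
}

# ---- geometry values ------------------------------------------------------

#' Hirshfeld rigid-bond difference
#'
#' Difference of the two atoms' mean-square displacement amplitudes along
#' their bond: `Delta_AB = z' U_A^cart z - z' U_B^cart z` with `z` the unit
#' Cartesian bond vector.  Near zero for rigidly bonded atom pairs.
#'
#' @param atomA,atomB [atom_site()] objects (isotropic ADPs are promoted to
#'   the equivalent tensor).
#' @param cell The [unit_cell()].
#' @return Delta in A^2.
#' @export
hirshfeld_delta <- function(atomA, atomB, cell) {
  M <- orthogonalization_matrix(cell)
  r <- drop(M %*% (atomA$xyz - atomB$xyz))
  nr <- sqrt(sum(r^2))
  if (nr < 1e-8)
    stop("coincident atoms: rigid-bond direction undefined", call. = FALSE)
  z <- r / nr
  drop(t(z) %*% u_cartesian(atomA, cell) %*% z -
       t(z) %*% u_cartesian(atomB, cell) %*% z)
}

# ---- observational equations ---------------------------------------------

# value + sparse gradient over model quantities for a plain distance
.distance_value <- function(model, a, b) {
  M <- orthogonalization_matrix(model$cell)
  xa <- model$atoms[[find_atom(model, a)]]$xyz
  xb <- model$atoms[[find_atom(model, b)]]$xyz
  r <- drop(M %*% (xa - xb))
  d <- sqrt(sum(r^2))
  if (d < 1e-10) stop("coincident atoms in distance restraint", call. = FALSE)
  u <- r / d
  g <- drop(t(M) %*% u)  # d(d)/d(frac of a); negated for b
  list(value = d, grads = list(a = g, b = -g))
}

.angle_value <- function(model, a, b, c) {
  M <- orthogonalization_matrix(model$cell)
  ra <- drop(M %*% model$atoms[[find_atom(model, a)]]$xyz)
  rb <- drop(M %*% model$atoms[[find_atom(model, b)]]$xyz)
  rc <- drop(M %*% model$atoms[[find_atom(model, c)]]$xyz)
  u <- ra - rb; v <- rc - rb
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  u <- u / nu; v <- v / nv
  ct <- max(-1, min(1, sum(u * v)))
  st <- sqrt(max(1 - ct^2, 1e-12))
  theta <- acos(ct) * 180 / pi
  k <- 180 / pi
  dA <- k * (ct * u - v) / (nu * st)
  dC <- k * (ct * v - u) / (nv * st)
  dB <- -(dA + dC)
  Mt <- t(M)
  list(value = theta,
       grads = list(a = drop(Mt %*% dA), b = drop(Mt %*% dB),
                    c = drop(Mt %*% dC)))
}

# map sparse quantity-space entries to free-parameter space via the chain
.fold_row <- function(pmap, qids, qvals) {
  row <- numeric(pmap$n_free)
  for (k in seq_along(qids)) {
    tr <- pmap$T[qids[k], ]
    nz <- which(tr != 0)
    row[nz] <- row[nz] + qvals[k] * tr[nz]
  }
  idx <- which(row != 0)
  list(idx = idx, vals = row[idx])
}

.qid_of <- function(pmap, label, param) {
  k <- which(pmap$qtab$label == label & pmap$qtab$param == param)
  if (length(k) != 1)
    stop("no model quantity ", label, ".", param, call. = FALSE)
  k
}

# coefficients of U_eq (or a Hirshfeld projection) in the CIF Uij basis:
# both are linear in Uij, so evaluate on basis tensors
.ueq_coeffs <- function(cell) {
  M <- orthogonalization_matrix(cell)
  N <- diag(recip_lengths(cell))
  vapply(1:6, function(j) {
    u <- numeric(6); u[j] <- 1
    sum(diag(M %*% N %*% uij_to_matrix(u) %*% N %*% t(M))) / 3
  }, 0)
}

#' Evaluate a restraint's observational equation
#'
#' Returns the weighted residual `(current - target)/sigma` and the sparse
#' weighted Jacobian row (entries only for parameters of the involved
#' atoms, folded through the parameter map).  For asymmetric restraints,
#' entries on the reference group's parameters are zeroed: the reference
#' geometry is re-read each cycle but never pulled.
#'
#' @param r A [restraint()] (expanded kind).
#' @param model The [crystal_model()].
#' @param pmap A [build_parameter_map()] result.
#' @return List with `residual`, `idx` (free-parameter indices), `vals`
#'   (Jacobian entries divided by sigma).
#' @export
restraint_equation <- function(r, model, pmap) {
  qids <- integer(); qvals <- numeric(); value <- NA_real_; target <- r$target
  cell <- model$cell
  add <- function(label, params, g) {
    for (i in seq_along(params)) {
      qids <<- c(qids, .qid_of(pmap, label, params[i]))
      qvals <<- c(qvals, g[i])
    }
  }
  if (r$kind == "DISTANCE") {
    dv <- .distance_value(model, r$atoms[1], r$atoms[2])
    value <- dv$value
    add(r$atoms[1], c("x", "y", "z"), dv$grads$a)
    add(r$atoms[2], c("x", "y", "z"), dv$grads$b)
  } else if (r$kind == "ANGLE") {
    av <- .angle_value(model, r$atoms[1], r$atoms[2], r$atoms[3])
    value <- av$value
    add(r$atoms[1], c("x", "y", "z"), av$grads$a)
    add(r$atoms[2], c("x", "y", "z"), av$grads$b)
    add(r$atoms[3], c("x", "y", "z"), av$grads$c)
  } else if (r$kind %in% c("EQUIV_DISTANCE", "EQUIV_ANGLE")) {
    # residual = (d(mapped) - d(reference)) / sigma; for self-pairs from
    # mirror self-maps the contributions cancel to an all-zero row
    d_ref <- .distance_value(model, r$atoms[1], r$atoms[2])
    d_map <- .distance_value(model, r$atoms2[1], r$atoms2[2])
    value <- d_map$value - d_ref$value
    target <- 0
    add(r$atoms2[1], c("x", "y", "z"), d_map$grads$a)
    add(r$atoms2[2], c("x", "y", "z"), d_map$grads$b)
    add(r$atoms[1], c("x", "y", "z"), -d_ref$grads$a)
    add(r$atoms[2], c("x", "y", "z"), -d_ref$grads$b)
  } else if (r$kind == "SIMU") {
    A <- model$atoms[[find_atom(model, r$atoms[1])]]
    B <- model$atoms[[find_atom(model, r$atoms[2])]]
    comp <- r$component
    if (comp == "ueq") {
      value <- u_equiv(A, cell) - u_equiv(B, cell)
      co <- .ueq_coeffs(cell)
      un <- c("u11", "u22", "u33", "u12", "u13", "u23")
      for (at in list(list(s = A, sg = 1), list(s = B, sg = -1))) {
        if (at$s$adp_type == "iso") add(at$s$label, "uiso", at$sg)
        else add(at$s$label, un, at$sg * co)
      }
    } else if (comp == "uiso") {
      value <- A$uiso - B$uiso
      add(A$label, "uiso", 1); add(B$label, "uiso", -1)
    } else {
      j <- match(comp, c("u11", "u22", "u33", "u12", "u13", "u23"))
      value <- A$uaniso[j] - B$uaniso[j]
      add(A$label, comp, 1); add(B$label, comp, -1)
    }
    target <- 0
  } else if (r$kind == "RIGID_BOND") {
    A <- model$atoms[[find_atom(model, r$atoms[1])]]
    B <- model$atoms[[find_atom(model, r$atoms[2])]]
    value <- hirshfeld_delta(A, B, cell)
    # ADP part is exactly linear: coefficients from the projected basis
    M <- orthogonalization_matrix(cell)
    rr <- drop(M %*% (A$xyz - B$xyz))
    z <- rr / sqrt(sum(rr^2))
    v <- drop(diag(recip_lengths(cell)) %*% t(M) %*% z)
    w6 <- c(v[1]^2, v[2]^2, v[3]^2, 2 * v[1] * v[2], 2 * v[1] * v[3],
            2 * v[2] * v[3])
    un <- c("u11", "u22", "u33", "u12", "u13", "u23")
    for (at in list(list(s = A, sg = 1), list(s = B, sg = -1))) {
      if (at$s$adp_type == "iso") add(at$s$label, "uiso", at$sg)
      else add(at$s$label, un, at$sg * w6)
    }
    # positional dependence through the bond direction: central differences
    h <- 1e-6
    for (at in c(r$atoms[1], r$atoms[2])) {
      i <- find_atom(model, at)
      for (ax in 1:3) {
        mp <- model; mp$atoms[[i]]$xyz[ax] <- mp$atoms[[i]]$xyz[ax] + h
        mm <- model; mm$atoms[[i]]$xyz[ax] <- mm$atoms[[i]]$xyz[ax] - h
        g <- (hirshfeld_delta(mp$atoms[[find_atom(mp, r$atoms[1])]],
                              mp$atoms[[find_atom(mp, r$atoms[2])]], cell) -
              hirshfeld_delta(mm$atoms[[find_atom(mm, r$atoms[1])]],
                              mm$atoms[[find_atom(mm, r$atoms[2])]], cell)) /
          (2 * h)
        add(at, c("x", "y", "z")[ax], g)
      }
    }
    target <- 0
  } else {
    stop("cannot evaluate restraint kind ", r$kind,
         " (unexpanded directive?)", call. = FALSE)
  }
  if (is.na(target)) target <- 0
  # asymmetric: zero all entries on reference-group parameters
  if (isTRUE(r$asym) && length(r$ref_atoms)) {
    keep <- !(pmap$qtab$label[qids] %in% r$ref_atoms)
    qids <- qids[keep]; qvals <- qvals[keep]
  }
  fr <- .fold_row(pmap, qids, qvals / r$sigma)
  list(residual = (value - target) / r$sigma, idx = fr$idx, vals = fr$vals,
       value = value)
}

#' Shift-limiting restraint rows
#'
#' One diagonal damping equation per free parameter: residual 0, Jacobian
#' `1/sigma` on that parameter.  Accumulating these is algebraically
#' identical to adding `1/sigma^2` to every diagonal element of the normal
#' matrix (Levenberg-style damping), the sanctioned way to coax a slowly
#' converging refinement to convergence.
#'
#' @param pmap A [build_parameter_map()] result.
#' @param sigma Damping sigma (> 0); larger means weaker damping.
#' @return List of equation rows (as from [restraint_equation()]).
#' @export
shift_limit_equations <- function(pmap, sigma) {
  if (sigma <= 0) stop("shift-limit sigma must be > 0", call. = FALSE)
  lapply(seq_len(pmap$n_free), function(i)
    list(residual = 0, idx = i, vals = 1 / sigma, value = 0))
}

#' Evaluate every restraint in a set
#'
#' @param rset Expanded [restraint_set()].
#' @param model The [crystal_model()].
#' @param pmap A [build_parameter_map()] result.
#' @return List of equation rows (LIMIT entries become shift-limit rows).
#' @export
restraint_equations <- function(rset, model, pmap) {
  rows <- list()
  for (r in rset$restraints) {
    if (r$kind == "LIMIT") {
      rows <- c(rows, shift_limit_equations(pmap, r$sigma))
    } else {
      rows[[length(rows) + 1]] <- restraint_equation(r, model, pmap)
    }
  }
  rows
}
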