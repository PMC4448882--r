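#' Hydrogen placement plan
#'
#' One row per parent carbon: geometry class, number of hydrogens, target
#' bond length and u_iso rule.  Defaults follow standard small-molecule
#' X-ray conventions: C-H 0.95 A (sp1/sp2), 0.98 A (sp3);
#' `u_iso(H) = 1.2 x U_eq(parent)`, 1.5 for methyl.
#'
#' @param parent Parent atom labels.
#' @param class Geometry class per parent: `"sp1"`, `"sp2"` or `"sp3"`.
#' @param n_h Hydrogens to add per parent.
#' @param length Target C-H distance (A); `NA` picks the class default.
#' @param u_mult u_iso multiplier; `NA` picks 1.2 (1.5 for 3H sp3).
#' @return data.frame of class `hydrogen_plan`.
#' @export
hydrogen_plan <- function(parent, class, n_h = 1, length = NA, u_mult = NA) {
  df <- data.frame(parent = parent, class = class, n_h = n_h,
                   length = length, u_mult = u_mult,
                   stringsAsFactors = FALSE)
  df$length <- ifelse(is.na(df$length),
                      ifelse(df$class == "sp3", 0.98, 0.95), df$length)
  df$u_mult <- ifelse(is.na(df$u_mult),
                      ifelse(df$class == "sp3" & df$n_h == 3, 1.5, 1.2),
                      df$u_mult)
  if (any(df$u_mult <= 0)) stop("u_iso multiplier must be > 0", call. = FALSE)
  class(df) <- c("hydrogen_plan", class(df))
  df
}

.unit <- function(v) v / sqrt(sum(v^2))

#' Add hydrogen atoms geometrically
#'
#' Places hydrogens on sp1, sp2 and sp3 carbons from the heavy-atom
#' geometry: linear continuation (sp1), in-plane external bisector (sp2),
#' tetrahedron completion (sp3 with 3 neighbors), staggered pairs/methyls
#' about the remaining axis (sp3 with 2/1 neighbors).  A methyl with no
#' reference substituent on its neighbor gets a documented default torsion
#' with a warning.
#'
#' @param model A [crystal_model()].
#' @param conn A [connectivity()] over the heavy atoms.
#' @param plan A [hydrogen_plan()].
#' @return The model with hydrogen [atom_site()]s appended and a
#'   `hydrogens` bookkeeping table (label, parent, length, u_mult) stored
#'   as `model$hydrogens`.
#' @export
place_hydrogens <- function(model, conn, plan) {
  M <- orthogonalization_matrix(model$cell)
  Minv <- solve(M)
  cart <- function(label) drop(M %*% model$atoms[[find_atom(model, label)]]$xyz)
  book <- model$hydrogens
  tet <- 109.4712206  # ideal tetrahedral angle, degrees
  for (k in seq_len(nrow(plan))) {
    p <- plan[k, ]
    rp <- cart(p$parent)
    nbrs <- bonded_neighbors(conn, p$parent)
    nbrs <- nbrs[nbrs %in% site_labels(model)]
    U <- lapply(nbrs, function(nb) .unit(cart(nb) - rp))
    dirs <- NULL
    if (p$class == "sp1") {
      if (length(U) < 1) stop("sp1 parent ", p$parent, " has no neighbor",
                              call. = FALSE)
      dirs <- list(-U[[1]])
    } else if (p$class == "sp2") {
      if (length(U) < 2)
        stop("sp2 parent ", p$parent, " needs two neighbors", call. = FALSE)
      dirs <- list(.unit(-(U[[1]] + U[[2]])))
    } else if (p$class == "sp3") {
      if (length(U) >= 3 && p$n_h == 1) {
        dirs <- list(.unit(-(U[[1]] + U[[2]] + U[[3]])))
      } else if (length(U) == 2 && p$n_h == 2) {
        b <- .unit(-(U[[1]] + U[[2]]))
        perp <- .unit(pracma_cross(U[[1]], U[[2]]))
        half <- tet / 2 * pi / 180
        dirs <- list(.unit(b * cos(half) + perp * sin(half)),
                     .unit(b * cos(half) - perp * sin(half)))
      } else if (length(U) == 1 && p$n_h == 3) {
        ax <- -U[[1]]  # from neighbor through parent
        nb2 <- setdiff(bonded_neighbors(conn, nbrs[1]), p$parent)
        nb2 <- nb2[nb2 %in% site_labels(model)]
        if (length(nb2) == 0) {
          warning("methyl on ", p$parent,
                  ": no reference substituent, using default torsion",
                  call. = FALSE)
          e1 <- .unit(pracma_cross(ax, if (abs(ax[1]) < 0.9) c(1, 0, 0)
                                       else c(0, 1, 0)))
        } else {
          vref <- cart(nb2[1]) - cart(nbrs[1])
          e1 <- .unit(vref - sum(vref * ax) * ax)
        }
        e2 <- pracma_cross(ax, e1)
        pol <- (180 - tet) * pi / 180  # angle of C-H from the axis
        dirs <- lapply(0:2, function(j) {
          phi <- pi + j * 2 * pi / 3  # staggered: first H anti to reference
          .unit(ax * cos(pol) + (e1 * cos(phi) + e2 * sin(phi)) * sin(pol))
        })
      } else {
        stop("unsupported sp3 pattern on ", p$parent, ": ", length(U),
             " neighbors / ", p$n_h, " H", call. = FALSE)
      }
    } else stop("unknown geometry class: ", p$class, call. = FALSE)
    parent_site <- model$atoms[[find_atom(model, p$parent)]]
    for (j in seq_len(p$n_h)) {
      lab <- if (p$n_h == 1) paste0("H", p$parent)
             else paste0("H", p$parent, LETTERS[j])
      xyz <- drop(Minv %*% (rp + p$length * dirs[[j]]))
      model$atoms[[length(model$atoms) + 1]] <-
        atom_site(lab, "H", xyz, occ = parent_site$occ,
                  uiso = p$u_mult * u_equiv(parent_site, model$cell))
      book <- rbind(book, data.frame(label = lab, parent = p$parent,
                                     length = p$length, u_mult = p$u_mult,
                                     stringsAsFactors = FALSE))
    }
  }
  model$hydrogens <- book
  model
}

# cross product (kept local; avoids a dependency for one primitive)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Parameter map with riding hydrogens
#'
#' Builds the parameter map with one riding constraint per placed
#' hydrogen: positional shifts chain onto the parent (a parent shift moves
#' the hydrogen identically, preserving the X-H vector under translation)
#' and `u_iso(H) = multiplier x U_eq(parent)` is refreshed every cycle.
#' No new positional parameters are introduced.
#'
#' @param model A model whose hydrogens were placed by [place_hydrogens()].
#' @param constraints Additional constraint descriptors.
#' @param refine Passed to [build_parameter_map()].
#' @return A `parameter_map`.
#' @export
riding_constraints <- function(model, constraints = list(),
                               refine = c("xyz", "adp", "scale", "shape")) {
  if (is.null(model$hydrogens) || nrow(model$hydrogens) == 0)
    return(build_parameter_map(model, constraints, refine))
  rides <- lapply(seq_len(nrow(model$hydrogens)), function(i)
    list(type = "ride", follower = model$hydrogens$label[i],
         leader = model$hydrogens$parent[i],
         u_mult = model$hydrogens$u_mult[i]))
  build_parameter_map(model, c(constraints, rides), refine)
}

#' Soft-restrained hydrogen refinement cycle
#'
#' A separate least-squares pass, run prior to the final riding-model
#' refinement, in which only hydrogen positions are free.  X-H distance
#' restraints (targets from the placement plan) and 1-3 distance restraints
#' to the parent's heavy neighbors (targets from the current geometry,
#' preserving the placement angles) keep the geometry sensible while the
#' hydrogens settle into the data.
#'
#' @param model Model with placed hydrogens.
#' @param reflections A [reflection_set()].
#' @param conn Heavy-atom [connectivity()].
#' @param config A [refine_config()].
#' @param sigma_d Sigma of the X-H distance restraints (A).
#' @param sigma_13 Sigma of the 1-3 angle-preserving distances (A).
#' @return The model with refined hydrogen positions.
#' @export
restrained_h_cycle <- function(model, reflections, conn,
                               config = refine_config(max_cycles = 5),
                               sigma_d = 0.02, sigma_13 = 0.04) {
  hb <- model$hydrogens
  if (is.null(hb) || nrow(hb) == 0) return(model)
  heavy <- setdiff(site_labels(model), hb$label)
  # heavy atoms and all non-positional parameters stay fixed
  constraints <- list(list(type = "fix", labels = heavy))
  pmap <- build_parameter_map(model, constraints, refine = "xyz")
  rl <- list()
  for (i in seq_len(nrow(hb))) {
    rl[[length(rl) + 1]] <- restraint("DISTANCE",
                                      c(hb$parent[i], hb$label[i]),
                                      target = hb$length[i], sigma = sigma_d)
    for (nb in bonded_neighbors(conn, hb$parent[i])) {
      if (!nb %in% site_labels(model)) next
      cur <- .distance_value(model, nb, hb$label[i])$value
      rl[[length(rl) + 1]] <- restraint("DISTANCE", c(nb, hb$label[i]),
                                        target = cur, sigma = sigma_13)
    }
  }
  res <- refine(model, reflections, restraint_set(rl), config, pmap = pmap)
  out <- res$model
  out$hydrogens <- hb
  out
}
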