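#' Enumerate refinable model quantities
#'
#' Returns one row per scalar model quantity in a fixed canonical order:
#' for each atom x, y, z, then uiso or u11..u23, then occ; for each shape
#' x, y, z, uiso, magnitude, declination, azimuth, occ; finally the overall
#' scale.
#'
#' @param model A [crystal_model()].
#' @return data.frame with columns `site_type`, `site`, `label`, `param`.
#' @export
quantity_table <- function(model) {
  rows <- list()
  for (i in seq_along(model$atoms)) {
    a <- model$atoms[[i]]
    adp <- if (a$adp_type == "iso") "uiso" else
      c("u11", "u22", "u33", "u12", "u13", "u23")
    rows[[length(rows) + 1]] <- data.frame(
      site_type = "atom", site = i, label = a$label,
      param = c("x", "y", "z", adp, "occ"), stringsAsFactors = FALSE)
  }
  for (i in seq_along(model$shapes)) {
    s <- model$shapes[[i]]
    rows[[length(rows) + 1]] <- data.frame(
      site_type = "shape", site = i, label = s$label,
      param = c("x", "y", "z", "uiso", "magnitude", "declination",
                "azimuth", "occ"), stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1]] <- data.frame(site_type = "global", site = 0L,
                                         label = "", param = "scale",
                                         stringsAsFactors = FALSE)
  qt <- do.call(rbind, rows)
  qt$qid <- seq_len(nrow(qt))
  qt$qname <- ifelse(qt$site_type == "global", qt$param,
                     paste(qt$label, qt$param, sep = "."))
  qt
}

#' Extract the model quantity vector
#' @param model A [crystal_model()].
#' @return Numeric vector in [quantity_table()] order.
#' @export
get_quantities <- function(model) {
  qt <- quantity_table(model)
  v <- numeric(nrow(qt))
  for (k in seq_len(nrow(qt))) {
    p <- qt$param[k]
    v[k] <- switch(qt$site_type[k],
      atom = {
        a <- model$atoms[[qt$site[k]]]
        switch(p, x = a$xyz[1], y = a$xyz[2], z = a$xyz[3],
               uiso = a$uiso, occ = a$occ,
               u11 = a$uaniso[1], u22 = a$uaniso[2], u33 = a$uaniso[3],
               u12 = a$uaniso[4], u13 = a$uaniso[5], u23 = a$uaniso[6])
      },
      shape = {
        s <- model$shapes[[qt$site[k]]]
        switch(p, x = s$xyz[1], y = s$xyz[2], z = s$xyz[3],
               uiso = s$uiso, magnitude = s$magnitude,
               declination = s$declination, azimuth = s$azimuth, occ = s$occ)
      },
      global = model$scale)
  }
  v
}

#' Write a quantity vector back into a model
#' @param model A [crystal_model()].
#' @param values Numeric vector as returned by [get_quantities()].
#' @return Updated model.
#' @export
set_quantities <- function(model, values) {
  qt <- quantity_table(model)
  stopifnot(length(values) == nrow(qt))
  for (k in seq_len(nrow(qt))) {
    p <- qt$param[k]; v <- values[k]
    if (qt$site_type[k] == "atom") {
      i <- qt$site[k]
      a <- model$atoms[[i]]
      if (p == "x") a$xyz[1] <- v else if (p == "y") a$xyz[2] <- v
      else if (p == "z") a$xyz[3] <- v else if (p == "uiso") a$uiso <- v
      else if (p == "occ") a$occ <- v
      else a$uaniso[match(p, c("u11", "u22", "u33", "u12", "u13", "u23"))] <- v
      model$atoms[[i]] <- a
    } else if (qt$site_type[k] == "shape") {
      i <- qt$site[k]
      s <- model$shapes[[i]]
      if (p == "x") s$xyz[1] <- v else if (p == "y") s$xyz[2] <- v
      else if (p == "z") s$xyz[3] <- v
      else s[[p]] <- v
      model$shapes[[i]] <- s
    } else model$scale <- v
  }
  model
}

#' Build the parameter map
#'
#' Maps refinable model quantities to refinement-vector indices and encodes
#' constraints as a linear chain: design-matrix columns for constrained
#' quantities fold onto the indices of the quantities that carry them, and
#' shifts propagate back the same way.  Removing correlated parameters by
#' constraint (rather than restraint) is the sanctioned cure for
#' multicollinearity.
#'
#' Supported constraint list entries:
#' \describe{
#'   \item{`list(type="fix", labels, params=NULL)`}{fix all (or named)
#'     parameters of the labelled sites.}
#'   \item{`list(type="free", labels, params)`}{free parameters that are
#'     fixed by default (e.g. `"occ"`).}
#'   \item{`list(type="ride", follower, leader, u_mult=1.2)`}{riding
#'     hydrogen: follower's positional shifts equal the leader's; the
#'     follower's u_iso is derived as `u_mult * U_eq(leader)` each cycle
#'     and carries no index.}
#'   \item{`list(type="share_adp", labels)`}{all members share one set of
#'     ADP indices (the first member's).}
#'   \item{`list(type="occ_sum", labels, total=1)`}{occupancies free but
#'     summing to `total`; the last member is eliminated with coefficient
#'     -1 against the others.}
#' }
#'
#' @param model A [crystal_model()].
#' @param constraints List of constraint descriptors (above).
#' @param refine Character vector naming which default classes refine:
#'   subset of `c("xyz", "adp", "occ", "scale", "shape")`.
#' @return Object of class `parameter_map` with elements `qtab`, `T`
#'   (n_quantities x n_free chain matrix), `n_free`, `free_names`,
#'   `riders`.
#' @export
build_parameter_map <- function(model, constraints = list(),
                                refine = c("xyz", "adp", "scale", "shape")) {
  qt <- quantity_table(model)
  nq <- nrow(qt)
  labels <- site_labels(model)
  for (cs in constraints) {
    bad <- setdiff(unlist(cs[c("labels", "follower", "leader")]), labels)
    if (length(bad))
      stop("constraint references unknown site(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }

  adp_params <- c("uiso", "u11", "u22", "u33", "u12", "u13", "u23")
  # default status
  status <- rep("fixed", nq)
  is_xyz <- qt$param %in% c("x", "y", "z")
  is_adp <- qt$param %in% adp_params
  if ("xyz" %in% refine) status[is_xyz] <- "free"
  if ("adp" %in% refine) status[is_adp & qt$site_type == "atom"] <- "free"
  if ("occ" %in% refine) status[qt$param == "occ"] <- "free"
  if ("scale" %in% refine) status[qt$param == "scale"] <- "free"
  if ("shape" %in% refine) {
    sh <- qt$site_type == "shape"
    status[sh & qt$param %in% c("uiso", "magnitude")] <- "free"
    for (i in seq_along(model$shapes)) {
      if (model$shapes[[i]]$kind != "shell") {
        status[sh & qt$site == i &
               qt$param %in% c("declination", "azimuth")] <- "free"
      }
    }
  }

  qrows <- function(lab, params = NULL) {
    sel <- qt$label == lab
    if (!is.null(params)) sel <- sel & qt$param %in% params
    which(sel)
  }

  explicit <- rep(NA_character_, nq)  # user-forced status, for conflicts
  chains <- vector("list", nq)        # list of (qid, coeff) targets
  riders <- list()

  for (cs in constraints) {
    type <- cs$type
    if (type == "fix") {
      # last-wins against earlier free/fix; conflicts with sharing are
      # detected when the share constraint is processed
      for (lab in cs$labels) for (k in qrows(lab, cs$params)) {
        explicit[k] <- "fixed"; status[k] <- "fixed"
      }
    } else if (type == "free") {
      for (lab in cs$labels) for (k in qrows(lab, cs$params)) {
        explicit[k] <- "free"; status[k] <- "free"
      }
    } else if (type == "ride") {
      if (length(qrows(cs$leader)) == 0)
        stop("riding leader not found: ", cs$leader, call. = FALSE)
      for (ax in c("x", "y", "z")) {
        kf <- qrows(cs$follower, ax); kl <- qrows(cs$leader, ax)
        status[kf] <- "chained"
        chains[[kf]] <- list(list(qid = kl, coeff = 1))
      }
      ku <- qrows(cs$follower, "uiso")
      status[ku] <- "derived"
      riders[[length(riders) + 1]] <- list(follower = cs$follower,
                                           leader = cs$leader,
                                           u_mult = if (is.null(cs$u_mult)) 1.2 else cs$u_mult)
    } else if (type == "share_adp") {
      lead <- cs$labels[1]
      lead_rows <- qrows(lead, adp_params)
      types <- vapply(cs$labels, function(l)
        model$atoms[[find_atom(model, l)]]$adp_type, "")
      if (length(unique(types)) > 1)
        stop("share_adp members mix isotropic and anisotropic ADPs", call. = FALSE)
      for (lab in cs$labels[-1]) {
        mem_rows <- qrows(lab, adp_params)
        for (j in seq_along(mem_rows)) {
          k <- mem_rows[j]
          if (identical(explicit[k], "fixed"))
            stop("constraint conflict: ", qt$qname[k],
                 " fixed but shared to a free group", call. = FALSE)
          status[k] <- "chained"
          chains[[k]] <- list(list(qid = lead_rows[j], coeff = 1))
        }
      }
    } else if (type == "occ_sum") {
      occ_rows <- vapply(cs$labels, function(l) qrows(l, "occ"), 0L)
      status[occ_rows] <- "free"
      last <- occ_rows[length(occ_rows)]
      status[last] <- "chained"
      chains[[last]] <- lapply(occ_rows[-length(occ_rows)],
                               function(q) list(qid = q, coeff = -1))
    } else stop("unknown constraint type: ", type, call. = FALSE)
  }

  # no chains-of-chains (riding on a riding atom, sharing with a rider...)
  for (k in which(status == "chained")) {
    for (tgt in chains[[k]]) {
      if (status[tgt$qid] %in% c("chained", "derived"))
        stop("chained constraint targets a constrained quantity (",
             qt$qname[k], " -> ", qt$qname[tgt$qid],
             "): chains must terminate on free parameters", call. = FALSE)
    }
  }

  free_qids <- which(status == "free")
  n_free <- length(free_qids)
  index_of <- rep(NA_integer_, nq)
  index_of[free_qids] <- seq_len(n_free)

  T <- matrix(0, nq, n_free)
  for (j in seq_len(n_free)) T[free_qids[j], j] <- 1
  for (k in which(status == "chained")) {
    for (tgt in chains[[k]]) {
      jj <- index_of[tgt$qid]
      if (is.na(jj)) next  # chained to a fixed quantity: stays put
      T[k, jj] <- T[k, jj] + tgt$coeff
    }
  }

  structure(list(qtab = qt, status = status, T = T, n_free = n_free,
                 free_qids = free_qids, free_names = qt$qname[free_qids],
                 riders = riders),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("parameter map: %d free of %d model quantities (%d constrained, %d fixed)\n",
              x$n_free, nrow(x$qtab), sum(x$status %in% c("chained", "derived")),
              sum(x$status == "fixed")))
  invisible(x)
}

#' Apply refinement shifts to a model
#'
#' Propagates a shift vector through the constraint chain
#' (`delta_q = T %*% shifts`), writes the updated quantities back, and
#' refreshes derived riding-hydrogen u_iso values.
#'
#' @param model A [crystal_model()].
#' @param pmap The [build_parameter_map()] result.
#' @param shifts Numeric vector of length `pmap$n_free`.
#' @return Updated model.
#' @export
apply_shifts <- function(model, pmap, shifts) {
  stopifnot(length(shifts) == pmap$n_free)
  q <- get_quantities(model) + drop(pmap$T %*% shifts)
  model <- set_quantities(model, q)
  refresh_riders(model, pmap)
}

# u_iso(H) = mult * U_eq(parent), re-evaluated whenever the model changes
refresh_riders <- function(model, pmap) {
  for (r in pmap$riders) {
    i <- find_atom(model, r$follower)
    p <- find_atom(model, r$leader)
    model$atoms[[i]]$uiso <- r$u_mult * u_equiv(model$atoms[[p]], model$cell)
  }
  model
}
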