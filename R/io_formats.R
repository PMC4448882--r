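#' Read a SHELX-style .hkl file (HKLF 4)
#'
#' Fixed-width `3I4, 2F8.2` records holding h, k, l, Fo^2, sigma(Fo^2).
#' Parsing stops at the all-zero terminator record (or end of file).
#'
#' @param path File path.
#' @return A [reflection_set()] (values stored as Fo^2).
#' @export
read_hkl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hkl <- matrix(0L, 0, 3); Fsq <- numeric(); sig <- numeric()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    if (nchar(line) < 28)
      stop("hkl parse error at line ", ln, ": record shorter than 3I4,2F8.2",
           call. = FALSE)
    fields <- c(substr(line, 1, 4), substr(line, 5, 8), substr(line, 9, 12),
                substr(line, 13, 20), substr(line, 21, 28))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop("hkl parse error at line ", ln, ": non-numeric field", call. = FALSE)
    if (all(vals[1:3] == 0)) break  # terminator: ignore anything after
    hkl <- rbind(hkl, as.integer(vals[1:3]))
    Fsq <- c(Fsq, vals[4]); sig <- c(sig, vals[5])
  }
  reflection_set(hkl, Fsq, sig)
}

#' Write a SHELX-style .hkl file (HKLF 4)
#'
#' @param rs A [reflection_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hkl <- function(rs, path) {
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f",
                   rs$hkl[, 1], rs$hkl[, 2], rs$hkl[, 3], rs$Fsq, rs$sigma)
  writeLines(c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0, 0, 0, 0, 0)), path)
  invisible(path)
}

#' Read a SQUEEZE-style .fab solvent-contribution file
#'
#' Whitespace-delimited `h k l A B` records giving the complex
#' disordered-solvent structure factor per reflection, to be added to the
#' calculated structure factors.  Comment lines starting with `!` or `#`
#' are skipped.  Contributions are aligned to the reflection set by hkl;
#' reflections absent from the file get zero.
#'
#' @param path File path.
#' @param rs A [reflection_set()] to align against.
#' @return The reflection set with its `solvent` component filled;
#'   attribute `n_missing` reports reflections with no file entry.
#' @export
read_fab <- function(path, rs) {
  lines <- readLines(path, warn = FALSE)
  key <- character(); A <- numeric(); B <- numeric()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw) || grepl("^[!#]", raw)) next
    toks <- strsplit(raw, "[[:space:]]+")[[1]]
    if (length(toks) != 5)
      stop("fab parse error at line ", ln, ": expected 'h k l A B'",
           call. = FALSE)
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals))
      stop("fab parse error at line ", ln, ": non-numeric field", call. = FALSE)
    k <- paste(vals[1:3], collapse = " ")
    if (k %in% key)
      stop("fab parse error at line ", ln, ": duplicate hkl ", k, call. = FALSE)
    key <- c(key, k); A <- c(A, vals[4]); B <- c(B, vals[5])
  }
  rkey <- paste(rs$hkl[, 1], rs$hkl[, 2], rs$hkl[, 3])
  m <- match(rkey, key)
  solv <- complex(real = ifelse(is.na(m), 0, A[m]),
                  imaginary = ifelse(is.na(m), 0, B[m]))
  rs$solvent <- solv
  attr(rs, "n_missing") <- sum(is.na(m))
  rs
}

#' Write a .fab solvent-contribution file
#' @param hkl n x 3 matrix.
#' @param solvent Complex vector of contributions.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fab <- function(hkl, solvent, path) {
  writeLines(c("! solvent contribution (h k l A B)",
               sprintf("%4d %4d %4d %12.4f %12.4f", hkl[, 1], hkl[, 2],
                       hkl[, 3], Re(solvent), Im(solvent))), path)
  invisible(path)
}

#' Write an fcf-like structure-factor table
#'
#' Plain-text columns `h k l Fo^2 sigma |Fc| phase`.
#'
#' @param rs A [reflection_set()].
#' @param sf A `structure_factor_set` from [calc_structure_factors()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fcf <- function(rs, sf, path) {
  writeLines(c("#  h   k   l      Fo^2     sigma       |Fc|    phase",
               sprintf("%4d%4d%4d%12.3f%10.3f%12.4f%9.2f",
                       rs$hkl[, 1], rs$hkl[, 2], rs$hkl[, 3],
                       rs$Fsq, rs$sigma, sf$Fabs, sf$phase)), path)
  invisible(path)
}

# ---- minimal CIF dialect --------------------------------------------------

.cif_tokens <- function(line) {
  # split on whitespace, honoring single/double quotes
  out <- character(); i <- 1; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (grepl("[[:space:]]", ch)) { i <- i + 1; next }
    if (ch %in% c("'", '"')) {
      j <- regexpr(ch, substr(line, i + 1, n), fixed = TRUE)
      if (j < 0) stop("unterminated quote in CIF line: ", line, call. = FALSE)
      out <- c(out, substr(line, i + 1, i + j - 1))
      i <- i + j + 1
    } else {
      rest <- substr(line, i, n)
      tok <- sub("[[:space:]].*$", "", rest)
      out <- c(out, tok)
      i <- i + nchar(tok)
    }
  }
  out
}

.cif_num <- function(x) as.numeric(sub("\\(.*\\)$", "", x))  # strip esds

#' Read a crystal model from a minimal CIF dialect
#'
#' Supports `_cell_length_*`/`_cell_angle_*`, a
#' `_symmetry_equiv_pos_as_xyz` loop, `_atom_site_*` and
#' `_atom_site_aniso_*` loops, and the custom `_microrefine_shape_*` loop
#' for special-shape sites.  Single data block, no save frames.
#'
#' @param path File path.
#' @return A [crystal_model()].
#' @export
read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^[[:space:]]*#", lines)]
  kv <- list(); loops <- list()
  i <- 1; n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (!nzchar(line) || grepl("^data_", line)) { i <- i + 1; next }
    if (tolower(line) == "loop_") {
      i <- i + 1; tags <- character()
      while (i <= n && grepl("^_", trimws(lines[i]))) {
        tags <- c(tags, trimws(lines[i])); i <- i + 1
      }
      rows <- list()
      while (i <= n) {
        l2 <- trimws(lines[i])
        if (!nzchar(l2) || grepl("^(_|loop_|data_)", l2, ignore.case = TRUE))
          break
        toks <- .cif_tokens(l2)
        if (length(toks) != length(tags))
          stop("CIF loop row at line ", i, " has ", length(toks),
               " values for ", length(tags), " tags", call. = FALSE)
        rows[[length(rows) + 1]] <- toks
        i <- i + 1
      }
      tab <- if (length(rows)) do.call(rbind, rows) else
        matrix(character(), 0, length(tags))
      colnames(tab) <- tags
      loops[[length(loops) + 1]] <- tab
    } else if (grepl("^_", line)) {
      toks <- .cif_tokens(line)
      if (length(toks) >= 2) kv[[toks[1]]] <- paste(toks[-1], collapse = " ")
      i <- i + 1
    } else i <- i + 1
  }
  need <- c("_cell_length_a", "_cell_length_b", "_cell_length_c",
            "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma")
  if (!all(need %in% names(kv)))
    stop("CIF is missing cell items: ",
         paste(setdiff(need, names(kv)), collapse = ", "), call. = FALSE)
  cell <- unit_cell(.cif_num(kv$`_cell_length_a`), .cif_num(kv$`_cell_length_b`),
                    .cif_num(kv$`_cell_length_c`), .cif_num(kv$`_cell_angle_alpha`),
                    .cif_num(kv$`_cell_angle_beta`), .cif_num(kv$`_cell_angle_gamma`))
  find_loop <- function(tag) {
    for (lp in loops) if (tag %in% colnames(lp)) return(lp)
    NULL
  }
  symloop <- find_loop("_symmetry_equiv_pos_as_xyz")
  symops <- if (is.null(symloop) || nrow(symloop) == 0)
    spacegroup_symops("P1")
  else lapply(symloop[, "_symmetry_equiv_pos_as_xyz"], parse_symop)

  atoms <- list()
  atloop <- find_loop("_atom_site_label")
  aniso <- find_loop("_atom_site_aniso_label")
  if (!is.null(atloop)) {
    for (r in seq_len(nrow(atloop))) {
      lab <- atloop[r, "_atom_site_label"]
      atoms[[r]] <- atom_site(
        lab, atloop[r, "_atom_site_type_symbol"],
        c(.cif_num(atloop[r, "_atom_site_fract_x"]),
          .cif_num(atloop[r, "_atom_site_fract_y"]),
          .cif_num(atloop[r, "_atom_site_fract_z"])),
        occ = .cif_num(atloop[r, "_atom_site_occupancy"]),
        uiso = .cif_num(atloop[r, "_atom_site_U_iso_or_equiv"]))
    }
    if (!is.null(aniso)) {
      labels <- vapply(atoms, `[[`, "", "label")
      for (r in seq_len(nrow(aniso))) {
        lab <- aniso[r, "_atom_site_aniso_label"]
        j <- match(lab, labels)
        if (is.na(j))
          stop("CIF aniso loop label '", lab,
               "' has no matching _atom_site entry", call. = FALSE)
        u <- vapply(c("_atom_site_aniso_U_11", "_atom_site_aniso_U_22",
                      "_atom_site_aniso_U_33", "_atom_site_aniso_U_12",
                      "_atom_site_aniso_U_13", "_atom_site_aniso_U_23"),
                    function(tg) .cif_num(aniso[r, tg]), 0)
        a <- atoms[[j]]
        atoms[[j]] <- atom_site(a$label, a$element, a$xyz, a$occ,
                                uaniso = unname(u))
      }
    }
  }
  shapes <- list()
  shloop <- find_loop("_microrefine_shape_label")
  if (!is.null(shloop)) {
    for (r in seq_len(nrow(shloop))) {
      shapes[[r]] <- shape_site(
        shloop[r, "_microrefine_shape_label"],
        shloop[r, "_microrefine_shape_kind"],
        c(.cif_num(shloop[r, "_microrefine_shape_fract_x"]),
          .cif_num(shloop[r, "_microrefine_shape_fract_y"]),
          .cif_num(shloop[r, "_microrefine_shape_fract_z"])),
        element = shloop[r, "_microrefine_shape_element"],
        multiplicity = .cif_num(shloop[r, "_microrefine_shape_multiplicity"]),
        magnitude = .cif_num(shloop[r, "_microrefine_shape_magnitude"]),
        declination = .cif_num(shloop[r, "_microrefine_shape_declination"]),
        azimuth = .cif_num(shloop[r, "_microrefine_shape_azimuth"]),
        uiso = .cif_num(shloop[r, "_microrefine_shape_U_iso"]),
        occ = .cif_num(shloop[r, "_microrefine_shape_occupancy"]))
    }
  }
  scale <- if (!is.null(kv$`_microrefine_scale`))
    .cif_num(kv$`_microrefine_scale`) else 1
  crystal_model(cell, symops, atoms, shapes, scale)
}

#' Write a crystal model in the minimal CIF dialect
#'
#' @param model A [crystal_model()].
#' @param path Output path.
#' @param data_name CIF data block name.
#' @return Invisibly, `path`.
#' @export
write_cif <- function(model, path, data_name = "refined") {
  out <- c(paste0("data_", data_name),
           sprintf("_cell_length_a     %.6f", model$cell$a),
           sprintf("_cell_length_b     %.6f", model$cell$b),
           sprintf("_cell_length_c     %.6f", model$cell$c),
           sprintf("_cell_angle_alpha  %.5f", model$cell$alpha),
           sprintf("_cell_angle_beta   %.5f", model$cell$beta),
           sprintf("_cell_angle_gamma  %.5f", model$cell$gamma),
           sprintf("_microrefine_scale %.8g", model$scale),
           "loop_", "_symmetry_equiv_pos_as_xyz",
           vapply(model$symops, function(op)
             paste0("'", format_symop(op), "'"), ""))
  if (length(model$atoms)) {
    out <- c(out, "loop_", "_atom_site_label", "_atom_site_type_symbol",
             "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
             "_atom_site_occupancy", "_atom_site_U_iso_or_equiv",
             "_atom_site_adp_type",
             vapply(model$atoms, function(a) sprintf(
               "%s %s %.6f %.6f %.6f %.4f %.5f %s",
               a$label, a$element, a$xyz[1], a$xyz[2], a$xyz[3], a$occ,
               u_equiv(a, model$cell),
               if (a$adp_type == "iso") "Uiso" else "Uani"), ""))
    aniso <- Filter(function(a) a$adp_type == "aniso", model$atoms)
    if (length(aniso)) {
      out <- c(out, "loop_", "_atom_site_aniso_label",
               "_atom_site_aniso_U_11", "_atom_site_aniso_U_22",
               "_atom_site_aniso_U_33", "_atom_site_aniso_U_12",
               "_atom_site_aniso_U_13", "_atom_site_aniso_U_23",
               vapply(aniso, function(a) sprintf(
                 "%s %.6f %.6f %.6f %.6f %.6f %.6f", a$label,
                 a$uaniso[1], a$uaniso[2], a$uaniso[3], a$uaniso[4],
                 a$uaniso[5], a$uaniso[6]), ""))
    }
  }
  if (length(model$shapes)) {
    out <- c(out, "loop_", "_microrefine_shape_label",
             "_microrefine_shape_kind", "_microrefine_shape_fract_x",
             "_microrefine_shape_fract_y", "_microrefine_shape_fract_z",
             "_microrefine_shape_U_iso", "_microrefine_shape_magnitude",
             "_microrefine_shape_declination", "_microrefine_shape_azimuth",
             "_microrefine_shape_element", "_microrefine_shape_multiplicity",
             "_microrefine_shape_occupancy",
             vapply(model$shapes, function(s) sprintf(
               "%s %s %.6f %.6f %.6f %.5f %.5f %.4f %.4f %s %d %.4f",
               s$label, s$kind, s$xyz[1], s$xyz[2], s$xyz[3], s$uiso,
               s$magnitude, s$declination, s$azimuth, s$element,
               as.integer(s$multiplicity), s$occ), ""))
  }
  writeLines(out, path)
  invisible(path)
}
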