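#' Symmetry operator
#'
#' A crystallographic symmetry operation acting on fractional coordinates:
#' `x' = R x + t`.
#'
#' @param rotation 3x3 integer matrix with determinant +1 or -1.
#' @param translation Length-3 fractional vector; reduced into `[0,1)`.
#' @return Object of class `symop`.
#' @export
symop <- function(rotation, translation = c(0, 0, 0)) {
  R <- matrix(as.numeric(rotation), 3, 3)
  if (any(abs(R - round(R)) > 1e-9))
    stop("symop rotation must be an integer matrix", call. = FALSE)
  dR <- round(det(R))
  if (!dR %in% c(-1, 1))
    stop("symop rotation must have determinant +1 or -1", call. = FALSE)
  t <- as.numeric(translation) %% 1
  structure(list(R = round(R), t = t), class = "symop")
}

#' Parse a CIF-style symmetry string
#'
#' Parses strings such as `"x, y, z"` or `"-x, y+1/2, -z+1/2"` into a
#' [symop()].
#'
#' @param s Symmetry string with three comma-separated components.
#' @return A [symop()].
#' @export
parse_symop <- function(s) {
  parts <- strsplit(gsub("[ '\"]", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3)
    stop("symmetry string must have three comma-separated components: ", s,
         call. = FALSE)
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # split into signed terms
    expr <- gsub("-", "+-", expr)
    terms <- strsplit(expr, "\\+")[[1]]
    terms <- terms[nzchar(terms)]
    for (term in terms) {
      sign <- 1
      if (startsWith(term, "-")) { sign <- -1; term <- substring(term, 2) }
      if (term %in% c("x", "y", "z")) {
        R[i, match(term, c("x", "y", "z"))] <-
          R[i, match(term, c("x", "y", "z"))] + sign
      } else if (grepl("^[0-9]+/[0-9]+$", term)) {
        num <- as.numeric(strsplit(term, "/")[[1]])
        t[i] <- t[i] + sign * num[1] / num[2]
      } else if (grepl("^[0-9.]+$", term)) {
        t[i] <- t[i] + sign * as.numeric(term)
      } else {
        stop("cannot parse symmetry term '", term, "' in: ", s, call. = FALSE)
      }
    }
  }
  symop(R, t)
}

#' Format a symop as a CIF-style string
#' @param op A [symop()].
#' @return Character string such as `"-x, y+1/2, -z+1/2"`.
#' @export
format_symop <- function(op) {
  ax <- c("x", "y", "z")
  comps <- vapply(1:3, function(i) {
    s <- ""
    for (j in 1:3) {
      r <- op$R[i, j]
      if (r == 0) next
      s <- paste0(s, if (r > 0 && nzchar(s)) "+" else if (r < 0) "-" else "",
                  ax[j])
    }
    ti <- op$t[i]
    if (abs(ti) > 1e-9) {
      fr <- .as_fraction(ti)
      s <- paste0(s, "+", fr)
    }
    s
  }, character(1))
  paste(comps, collapse = ", ")
}

.as_fraction <- function(x) {
  for (den in c(2, 3, 4, 6)) {
    num <- x * den
    if (abs(num - round(num)) < 1e-9) return(paste0(round(num), "/", den))
  }
  format(x)
}

#' Apply a symmetry operator to fractional coordinates
#'
#' @param op A [symop()].
#' @param frac_xyz Fractional coordinate triple.
#' @param wrap If `TRUE`, wrap the result into `[0,1)`.
#' @return Transformed fractional coordinates.
#' @export
apply_symmetry <- function(op, frac_xyz, wrap = FALSE) {
  x <- drop(op$R %*% as.numeric(frac_xyz)) + op$t
  if (wrap) x <- x %% 1
  x
}

#' Built-in symmetry operator lists
#'
#' Explicit operator lists for a few common space groups used by the
#' synthetic fixtures.  General symmetry is supplied through CIF
#' `_symmetry_equiv_pos_as_xyz` strings; no symbol lookup tables exist.
#'
#' @param name One of `"P1"`, `"P-1"`, `"P21"`, `"P21/c"`.
#' @return List of [symop()] objects.
#' @export
spacegroup_symops <- function(name) {
  strings <- switch(name,
    "P1"    = "x, y, z",
    "P-1"   = c("x, y, z", "-x, -y, -z"),
    "P21"   = c("x, y, z", "-x, y+1/2, -z"),
    "P21/c" = c("x, y, z", "-x, y+1/2, -z+1/2", "-x, -y, -z", "x, -y+1/2, z+1/2"),
    stop("unknown built-in space group: ", name, call. = FALSE))
  lapply(strings, parse_symop)
}
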