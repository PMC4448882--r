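#' Reflection data set
#'
#' Observed reflection data: Miller indices with intensities Fo^2 and
#' standard uncertainties (HKLF 4 convention), plus an optional
#' per-reflection complex disordered-solvent contribution.
#'
#' @param hkl n x 3 integer matrix.
#' @param Fsq Observed Fo^2 values.
#' @param sigma Standard uncertainties of Fo^2 (> 0).
#' @param solvent Optional complex vector (solvent contribution to Fc).
#' @return Object of class `reflection_set`.
#' @export
reflection_set <- function(hkl, Fsq, sigma, solvent = NULL) {
  hkl <- matrix(as.integer(round(hkl)), ncol = 3)
  n <- nrow(hkl)
  stopifnot(length(Fsq) == n, length(sigma) == n)
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  if (!is.null(solvent) && length(solvent) != n)
    stop("solvent contribution length does not match reflection count",
         call. = FALSE)
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  if (anyDuplicated(key))
    stop("duplicate Miller indices in reflection set", call. = FALSE)
  structure(list(hkl = hkl, Fsq = as.numeric(Fsq), sigma = as.numeric(sigma),
                 solvent = solvent), class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("reflection set: %d reflections%s\n", nrow(x$hkl),
              if (is.null(x$solvent)) "" else " (with solvent contribution)"))
  invisible(x)
}

#' Observed quantity on the refinement target scale
#'
#' Data are stored as Fo^2.  Refinement on F uses
#' `|Fo| = sqrt(max(Fo^2, 0))` with sigma propagated as
#' `sigma(F) = sigma(F^2) / (2 F)`, guarded at weak intensities where the
#' linearised propagation breaks down.
#'
#' @param rs A [reflection_set()].
#' @param mode `"F2"` or `"F"`.
#' @return List with `Yo` and `sigma` on the requested scale.
#' @export
reflection_target <- function(rs, mode = c("F2", "F")) {
  mode <- match.arg(mode)
  if (mode == "F2") return(list(Yo = rs$Fsq, sigma = rs$sigma))
  Fo <- sqrt(pmax(rs$Fsq, 0))
  guard <- pmax(Fo, sqrt(pmax(rs$sigma, 1e-12)) / 2)
  list(Yo = Fo, sigma = rs$sigma / (2 * guard))
}
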