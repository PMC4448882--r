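# X-ray scattering factors: 4-Gaussian + constant approximation
# f(s) = sum_i a_i exp(-b_i s^2) + c,  s = sin(theta)/lambda in 1/A
# (standard International Tables neutral-atom coefficients)
.ff_table <- local({
  m <- rbind(
    H  = c(0.493002, 0.322912, 0.140191, 0.040810, 10.5109, 26.1257, 3.14236, 57.7997, 0.003038),
    C  = c(2.310000, 1.020000, 1.588600, 0.865000, 20.8439, 10.2075, 0.56870, 51.6512, 0.215600),
    N  = c(12.21260, 3.132200, 2.012500, 1.166300, 0.00570, 9.89330, 28.9975, 0.58260, -11.52900),
    O  = c(3.048500, 2.286800, 1.546300, 0.867000, 13.2771, 5.70110, 0.32390, 32.9089, 0.250800),
    F  = c(3.539200, 2.641200, 1.517000, 1.024300, 10.2825, 4.29440, 0.26150, 26.1476, 0.277600),
    P  = c(6.434500, 4.179100, 1.780000, 1.490800, 1.90670, 27.1570, 0.52600, 68.1645, 1.114900),
    S  = c(6.905300, 5.203400, 1.437900, 1.586300, 1.46790, 22.2151, 0.25360, 56.1720, 0.866900),
    Cl = c(11.46040, 7.196400, 6.255600, 1.645500, 0.01040, 1.16620, 18.5194, 47.7784, -9.557400),
    K  = c(8.218600, 7.439800, 1.051900, 0.865900, 12.7949, 0.77480, 213.187, 41.6841, 1.422800),
    Ni = c(12.83760, 7.292000, 4.443800, 2.380000, 3.87850, 0.25650, 12.1763, 66.3421, 1.034100),
    Br = c(17.17890, 5.235800, 5.637700, 3.985100, 2.17230, 16.5796, 0.26090, 41.4328, 2.955700),
    I  = c(20.14720, 18.99490, 7.513800, 2.273500, 4.34700, 0.38140, 27.7660, 66.8776, 4.071200))
  colnames(m) <- c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4", "c")
  m
})

# user-extensible overlay; see register_form_factor()
.ff_extra <- new.env(parent = emptyenv())

#' Atomic scattering factor
#'
#' Evaluates the sum-of-Gaussians X-ray form factor of a neutral atom.
#'
#' @param element Element symbol (built-in: H, C, N, O, F, P, S, Cl, K, Ni,
#'   Br, I; extensible with [register_form_factor()]).
#' @param s `sin(theta)/lambda` in 1/A (scalar or vector, >= 0).
#' @return Form factor in electrons.
#' @examples
#' atomic_form_factor("C", 0)     # ~ 6 electrons
#' atomic_form_factor("C", 0.5)
#' @export
atomic_form_factor <- function(element, s) {
  cf <- form_factor_coefficients(element)
  if (any(s < 0)) stop("s must be >= 0", call. = FALSE)
  s2 <- s * s
  unname(cf["a1"] * exp(-cf["b1"] * s2) + cf["a2"] * exp(-cf["b2"] * s2) +
           cf["a3"] * exp(-cf["b3"] * s2) + cf["a4"] * exp(-cf["b4"] * s2) +
           cf["c"])
}

form_factor_coefficients <- function(element) {
  if (!is.null(.ff_extra[[element]])) return(.ff_extra[[element]])
  if (!element %in% rownames(.ff_table))
    stop("missing scatterer: no form factor for element '", element, "'",
         call. = FALSE)
  .ff_table[element, ]
}

#' Register a custom form factor
#'
#' @param element Symbol to register.
#' @param a,b Length-4 Gaussian amplitude and width coefficients.
#' @param c Constant term.
#' @return Invisibly, the stored coefficient vector.
#' @export
register_form_factor <- function(element, a, b, c) {
  stopifnot(length(a) == 4, length(b) == 4, length(c) == 1)
  v <- c(a, b, c)
  names(v) <- c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4", "c")
  .ff_extra[[element]] <- v
  invisible(v)
}
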