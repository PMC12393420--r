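# Normalized Hill activation.
#
# The activation kernel f(x) = B x^n / (K^n + x^n) is constrained so that
# f(0) = 0, f(ec50) = 0.5 and f(1) = 1. Those three identities fix the gain
# B and half-saturation constant K in closed form:
#   B = (ec50^n - 1) / (2 ec50^n - 1),   K = (B - 1)^(1/n)
# which requires ec50^n < 0.5 (otherwise B <= 1 and K is undefined).

#' Normalized Hill constants
#'
#' Computes the gain `B` and half-saturation constant `K` of the normalized
#' Hill activation from the Hill coefficient and half-maximal input.
#'
#' @param n Hill coefficient (> 0).
#' @param ec50 Half-maximal input activity; admissible range
#'   `0 < ec50 < 0.5^(1/n)`.
#' @return A list of class `hill_parameters` with elements `n`, `ec50`,
#'   `B` and `K`.
#' @examples
#' p <- hill_constants(1.4, 0.5)
#' hill_activation(c(0, 0.5, 1), p)  # 0, 0.5, 1
#' @export
hill_constants <- function(n, ec50) {
  stopifnot(is.numeric(n), length(n) == 1L, is.numeric(ec50), length(ec50) == 1L)
  if (n <= 0) stop("Hill coefficient n must be > 0", call. = FALSE)
  if (ec50 <= 0 || ec50^n >= 0.5) {
    stop("ec50 = ", ec50, " outside admissible range (0, ",
         formatC(0.5^(1 / n), digits = 4, format = "fg"),
         ") for n = ", n, call. = FALSE)
  }
  B <- (ec50^n - 1) / (2 * ec50^n - 1)
  K <- (B - 1)^(1 / n)
  structure(list(n = n, ec50 = ec50, B = B, K = K), class = "hill_parameters")
}

#' Normalized Hill activation function
#'
#' Evaluates `f(x) = B x^n / (K^n + x^n)`. With `B`, `K` from
#' [hill_constants()] the function satisfies `f(0) = 0`, `f(ec50) = 0.5`,
#' `f(1) = 1` and is monotone increasing; for `x > 1` it saturates towards
#' `B > 1` (gate terms clamp it back to 1, see [rule_flux()]).
#'
#' @param x Regulator activity (vectorized, >= 0).
#' @param p A `hill_parameters` object.
#' @return `f(x)`, same length as `x`.
#' @export
hill_activation <- function(x, p) {
  stopifnot(inherits(p, "hill_parameters"))
  if (any(x < 0)) stop("regulator activity must be >= 0", call. = FALSE)
  xn <- x^p$n
  p$B * xn / (p$K^p$n + xn)
}

#' @export
print.hill_parameters <- function(x, ...) {
  cat(sprintf("normalized Hill: n = %g, ec50 = %g, B = %.6g, K = %.6g\n",
              x$n, x$ec50, x$B, x$K))
  invisible(x)
}
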