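#' Truncated-normal initial phenotypic density
#'
#' The initial condition used by the worked examples: a normal density with
#' mean `x_bar0` and standard deviation `sigma0`, truncated to the domain
#' `[l, L]` and scaled so that it integrates to the initial population size
#' `P0`.  The normalizing constant is computed exactly from the normal CDF.
#'
#' @param x_bar0 centre of the initial density, strictly inside `(l, L)`.
#' @param sigma0 standard deviation, > 0.
#' @param l,L domain bounds.
#' @param P0 initial population size (mass of the density), > 0.
#' @return a function of `x` returning the density (zero outside `[l, L]`).
#' @export
truncated_normal_density <- function(x_bar0, sigma0, l, L, P0 = 1) {
  stopifnot(sigma0 > 0, P0 > 0, l < L)
  if (x_bar0 <= l || x_bar0 >= L)
    stop("'x_bar0' must lie strictly inside the domain (", l, ", ", L, ")")
  Z <- sigma0 * sqrt(2 * pi) *
    (stats::pnorm((L - x_bar0) / sigma0) - stats::pnorm((l - x_bar0) / sigma0))
  function(x) {
    v <- P0 * exp(-(x - x_bar0)^2 / (2 * sigma0^2)) / Z
    v[x < l | x > L] <- 0
    v
  }
}
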