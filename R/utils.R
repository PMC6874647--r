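#' @useDynLib ontodriver, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom stats predict
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Derive a stage-specific 32-bit seed from a master seed, so that each
# stochastic stage gets an independent but reproducible stream.
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  s <- (as.double(seed) * 48271 + sum(utf8ToInt(salt)) * 9973) %% 2147483647
  as.integer(s)
}
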