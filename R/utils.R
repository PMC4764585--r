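stop_netdecay <- function(msg, class = "netdecay_error", call = NULL) {
  rlang::abort(msg, class = c(class, "netdecay_error"))
}

#' Derive a reproducible child seed from a global seed
#'
#' Stochastic stages (clade evolution, read simulation, power simulation,
#' shuffling) each draw their own seed from one global seed plus a stream
#' name, so stages are independently reproducible and adding a stage never
#' perturbs the random draws of another.
#'
#' @param seed Integer global seed.
#' @param stream Character stream name (e.g. `"chip"`, `"power"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * (31L^(seq_along(utf8ToInt(stream)) %% 8L)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# 0-based half-open interval overlap width
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
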