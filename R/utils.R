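#' @useDynLib tfmicro, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rgamma rnbinom runif median quantile sd var
#'   coef cor prcomp predict t.test p.adjust spline splinefun setNames
#' @importFrom utils read.table write.table head modifyList
NULL

#' Derive a stage-specific random seed from a global seed
#'
#' Every stochastic stage draws its stream from the global seed plus the stage
#' name, so pipelines are reproducible stage-by-stage without seed collisions.
#' The derived seed is kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * (31L^(seq_along(utf8ToInt(as.character(stage))) %% 7L)))
  as.integer((abs(seed) * 7919 + h) %% .Machine$integer.max)
}

tf_log <- function(..., verbose = getOption("tfmicro.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[tfmicro] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
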