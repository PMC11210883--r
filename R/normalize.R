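#' Normalization specification
#'
#' Declares how a count matrix is placed on the modeling scale. The three
#' settings compared in the simulation study are `"none"`, `"size_factor"`
#' (median-of-ratios per-sample factors) and `"size_factor_asinh"` (size
#' factors followed by the inverse hyperbolic sine, a log-like transform
#' defined at zero). `"tss"` (total sum scaling, column proportions) and
#' `"clr"` (centered log-ratio with a pseudocount) are provided as
#' alternatives.
#'
#' @param method one of `"none"`, `"size_factor"`, `"size_factor_asinh"`,
#'   `"tss"`, `"clr"`.
#' @param pseudocount nonnegative real added before the log in `"clr"`.
#' @param renormalize logical; rescale fitted size factors to unit geometric
#'   mean (off by default).
#' @return an object of class `normalization_spec`.
#' @export
normalization_spec <- function(method = c("none", "size_factor", "size_factor_asinh",
                                          "tss", "clr"),
                               pseudocount = 0.5, renormalize = FALSE) {
  method <- match.arg(method)
  stopifnot(pseudocount >= 0)
  structure(list(method = method, pseudocount = pseudocount,
                 renormalize = renormalize, size_factors = NULL),
            class = "normalization_spec")
}

#' Median-of-ratios size factors
#'
#' The median-of-ratios estimator: each sample's factor is the median over
#' taxa of that sample's count divided by the taxon's geometric mean across
#' samples. Taxa with a zero anywhere have geometric mean 0 and are excluded;
#' if no taxon is positive in every sample the geometric means fall back to
#' averaging logs over positive entries only (poscounts-style), with a
#' warning. Factors are returned unscaled unless `renormalize` is set.
#'
#' @param counts taxa-by-sample nonnegative matrix.
#' @param renormalize rescale factors to unit geometric mean.
#' @return a positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts, renormalize = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  all_zero <- colSums(counts) == 0
  if (any(all_zero))
    stop("sample(s) with all-zero counts: ",
         paste(which(all_zero), collapse = ", "))
  pos_rows <- rowSums(counts > 0) == ncol(counts)
  logc <- log(counts)
  if (any(pos_rows)) {
    loggeo <- rowMeans(logc)       # -Inf for rows with zeros; excluded below
    use <- pos_rows
  } else {
    warning("no taxon positive in every sample; using geometric means over positive entries")
    loggeo <- apply(logc, 1L, function(r) mean(r[is.finite(r)]))
    use <- is.finite(loggeo) & rowSums(counts > 0) > 0
  }
  sf <- apply(counts, 2L, function(cts) {
    r <- log(cts[use]) - loggeo[use]
    exp(median(r[is.finite(r)]))
  })
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor(s); counts too sparse for median-of-ratios")
  if (renormalize) sf <- sf / exp(mean(log(sf)))
  sf
}

#' Apply a normalization to a study collection
#'
#' Transforms every subject's abundance matrix onto the scale declared by
#' `spec` and attaches the (fitted) spec to the returned collection so that
#' downstream forecasts and counterfactuals are interpreted on the right
#' scale. Size factors are fitted on the pooled taxa-by-sample matrix across
#' all subjects and timepoints.
#'
#' @param collection a [study_collection] of counts.
#' @param spec a [normalization_spec].
#' @return the transformed [study_collection] with `$normalization` set.
#' @export
apply_normalization <- function(collection, spec) {
  stopifnot(inherits(spec, "normalization_spec"))
  pooled <- do.call(cbind, collection$abundances)
  n_per <- vapply(collection$abundances, ncol, 1L)
  offsets <- cumsum(c(0L, n_per))
  out <- collection
  if (spec$method %in% c("size_factor", "size_factor_asinh")) {
    sf <- size_factors(pooled, renormalize = spec$renormalize)
    spec$size_factors <- sf
  }
  trans <- switch(
    spec$method,
    none = function(M, cols) M,
    size_factor = function(M, cols) sweep(M, 2L, spec$size_factors[cols], "/"),
    size_factor_asinh = function(M, cols) asinh(sweep(M, 2L, spec$size_factors[cols], "/")),
    tss = function(M, cols) {
      cs <- colSums(M)
      if (any(cs == 0)) stop("tss normalization undefined for all-zero sample(s)")
      sweep(M, 2L, cs, "/")
    },
    clr = function(M, cols) {
      if (spec$pseudocount == 0 && any(M == 0))
        stop("clr with pseudocount 0 requires strictly positive counts")
      L <- log(M + spec$pseudocount)
      sweep(L, 2L, colMeans(L), "-")
    })
  for (i in seq_along(collection$subjects)) {
    s <- collection$subjects[i]
    cols <- offsets[i] + seq_len(n_per[i])
    out$abundances[[s]] <- trans(collection$abundances[[s]], cols)
  }
  out$normalization <- spec
  out
}
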