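#' Simulate counterfactual trajectories under two intervention paths
#'
#' For each subject, runs two h-step forecasts from the same observed history
#' (anchored at `anchor`: by default the first intervention onset when one is
#' present and leaves at least P observed timepoints, otherwise the last
#' observed time), one under `W_on` and one under `W_off`, and records the
#' elementwise difference on - off. An optional covariate override is applied
#' to both arms.
#'
#' @param model a `tf_model`.
#' @param collection a [study_collection] on the model's scale.
#' @param W_on,W_off D x horizon hypothetical intervention paths.
#' @param horizon number of forecast steps.
#' @param z_override optional length-S covariate vector applied to all
#'   subjects in both arms.
#' @param anchor optional named vector of per-subject anchor time indices
#'   (forecasts start after this index).
#' @return an object of class `counterfactual_result`: arrays `y_on`,
#'   `y_off`, `diff` of dimension subject x taxon x horizon.
#' @export
simulate_counterfactuals <- function(model, collection, W_on, W_off, horizon,
                                     z_override = NULL, anchor = NULL) {
  W_on <- as.matrix(W_on); W_off <- as.matrix(W_off)
  if (horizon < 1) stop("horizon must be >= 1")
  if (ncol(W_on) < horizon || ncol(W_off) < horizon)
    stop("both intervention paths must span the horizon")
  if (!is.null(z_override) && length(z_override) != model$S)
    stop("z_override must have length S = ", model$S)
  subs <- collection$subjects
  dims <- c(length(subs), model$J, horizon)
  y_on <- array(NA_real_, dims, dimnames = list(subs, model$taxa, NULL))
  y_off <- y_on
  for (si in seq_along(subs)) {
    s <- subs[si]
    Tn <- length(collection$times[[s]])
    a <- if (!is.null(anchor)) anchor[[s]] else {
      on_t <- which(colSums(collection$interventions[[s]] > 0) > 0)
      if (length(on_t) && on_t[1L] - 1L >= model$P) on_t[1L] - 1L else Tn
    }
    if (a < model$P) stop("anchor leaves fewer than P observed timepoints for subject ", s)
    Yobs <- collection$abundances[[s]][, seq_len(a), drop = FALSE]
    Wobs <- collection$interventions[[s]][, seq_len(a), drop = FALSE]
    z <- if (!is.null(z_override)) z_override
         else if (model$S > 0) collection$covariates[s, ] else numeric(0)
    y_on[si, , ] <- forecast_subject(model, Yobs, cbind(Wobs, W_on), z, horizon)
    y_off[si, , ] <- forecast_subject(model, Yobs, cbind(Wobs, W_off), z, horizon)
  }
  structure(list(y_on = y_on, y_off = y_off, diff = y_on - y_off,
                 W_on = W_on, W_off = W_off, horizon = horizon,
                 z_override = z_override, subjects = subs, taxa = model$taxa),
            class = "counterfactual_result")
}

#' @export
print.counterfactual_result <- function(x, ...) {
  cat("counterfactual_result:", length(x$subjects), "subjects x",
      length(x$taxa), "taxa x horizon", x$horizon, "\n")
  invisible(x)
}

#' Quantile bands of counterfactual differences
#'
#' Per taxon and horizon, the requested quantiles (type-7, linear
#' interpolation) of the subject-level differences; optionally split by a
#' binary subject covariate.
#'
#' @param result a `counterfactual_result`.
#' @param quantiles three probabilities `(q_lo, q_mid, q_hi)`.
#' @param group_by optional name of a binary covariate; `collection` must
#'   then be supplied.
#' @param collection the [study_collection] carrying the covariates (only
#'   needed with `group_by`).
#' @return a data.frame with columns `taxon`, `horizon`, (`group`,) `lo`,
#'   `mid`, `hi`.
#' @export
summarize_differences <- function(result, quantiles = c(0.25, 0.5, 0.75),
                                  group_by = NULL, collection = NULL) {
  stopifnot(length(quantiles) == 3L)
  if (length(result$subjects) == 0L) stop("empty counterfactual result")
  groups <- if (is.null(group_by)) {
    list(all = seq_along(result$subjects))
  } else {
    stopifnot(!is.null(collection))
    gv <- collection$covariates[result$subjects, group_by]
    if (!all(gv %in% c(0, 1))) stop("group covariate must be binary (0/1)")
    split(seq_along(result$subjects), gv)
  }
  out <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    for (j in seq_along(result$taxa)) for (h in seq_len(result$horizon)) {
      qs <- quantile(result$diff[idx, j, h], probs = quantiles, type = 7,
                     names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        taxon = result$taxa[j], horizon = h, group = g,
        lo = qs[1L], mid = qs[2L], hi = qs[3L])
    }
  }
  out <- do.call(rbind, out)
  if (is.null(group_by)) out$group <- NULL
  out
}

#' Representative taxa along the first principal component of differences
#'
#' Orders taxa by their score on the first principal component of the
#' taxon-by-(subject x horizon) counterfactual-difference matrix (the PC sign
#' is fixed by making the largest-magnitude loading positive) and returns
#' every k-th taxon along that ordering. This compresses a large selection
#' set into a displayable, dynamics-spanning subset.
#'
#' @param result a `counterfactual_result`.
#' @param every_kth positive integer stride along the PC1 ordering.
#' @return a character vector of taxon names.
#' @export
select_representative_taxa <- function(result, every_kth = 1L) {
  stopifnot(every_kth >= 1)
  if (length(result$taxa) < every_kth)
    stop("fewer taxa than every_kth")
  M <- matrix(aperm(result$diff, c(2L, 1L, 3L)), length(result$taxa))
  if (all(abs(M) < 1e-12)) {
    warning("all counterfactual differences are zero; returning taxon order")
    ord <- seq_along(result$taxa)
  } else {
    Mc <- sweep(M, 2L, colMeans(M))        # taxa are the observations here
    sv <- svd(Mc, nu = 0L, nv = 1L)
    v <- sv$v[, 1L]                        # PC1 loading over subject x horizon
    if (v[which.max(abs(v))] < 0) v <- -v
    scores <- drop(Mc %*% v)               # taxon scores on PC1
    ord <- order(scores, decreasing = TRUE)
  }
  result$taxa[ord[seq(1L, length(ord), by = every_kth)]]
}

#' Write counterfactual differences as tidy TSV
#'
#' @param result a `counterfactual_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counterfactuals <- function(result, path) {
  rows <- expand.grid(subject = result$subjects, taxon = result$taxa,
                      horizon = seq_len(result$horizon),
                      stringsAsFactors = FALSE)
  rows$y_on <- as.vector(result$y_on)
  rows$y_off <- as.vector(result$y_off)
  rows$diff <- as.vector(result$diff)
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
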