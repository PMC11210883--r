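#' Split subjects and fit one transfer-function model per half
#'
#' Partitions the subjects uniformly at random into two halves (sizes differ
#' by one for odd n) and fits an independent model on each half using fully
#' disjoint (nonoverlapping) history segments, i.e. `stride = max(P, Q) + 1`.
#'
#' @param collection a [study_collection] on the modeling scale.
#' @param config a [boosting_config].
#' @param P,Q history lengths.
#' @param seed integer seed controlling the partition.
#' @return an object of class `split_pair`: models `m1`, `m2`, designs `d1`,
#'   `d2`, the two subject sets and the seed.
#' @export
split_and_fit <- function(collection, config = boosting_config(), P, Q, seed = 1L) {
  n <- n_subjects(collection)
  if (n < 2L) stop("need at least 2 subjects to split")
  set.seed(seed)
  perm <- sample(collection$subjects)
  s1 <- sort(perm[seq_len(n %/% 2L)])
  s2 <- sort(setdiff(collection$subjects, s1))
  stride <- max(P, Q) + 1L
  d1 <- tile_windows(subset_subjects(collection, s1), P, Q, stride = stride)
  d2 <- tile_windows(subset_subjects(collection, s2), P, Q, stride = stride)
  m1 <- fit_transfer(d1, config = config, normalization = collection$normalization)
  m2 <- fit_transfer(d2, config = config, normalization = collection$normalization)
  structure(list(m1 = m1, m2 = m2, d1 = d1, d2 = d2,
                 subjects1 = s1, subjects2 = s2, seed = seed),
            class = "split_pair")
}

#' Partial-dependence intervention effect per taxon
#'
#' Averages, over the split's design windows, the difference between
#' predictions with the whole intervention block set to `W_on` versus
#' `W_off`, holding abundance history and covariates at their observed values
#' (interaction products are recomputed). This is the plug-in partial
#' dependence contrast between the two intervention paths.
#'
#' @param model a `tf_model`.
#' @param design the split's `lagged_design`.
#' @param W_on,W_off D x Q intervention matrices (column q = lag q - 1);
#'   defaults all-ones vs all-zeros. An isolated pulse can be encoded by a
#'   single 1 at the pulse lag.
#' @param taxon optional taxon index/name; default all taxa.
#' @return a named numeric vector of per-taxon effects (or a scalar).
#' @export
pd_effect <- function(model, design,
                      W_on = matrix(1, model$D, model$Q),
                      W_off = matrix(0, model$D, model$Q),
                      taxon = NULL) {
  if (nrow(design$X) == 0L) stop("empty design")
  blk <- intervention_block(model)
  Xb <- design$X[, seq_len(model$base_cols), drop = FALSE]
  Xon <- Xb; Xoff <- Xb
  Xon[, blk] <- matrix(as.vector(as.matrix(W_on)), nrow(Xb),
                       length(blk), byrow = TRUE)
  Xoff[, blk] <- matrix(as.vector(as.matrix(W_off)), nrow(Xb),
                        length(blk), byrow = TRUE)
  pd <- colMeans(predict_design(model, Xon) - predict_design(model, Xoff))
  pd <- setNames(pd, model$taxa)
  if (!is.null(taxon)) pd[[taxon]] else pd
}

# Lag-h partial-dependence effect: h-step forecasts from each window's
# observed history under all-on vs all-off intervention paths, averaged over
# windows. h = 1 reduces to pd_effect up to the recursion bookkeeping.
pd_effect_lagged <- function(model, collection, design, h,
                             on_value = 1, off_value = 0) {
  acc <- numeric(model$J); nwin <- 0L
  for (s in unique(design$window_index$subject)) {
    tms <- design$window_index$t_index[design$window_index$subject == s]
    Y <- collection$abundances[[s]]
    z <- if (model$S > 0) collection$covariates[s, ] else numeric(0)
    for (t0 in tms) {
      Yobs <- Y[, seq_len(t0 - 1L), drop = FALSE]
      Wc <- function(v) matrix(v, model$D, ncol(Yobs) + h)
      fon <- forecast_subject(model, Yobs, Wc(on_value), z, h)
      foff <- forecast_subject(model, Yobs, Wc(off_value), z, h)
      acc <- acc + (fon[, h] - foff[, h])
      nwin <- nwin + 1L
    }
  }
  setNames(acc / nwin, model$taxa)
}

#' Mirror statistics from two split-wise effect estimates
#'
#' `M_j = sign(PD_j^(1) PD_j^(2)) (|PD_j^(1)| + |PD_j^(2)|)`, with
#' `sign(0) = 0` so a zero effect in either split yields `M_j = 0`.
#'
#' @param pd1,pd2 equal-length numeric vectors of per-taxon effects.
#' @return a numeric vector of mirror statistics.
#' @export
mirror_statistics <- function(pd1, pd2) {
  stopifnot(length(pd1) == length(pd2))
  sign(pd1 * pd2) * (abs(pd1) + abs(pd2))
}

#' Estimated false discovery proportion at a threshold
#'
#' `FDR^(t) = |{j : M_j < -t}| / |{j : M_j > t}|`. An empty denominator gives
#' 0 when the numerator is also 0 and `Inf` otherwise (no selection possible
#' at that threshold).
#'
#' @param M mirror statistics.
#' @param t threshold, strictly positive.
#' @return a nonnegative number (possibly `Inf`).
#' @export
fdr_hat <- function(M, t) {
  if (t <= 0) stop("threshold t must be > 0")
  num <- sum(M < -t); den <- sum(M > t)
  if (den == 0) return(if (num == 0) 0 else Inf)
  num / den
}

#' Select taxa by mirror-statistic thresholding
#'
#' Candidate thresholds are the distinct positive values of `|M_j|` (of the
#' pooled vector when lag pooling is in use). The chosen threshold `t*` is
#' the smallest candidate with `FDR^(t*) <= q`; the selection set is
#' `{j : M_j > t*}`. If no candidate qualifies the selection is empty with
#' `t* = Inf`. Setting `plus_one = TRUE` adds the conservative `+1` to the
#' numerator of the estimate (off by default).
#'
#' @param M per-taxon mirror statistics.
#' @param q target FDR level in (0, 1).
#' @param M_pool mirror vector used for the FDR counts (defaults to `M`;
#'   lagged pooling passes the union over lags here).
#' @param plus_one use the conservative numerator correction.
#' @return an object of class `mirror_result` with fields `M`, `fdr_curve`,
#'   `threshold`, `selected` (integer indices), `q`.
#' @export
select_taxa <- function(M, q, M_pool = M, plus_one = FALSE) {
  stopifnot(q > 0, q < 1)
  cand <- sort(unique(abs(M_pool[M_pool != 0])))
  est <- function(t) {
    num <- sum(M_pool < -t) + if (plus_one) 1 else 0
    den <- sum(M_pool > t)
    if (den == 0) (if (num == 0) 0 else Inf) else num / den
  }
  fdr_curve <- if (length(cand)) vapply(cand, est, 0) else numeric(0)
  ok <- which(fdr_curve <= q)
  tstar <- if (length(ok)) cand[ok[1L]] else Inf
  structure(list(M = M, fdr_curve = data.frame(t = cand, fdr_hat = fdr_curve),
                 threshold = tstar,
                 selected = unname(which(M > tstar)), q = q),
            class = "mirror_result")
}

#' @export
print.mirror_result <- function(x, ...) {
  cat("mirror_result:", length(x$selected), "of", length(x$M),
      "taxa selected at q =", x$q, "(t* =", signif(x$threshold, 4), ")\n")
  invisible(x)
}

# Inclusion-rate aggregation across splits: I_j = mean_k 1{j in S_k}/|S_k|
# (empty selections contribute 0); sort ascending, drop the largest prefix
# whose cumulative rate sum stays <= q, keep the rest.
aggregate_inclusion <- function(selections, J, q) {
  rates <- rowMeans(vapply(selections, function(s) {
    v <- numeric(J)
    if (length(s)) v[s] <- 1 / length(s)
    v
  }, numeric(J)))
  ord <- order(rates)                       # ties broken by index, deterministic
  cum <- cumsum(rates[ord])
  drop_n <- sum(cum <= q)
  keep <- if (drop_n < J) ord[(drop_n + 1L):J] else integer(0)
  list(inclusion_rates = rates, selected = sort(keep))
}

#' Multi-split mirror selection with inclusion-rate aggregation
#'
#' Runs split, fit, partial-dependence contrast, mirror statistics and
#' thresholding for `n_splits` random subject splits, then aggregates the
#' per-split selections by inclusion rates: `I_j` averages `1/|S_k|` over the
#' splits that selected j, the rates are sorted ascending and the largest
#' low-rate prefix whose cumulative sum stays below `q` is discarded; the
#' remaining taxa form the aggregate selection.
#'
#' @param collection a [study_collection] on the modeling scale.
#' @param config a [boosting_config].
#' @param P,Q history lengths.
#' @param q target FDR level.
#' @param n_splits number of random splits (25 by default).
#' @param seed global seed; each split draws a derived seed.
#' @param W_on,W_off intervention contrast matrices (defaults all-ones vs
#'   all-zeros over the Q-lag block).
#' @return a `mirror_result` with aggregate `selected`, `inclusion_rates`,
#'   and per-split detail in `$splits`.
#' @export
multi_split_select <- function(collection, config = boosting_config(), P, Q,
                               q = 0.2, n_splits = 25L, seed = 1L,
                               W_on = NULL, W_off = NULL) {
  stopifnot(n_splits >= 1)
  J <- n_taxa(collection)
  splits <- vector("list", n_splits)
  for (k in seq_len(n_splits)) {
    sp <- split_and_fit(collection, config, P, Q,
                        seed = derive_seed(seed, paste0("split", k)))
    won <- W_on %||% matrix(1, sp$m1$D, Q)
    woff <- W_off %||% matrix(0, sp$m1$D, Q)
    pd1 <- pd_effect(sp$m1, sp$d1, won, woff)
    pd2 <- pd_effect(sp$m2, sp$d2, won, woff)
    M <- mirror_statistics(pd1, pd2)
    res <- select_taxa(M, q)
    splits[[k]] <- list(pd1 = pd1, pd2 = pd2, M = M,
                        threshold = res$threshold, selected = res$selected,
                        seed = sp$seed)
  }
  agg <- aggregate_inclusion(lapply(splits, `[[`, "selected"), J, q)
  structure(list(M = splits[[1L]]$M, fdr_curve = NULL, threshold = NA_real_,
                 selected = agg$selected,
                 inclusion_rates = setNames(agg$inclusion_rates, collection$taxa),
                 q = q, n_splits = n_splits, splits = splits, seed = seed),
            class = "mirror_result")
}

#' Lagged mirror selection for delayed intervention effects
#'
#' For each lag `h <= h_max`, partial-dependence contrasts are computed from
#' h-step forecasts (with observed-value substitution) under the all-on vs
#' all-off intervention paths, per split. The lag-h FDR counts pool the
#' mirror vectors across all lags `h' <= h` (set `pool_lags = FALSE` for
#' per-lag-only counting); selection at lag h applies the pooled threshold to
#' the lag-h mirrors. Selections are aggregated across splits per lag as in
#' [multi_split_select()].
#'
#' @inheritParams multi_split_select
#' @param h_max largest lag examined.
#' @param pool_lags pool mirror vectors across lags `h' <= h` in the FDR
#'   counts (default) or count per lag only.
#' @return a list with one `mirror_result` per lag and `$per_lag_selected`.
#' @export
lagged_mirrors <- function(collection, config = boosting_config(), P, Q,
                           q = 0.2, h_max = 2L, n_splits = 5L, seed = 1L,
                           pool_lags = TRUE) {
  stopifnot(h_max >= 1)
  J <- n_taxa(collection)
  M_all <- vector("list", n_splits)   # per split: h_max x J mirrors
  for (k in seq_len(n_splits)) {
    sp <- split_and_fit(collection, config, P, Q,
                        seed = derive_seed(seed, paste0("split", k)))
    Mk <- matrix(NA_real_, h_max, J)
    for (h in seq_len(h_max)) {
      pd1 <- pd_effect_lagged(sp$m1, collection, sp$d1, h)
      pd2 <- pd_effect_lagged(sp$m2, collection, sp$d2, h)
      Mk[h, ] <- mirror_statistics(pd1, pd2)
    }
    M_all[[k]] <- Mk
  }
  out <- list()
  for (h in seq_len(h_max)) {
    sels <- lapply(M_all, function(Mk) {
      pool <- if (pool_lags) as.vector(Mk[seq_len(h), , drop = FALSE]) else Mk[h, ]
      select_taxa(Mk[h, ], q, M_pool = pool)$selected
    })
    agg <- aggregate_inclusion(sels, J, q)
    out[[h]] <- structure(
      list(M = M_all[[1L]][h, ], threshold = NA_real_,
           selected = agg$selected,
           inclusion_rates = setNames(agg$inclusion_rates, collection$taxa),
           q = q, n_splits = n_splits, lag = h),
      class = "mirror_result")
  }
  list(per_lag = out,
       per_lag_selected = lapply(out, `[[`, "selected"))
}
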