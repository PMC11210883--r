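#' Cross-validated forecasting error by horizon
#'
#' Splits subjects into folds; per fold, fits a transfer-function model on
#' the training subjects and forecasts every held-out subject from every
#' admissible anchor time (each t0 with at least `max(P, Q)` observed
#' timepoints and h more observed ahead) using the true future interventions.
#' The mean absolute error `|yhat_{t0+h} - y_{t0+h}|` is averaged over taxa,
#' anchors and held-out subjects, per horizon h = 1..`h_max`.
#'
#' @param collection a [study_collection] on the modeling scale.
#' @param P,Q history lengths.
#' @param config a [boosting_config].
#' @param n_folds number of subject-level folds (>= 2).
#' @param h_max largest forecast horizon.
#' @param seed integer seed for the fold assignment.
#' @param anchor_stride evaluate anchors every this many timepoints (1 = all).
#' @return an object of class `evaluation_report`: `mae` (fold x horizon
#'   matrix), `mae_by_horizon` (pooled means), `folds` (assignment).
#' @export
cv_forecast_mae <- function(collection, P, Q, config = boosting_config(),
                            n_folds = 4L, h_max = 5L, seed = 1L,
                            anchor_stride = 1L) {
  n <- n_subjects(collection)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (n < n_folds) stop("need at least as many subjects as folds")
  set.seed(seed)
  fold_of <- setNames(sample(rep(seq_len(n_folds), length.out = n)),
                      collection$subjects)
  mae <- matrix(NA_real_, n_folds, h_max,
                dimnames = list(paste0("fold", seq_len(n_folds)),
                                paste0("h", seq_len(h_max))))
  start <- max(P, Q)
  for (f in seq_len(n_folds)) {
    train <- names(fold_of)[fold_of != f]
    test <- names(fold_of)[fold_of == f]
    design <- tile_windows(subset_subjects(collection, train), P, Q, stride = 1L)
    model <- fit_transfer(design, config = config,
                          normalization = collection$normalization)
    err <- matrix(0, 1L, h_max); cnt <- matrix(0, 1L, h_max)
    for (s in test) {
      Y <- collection$abundances[[s]]; W <- collection$interventions[[s]]
      z <- if (model$S > 0) collection$covariates[s, ] else numeric(0)
      Tn <- ncol(Y)
      anchors <- seq.int(start, Tn - 1L, by = anchor_stride)
      if (Tn - 1L < start) {
        warning("held-out subject ", s, " shorter than P + 1; skipped")
        next
      }
      for (t0 in anchors) {
        hs <- min(h_max, Tn - t0)
        fc <- forecast_subject(model, Y[, seq_len(t0), drop = FALSE],
                               W[, seq_len(t0 + hs), drop = FALSE], z, hs)
        for (h in seq_len(hs)) {
          err[1L, h] <- err[1L, h] + mean(abs(fc[, h] - Y[, t0 + h]))
          cnt[1L, h] <- cnt[1L, h] + 1
        }
      }
    }
    mae[f, ] <- ifelse(cnt > 0, err / cnt, NA_real_)
  }
  structure(list(mae = mae,
                 mae_by_horizon = colMeans(mae, na.rm = TRUE),
                 folds = fold_of, seed = seed, P = P, Q = Q),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report: MAE by horizon\n")
  print(round(x$mae_by_horizon, 4))
  invisible(x)
}

#' False discovery proportion and power against ground truth, by lag
#'
#' `FDP = |selected & null_h| / max(|selected|, 1)` and
#' `power = |selected & nonnull_h| / max(|nonnull_h|, 1)` with `null_h`
#' defined by the lag-h column of the truth matrix.
#'
#' @param selection list of integer taxon index vectors, one per lag.
#' @param truth J x h logical truth matrix from [truth_labels()].
#' @return a data.frame with columns `lag`, `fdp`, `power`, `n_selected`.
#' @export
fdp_power_by_lag <- function(selection, truth) {
  truth <- as.matrix(truth)
  out <- lapply(seq_along(selection), function(h) {
    sel <- selection[[h]]
    nonnull <- which(truth[, h])
    data.frame(lag = h,
               fdp = length(setdiff(sel, nonnull)) / max(length(sel), 1L),
               power = length(intersect(sel, nonnull)) / max(length(nonnull), 1L),
               n_selected = length(sel))
  })
  do.call(rbind, out)
}

#' Pre/post t-test baseline with Benjamini-Hochberg adjustment
#'
#' For each taxon, pools the `window` samples before and after each
#' subject's intervention onset across subjects and applies a Welch
#' two-sample t-test; p-values are adjusted across taxa by the
#' Benjamini-Hochberg step-up procedure and taxa with adjusted p <= q are
#' selected. Subjects with fewer than `window` samples on a side contribute
#' what they have.
#'
#' @param collection a [study_collection].
#' @param onset named per-subject intervention start index; `NULL` infers the
#'   first timepoint with any active intervention.
#' @param window samples pooled on each side of the onset.
#' @param q selection level on the adjusted p-values.
#' @return a data.frame with columns `taxon`, `p`, `p_adj`, `selected`.
#' @export
prepost_ttest <- function(collection, onset = NULL, window = 4L, q = 0.2) {
  if (is.null(onset))
    onset <- vapply(collection$subjects, function(s) {
      on_t <- which(colSums(collection$interventions[[s]] > 0) > 0)
      if (!length(on_t)) stop("no active intervention for subject ", s,
                              "; supply onset explicitly")
      on_t[1L]
    }, 0L)
  J <- n_taxa(collection)
  p <- rep(NA_real_, J)
  for (j in seq_len(J)) {
    pre <- c(); post <- c()
    for (s in collection$subjects) {
      o <- onset[[s]]; Y <- collection$abundances[[s]]
      pre_idx <- if (o > 1L) seq.int(max(1L, o - window), o - 1L) else integer(0)
      post_idx <- seq.int(min(o, ncol(Y)), min(ncol(Y), o + window - 1L))
      pre <- c(pre, Y[j, pre_idx]); post <- c(post, Y[j, post_idx])
    }
    if (length(pre) > 1L && length(post) > 1L &&
        var(pre) == 0 && var(post) == 0) {
      warning("taxon ", collection$taxa[j], " has zero variance pre and post; p = 1")
      p[j] <- 1
    } else {
      p[j] <- tryCatch(t.test(pre, post)$p.value, error = function(e) 1)
    }
  }
  p_adj <- p.adjust(p, method = "BH")
  data.frame(taxon = collection$taxa, p = p, p_adj = p_adj,
             selected = p_adj <= q)
}
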