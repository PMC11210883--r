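#' Tile subject trajectories into a lagged design matrix
#'
#' Builds one row per (subject, response time t): lagged abundances
#' `y_{t-1} .. y_{t-P}` for all J taxa, interventions `w_t .. w_{t-Q+1}`
#' (the intervention memory includes the current timepoint, the abundance
#' memory does not), static covariates, and optional screened interaction
#' products. Response times start at index `max(P, Q) + 1` and advance by
#' `stride`; `stride = max(P, Q) + 1` yields fully disjoint history segments
#' as used for mirror-statistic estimation, while `stride = 1` maximizes data
#' for fitting.
#'
#' @param collection a [study_collection] on regular time grids.
#' @param P,Q abundance and intervention history lengths (each >= 1).
#' @param stride positive integer step between response times.
#' @param interactions an [interaction_set] of base-column index pairs, or
#'   `NULL` for none.
#' @return an object of class `lagged_design` with fields `X`, `Y_response`,
#'   `window_index`, `P`, `Q`, `base_cols`, `feature_names`, `interactions`.
#' @export
tile_windows <- function(collection, P, Q, stride = 1L, interactions = NULL) {
  if (P < 1 || Q < 1) stop("P and Q must each be at least 1")
  stopifnot(stride >= 1)
  J <- n_taxa(collection); D <- length(collection$intervention_names)
  S <- length(collection$covariate_names)
  fn <- c(
    as.vector(outer(collection$taxa, seq_len(P),
                    function(tx, p) paste0("y_", tx, "_lag", p))),
    as.vector(outer(collection$intervention_names, seq_len(Q) - 1L,
                    function(w, q) paste0("w_", w, "_lag", q))),
    if (S > 0) paste0("z_", collection$covariate_names))
  rows <- list(); resp <- list(); widx <- list(); k <- 0L
  start <- max(P, Q) + 1L
  for (s in collection$subjects) {
    tm <- collection$times[[s]]
    if (length(tm) > 2L && max(abs(diff(diff(tm)))) > 1e-8 * max(abs(diff(tm))))
      stop("subject ", s, " is not on a regular time grid; run interpolate_to_grid() first")
    Tn <- length(tm)
    if (Tn < start) {
      warning("subject ", s, " too short for P = ", P, ", Q = ", Q, "; skipped")
      next
    }
    Y <- collection$abundances[[s]]; W <- collection$interventions[[s]]
    z <- if (S > 0) collection$covariates[s, ] else numeric(0)
    for (t in seq.int(start, Tn, by = stride)) {
      k <- k + 1L
      yh <- Y[, t - seq_len(P), drop = FALSE]           # col p = y_{t-p}
      wh <- W[, t - seq_len(Q) + 1L, drop = FALSE]      # col q = w_{t-q+1}
      rows[[k]] <- c(as.vector(yh), as.vector(wh), z)
      resp[[k]] <- Y[, t]
      widx[[k]] <- data.frame(subject = s, time = tm[t], t_index = t,
                              stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) stop("no subject long enough to tile any window")
  X <- do.call(rbind, rows)
  colnames(X) <- fn
  out <- structure(
    list(X = X, Y_response = do.call(rbind, resp),
         window_index = do.call(rbind, widx),
         P = P, Q = Q, J = J, D = D, S = S,
         base_cols = P * J + Q * D + S,
         feature_names = fn, interactions = NULL,
         taxa = collection$taxa,
         intervention_names = collection$intervention_names,
         covariate_names = collection$covariate_names),
    class = "lagged_design")
  colnames(out$Y_response) <- collection$taxa
  if (!is.null(interactions) && length(interactions$pairs) > 0)
    out <- add_interactions(out, interactions)
  out
}

#' @export
print.lagged_design <- function(x, ...) {
  cat("lagged_design:", nrow(x$X), "windows x", ncol(x$X), "features (",
      x$base_cols, "base +", ncol(x$X) - x$base_cols, "interaction ),",
      "P =", x$P, ", Q =", x$Q, "\n")
  invisible(x)
}

# Append interaction product columns for base-column index pairs.
add_interactions <- function(design, interactions) {
  prs <- interactions$pairs
  Xb <- design$X[, seq_len(design$base_cols), drop = FALSE]
  prod_cols <- vapply(prs, function(p) Xb[, p[1L]] * Xb[, p[2L]],
                      numeric(nrow(Xb)))
  if (nrow(Xb) == 1L) prod_cols <- matrix(prod_cols, nrow = 1L)
  colnames(prod_cols) <- vapply(prs, function(p)
    paste0("int_", design$feature_names[p[1L]], "_x_", design$feature_names[p[2L]]), "")
  design$X <- cbind(Xb, prod_cols)
  design$feature_names <- colnames(design$X)
  design$interactions <- interactions
  design
}

# Column indices of the intervention block (lags 0..Q-1, all D channels)
# within the base design.
intervention_block <- function(design_or_model) {
  d <- design_or_model
  P <- d$P; J <- d$J; Q <- d$Q; D <- d$D
  P * J + seq_len(Q * D)
}
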