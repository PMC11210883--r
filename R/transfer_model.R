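#' Interaction set
#'
#' An ordered list of base-design column index pairs (a, b) with a <= b whose
#' elementwise products are appended to the design as interaction features.
#'
#' @param pairs list of length-2 integer vectors, or a 2-column matrix.
#' @param base_cols number of columns of the base (pre-interaction) design.
#' @return an object of class `interaction_set`.
#' @export
interaction_set <- function(pairs = list(), base_cols = NULL) {
  if (is.matrix(pairs)) pairs <- lapply(seq_len(nrow(pairs)), function(i) pairs[i, ])
  pairs <- lapply(pairs, function(p) sort(as.integer(p)))
  if (length(pairs) > 0) {
    key <- vapply(pairs, paste, "", collapse = "_")
    if (anyDuplicated(key)) stop("duplicate interaction pairs")
    if (!is.null(base_cols) && any(unlist(pairs) > base_cols))
      stop("interaction index outside the base design")
  }
  structure(list(pairs = pairs, base_cols = base_cols), class = "interaction_set")
}

#' Boosting configuration
#'
#' @param n_iterations number of componentwise boosting iterations (>= 0).
#' @param learning_rate shrinkage in (0, 1].
#' @param max_interactions maximum number of screened interaction pairs.
#' @param screen_method `"none"`, `"exhaustive"`, or
#'   `"xyz_random_projection"` (randomized sketch of the exhaustive scores).
#' @param n_projections number of random probes for the randomized screener.
#' @param exhaustive_cap largest base-design column count for which the
#'   exhaustive pair scan is permitted.
#' @param random_seed integer seed for the screener.
#' @return an object of class `boosting_config`.
#' @export
boosting_config <- function(n_iterations = 500L, learning_rate = 0.1,
                            max_interactions = 20L,
                            screen_method = c("none", "exhaustive", "xyz_random_projection"),
                            n_projections = 50L, exhaustive_cap = 200L,
                            random_seed = 1L) {
  screen_method <- match.arg(screen_method)
  stopifnot(n_iterations >= 0, learning_rate > 0, learning_rate <= 1,
            max_interactions >= 0, n_projections >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 learning_rate = learning_rate,
                 max_interactions = as.integer(max_interactions),
                 screen_method = screen_method,
                 n_projections = as.integer(n_projections),
                 exhaustive_cap = as.integer(exhaustive_cap),
                 random_seed = as.integer(random_seed)),
            class = "boosting_config")
}

#' Screen candidate interaction pairs
#'
#' Ranks base-column pairs (a, b) by the strength of association between the
#' product feature `x_a * x_b` and the responses. Exhaustive mode scores every
#' pair by the absolute correlation with each response, maximized over
#' responses — it is the oracle for the randomized mode. The randomized mode
#' estimates the score matrix `X' diag(y) X` for each response from
#' `n_projections` Rademacher probes (E[(X'(y.s))(X's)'] recovers the bilinear
#' scores), trading exactness for O(p^2 R + n p R) cost.
#'
#' @param design a `lagged_design` (only base columns are used).
#' @param responses matrix of responses, defaults to `design$Y_response`.
#' @param config a [boosting_config].
#' @return an [interaction_set] of at most `config$max_interactions` pairs,
#'   ranked by score.
#' @export
screen_interactions <- function(design, responses = design$Y_response, config) {
  if (config$screen_method == "none" || config$max_interactions == 0L)
    return(interaction_set(list(), design$base_cols))
  Xb <- design$X[, seq_len(design$base_cols), drop = FALSE]
  stopifnot(nrow(Xb) == nrow(responses))
  p <- ncol(Xb); n <- nrow(Xb)
  keep_y <- apply(responses, 2L, sd) > 0
  if (!all(keep_y)) warning("constant response column(s) skipped in screening")
  if (!any(keep_y)) return(interaction_set(list(), design$base_cols))
  Y <- scale(responses[, keep_y, drop = FALSE])
  Xs <- scale(Xb)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  score <- matrix(0, p, p)
  if (config$screen_method == "exhaustive") {
    if (p > config$exhaustive_cap)
      stop("exhaustive screening capped at ", config$exhaustive_cap, " base columns")
    for (a in seq_len(p)) {
      prods <- Xb[, a] * Xb[, a:p, drop = FALSE]
      ok <- apply(prods, 2L, sd) > 0
      if (!any(ok)) next
      cors <- abs(cor(prods[, ok, drop = FALSE], Y))
      score[a, (a:p)[ok]] <- apply(cors, 1L, max)
    }
  } else {
    set.seed(config$random_seed)
    R <- config$n_projections
    for (j in seq_len(ncol(Y))) {
      S <- matrix(sample(c(-1, 1), n * R, replace = TRUE), n, R)
      U <- crossprod(Xs, S * Y[, j])            # p x R
      V <- crossprod(Xs, S)                     # p x R
      Mj <- tcrossprod(U, V) / R
      Mj <- abs(Mj + t(Mj)) / 2
      score <- pmax(score, Mj / n)              # comparable to a correlation scale
    }
    score[lower.tri(score)] <- 0
  }
  ord <- order(score, decreasing = TRUE)
  pairs <- list()
  for (idx in ord) {
    if (length(pairs) >= config$max_interactions || score[idx] <= 0) break
    a <- (idx - 1L) %% p + 1L; b <- (idx - 1L) %/% p + 1L
    pr <- Xb[, a] * Xb[, b]
    if (sd(pr) == 0) next
    pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  interaction_set(pairs, design$base_cols)
}

# Pure-R componentwise L2 boosting; reference/oracle path for the compiled
# kernel and source of the per-iteration training-error trace.
boost_fit_r <- function(Xs, Yc, n_iter, lr, ss, trace = FALSE) {
  p <- ncol(Xs); J <- ncol(Yc)
  R <- Yc; coef <- matrix(0, p, J)
  inv_ss <- ifelse(ss > 0, 1 / ss, 0)
  sse <- if (trace) matrix(NA_real_, n_iter + 1L, J) else NULL
  if (trace) sse[1L, ] <- colSums(R^2)
  for (it in seq_len(n_iter)) {
    C <- crossprod(Xs, R)
    sc <- C^2 * inv_ss
    for (j in seq_len(J)) {
      sel <- which.max(sc[, j])
      if (sc[sel, j] <= 0) next
      beta <- lr * C[sel, j] * inv_ss[sel]
      coef[sel, j] <- coef[sel, j] + beta
      R[, j] <- R[, j] - beta * Xs[, sel]
    }
    if (trace) sse[it + 1L, ] <- colSums(R^2)
  }
  list(coef = coef, sse = sse)
}

#' Fit a transfer-function model by componentwise linear boosting
#'
#' Trains one additive linear predictor per taxon on the lagged design:
#' columns are standardized, each predictor starts at the response mean, and
#' each boosting iteration adds `learning_rate` times the least-squares fit of
#' the single best column to the current residual. The accumulated
#' coefficients are collapsed to an intercept plus a sparse coefficient vector
#' on the original feature scale. When `config$screen_method` is not
#' `"none"` and the design carries no interactions yet, interactions are
#' screened here (once, shared across taxa) and appended.
#'
#' @param design a `lagged_design` from [tile_windows()].
#' @param responses response matrix, default `design$Y_response`.
#' @param config a [boosting_config].
#' @param normalization optional [normalization_spec] recorded in the model.
#' @param engine `"cpp"` (default) or `"r"` (reference implementation).
#' @return an object of class `tf_model`.
#' @export
fit_transfer <- function(design, responses = design$Y_response, config = boosting_config(),
                         normalization = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(design, "lagged_design"))
  if (is.null(design$interactions) && config$screen_method != "none") {
    iset <- screen_interactions(design, responses, config)
    if (length(iset$pairs) > 0) design <- add_interactions(design, iset)
  }
  X <- design$X
  if (nrow(X) < 2L && config$n_iterations > 0L)
    stop("need at least 2 design rows to fit")
  if (anyNA(X) || anyNA(responses)) stop("missing values in design or responses")
  mu <- colMeans(X); sds <- apply(X, 2L, sd)
  Xs <- sweep(X, 2L, mu, "-")
  ok <- sds > 0
  Xs[, ok] <- sweep(Xs[, ok, drop = FALSE], 2L, sds[ok], "/")
  Xs[, !ok] <- 0
  ss <- colSums(Xs^2)
  ybar <- colMeans(responses)
  Yc <- sweep(responses, 2L, ybar, "-")
  coef_std <-
    if (config$n_iterations == 0L) matrix(0, ncol(X), ncol(responses))
    else if (engine == "cpp") boost_fit_cpp(Xs, Yc, config$n_iterations,
                                            config$learning_rate, ss)
    else boost_fit_r(Xs, Yc, config$n_iterations, config$learning_rate, ss)$coef
  beta <- coef_std
  beta[ok, ] <- coef_std[ok, , drop = FALSE] / sds[ok]
  intercept <- ybar - drop(crossprod(beta, mu))
  structure(
    list(beta = beta, intercept = intercept,
         P = design$P, Q = design$Q, J = design$J, D = design$D, S = design$S,
         base_cols = design$base_cols,
         interactions = design$interactions %||% interaction_set(list(), design$base_cols),
         feature_names = design$feature_names,
         taxa = design$taxa, intervention_names = design$intervention_names,
         covariate_names = design$covariate_names,
         normalization = normalization, config = config),
    class = "tf_model")
}

#' @export
print.tf_model <- function(x, ...) {
  cat("tf_model:", x$J, "taxa, P =", x$P, ", Q =", x$Q, ",",
      length(x$interactions$pairs), "interaction(s),",
      sum(x$beta != 0), "nonzero coefficients\n")
  invisible(x)
}

# Predict all taxa for a base-column design matrix; interaction products are
# recomputed from the base columns so callers may overwrite any block.
predict_design <- function(model, X_base) {
  stopifnot(ncol(X_base) == model$base_cols)
  prs <- model$interactions$pairs
  X <- if (length(prs) > 0) {
    P <- vapply(prs, function(p) X_base[, p[1L]] * X_base[, p[2L]],
                numeric(nrow(X_base)))
    if (nrow(X_base) == 1L) P <- matrix(P, nrow = 1L)
    cbind(X_base, P)
  } else X_base
  sweep(X %*% model$beta, 2L, model$intercept, "+")
}

#' One-step prediction
#'
#' Evaluates every fitted per-taxon predictor at one history configuration.
#' `Y_hist` column p holds the community profile at lag p (most recent
#' first); `W_hist` column q holds the intervention vector at lag q - 1 (the
#' first column is the current timepoint).
#'
#' @param model a `tf_model`.
#' @param Y_hist J x P matrix of lagged abundances.
#' @param W_hist D x Q matrix of interventions.
#' @param z length-S covariate vector (omit when S = 0).
#' @return a named length-J vector on the model's normalization scale.
#' @export
predict_one_step <- function(model, Y_hist, W_hist, z = numeric(0)) {
  Y_hist <- as.matrix(Y_hist); W_hist <- as.matrix(W_hist)
  if (!all(dim(Y_hist) == c(model$J, model$P)))
    stop("Y_hist must be ", model$J, " x ", model$P, ", got ",
         nrow(Y_hist), " x ", ncol(Y_hist))
  if (!all(dim(W_hist) == c(model$D, model$Q)))
    stop("W_hist must be ", model$D, " x ", model$Q, ", got ",
         nrow(W_hist), " x ", ncol(W_hist))
  if (length(z) != model$S)
    stop("expected ", model$S, " covariate(s), got ", length(z))
  x <- matrix(c(as.vector(Y_hist), as.vector(W_hist), z), nrow = 1L)
  setNames(drop(predict_design(model, x)), model$taxa)
}

# Recursive h-step forecast for one subject's observed history.
# Y_obs: J x T_obs (model scale), W_ext: D x (T_obs + h).
forecast_subject <- function(model, Y_obs, W_ext, z, horizon, clip_zero = FALSE) {
  Tobs <- ncol(Y_obs)
  if (Tobs < model$P) stop("need at least P = ", model$P, " observed timepoints")
  Yfull <- cbind(Y_obs, matrix(NA_real_, nrow(Y_obs), horizon))
  out <- matrix(NA_real_, model$J, horizon,
                dimnames = list(model$taxa, NULL))
  for (k in seq_len(horizon)) {
    t <- Tobs + k
    yh <- Yfull[, t - seq_len(model$P), drop = FALSE]
    wh <- W_ext[, t - seq_len(model$Q) + 1L, drop = FALSE]
    pred <- predict_one_step(model, yh, wh, z)
    if (clip_zero) pred <- pmax(pred, 0)
    out[, k] <- pred
    Yfull[, t] <- pred
  }
  out
}

#' h-step forecast with observed-value substitution
#'
#' Iterates one-step predictions for each subject: whenever the required
#' history lies at or before the last observed time, the observed values are
#' used verbatim; later positions are filled with the model's own
#' predictions. Intervention history mixes the observed series with the
#' supplied hypothetical future columns.
#'
#' @param model a `tf_model`.
#' @param observed a [study_collection] on the model's scale, truncated at
#'   the forecast anchor.
#' @param future_interventions a D x `horizon` matrix applied to every
#'   subject, or a named list with one such matrix per subject.
#' @param horizon number of steps ahead (>= 1).
#' @param clip_zero clip each prediction at 0 before it re-enters the history.
#' @return a named list of J x horizon forecast matrices, one per subject.
#' @export
forecast <- function(model, observed, future_interventions, horizon,
                     clip_zero = FALSE) {
  if (horizon < 1) stop("horizon must be >= 1")
  if (is.matrix(future_interventions))
    future_interventions <- setNames(
      rep(list(future_interventions), length(observed$subjects)),
      observed$subjects)
  out <- list()
  for (s in observed$subjects) {
    Wf <- future_interventions[[s]]
    if (is.null(Wf) || ncol(Wf) < horizon)
      stop("future interventions missing or shorter than horizon for subject ", s)
    z <- if (model$S > 0) observed$covariates[s, ] else numeric(0)
    out[[s]] <- forecast_subject(
      model, observed$abundances[[s]],
      cbind(observed$interventions[[s]], Wf[, seq_len(horizon), drop = FALSE]),
      z, horizon, clip_zero)
  }
  out
}

#' Partial dependence profile of one fitted predictor
#'
#' For each grid value v, overwrites the chosen base feature column with v in
#' every design row (interaction columns involving that feature are
#' recomputed) and averages taxon `taxon`'s prediction over rows.
#'
#' @param model a `tf_model`.
#' @param taxon taxon index or name.
#' @param feature base-column index or feature name.
#' @param grid numeric vector of values to profile.
#' @param design a `lagged_design` providing the background rows.
#' @return a data.frame with columns `value` and `profile`.
#' @export
partial_dependence_profile <- function(model, taxon, feature, grid, design) {
  if (nrow(design$X) == 0L) stop("empty design")
  if (length(grid) == 0L) stop("empty grid")
  if (is.character(taxon)) taxon <- match(taxon, model$taxa)
  if (is.character(feature)) feature <- match(feature, model$feature_names)
  stopifnot(!is.na(taxon), !is.na(feature), feature <= model$base_cols)
  Xb <- design$X[, seq_len(model$base_cols), drop = FALSE]
  prof <- vapply(grid, function(v) {
    Xv <- Xb; Xv[, feature] <- v
    mean(predict_design(model, Xv)[, taxon])
  }, 0)
  data.frame(value = grid, profile = prof)
}

#' Serialize a fitted model to a versioned JSON file
#'
#' Stores lags, names, dense coefficients, interaction pairs, the
#' normalization spec (including fitted size factors) and the boosting
#' configuration, so forecasts elsewhere declare their scale.
#'
#' @param model a `tf_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tf_model <- function(model, path) {
  obj <- list(
    format = "tfmicro_model", version = 1L,
    P = model$P, Q = model$Q, J = model$J, D = model$D, S = model$S,
    base_cols = model$base_cols,
    taxa = model$taxa, intervention_names = model$intervention_names,
    covariate_names = model$covariate_names,
    feature_names = model$feature_names,
    intercept = model$intercept, beta = model$beta,
    interactions = if (length(model$interactions$pairs) > 0)
      do.call(rbind, model$interactions$pairs) else matrix(0L, 0L, 2L),
    normalization = if (!is.null(model$normalization))
      unclass(model$normalization) else NULL,
    config = unclass(model$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a model serialized by [write_tf_model()]
#' @param path file path.
#' @return a `tf_model`.
#' @export
read_tf_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "tfmicro_model"))
    stop("not a tfmicro model file: ", path)
  cfg <- do.call(boosting_config, obj$config[setdiff(names(obj$config), NULL)])
  norm <- NULL
  if (!is.null(obj$normalization)) {
    norm <- normalization_spec(obj$normalization$method,
                               obj$normalization$pseudocount %||% 0.5,
                               isTRUE(obj$normalization$renormalize))
    norm$size_factors <- obj$normalization$size_factors
  }
  prs <- if (length(obj$interactions) > 0 && nrow(obj$interactions) > 0)
    lapply(seq_len(nrow(obj$interactions)), function(i) as.integer(obj$interactions[i, ]))
  else list()
  beta <- matrix(obj$beta, obj$base_cols + length(prs), obj$J)
  structure(
    list(beta = beta, intercept = setNames(as.numeric(obj$intercept), obj$taxa),
         P = obj$P, Q = obj$Q, J = obj$J, D = obj$D, S = obj$S,
         base_cols = obj$base_cols,
         interactions = interaction_set(prs, obj$base_cols),
         feature_names = obj$feature_names,
         taxa = obj$taxa,
         intervention_names = obj$intervention_names %||% character(0),
         covariate_names = obj$covariate_names %||% character(0),
         normalization = norm, config = cfg),
    class = "tf_model")
}
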