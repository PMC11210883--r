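#' Phylogenetic covariance from a balanced binary tree
#'
#' Builds a balanced binary tree with unit branch lengths over `n_leaves`
#' leaves and returns `Sigma[j, j'] = (1 + d[j, j'])^(-alpha)` where d is the
#' cophenetic distance (total branch length on the path between leaves).
#' The diagonal is exactly 1. Small `alpha` yields high intertaxa
#' correlation; large `alpha` is the near-diagonal regime.
#'
#' @param n_leaves number of leaves, a power of 2 (>= 2).
#' @param alpha positive decay exponent.
#' @return an `n_leaves` x `n_leaves` covariance matrix.
#' @export
phylo_covariance <- function(n_leaves, alpha) {
  if (n_leaves < 2 || bitwAnd(n_leaves, n_leaves - 1L) != 0)
    stop("n_leaves must be a power of 2 (got ", n_leaves, ")")
  stopifnot(alpha > 0)
  tree <- ape::stree(n_leaves, type = "balanced")
  tree$edge.length <- rep(1, nrow(tree$edge))
  d <- ape::cophenetic.phylo(tree)
  ord <- order(as.integer(sub("^t", "", rownames(d))))
  d <- d[ord, ord]
  (1 + d)^(-alpha)
}

#' Generate benchmark simulator parameters
#'
#' Draws the parameter set of the negative-binomial autoregressive factor
#' model: low-rank lag matrices `A_p = U_p V_p'` rescaled so the companion
#' form has spectral radius below 0.95 (stationarity), low-rank intervention
#' effects `B_q` with exactly `ceiling(pi_nonnull * J)` nonzero rows (null
#' taxa have all-zero intervention rows at every lag), an analogous
#' covariate-interaction tensor `C_q`, and the phylogenetic noise covariance
#' from [phylo_covariance()] on the next power-of-2 tree (restricted to the
#' first J leaves when J is not itself a power of 2).
#'
#' @param J number of taxa.
#' @param D number of intervention channels.
#' @param S number of static covariates (0 for none).
#' @param rank rank of the A/B/C factors.
#' @param pi_nonnull fraction of taxa directly affected by the intervention.
#' @param signal_strength multiplier on `B_q` and `C_q`.
#' @param P,Q autoregressive and intervention lag orders of the truth.
#' @param phi negative-binomial dispersion (variance `mu + mu^2/phi`).
#' @param lambda Gamma scale of the per-subject depth factor `b ~ Gamma(10,
#'   lambda)` (mean `10*lambda`, variance `10*lambda^2`).
#' @param alpha phylogenetic correlation decay (0.1 = high correlation, 10 =
#'   low).
#' @param seed integer seed; the draw is reproducible bitwise.
#' @return an object of class `dgm_params`.
#' @export
generate_params <- function(J, D = 1L, S = 0L, rank = 2L, pi_nonnull = 0.2,
                            signal_strength = 1, P = 2L, Q = 2L,
                            phi = 1, lambda = 0.1, alpha = 10, seed = 1L) {
  stopifnot(rank <= J, pi_nonnull >= 0, pi_nonnull <= 1, phi > 0, lambda > 0)
  set.seed(seed)
  A <- lapply(seq_len(P), function(p) {
    U <- matrix(rnorm(J * rank), J, rank)
    V <- matrix(rnorm(J * rank), J, rank)
    tcrossprod(U, V) * (0.4 / J)
  })
  radius <- function(Alist) {
    comp <- matrix(0, J * P, J * P)
    for (p in seq_len(P)) comp[seq_len(J), (p - 1L) * J + seq_len(J)] <- Alist[[p]]
    if (P > 1) comp[J + seq_len(J * (P - 1L)), seq_len(J * (P - 1L))] <- diag(J * (P - 1L))
    max(Mod(eigen(comp, only.values = TRUE)$values))
  }
  steps <- 0L
  while (radius(A) >= 0.95) {
    A <- lapply(A, function(M) 0.9 * M)
    steps <- steps + 1L
    if (steps > 200L) stop("failed to rescale A to spectral radius < 0.95")
  }
  n_nonnull <- ceiling(pi_nonnull * J)
  nonnull <- if (n_nonnull > 0) sort(sample.int(J, n_nonnull)) else integer(0)
  lowrank_B <- function() {
    B <- tcrossprod(matrix(rnorm(J * rank), J, rank),
                    matrix(rnorm(D * rank), D, rank)) / sqrt(rank)
    B[setdiff(seq_len(J), nonnull), ] <- 0
    B * signal_strength
  }
  B <- lapply(seq_len(Q), function(q) lowrank_B())
  C <- lapply(seq_len(Q), function(q) {
    arr <- array(0, dim = c(J, D, max(S, 1L)))
    if (S > 0) for (s in seq_len(S)) arr[, , s] <- lowrank_B()
    arr
  })
  n_leaves <- 2^ceiling(log2(max(J, 2L)))
  Sigma <- phylo_covariance(n_leaves, alpha)[seq_len(J), seq_len(J), drop = FALSE]
  structure(list(J = J, D = D, S = S, rank = rank, P = P, Q = Q,
                 A = A, B = B, C = C, Sigma = Sigma,
                 phi = phi, lambda = lambda, alpha = alpha,
                 pi_nonnull = pi_nonnull, nonnull = nonnull,
                 signal_strength = signal_strength,
                 burn_in = 20L, seed = seed),
            class = "dgm_params")
}

#' Ground-truth nonnull labels by lag
#'
#' A taxon is nonnull at lag h if it is directly affected via a nonzero row
#' of `B_q` (or `C_q`) for some q <= h, or reachable from a taxon that is
#' nonnull at lag h - p through a nonzero entry of `A_p` (total lag budget
#' h). Labels are monotone nondecreasing in h.
#'
#' @param params a `dgm_params`.
#' @param h_max largest lag labelled.
#' @param tol entries with absolute value above `tol` count as links.
#' @return a J x h_max logical matrix, `[j, h]` = nonnull at lag h.
#' @export
truth_labels <- function(params, h_max = 4L, tol = 1e-10) {
  J <- params$J
  direct_row <- function(q) {
    nz <- rowSums(abs(params$B[[q]]) > tol) > 0
    if (params$S > 0)
      nz <- nz | apply(abs(params$C[[q]]) > tol, 1L, any)
    nz
  }
  lab <- matrix(FALSE, J, h_max)
  for (h in seq_len(h_max)) {
    nn <- rep(FALSE, J)
    for (q in seq_len(min(h, params$Q))) nn <- nn | direct_row(q)
    for (p in seq_len(params$P)) {
      if (h - p >= 1L) {
        src <- lab[, h - p]
        if (any(src))
          nn <- nn | (rowSums(abs(params$A[[p]][, src, drop = FALSE]) > tol) > 0)
      }
    }
    if (h > 1L) nn <- nn | lab[, h - 1L]   # cumulative: monotone in h
    lab[, h] <- nn
  }
  rownames(lab) <- paste0("tax", seq_len(J))
  colnames(lab) <- paste0("lag", seq_len(h_max))
  lab
}

#' Default single-pulse intervention schedule
#'
#' One contiguous pulse per subject, the same for all channels.
#'
#' @param T_len number of timepoints.
#' @param D number of channels.
#' @param onset first pulse timepoint (1-based index).
#' @param duration pulse length in timepoints.
#' @return a D x T_len 0/1 matrix.
#' @export
pulse_schedule <- function(T_len, D = 1L, onset = 11L, duration = 5L) {
  W <- matrix(0, D, T_len)
  on <- intersect(seq.int(onset, onset + duration - 1L), seq_len(T_len))
  W[, on] <- 1
  W
}

#' Simulate a benchmark dataset from the autoregressive NB factor model
#'
#' The latent log-abundance recursion is
#' `theta_t = sum_p A_p theta_{t-p} + sum_q (B_q + C_q . z) w_{t-q} + eps_t`
#' with `eps_t ~ N(0, Sigma)`, initialized at 0 with a discarded burn-in
#' (no intervention during burn-in). Counts are drawn taxon-wise as
#' `y_tj ~ NB(mean = b_i exp(theta_tj), dispersion = phi)` with per-subject
#' depth `b_i ~ Gamma(shape 10, scale lambda)`.
#'
#' @param params a `dgm_params`.
#' @param n_subjects number of subjects.
#' @param T_len number of retained timepoints per subject.
#' @param schedule D x T_len intervention matrix applied to every subject, or
#'   a list with one per subject; default [pulse_schedule()].
#' @param z optional n x S covariate matrix (drawn as standard normals when S
#'   > 0 and `z` is `NULL`).
#' @param seed integer seed.
#' @param h_max number of lags to label in the returned truth.
#' @return a list with `collection` (a [study_collection] of counts),
#'   `truth` (J x h_max logical), `params`, and `depths` (the b_i draws).
#' @export
simulate_dataset <- function(params, n_subjects, T_len, schedule = NULL,
                             z = NULL, seed = 1L, h_max = 4L) {
  stopifnot(inherits(params, "dgm_params"))
  J <- params$J; D <- params$D; S <- params$S
  if (is.null(schedule)) schedule <- pulse_schedule(T_len, D)
  if (is.matrix(schedule)) schedule <- rep(list(schedule), n_subjects)
  if (any(vapply(schedule, ncol, 1L) < T_len))
    stop("schedule must span at least T_len timepoints")
  set.seed(seed)
  if (S > 0 && is.null(z))
    z <- matrix(rnorm(n_subjects * S), n_subjects, S,
                dimnames = list(NULL, paste0("z", seq_len(S))))
  cS <- chol(params$Sigma + diag(1e-10, J))
  burn <- params$burn_in
  Ttot <- burn + T_len
  maxlag <- max(params$P, params$Q)
  taxa <- paste0("tax", seq_len(J))
  abundances <- list(); interventions <- list(); times <- list()
  depths <- numeric(n_subjects)
  for (i in seq_len(n_subjects)) {
    W <- cbind(matrix(0, D, burn), schedule[[i]][, seq_len(T_len), drop = FALSE])
    theta <- matrix(0, J, Ttot + maxlag)   # leading maxlag zero columns
    eps <- crossprod(cS, matrix(rnorm(J * Ttot), J, Ttot))
    Wpad <- cbind(matrix(0, D, maxlag), W)
    for (t in seq_len(Ttot)) {
      tc <- t + maxlag
      th <- eps[, t]
      for (p in seq_len(params$P)) th <- th + params$A[[p]] %*% theta[, tc - p]
      for (q in seq_len(params$Q)) {
        Bq <- params$B[[q]]
        if (S > 0) for (s in seq_len(S)) Bq <- Bq + params$C[[q]][, , s] * z[i, s]
        th <- th + Bq %*% Wpad[, tc - q]
      }
      theta[, tc] <- th
    }
    theta <- theta[, maxlag + burn + seq_len(T_len), drop = FALSE]
    if (max(theta) > 27)
      stop("exp(theta) overflow; reduce signal_strength or Sigma")
    b_i <- rgamma(1L, shape = 10, scale = params$lambda)
    depths[i] <- b_i
    mu <- b_i * exp(theta)
    cnt <- matrix(rnbinom(J * T_len, mu = mu, size = params$phi), J, T_len,
                  dimnames = list(taxa, NULL))
    sid <- sprintf("s%02d", i)
    abundances[[sid]] <- cnt
    interventions[[sid]] <- matrix(W[, burn + seq_len(T_len), drop = FALSE],
                                   D, T_len,
                                   dimnames = list(paste0("w", seq_len(D)), NULL))
    times[[sid]] <- seq_len(T_len)
  }
  collection <- study_collection(abundances, interventions, times,
                                 covariates = if (S > 0) z else NULL)
  list(collection = collection, truth = truth_labels(params, h_max),
       params = params, depths = depths)
}
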