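# Fixture builders shared across the suite. Everything is generated in code;
# no stored data files.

# A minimal deterministic collection: values are simple functions of time so
# expected designs can be enumerated by hand.
toy_collection <- function(n_subjects = 1L, T_len = 10L, J = 2L, D = 1L,
                           covariates = NULL, fill = NULL) {
  abundances <- list(); interventions <- list(); times <- list()
  for (i in seq_len(n_subjects)) {
    sid <- paste0("s", i)
    Y <- if (is.null(fill))
      outer(seq_len(J), seq_len(T_len), function(j, t) 10 * j + t + i / 10)
    else matrix(fill, J, T_len)
    rownames(Y) <- paste0("tax", seq_len(J))
    W <- matrix(rep(c(0, 1), length.out = D * T_len), D, T_len,
                dimnames = list(paste0("w", seq_len(D)), NULL))
    abundances[[sid]] <- Y; interventions[[sid]] <- W
    times[[sid]] <- seq_len(T_len)
  }
  study_collection(abundances, interventions, times, covariates)
}

# Collection whose responses follow a known sparse linear transfer model:
#   y_t[j] = beta0 + sum_k beta_y[j,k] * y_{t-1}[k] + beta_w[j] * w_t + noise
linear_collection <- function(n_subjects = 6L, T_len = 20L, J = 3L,
                              beta_y = NULL, beta_w = NULL, beta0 = 0,
                              noise_sd = 0.1, seed = 1L) {
  set.seed(seed)
  if (is.null(beta_y)) beta_y <- diag(0.5, J)
  if (is.null(beta_w)) beta_w <- c(2, rep(0, J - 1L))
  abundances <- list(); interventions <- list(); times <- list()
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("s%02d", i)
    W <- matrix(0, 1L, T_len, dimnames = list("w1", NULL))
    W[1L, 8:12] <- 1
    Y <- matrix(0, J, T_len, dimnames = list(paste0("tax", seq_len(J)), NULL))
    Y[, 1L] <- rnorm(J, sd = 1)
    for (t in 2:T_len)
      Y[, t] <- beta0 + beta_y %*% Y[, t - 1L] + beta_w * W[1L, t] +
        rnorm(J, sd = noise_sd)
    abundances[[sid]] <- Y; interventions[[sid]] <- W
    times[[sid]] <- seq_len(T_len)
  }
  study_collection(abundances, interventions, times)
}

# Hand-assembled DGM parameter object for the intervention -> taxon 1 ->
# taxon 2 linear chain (lag-1 autoregressive link), all other taxa null.
chain_params <- function(J = 20L, b_effect = 2, a_link = 0.6,
                         noise_sd = 0.5, phi = 10, lambda = 10) {
  A1 <- matrix(0, J, J); A1[2L, 1L] <- a_link
  B1 <- matrix(0, J, 1L); B1[1L, 1L] <- b_effect
  structure(list(J = J, D = 1L, S = 0L, rank = 1L, P = 1L, Q = 1L,
                 A = list(A1), B = list(B1),
                 C = list(array(0, dim = c(J, 1L, 1L))),
                 Sigma = diag(noise_sd^2, J),
                 phi = phi, lambda = lambda, alpha = 10,
                 pi_nonnull = 1 / J, nonnull = 1L,
                 signal_strength = b_effect, burn_in = 20L, seed = NA_integer_),
            class = "dgm_params")
}

# Raw design wrapper: treats an arbitrary numeric matrix as the base design
# so boosting/screening/PD machinery can be exercised on hand-built problems.
raw_design <- function(X, Y, P = 1L, Q = 1L, D = 0L, S = 0L) {
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("tax", seq_len(ncol(Y)))
  structure(list(X = X, Y_response = Y,
                 window_index = data.frame(subject = "s1",
                                           time = seq_len(nrow(X)),
                                           t_index = seq_len(nrow(X))),
                 P = P, Q = Q, J = ncol(Y), D = D, S = S,
                 base_cols = ncol(X), feature_names = colnames(X),
                 interactions = NULL, taxa = colnames(Y),
                 intervention_names = if (D > 0) paste0("w", seq_len(D)) else character(0),
                 covariate_names = character(0)),
            class = "lagged_design")
}

# Exhaustive reachability oracle for ground-truth labels: breadth-first
# search over (taxon, consumed-lag) states starting from the direct B_q rows,
# following A_p links while the lag budget h allows.
truth_reach_oracle <- function(p, h_max) {
  oracle <- matrix(FALSE, p$J, h_max)
  direct <- lapply(seq_len(p$Q), function(q) which(rowSums(abs(p$B[[q]])) > 1e-10))
  for (h in seq_len(h_max)) {
    reach <- integer(0)
    states <- list()
    for (q in seq_len(min(h, p$Q))) for (j in direct[[q]])
      states[[length(states) + 1L]] <- c(j, q)
    seen <- matrix(FALSE, p$J, h)
    while (length(states)) {
      st <- states[[1L]]; states <- states[-1L]
      j <- st[1L]; l <- st[2L]
      if (l > h || seen[j, l]) next
      seen[j, l] <- TRUE
      reach <- union(reach, j)
      for (pp in seq_len(p$P)) if (l + pp <= h) {
        for (tg in which(abs(p$A[[pp]][, j]) > 1e-10))
          states[[length(states) + 1L]] <- c(tg, l + pp)
      }
    }
    oracle[sort(reach), h] <- TRUE
  }
  oracle
}

# Independent natural-cubic-spline oracle: solves the standard tridiagonal
# second-derivative system for knots (x, y) and evaluates the piecewise cubic
# at xout. Kept free of stats::spline so interpolation tests have a second
# route.
natural_spline_oracle <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n); rhs <- numeric(n)
  A[1L, 1L] <- 1; A[n, n] <- 1
  for (i in 2:(n - 1L)) {
    A[i, i - 1L] <- h[i - 1L]
    A[i, i] <- 2 * (h[i - 1L] + h[i])
    A[i, i + 1L] <- h[i]
    rhs[i] <- 6 * ((y[i + 1L] - y[i]) / h[i] - (y[i] - y[i - 1L]) / h[i - 1L])
  }
  m <- solve(A, rhs)   # second derivatives at the knots
  vapply(xout, function(x0) {
    i <- max(1L, min(n - 1L, findInterval(x0, x)))
    d <- x0 - x[i]
    y[i] +
      ((y[i + 1L] - y[i]) / h[i] - h[i] / 6 * (2 * m[i] + m[i + 1L])) * d +
      m[i] / 2 * d^2 +
      (m[i + 1L] - m[i]) / (6 * h[i]) * d^3
  }, 0)
}
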