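#' Lotka-Volterra toy-system parameters
#'
#' The classical predator-prey system `dy1/dt = b1 y1 - a12 y1 y2`,
#' `dy2/dt = -b2 y2 + a21 y1 y2`, with the prey growth rate `b1` replaced by
#' `perturb_value` inside the perturbation windows. Defaults follow the
#' standard configuration: `b1 = 2`, `b2 = a12 = a21 = 1`, discretization
#' `delta = 0.2` over 10 time units, perturbation windows \[3, 4\] and
#' \[8, 9\] switching `b1` to 1, initial states Unif\[0, 4\].
#'
#' @param b1,b2,a12,a21 positive rates.
#' @param delta discretization step.
#' @param horizon total simulated time.
#' @param perturb_windows list of `c(start, end)` intervals inside
#'   \[0, horizon\].
#' @param perturb_value growth rate used inside the windows.
#' @param init_min,init_max bounds of the uniform initial-state draw.
#' @return an object of class `lv_params`.
#' @export
lv_params <- function(b1 = 2, b2 = 1, a12 = 1, a21 = 1, delta = 0.2,
                      horizon = 10, perturb_windows = list(c(3, 4), c(8, 9)),
                      perturb_value = 1, init_min = 0, init_max = 4) {
  if (delta <= 0) stop("delta must be positive")
  stopifnot(b1 > 0, b2 > 0, a12 > 0, a21 > 0, horizon > 0)
  for (w in perturb_windows)
    if (w[1L] < 0 || w[2L] > horizon || w[1L] >= w[2L])
      stop("perturbation windows must be increasing intervals inside [0, horizon]")
  structure(list(b1 = b1, b2 = b2, a12 = a12, a21 = a21, delta = delta,
                 horizon = horizon, perturb_windows = perturb_windows,
                 perturb_value = perturb_value,
                 init_min = init_min, init_max = init_max),
            class = "lv_params")
}

# Indicator of the perturbation at time t (half-open windows [a, b)).
lv_perturbed <- function(params, t) {
  for (w in params$perturb_windows)
    if (t >= w[1L] && t < w[2L]) return(TRUE)
  FALSE
}

# One discrete-time update (the discretized, perturbed system):
#   y1 <- (1 + delta * b1(t) - delta * a12 * y2) * y1
#   y2 <- (1 - delta * b2 + delta * a21 * y1) * y2
# with b1(t) switched to perturb_value inside the windows.
lv_step_discrete <- function(params, y, t) {
  b1t <- if (lv_perturbed(params, t)) params$perturb_value else params$b1
  c((1 + params$delta * b1t - params$delta * params$a12 * y[2L]) * y[1L],
    (1 - params$delta * params$b2 + params$delta * params$a21 * y[1L]) * y[2L])
}

lv_deriv <- function(params, y, t) {
  b1t <- if (lv_perturbed(params, t)) params$perturb_value else params$b1
  c(b1t * y[1L] - params$a12 * y[1L] * y[2L],
    -params$b2 * y[2L] + params$a21 * y[1L] * y[2L])
}

# Classical fixed-step RK4 from t to t + delta with n_sub substeps.
lv_rk4 <- function(params, y, t, n_sub = 20L) {
  h <- params$delta / n_sub
  for (k in seq_len(n_sub)) {
    k1 <- lv_deriv(params, y, t)
    k2 <- lv_deriv(params, y + h / 2 * k1, t + h / 2)
    k3 <- lv_deriv(params, y + h / 2 * k2, t + h / 2)
    k4 <- lv_deriv(params, y + h * k3, t + h)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

#' Simulate predator-prey trajectories with growth-rate perturbation
#'
#' Generates `n_subjects` trajectories of (prey, predator) on the grid
#' `0, delta, ..., horizon`, each from an independent uniform initial state,
#' together with the binary perturbation series as the intervention channel.
#' `mode = "discrete"` applies the printed one-step recursion; `mode =
#' "continuous"` integrates the ODE system with RK4 substeps (the growth rate
#' switches inside the windows).
#'
#' @param params an [lv_params].
#' @param n_subjects number of trajectories.
#' @param seed integer seed for the initial states.
#' @param mode `"discrete"` or `"continuous"`.
#' @param init optional 2-column matrix of initial states overriding the
#'   uniform draw.
#' @return a [study_collection] with taxa `prey`, `predator` and
#'   intervention channel `perturb`.
#' @export
lv_simulate <- function(params, n_subjects, seed = 1L,
                        mode = c("discrete", "continuous"), init = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "lv_params"))
  set.seed(seed)
  grid <- seq(0, params$horizon, by = params$delta)
  Tn <- length(grid)
  if (is.null(init))
    init <- matrix(runif(2L * n_subjects, params$init_min, params$init_max),
                   n_subjects, 2L)
  w <- vapply(grid, function(t) as.numeric(lv_perturbed(params, t)), 0)
  abundances <- list(); interventions <- list(); times <- list()
  for (i in seq_len(n_subjects)) {
    Y <- matrix(NA_real_, 2L, Tn, dimnames = list(c("prey", "predator"), NULL))
    Y[, 1L] <- init[i, ]
    for (t in seq_len(Tn - 1L)) {
      Y[, t + 1L] <- if (mode == "discrete")
        lv_step_discrete(params, Y[, t], grid[t])
      else lv_rk4(params, Y[, t], grid[t])
    }
    sid <- sprintf("s%03d", i)
    abundances[[sid]] <- Y
    interventions[[sid]] <- matrix(w, 1L, Tn, dimnames = list("perturb", NULL))
    times[[sid]] <- grid
  }
  study_collection(abundances, interventions, times)
}

#' Conserved quantity of the unperturbed Lotka-Volterra system
#'
#' `H(y1, y2) = a21 y1 - b2 log y1 + a12 y2 - b1 log y2` is constant along
#' trajectories of the continuous system without perturbation; its drift is a
#' direct integrator-accuracy diagnostic.
#'
#' @param params an [lv_params].
#' @param y1,y2 positive state values (vectorized).
#' @return the invariant value(s).
#' @export
lv_invariant <- function(params, y1, y2) {
  params$a21 * y1 - params$b2 * log(y1) + params$a12 * y2 - params$b1 * log(y2)
}
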