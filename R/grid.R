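# Spatial engine: periodic 8-neighbor lattice, explicit diffusion operator,
# clamped forward-Euler stepping with adaptive dt.
#
# Grid coordinates are 0-based (i = row, j = column, 0 <= i,j < N) so the
# periodic wrap is plain modulo arithmetic; linear cell index is
# column-major, c = j*N + i + 1, matching as.vector() on an N x N matrix.

#' Step-size policy for the explicit integrator
#'
#' @param dt_max largest allowed time step (default 0.1).
#' @param safety_theta largest allowed per-step change of any state
#'   variable; the adaptive step is `safety_theta / max|dX/dt|`, capped at
#'   `dt_max` (default 0.1).
#' @return A list of class `"ecm_step_policy"`.
#' @export
step_policy <- function(dt_max = 0.1, safety_theta = 0.1) {
  stopifnot(is.numeric(dt_max), dt_max > 0,
            is.numeric(safety_theta), safety_theta > 0)
  structure(list(dt_max = dt_max, safety_theta = safety_theta),
            class = "ecm_step_policy")
}

#' Simulation configuration
#'
#' @param grid_size lattice size N; the tissue is N x N cells (default
#'   100). Must be at least 3 so the 8-neighborhood never wraps onto the
#'   cell itself.
#' @param rates optional [rate_constants()] overrides (named subset
#'   allowed); `NULL` (the default) uses the network's own rates.
#' @param step a [step_policy()].
#' @param seed RNG seed for the random initial state.
#' @param initial_noise_amplitude upper bound of the uniform random
#'   initial concentrations (default 0.1).
#' @return A list of class `"ecm_config"`.
#' @export
simulation_config <- function(grid_size = 100, rates = NULL,
                              step = step_policy(), seed = 1L,
                              initial_noise_amplitude = 0.1) {
  grid_size <- as.integer(grid_size)
  if (is.na(grid_size) || grid_size < 3L)
    stop("grid_size must be an integer >= 3", call. = FALSE)
  if (initial_noise_amplitude < 0 || initial_noise_amplitude > 1)
    stop("initial_noise_amplitude must lie in [0, 1]", call. = FALSE)
  structure(list(grid_size = grid_size,
                 rates = if (is.null(rates)) NULL else as_rates(rates),
                 step = step, seed = as.integer(seed),
                 initial_noise_amplitude = initial_noise_amplitude),
            class = "ecm_config")
}

#' Periodic 8-neighborhood of a grid cell
#'
#' Returns the eight lattice neighbors (orthogonal and diagonal) of cell
#' `(i, j)` with periodic wrap-around: coordinates are reduced modulo `N`,
#' so boundary cells neighbor the opposite edge. Coordinates are 0-based.
#'
#' @param i,j 0-based row and column, `0 <= i, j < N`.
#' @param N grid size (>= 3).
#' @return An 8 x 2 integer matrix of `(row, col)` pairs.
#' @examples
#' neighbor_coords(0, 0, 100)  # wraps to row/col 99
#' @export
neighbor_coords <- function(i, j, N) {
  N <- as.integer(N)
  if (N < 3L) stop("N must be >= 3", call. = FALSE)
  if (i < 0 || i >= N || j < 0 || j >= N)
    stop(sprintf("cell (%d, %d) out of range for grid size %d", i, j, N),
         call. = FALSE)
  off <- cbind(di = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
               dj = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  cbind(row = (i + off[, 1L]) %% N, col = (j + off[, 2L]) %% N)
}

# ncell x 8 matrix of linear neighbor indices (column-major cell order)
neighbor_index <- function(N) {
  i <- rep(0:(N - 1L), times = N)
  j <- rep(0:(N - 1L), each = N)
  off <- cbind(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
               c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  nb <- matrix(0L, N * N, 8L)
  for (k in 1:8) {
    ii <- (i + off[k, 1L]) %% N
    jj <- (j + off[k, 2L]) %% N
    nb[, k] <- jj * N + ii + 1L
  }
  nb
}

# sum over the 8 neighbors minus 8x self, as a vector over cells
lap8 <- function(f, nb) {
  s <- f[nb[, 1L]]
  for (k in 2:8) s <- s + f[nb[, k]]
  s - 8 * f
}

#' Discrete diffusion operator on the periodic lattice
#'
#' Applies the 8-neighbor finite-difference diffusion term
#' `D * sum_{(m,n) in N(i,j)} (C[m,n] - C[i,j])` with periodic boundaries.
#' The operator moves mass between neighbors only, so the grid total of
#' the returned plane is zero.
#'
#' @param field N x N numeric matrix.
#' @param D diffusion coefficient.
#' @return N x N matrix of rates `dC/dt` due to diffusion.
#' @examples
#' f <- matrix(0, 5, 5); f[3, 3] <- 1
#' sum(diffusion_term(f, 0.25))  # 0: the operator conserves mass
#' @export
diffusion_term <- function(field, D) {
  stopifnot(is.matrix(field), nrow(field) == ncol(field))
  if (any(!is.finite(field))) stop("field must be finite", call. = FALSE)
  N <- nrow(field)
  matrix(D * lap8(as.vector(field), neighbor_index(N)), N, N)
}

#' Adaptive forward-Euler time step
#'
#' `dt = min(dt_max, safety_theta / max_abs_rate)`: the step shrinks when
#' the system changes fast so no variable moves more than `safety_theta`
#' per step, and caps at `dt_max` when the system is quiescent.
#'
#' @param max_abs_rate largest `|dX/dt|` over all state variables (>= 0).
#' @param policy a [step_policy()].
#' @return The time step.
#' @export
adaptive_dt <- function(max_abs_rate, policy = step_policy()) {
  stopifnot(max_abs_rate >= 0)
  if (max_abs_rate == 0) return(policy$dt_max)
  min(policy$dt_max, policy$safety_theta / max_abs_rate)
}

#' Initial grid state
#'
#' Allocates the spatial state and draws the random initial condition:
#' every intracellular species and every ECM plane starts uniformly in
#' `[0, initial_noise_amplitude]` (species declaring a non-default
#' `init_lo`/`init_hi` range use that range verbatim); the secreted
#' feedback fields start at zero.
#'
#' @param spec an `ecm_network`.
#' @param config a [simulation_config()]; its `seed` fixes the draw.
#' @return A list of class `"ecm_grid_state"` with elements `X` (cells x
#'   species), `fb` (cells x feedback fields), `ecm` (cells x ECM
#'   fields), `N`, `time`, `iteration`.
#' @export
grid_state <- function(spec, config = simulation_config()) {
  comp <- compile_network(spec)
  N <- config$grid_size
  ncell <- N * N
  set.seed(config$seed)
  amp <- config$initial_noise_amplitude
  lo <- spec$species$init_lo
  hi <- spec$species$init_hi
  default <- lo == 0 & hi == 0.1
  lo <- ifelse(default, 0, lo)
  hi <- ifelse(default, amp, hi)
  X <- matrix(0, ncell, comp$S, dimnames = list(NULL, comp$names))
  for (s in seq_len(comp$S)) X[, s] <- runif(ncell, lo[s], hi[s])
  fb <- matrix(0, ncell, comp$n_fb, dimnames = list(NULL, comp$fb_names))
  ecm <- matrix(0, ncell, comp$n_ecm, dimnames = list(NULL, comp$ecm_names))
  for (m in seq_len(comp$n_ecm)) ecm[, m] <- runif(ncell, 0, amp)
  structure(list(X = X, fb = fb, ecm = ecm, N = N, time = 0,
                 iteration = 0L),
            class = "ecm_grid_state")
}

# One Euler update with precompiled network and neighbor table.
# inputs: ncell x n_inputs matrix. Returns the updated state.
step_impl <- function(state, comp, config, inputs, nb,
                      fixed_dt = NULL) {
  r <- comp$rates
  dX <- deriv_matrix(state$X, inputs, state$fb, comp)
  dfb <- state$fb
  for (k in seq_len(comp$n_fb)) {
    dfb[, k] <- comp$fb_D[k] * lap8(state$fb[, k], nb) +
      r[["k_production"]] * state$X[, comp$fb_precursor_idx[k]] -
      comp$fb_lambda[k] * state$fb[, k]
  }
  decm <- state$ecm
  D_ecm <- 0.2 * r[["k_diffusion"]]  # ECM diffuses at 20% the feedback rate
  for (m in seq_len(comp$n_ecm)) {
    decm[, m] <- D_ecm * lap8(state$ecm[, m], nb) +
      r[["k_production"]] * state$X[, comp$ecm_precursor_idx[m]] -
      r[["k_degradation"]] * state$ecm[, m]
  }
  if (anyNA(dX) || any(!is.finite(dX))) {
    bad <- which(!is.finite(dX), arr.ind = TRUE)[1L, ]
    cell <- bad[1L] - 1L
    stop(sprintf(
      "non-finite derivative at cell (%d, %d), species %s",
      cell %% state$N, cell %/% state$N, comp$names[bad[2L]]),
      call. = FALSE)
  }
  if (any(!is.finite(dfb)) || any(!is.finite(decm)))
    stop("non-finite derivative in a spatial field", call. = FALSE)
  dt <- if (!is.null(fixed_dt)) fixed_dt
        else adaptive_dt(max(abs(dX),
                             if (length(dfb)) abs(dfb) else 0,
                             if (length(decm)) abs(decm) else 0),
                         config$step)
  clamp <- function(M) pmin(pmax(M, 0), 1)
  state$X <- clamp(state$X + dt * dX)
  if (comp$n_fb) state$fb <- clamp(state$fb + dt * dfb)
  if (comp$n_ecm) state$ecm <- clamp(state$ecm + dt * decm)
  state$time <- state$time + dt
  state$iteration <- state$iteration + 1L
  state
}

#' One forward-Euler step of the full spatial system
#'
#' Advances intracellular species (per-cell network derivatives), the
#' diffusible feedback fields (8-neighbor diffusion at `k_diffusion`,
#' production `k_production * precursor`, first-order clearance) and the
#' ECM fields (same form but diffusing at 20% of the feedback rate) by one
#' clamped Euler update. Derivatives are evaluated on the current
#' (unclamped) state; the clamp to \[0, 1\] is applied once after the
#' update. Time advances by the adaptive step unless `fixed_dt` is given.
#'
#' @param state an `ecm_grid_state`.
#' @param spec the `ecm_network` the state was built from.
#' @param config a [simulation_config()].
#' @param inputs per-cell external inputs: a `cells x inputs` matrix or an
#'   `N x N x inputs` array (see [apply_inputs()]); defaults to all zero.
#' @param fixed_dt optional fixed time step overriding the adaptive rule.
#' @return The updated `ecm_grid_state`.
#' @export
grid_step <- function(state, spec, config = simulation_config(grid_size = state$N),
                      inputs = NULL, fixed_dt = NULL) {
  if (!is.null(config$rates)) spec$rates <- config$rates
  comp <- compile_network(spec)
  inputs <- as_input_matrix(inputs, state$N, comp$n_inputs)
  step_impl(state, comp, config, inputs, neighbor_index(state$N), fixed_dt)
}

as_input_matrix <- function(inputs, N, n_inputs) {
  ncell <- N * N
  if (is.null(inputs)) return(matrix(0, ncell, n_inputs))
  if (is.array(inputs) && length(dim(inputs)) == 3L) {
    stopifnot(dim(inputs)[1L] == N, dim(inputs)[2L] == N,
              dim(inputs)[3L] == n_inputs)
    return(matrix(inputs, ncell, n_inputs))
  }
  stopifnot(is.matrix(inputs), nrow(inputs) == ncell,
            ncol(inputs) == n_inputs)
  inputs
}

#' Total number of coupled state variables
#'
#' Each grid cell carries one ODE per intracellular species and the
#' domain carries one ODE per feedback field per cell:
#' `n_species * N^2 + n_feedback_fields * N^2`. For the reference network
#' at N = 100 this is 1,320,000 + 40,000 = 1,360,000.
#'
#' @param spec an `ecm_network`.
#' @param N grid size.
#' @return Integer count.
#' @export
count_state_variables <- function(spec, N = 100) {
  N <- as.integer(N)
  nrow(spec$species) * N^2 + nrow(spec$feedback_fields) * N^2
}

#' Extract one spatial plane from a grid state
#'
#' Looks the name up among ECM fields first, then feedback fields, then
#' intracellular species (use prefix `"species:"` to force the species
#' plane when an ECM field shares the precursor's name).
#'
#' @param state an `ecm_grid_state`.
#' @param field field or species name.
#' @return N x N numeric matrix.
#' @export
get_plane <- function(state, field) {
  N <- state$N
  if (startsWith(field, "species:")) {
    nm <- sub("^species:", "", field)
    if (nm %in% colnames(state$X)) return(matrix(state$X[, nm], N, N))
    stop("unknown species: ", nm, call. = FALSE)
  }
  if (field %in% colnames(state$ecm)) return(matrix(state$ecm[, field], N, N))
  if (field %in% colnames(state$fb)) return(matrix(state$fb[, field], N, N))
  if (field %in% colnames(state$X)) return(matrix(state$X[, field], N, N))
  stop("unknown field: ", field, call. = FALSE)
}

#' @export
print.ecm_grid_state <- function(x, ...) {
  cat(sprintf(
    "<ecm_grid_state> %d x %d cells, %d species, t = %.4g, iteration %d\n",
    x$N, x$N, ncol(x$X), x$time, x$iteration))
  invisible(x)
}
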