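#' Run a scenario on the cellular grid
#'
#' The main entry point of the simulator. Builds the seeded random initial
#' state, expands the scenario's brush mask into the constant per-cell
#' input field, then advances the clamped forward-Euler integrator for
#' `duration_iterations` steps, keeping a full copy of the state at every
#' requested snapshot iteration and recording the probed cells' selected
#' molecules at every step. The trajectory is a deterministic function of
#' `(scenario, spec, config)` including the seed.
#'
#' @param scen an [scenario()]; its mask size must equal
#'   `config$grid_size`.
#' @param spec an `ecm_network`.
#' @param config a [simulation_config()].
#' @param record character vector of fields to record at the probe cells
#'   (default: the proCI ECM field, if present, plus all feedback fields).
#' @return An object of class `"ecm_simulation"`: list with `snapshots`
#'   (named list of `ecm_grid_state`, one per snapshot iteration),
#'   `probes` (data.frame: iteration, time, one column per probe cell and
#'   molecule), `final` (final state), `scenario`, `config`.
#' @examples
#' net <- build_reference_network()
#' cfg <- simulation_config(grid_size = 10, seed = 7)
#' sim <- run_simulation(scenario_case(2, 10), net, cfg)
#' region_summary(sim$final, sim$scenario$mask, "proCI")$inside
#' @export
run_simulation <- function(scen, spec, config = simulation_config(),
                           record = NULL) {
  stopifnot(inherits(scen, "ecm_scenario"), inherits(spec, "ecm_network"))
  if (!is.null(config$rates)) spec$rates <- config$rates
  N <- nrow(scen$mask)
  if (N != config$grid_size)
    stop(sprintf("scenario mask is %d x %d but config grid_size is %d",
                 N, N, config$grid_size), call. = FALSE)
  if (any(scen$snapshot_iterations > scen$duration_iterations))
    stop("snapshot iteration beyond scenario duration", call. = FALSE)
  comp <- compile_network(spec)
  if (is.null(record)) {
    record <- c(intersect("proCI", comp$ecm_names), comp$fb_names)
    if (!length(record)) record <- comp$names[comp$S]
  }
  inputs <- matrix(apply_inputs(scen, spec), N * N, comp$n_inputs)
  nb <- neighbor_index(N)
  state <- grid_state(spec, config)
  snapshots <- list()
  take <- function(st) {
    if (st$iteration %in% scen$snapshot_iterations)
      snapshots[[as.character(st$iteration)]] <<- st
  }
  probe_idx <- NULL
  if (!is.null(scen$probe_cells))
    probe_idx <- scen$probe_cells[, 2L] * N + scen$probe_cells[, 1L] + 1L
  n_it <- scen$duration_iterations
  probes <- NULL
  if (length(probe_idx)) {
    cols <- as.vector(outer(record, seq_along(probe_idx),
                            function(f, k) paste0("cell", k, "_", f)))
    probes <- matrix(NA_real_, n_it + 1L, 2L + length(cols),
                     dimnames = list(NULL, c("iteration", "time", cols)))
  }
  record_probe <- function(st) {
    if (is.null(probes)) return()
    row <- st$iteration + 1L
    vals <- numeric(0)
    for (k in seq_along(probe_idx)) {
      for (f in record) {
        v <- if (f %in% comp$ecm_names) st$ecm[probe_idx[k], f]
             else if (f %in% comp$fb_names) st$fb[probe_idx[k], f]
             else st$X[probe_idx[k], f]
        vals <- c(vals, v)
      }
    }
    probes[row, ] <<- c(st$iteration, st$time, vals)
  }
  take(state); record_probe(state)
  for (it in seq_len(n_it)) {
    state <- step_impl(state, comp, config, inputs, nb,
                       fixed_dt = scen$fixed_dt)
    take(state); record_probe(state)
  }
  structure(list(snapshots = snapshots,
                 probes = if (is.null(probes)) NULL else as.data.frame(probes),
                 final = state, scenario = scen, config = config,
                 rates = spec$rates),
            class = "ecm_simulation")
}

#' @export
print.ecm_simulation <- function(x, ...) {
  cat(sprintf(
    "<ecm_simulation>%s %d iterations (t = %.4g), %d snapshots, %d x %d grid\n",
    if (is.null(x$scenario$name)) "" else paste0(" [", x$scenario$name, "]"),
    x$final$iteration, x$final$time, length(x$snapshots), x$final$N,
    x$final$N))
  invisible(x)
}

#' @export
summary.ecm_simulation <- function(object, field = "proCI", ...) {
  print(object)
  cat(sprintf("Region summary of %s at each snapshot:\n", field))
  for (it in names(object$snapshots)) {
    rs <- region_summary(object$snapshots[[it]], object$scenario$mask, field)
    cat(sprintf(
      "  iter %4s: inside %s, ring %s, far %s, range [%.4g, %.4g]\n",
      it,
      if (is.na(rs$inside)) "NA" else sprintf("%.4g", rs$inside),
      if (is.na(rs$ring)) "NA" else sprintf("%.4g", rs$ring),
      if (is.na(rs$far_outside)) "NA" else sprintf("%.4g", rs$far_outside),
      rs$min, rs$max))
  }
  invisible(object)
}

#' Plot a snapshot plane as a heatmap
#'
#' Draws one field at one snapshot on the black-to-yellow scale fixed to
#' \[0, 1\] used throughout the package (brighter = higher concentration).
#'
#' @param x an `ecm_simulation`.
#' @param field field name (default `"proCI"`).
#' @param iteration snapshot iteration (default: last snapshot).
#' @param ... passed to [graphics::image()].
#' @return The plotted matrix, invisibly.
#' @export
plot.ecm_simulation <- function(x, field = "proCI", iteration = NULL, ...) {
  its <- names(x$snapshots)
  if (is.null(iteration)) iteration <- its[length(its)]
  iteration <- as.character(iteration)
  if (!iteration %in% its)
    stop("no snapshot at iteration ", iteration, call. = FALSE)
  plane <- get_plane(x$snapshots[[iteration]], field)
  pal <- grDevices::rgb(seq(0, 1, length.out = 256),
                        seq(0, 1, length.out = 256), 0)
  graphics::image(t(plane)[, nrow(plane):1], col = pal, zlim = c(0, 1),
                  axes = FALSE, asp = 1,
                  main = sprintf("%s, iteration %s", field, iteration), ...)
  invisible(plane)
}
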