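# Spatial stimulation: brush masks, scenario presets, region statistics.

#' Build a brush mask
#'
#' A brush mask is a logical N x N plane selecting the cells that receive
#' the scenario's input concentrations. Supported shapes:
#' \describe{
#'   \item{`rect`}{`params = list(row, col, height, width)` — axis-aligned
#'     rectangle with 0-based top-left corner `(row, col)`.}
#'   \item{`disk`}{`params = list(row, col, radius)` — Euclidean disk
#'     around the 0-based center.}
#'   \item{`x_shape`}{no parameters — the union of the main diagonal and
#'     the anti-diagonal, each one cell wide (2N cells for even N, 2N-1
#'     for odd N where the diagonals share the center).}
#'   \item{`cells`}{`params = list(cells = <k x 2 matrix>)` — an explicit
#'     freehand list of 0-based `(row, col)` pairs.}
#' }
#'
#' @param shape one of `"rect"`, `"disk"`, `"x_shape"`, `"cells"`.
#' @param params shape parameters (see above).
#' @param N grid size (>= 3).
#' @return Logical N x N matrix.
#' @examples
#' sum(make_brush_mask("x_shape", N = 100))  # 200 cells
#' sum(make_brush_mask("rect", list(row = 0, col = 0, height = 3, width = 3), 100))
#' @export
make_brush_mask <- function(shape = c("rect", "disk", "x_shape", "cells"),
                            params = list(), N) {
  shape <- match.arg(shape)
  N <- as.integer(N)
  if (N < 3L) stop("N must be >= 3", call. = FALSE)
  mask <- matrix(FALSE, N, N)
  switch(shape,
    rect = {
      stopifnot(all(c("row", "col", "height", "width") %in% names(params)))
      r <- params$row; c0 <- params$col
      if (r < 0 || c0 < 0 || r + params$height > N || c0 + params$width > N)
        stop("rectangle extends outside the grid", call. = FALSE)
      mask[(r + 1):(r + params$height), (c0 + 1):(c0 + params$width)] <- TRUE
    },
    disk = {
      stopifnot(all(c("row", "col", "radius") %in% names(params)))
      ii <- matrix(0:(N - 1L), N, N)
      jj <- t(ii)
      mask <- (ii - params$row)^2 + (jj - params$col)^2 <= params$radius^2
    },
    x_shape = {
      d <- 0:(N - 1L)
      mask[cbind(d + 1L, d + 1L)] <- TRUE
      mask[cbind(d + 1L, N - d)] <- TRUE
    },
    cells = {
      cells <- params$cells
      stopifnot(!is.null(cells))
      cells <- matrix(as.integer(cells), ncol = 2L)
      if (any(cells < 0L) || any(cells >= N))
        stop("cell list contains coordinates outside the grid", call. = FALSE)
      mask[cells + 1L] <- TRUE
    })
  mask
}

#' Define a stimulation scenario
#'
#' A scenario holds everything that defines one experiment: the brush
#' mask, the input concentrations applied inside it (held constant for the
#' whole run), the run length, which iterations to snapshot, up to two
#' probe cells whose time series are recorded each step, and the stepping
#' mode.
#'
#' @param mask logical N x N brush mask (see [make_brush_mask()]).
#' @param assignments named numeric vector, input species -> concentration
#'   in \[0, 1\] applied inside the mask.
#' @param duration_iterations number of Euler steps to run.
#' @param snapshot_iterations iterations at which to keep a full copy of
#'   the state; must lie in `[0, duration_iterations]`.
#' @param probe_cells at most two 0-based `(row, col)` pairs (k x 2
#'   matrix) to record each iteration.
#' @param fixed_dt optional fixed time step; `NULL` selects adaptive
#'   stepping.
#' @param default_input concentration outside the mask (default 0).
#' @param name optional label.
#' @return A list of class `"ecm_scenario"`.
#' @export
scenario <- function(mask, assignments = numeric(),
                     duration_iterations = 500L,
                     snapshot_iterations = c(0L, 100L, 300L, 500L),
                     probe_cells = NULL, fixed_dt = 0.1,
                     default_input = 0, name = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask), nrow(mask) == ncol(mask))
  if (length(assignments)) {
    if (is.null(names(assignments)))
      stop("assignments must be named by input species", call. = FALSE)
    if (any(assignments < 0 | assignments > 1))
      stop("assignment concentrations must lie in [0, 1]", call. = FALSE)
  }
  duration_iterations <- as.integer(duration_iterations)
  snapshot_iterations <- sort(unique(as.integer(snapshot_iterations)))
  if (any(snapshot_iterations < 0L) ||
      any(snapshot_iterations > duration_iterations))
    stop("snapshot_iterations must lie in [0, duration_iterations]",
         call. = FALSE)
  if (!is.null(probe_cells)) {
    probe_cells <- matrix(as.integer(probe_cells), ncol = 2L)
    if (nrow(probe_cells) > 2L)
      stop("at most 2 probe cells can be selected", call. = FALSE)
    if (any(probe_cells < 0L) || any(probe_cells >= nrow(mask)))
      stop("probe cells outside the grid", call. = FALSE)
  }
  structure(list(mask = mask, assignments = assignments,
                 default_input = default_input,
                 duration_iterations = duration_iterations,
                 snapshot_iterations = snapshot_iterations,
                 probe_cells = probe_cells, fixed_dt = fixed_dt,
                 name = name),
            class = "ecm_scenario")
}

#' The three preset case scenarios
#'
#' Three canonical experiments on the reference network, each running 500
#' iterations at a fixed time step of 0.1 with snapshots at iterations 0,
#' 100, 300 and 500:
#' \describe{
#'   \item{Case 1}{baseline — empty mask, all inputs 0; the random initial
#'     state relaxes toward a spatially homogeneous steady state.}
#'   \item{Case 2}{localized fibrotic stimulus — TGFB = 1 inside an
#'     X-shaped brush mask, everything else 0.}
#'   \item{Case 3}{combinatorial stimulation — TGFB, AngII, IL6, IL1,
#'     TNFa and NE all set to 1 inside the same X mask.}
#' }
#' Presets are pure functions of `(case_id, N)`.
#'
#' @param case_id 1, 2 or 3.
#' @param N grid size.
#' @return An `ecm_scenario`.
#' @examples
#' sum(scenario_case(2, 100)$mask)  # the X selects 200 cells
#' @export
scenario_case <- function(case_id, N = 100) {
  if (!length(case_id) == 1L || !case_id %in% 1:3)
    stop("case_id must be 1, 2 or 3", call. = FALSE)
  N <- as.integer(N)
  empty <- matrix(FALSE, N, N)
  xmask <- make_brush_mask("x_shape", N = N)
  switch(case_id,
    scenario(empty, numeric(), name = "case01_baseline"),
    scenario(xmask, c(TGFB = 1), name = "case02_tgfb_x"),
    scenario(xmask, c(TGFB = 1, AngII = 1, IL6 = 1, IL1 = 1, TNFa = 1,
                      NE = 1), name = "case03_multi_x"))
}

#' Expand a scenario into the per-cell input field
#'
#' Builds the `N x N x inputs` concentration array fed to the integrator:
#' each assigned input takes its assigned value inside the mask and the
#' scenario's default (0) outside; unassigned inputs are 0 everywhere.
#'
#' @param scen an [scenario()].
#' @param spec the `ecm_network` declaring the input species.
#' @return `N x N x n_inputs` array, third dimension named by input
#'   species.
#' @export
apply_inputs <- function(scen, spec) {
  N <- nrow(scen$mask)
  inputs <- spec$inputs
  bad <- setdiff(names(scen$assignments), inputs)
  if (length(bad))
    stop("assignment to non-input species: ", paste(bad, collapse = ", "),
         call. = FALSE)
  field <- array(0, dim = c(N, N, length(inputs)),
                 dimnames = list(NULL, NULL, inputs))
  for (nm in names(scen$assignments)) {
    plane <- matrix(scen$default_input, N, N)
    plane[scen$mask] <- scen$assignments[[nm]]
    field[, , nm] <- plane
  }
  field
}

# cells on the outside of the mask touching it through an 8-neighbor
mask_ring <- function(mask) {
  N <- nrow(mask)
  nb <- neighbor_index(N)
  v <- as.vector(mask)
  touching <- matrix(v[nb], ncol = 8L)
  has_masked_nb <- rowSums(touching) > 0
  matrix(!v & has_masked_nb, N, N)
}

#' Regional summary statistics of one field
#'
#' Arithmetic means of a spatial plane over the brush mask, over all
#' unmasked cells, over the mask-adjacent ring (unmasked cells with at
#' least one masked 8-neighbor), over the far outside (unmasked and not in
#' the ring), plus the grid minimum and maximum. With an empty mask the
#' inside mean is `NA`.
#'
#' @param state an `ecm_grid_state`.
#' @param mask logical N x N brush mask.
#' @param field field name (see [get_plane()]).
#' @return Named list: `inside`, `outside`, `ring`, `far_outside`, `min`,
#'   `max`.
#' @export
region_summary <- function(state, mask, field) {
  plane <- get_plane(state, field)
  stopifnot(identical(dim(mask), dim(plane)))
  ring <- mask_ring(mask)
  far <- !mask & !ring
  list(inside = if (any(mask)) mean(plane[mask]) else NA_real_,
       outside = if (any(!mask)) mean(plane[!mask]) else NA_real_,
       ring = if (any(ring)) mean(plane[ring]) else NA_real_,
       far_outside = if (any(far)) mean(plane[far]) else NA_real_,
       min = min(plane), max = max(plane))
}

#' @export
print.ecm_scenario <- function(x, ...) {
  cat(sprintf("<ecm_scenario>%s %d iterations, %d cells masked\n",
              if (is.null(x$name)) "" else paste0(" [", x$name, "]"),
              x$duration_iterations, sum(x$mask)))
  if (length(x$assignments)) {
    cat("  inputs inside mask: ",
        paste(sprintf("%s=%g", names(x$assignments), x$assignments),
              collapse = ", "), "\n", sep = "")
  } else cat("  all inputs at default (", x$default_input, ")\n", sep = "")
  cat("  snapshots at: ", paste(x$snapshot_iterations, collapse = ", "),
      "; dt: ", if (is.null(x$fixed_dt)) "adaptive" else x$fixed_dt,
      "\n", sep = "")
  invisible(x)
}
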