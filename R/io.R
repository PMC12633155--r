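# Result writers: PNG heatmaps, full-precision CSV, scenario files and
# reproducible run manifests.

#' Render a concentration plane as a PNG heatmap
#'
#' Writes the plane with a monotone black-to-yellow colormap on a fixed
#' \[0, 1\] scale (never per-frame autoscaled, so frames from different
#' iterations stay visually comparable): concentration 0 maps to black,
#' 1 to full yellow.
#'
#' @param plane N x N numeric matrix with finite values in \[0, 1\].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(plane, path) {
  stopifnot(is.matrix(plane))
  if (any(!is.finite(plane)))
    stop("plane contains non-finite values", call. = FALSE)
  if (min(plane) < 0 || max(plane) > 1)
    stop("plane values must lie in [0, 1]", call. = FALSE)
  img <- array(0, dim = c(nrow(plane), ncol(plane), 3L))
  img[, , 1L] <- plane
  img[, , 2L] <- plane  # red + green, no blue: black -> yellow ramp
  png::writePNG(img, path)
  invisible(path)
}

#' Map concentrations to heatmap colors
#'
#' The exact colormap used by [render_heatmap()]: linear black-to-yellow,
#' fixed to the \[0, 1\] concentration scale.
#'
#' @param v numeric vector in \[0, 1\].
#' @return Matrix with columns r, g, b in \[0, 1\].
#' @export
heatmap_colormap <- function(v) {
  stopifnot(all(is.finite(v)), all(v >= 0 & v <= 1))
  cbind(r = v, g = v, b = 0 * v)
}

# 17 significant digits: enough for every double to re-parse exactly
fmt_full <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", out)
}

#' Write a spatial plane as a CSV matrix
#'
#' One row per grid row, no header; floats are written with 17
#' significant digits so re-reading reproduces them bit-exactly.
#'
#' @param plane N x N numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plane_csv <- function(plane, path) {
  ch <- matrix(fmt_full(plane), nrow(plane), ncol(plane))
  data.table::fwrite(data.table::as.data.table(ch), path,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the probe-cell time series as CSV
#'
#' Columns: iteration, time, then one column per probe cell and recorded
#' molecule; floats carry 17 significant digits for exact round-trips.
#'
#' @param probes the `probes` data.frame of an `ecm_simulation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probes_csv <- function(probes, path) {
  ch <- as.data.frame(lapply(probes, fmt_full), check.names = FALSE)
  data.table::fwrite(ch, path, quote = FALSE)
  invisible(path)
}

#' Read a plane written by [write_plane_csv()]
#' @param path CSV path.
#' @return Numeric matrix.
#' @export
read_plane_csv <- function(path) {
  as.matrix(data.table::fread(path, header = FALSE))
}

#' Write / read a scenario file
#'
#' Scenarios serialize to YAML with keys `mask` (either
#' `{shape, params}` or an explicit cell list), `assignments`, `duration`,
#' `snapshots`, `probe_cells`, `fixed_dt`, `grid_size`, `name`. The mask
#' is stored as its selected cell list, which round-trips any shape.
#'
#' @param scen an [scenario()].
#' @param path file path.
#' @return `write_scenario`: `path` invisibly; `load_scenario`: an
#'   `ecm_scenario`.
#' @export
write_scenario <- function(scen, path) {
  sel <- which(scen$mask, arr.ind = TRUE) - 1L
  doc <- list(grid_size = nrow(scen$mask),
              mask = list(cells = lapply(seq_len(nrow(sel)), function(k)
                as.integer(sel[k, ]))),
              assignments = as.list(scen$assignments),
              default_input = scen$default_input,
              duration = scen$duration_iterations,
              snapshots = as.integer(scen$snapshot_iterations),
              fixed_dt = scen$fixed_dt,
              name = scen$name)
  if (!is.null(scen$probe_cells))
    doc$probe_cells <- lapply(seq_len(nrow(scen$probe_cells)), function(k)
      as.integer(scen$probe_cells[k, ]))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
load_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  N <- as.integer(doc$grid_size)
  mask <- if (!is.null(doc$mask$shape)) {
    make_brush_mask(doc$mask$shape, doc$mask$params, N)
  } else {
    cells <- do.call(rbind, lapply(doc$mask$cells, as.integer))
    if (is.null(cells)) matrix(FALSE, N, N)
    else make_brush_mask("cells", list(cells = cells), N)
  }
  scenario(mask,
           assignments = unlist(doc$assignments) %||% numeric(),
           duration_iterations = doc$duration %||% 500L,
           snapshot_iterations = unlist(doc$snapshots) %||%
             c(0L, 100L, 300L, 500L),
           probe_cells = if (!is.null(doc$probe_cells))
             do.call(rbind, lapply(doc$probe_cells, as.integer)),
           fixed_dt = doc$fixed_dt,
           default_input = doc$default_input %||% 0,
           name = doc$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write simulation outputs and a run manifest
#'
#' Writes, under `out_dir`: one CSV matrix and one PNG heatmap per
#' requested field and snapshot iteration, the probe-cell time series
#' (`probes.csv`), the scenario file, and `manifest.json` recording the
#' network file and its MD5 hash, the scenario, the full configuration
#' and the output file index. Re-running with an identical manifest
#' reproduces byte-identical outputs.
#'
#' @param sim an `ecm_simulation`.
#' @param out_dir output directory (created if missing).
#' @param fields fields to write (default: proCI plus all feedback
#'   fields).
#' @param network_file path of the network file the run used (recorded,
#'   with its hash, in the manifest).
#' @return The manifest list, invisibly.
#' @export
write_run_outputs <- function(sim, out_dir, fields = NULL,
                              network_file = reference_network_path()) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  if (is.null(fields)) {
    fields <- c(intersect("proCI", colnames(sim$final$ecm)),
                colnames(sim$final$fb))
  }
  index <- list()
  for (f in fields) {
    for (it in names(sim$snapshots)) {
      plane <- get_plane(sim$snapshots[[it]], f)
      base <- sprintf("%s_iter%04d", gsub("[^A-Za-z0-9_.-]", "_", f),
                      as.integer(it))
      csv <- file.path(out_dir, paste0(base, ".csv"))
      pngf <- file.path(out_dir, paste0(base, ".png"))
      write_plane_csv(plane, csv)
      render_heatmap(plane, pngf)
      index[[length(index) + 1L]] <- list(field = f,
                                          iteration = as.integer(it),
                                          csv = basename(csv),
                                          png = basename(pngf))
    }
  }
  if (!is.null(sim$probes))
    write_probes_csv(sim$probes, file.path(out_dir, "probes.csv"))
  scen_path <- file.path(out_dir, "scenario.yaml")
  write_scenario(sim$scenario, scen_path)
  manifest <- list(
    software = list(package = "fibrogrid",
                    version = as.character(utils::packageVersion("fibrogrid"))),
    network = list(file = network_file,
                   md5 = unname(tools::md5sum(network_file))),
    scenario = list(file = basename(scen_path),
                    name = sim$scenario$name,
                    md5 = unname(tools::md5sum(scen_path))),
    config = list(grid_size = sim$config$grid_size,
                  seed = sim$config$seed,
                  initial_noise_amplitude = sim$config$initial_noise_amplitude,
                  rates = as.list(setNames(as.numeric(sim$rates),
                                           names(sim$rates))),
                  step = list(dt_max = sim$config$step$dt_max,
                              safety_theta = sim$config$step$safety_theta),
                  fixed_dt = sim$scenario$fixed_dt),
    fields = as.list(fields),
    snapshots = index)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
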