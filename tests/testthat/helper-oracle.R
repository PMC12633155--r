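# Independent naive oracles: plain term-by-term / per-cell loops reading
# the raw edge list, kept deliberately separate from the package's
# vectorized engine.

# derivative of every species of one cell, summed edge by edge
naive_cell_derivs <- function(state, external_inputs, feedback_local, spec) {
  r <- spec$rates
  d <- setNames(rep(0, nrow(spec$species)), spec$species$name)
  for (nm in names(d)) d[[nm]] <- -r[["k_degradation"]] * state[[nm]]
  for (nm in spec$inputs) {
    iext <- if (nm %in% names(external_inputs)) external_inputs[[nm]] else 0
    d[[nm]] <- d[[nm]] + r[["k_input"]] * iext
  }
  if (nrow(spec$feedback_fields)) {
    for (k in seq_len(nrow(spec$feedback_fields))) {
      tgt <- spec$feedback_fields$target_input[k]
      fnm <- spec$feedback_fields$name[k]
      cf <- if (fnm %in% names(feedback_local)) feedback_local[[fnm]] else 0
      if (!is.na(tgt)) d[[tgt]] <- d[[tgt]] + r[["k_feedback"]] * cf
    }
  }
  mod <- setNames(spec$species$module, spec$species$name)
  for (e in spec$edges) {
    rate <- if (!is.null(e$rate)) e$rate
            else if (e$sign == "inhibition") r[["k_inhibition"]]
            else if (mod[[e$target]] == "receptor") r[["k_receptor"]]
            else r[["k_activation"]]
    prodact <- 1
    for (a in e$activators) prodact <- prodact * state[[a]]
    if (e$sign == "production") {
      d[[e$target]] <- d[[e$target]] + rate * prodact
    } else {
      d[[e$target]] <- d[[e$target]] - rate * state[[e$target]] * prodact
    }
  }
  d
}

# one Euler step of the full grid, cell by cell and neighbor by neighbor
naive_grid_step <- function(state, spec, inputs_array, dt) {
  r <- spec$rates
  N <- state$N
  Xn <- state$X; fbn <- state$fb; ecmn <- state$ecm
  for (i in 0:(N - 1)) {
    for (j in 0:(N - 1)) {
      c0 <- j * N + i + 1
      x <- setNames(state$X[c0, ], colnames(state$X))
      iext <- setNames(inputs_array[i + 1, j + 1, ],
                       dimnames(inputs_array)[[3]])
      fbl <- setNames(state$fb[c0, ], colnames(state$fb))
      d <- naive_cell_derivs(x, iext, fbl, spec)
      Xn[c0, ] <- pmin(pmax(x + dt * d, 0), 1)
      nbs <- neighbor_coords(i, j, N)
      nb_idx <- nbs[, 2] * N + nbs[, 1] + 1
      for (k in seq_len(ncol(state$fb))) {
        Dk <- spec$feedback_fields$diffusion[k]
        if (is.na(Dk)) Dk <- r[["k_diffusion"]]
        lam <- spec$feedback_fields$clearance[k]
        if (is.na(lam)) lam <- r[["k_degradation"]]
        diff_sum <- sum(state$fb[nb_idx, k] - state$fb[c0, k])
        prec <- spec$feedback_fields$precursor[k]
        dC <- Dk * diff_sum + r[["k_production"]] * state$X[c0, prec] -
          lam * state$fb[c0, k]
        fbn[c0, k] <- min(max(state$fb[c0, k] + dt * dC, 0), 1)
      }
      for (m in seq_len(ncol(state$ecm))) {
        diff_sum <- sum(state$ecm[nb_idx, m] - state$ecm[c0, m])
        prec <- spec$ecm_fields$precursor[m]
        dE <- 0.2 * r[["k_diffusion"]] * diff_sum +
          r[["k_production"]] * state$X[c0, prec] -
          r[["k_degradation"]] * state$ecm[c0, m]
        ecmn[c0, m] <- min(max(state$ecm[c0, m] + dt * dE, 0), 1)
      }
    }
  }
  state$X <- Xn; state$fb <- fbn; state$ecm <- ecmn
  state$time <- state$time + dt
  state$iteration <- state$iteration + 1L
  state
}

# tiny helper networks used across test files
toy_chain_network <- function() {
  network_spec(
    species = data.frame(name = c("I", "A", "B", "C"),
                         module = c("input", "other", "other", "other")),
    edges = list(
      list(target = "A", activators = "I", sign = "production"),
      list(target = "B", activators = "A", sign = "production"),
      list(target = "C", activators = "B", sign = "production")),
    inputs = "I")
}

# one diffusible field fed by an inert precursor; clearance 0 so that a
# run with the precursor at zero is pure diffusion
diffusion_only_network <- function() {
  network_spec(
    species = data.frame(name = c("P"), module = "other",
                         init_lo = 0, init_hi = 0),
    edges = list(),
    feedback_fields = data.frame(name = "F", precursor = "P",
                                 target_input = NA_character_,
                                 diffusion = 0.25, clearance = 0))
}
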