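# Compiles a network into integer-indexed form so the same evaluation code
# serves both the single-cell API and the vectorized grid stepper.

compile_network <- function(spec) {
  nm <- spec$species$name
  idx <- setNames(seq_along(nm), nm)
  r <- spec$rates
  edges <- lapply(spec$edges, function(e) {
    tgt <- idx[[e$target]]
    rate <- if (!is.null(e$rate)) e$rate
            else if (e$sign == "inhibition") r[["k_inhibition"]]
            else if (spec$species$module[tgt] == "receptor") r[["k_receptor"]]
            else r[["k_activation"]]
    list(tgt = tgt, act = unname(idx[e$activators]),
         prod = e$sign == "production", rate = rate)
  })
  fb <- spec$feedback_fields
  list(S = length(nm), names = nm, idx = idx, edges = edges,
       rates = r,
       input_idx = unname(idx[spec$inputs]),
       n_inputs = length(spec$inputs),
       n_fb = nrow(fb),
       fb_names = fb$name,
       fb_precursor_idx = if (nrow(fb)) unname(idx[fb$precursor]) else integer(),
       # column of the input matrix each feedback field feeds (NA if none)
       fb_input_col = if (nrow(fb)) match(fb$target_input, spec$inputs)
                      else integer(),
       fb_D = if (nrow(fb))
         ifelse(is.na(fb$diffusion), r[["k_diffusion"]], fb$diffusion)
         else numeric(),
       fb_lambda = if (nrow(fb))
         ifelse(is.na(fb$clearance), r[["k_degradation"]], fb$clearance)
         else numeric(),
       ecm_names = spec$ecm_fields$name,
       ecm_precursor_idx = if (nrow(spec$ecm_fields))
         unname(idx[spec$ecm_fields$precursor]) else integer(),
       n_ecm = nrow(spec$ecm_fields))
}

row_product <- function(X, cols) {
  out <- X[, cols[1L]]
  for (k in cols[-1L]) out <- out * X[, k]
  out
}

# Derivatives for every cell at once. X: cells x species; I: cells x inputs
# (columns ordered as spec$inputs); FB: cells x feedback fields (local field
# value at each cell). Returns cells x species.
deriv_matrix <- function(X, I, FB, comp) {
  r <- comp$rates
  dX <- -r[["k_degradation"]] * X
  if (comp$n_inputs) {
    contrib <- r[["k_input"]] * I
    if (comp$n_fb) {
      for (k in seq_len(comp$n_fb)) {
        col <- comp$fb_input_col[k]
        if (!is.na(col))
          contrib[, col] <- contrib[, col] + r[["k_feedback"]] * FB[, k]
      }
    }
    dX[, comp$input_idx] <- dX[, comp$input_idx] + contrib
  }
  for (e in comp$edges) {
    term <- e$rate * row_product(X, e$act)
    if (e$prod) dX[, e$tgt] <- dX[, e$tgt] + term
    else dX[, e$tgt] <- dX[, e$tgt] - term * X[, e$tgt]
  }
  dX
}

#' Intracellular derivative vector for one cell
#'
#' Evaluates the per-cell ODE right-hand side. Input species follow
#' first-order input processing
#' `k_input * I_external + k_feedback * C_feedback - k_degradation * X`;
#' all other species sum their production edges
#' (`rate * prod(activators)`), subtract their inhibition edges
#' (`rate * X * prod(inhibitors)`) and first-order degradation
#' (`k_degradation * X`). Receptor activation and kinase/phosphatase
#' cycles are instances of this form: a ligand-to-receptor edge uses
#' `k_receptor` and competitive inhibition of a receptor uses
#' `k_inhibition`, so `dR/dt = k_receptor*L*R_total - k_inhibition*R*I -
#' k_degradation*R` with a unit receptor pool, and a kinase with upstream
#' kinase U, substrate S and phosphatase P obeys `dK/dt = k_activation*U*S
#' - k_inhibition*K*P - k_degradation*K`.
#'
#' The function is pure: the result depends only on its arguments.
#'
#' @param state numeric vector of species concentrations in \[0, 1\],
#'   ordered (or named) as `spec$species$name`.
#' @param external_inputs named numeric vector of external input
#'   concentrations (missing input species default to 0).
#' @param feedback_local named numeric vector of local feedback-field
#'   concentrations (missing fields default to 0).
#' @param spec an `ecm_network`.
#' @return Named numeric vector `dX/dt` over all species.
#' @examples
#' net <- build_reference_network()
#' x0 <- setNames(rep(0, nrow(net$species)), net$species$name)
#' d <- cell_derivatives(x0, c(TGFB = 1), numeric(), net)
#' d[["TGFB"]]  # k_input * 1 = 1
#' @export
cell_derivatives <- function(state, external_inputs = numeric(),
                             feedback_local = numeric(), spec) {
  comp <- compile_network(spec)
  if (length(state) != comp$S)
    stop(sprintf("state has length %d but the network has %d species",
                 length(state), comp$S), call. = FALSE)
  if (!is.null(names(state))) state <- state[comp$names]
  I <- matrix(0, 1L, comp$n_inputs)
  if (length(external_inputs)) {
    if (is.null(names(external_inputs))) {
      if (length(external_inputs) != comp$n_inputs)
        stop("unnamed external_inputs must have one value per input species",
             call. = FALSE)
      I[1L, ] <- external_inputs
    } else {
      pos <- match(names(external_inputs), spec$inputs)
      if (anyNA(pos))
        stop("external input for non-input species: ",
             paste(names(external_inputs)[is.na(pos)], collapse = ", "),
             call. = FALSE)
      I[1L, pos] <- external_inputs
    }
  }
  FB <- matrix(0, 1L, comp$n_fb)
  if (length(feedback_local)) {
    if (is.null(names(feedback_local))) {
      if (length(feedback_local) != comp$n_fb)
        stop("unnamed feedback_local must have one value per feedback field",
             call. = FALSE)
      FB[1L, ] <- feedback_local
    } else {
      pos <- match(names(feedback_local), comp$fb_names)
      if (anyNA(pos))
        stop("unknown feedback field: ",
             paste(names(feedback_local)[is.na(pos)], collapse = ", "),
             call. = FALSE)
      FB[1L, pos] <- feedback_local
    }
  }
  dX <- deriv_matrix(matrix(state, 1L, comp$S), I, FB, comp)
  setNames(as.numeric(dX), comp$names)
}
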