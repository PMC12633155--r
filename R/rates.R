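#' The eight global rate constants
#'
#' Constructs the set of user-tunable kinetic constants shared by every cell
#' of the grid. Each constant governs one class of term in the model:
#' `k_input` scales external stimuli, `k_feedback` the sensitivity of input
#' species to the diffusible feedback fields, `k_degradation` first-order
#' decay of every species (and, by default, clearance of the feedback
#' fields), `k_receptor` ligand-driven receptor activation, `k_inhibition`
#' every inhibitory interaction, `k_activation` generic production edges,
#' `k_production` secretion of feedback and ECM molecules from their
#' intracellular precursors, and `k_diffusion` the lattice diffusion
#' coefficient of the feedback fields (ECM fields diffuse at 20% of it).
#'
#' @param k_input input processing rate (default 1).
#' @param k_feedback feedback sensitivity (default 0.5).
#' @param k_degradation first-order degradation rate (default 1).
#' @param k_receptor receptor activation rate (default 2).
#' @param k_inhibition inhibition rate (default 0.5).
#' @param k_activation generic activation/production rate (default 1).
#' @param k_production feedback/ECM secretion rate (default 0.01).
#' @param k_diffusion feedback-field diffusion coefficient (default 0.25).
#' @return A named numeric vector of length 8, class `"ecm_rates"`.
#' @examples
#' rate_constants()
#' rate_constants(k_diffusion = 0.5)
#' @export
rate_constants <- function(k_input = 1.0, k_feedback = 0.5,
                           k_degradation = 1.0, k_receptor = 2.0,
                           k_inhibition = 0.5, k_activation = 1.0,
                           k_production = 0.01, k_diffusion = 0.25) {
  r <- c(k_input = k_input, k_feedback = k_feedback,
         k_degradation = k_degradation, k_receptor = k_receptor,
         k_inhibition = k_inhibition, k_activation = k_activation,
         k_production = k_production, k_diffusion = k_diffusion)
  validate_rates(r)
  class(r) <- "ecm_rates"
  r
}

#' Names of the eight tunable rate constants
#' @return Character vector of length 8.
#' @export
rate_constant_names <- function() {
  c("k_input", "k_feedback", "k_degradation", "k_receptor",
    "k_inhibition", "k_activation", "k_production", "k_diffusion")
}

validate_rates <- function(r) {
  nm <- rate_constant_names()
  if (!is.numeric(r) || length(r) != 8L || !identical(names(r), nm))
    stop("rates must be a named numeric vector with names: ",
         paste(nm, collapse = ", "), call. = FALSE)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("all rate constants must be strictly positive and finite",
         call. = FALSE)
  invisible(r)
}

as_rates <- function(x) {
  if (inherits(x, "ecm_rates")) return(x)
  if (is.null(x)) return(rate_constants())
  if (is.list(x)) x <- unlist(x)
  full <- rate_constants()
  unknown <- setdiff(names(x), names(full))
  if (length(unknown))
    stop("unknown rate constant(s): ", paste(unknown, collapse = ", "),
         "; valid names are: ", paste(rate_constant_names(), collapse = ", "),
         call. = FALSE)
  full[names(x)] <- as.numeric(x)
  validate_rates(unclass(full))
  class(full) <- "ecm_rates"
  full
}

#' @export
print.ecm_rates <- function(x, ...) {
  cat("Global rate constants:\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}
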