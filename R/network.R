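#' @importFrom stats setNames runif sd
#' @importFrom utils head modifyList
NULL

SPECIES_MODULES <- c("input", "receptor", "second_messenger",
                     "kinase_phosphatase", "mapk", "transcription_factor",
                     "mechanotransduction", "ecm_precursor",
                     "feedback_precursor", "other")

#' Construct a signaling network specification
#'
#' A network specification defines the per-cell reaction network: the
#' molecular species, the regulatory edges between them, which species are
#' external inputs, which intracellular precursors feed the diffusible
#' feedback fields and the ECM fields, and the global rate constants.
#'
#' Every species is a normalized activity in \[0, 1\]. Regulatory edges come
#' in two signs: a `production` edge contributes
#' `rate * prod(activators)` to its target's derivative (several activators
#' on one edge form an AND gate, combined multiplicatively); an
#' `inhibition` edge contributes `-rate * target * prod(inhibitors)`.
#' Every species additionally decays at `k_degradation`. Input species
#' instead follow first-order input processing
#' `k_input * I_external + k_feedback * C_feedback - k_degradation * X`
#' (plus any declared edges). The per-edge rate defaults by class:
#' `k_receptor` for production edges onto receptor-module species,
#' `k_inhibition` for inhibition edges, `k_activation` otherwise; an
#' explicit per-edge `rate` overrides the class default.
#'
#' @param species data.frame with columns `name`, `module` (one of
#'   `r paste(SPECIES_MODULES, collapse = ", ")`), and optionally
#'   `init_lo`/`init_hi` (initial-condition range, default \[0, 0.1\]).
#' @param edges list of edges; each edge is a list with `target` (species
#'   name), `activators` (character vector of species names), `sign`
#'   (`"production"` or `"inhibition"`; for inhibition the `activators`
#'   are the inhibitor species) and optional positive `rate`.
#' @param inputs ordered character vector of input species names.
#' @param feedback_fields data.frame with columns `name`, `precursor`
#'   (intracellular species secreted into the field), `target_input`
#'   (input species the field feeds back onto, or `NA`), and optional
#'   `diffusion` / `clearance` overrides (`NA` means use `k_diffusion` /
#'   `k_degradation`).
#' @param ecm_fields data.frame with columns `name` and `precursor`.
#' @param rates a [rate_constants()] vector (or named subset of overrides).
#' @return An object of class `"ecm_network"`.
#' @seealso [build_reference_network()], [load_network()]
#' @export
network_spec <- function(species, edges, inputs = character(),
                         feedback_fields = NULL, ecm_fields = NULL,
                         rates = rate_constants()) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  if (is.null(species$init_lo)) species$init_lo <- 0
  if (is.null(species$init_hi)) species$init_hi <- 0.1
  species$is_input <- species$name %in% inputs
  if (is.null(feedback_fields)) {
    feedback_fields <- data.frame(name = character(), precursor = character(),
                                  target_input = character(),
                                  diffusion = numeric(), clearance = numeric(),
                                  stringsAsFactors = FALSE)
  } else {
    feedback_fields <- as.data.frame(feedback_fields, stringsAsFactors = FALSE)
    if (is.null(feedback_fields$diffusion)) feedback_fields$diffusion <- NA_real_
    if (is.null(feedback_fields$clearance)) feedback_fields$clearance <- NA_real_
    if (is.null(feedback_fields$target_input))
      feedback_fields$target_input <- NA_character_
  }
  if (is.null(ecm_fields)) {
    ecm_fields <- data.frame(name = character(), precursor = character(),
                             stringsAsFactors = FALSE)
  } else {
    ecm_fields <- as.data.frame(ecm_fields, stringsAsFactors = FALSE)
  }
  spec <- structure(list(species = species, edges = edges,
                         inputs = as.character(inputs),
                         feedback_fields = feedback_fields,
                         ecm_fields = ecm_fields,
                         rates = as_rates(rates)),
                    class = "ecm_network")
  validate_network(spec)
  spec
}

#' Validate a network specification
#'
#' Checks all structural invariants: unique species names, every referenced
#' species resolves, edge signs and rates are well formed, initial ranges
#' lie inside \[0, 1\], and field precursors exist. Called by every
#' constructor; exported so externally edited files can be checked.
#'
#' @param spec an `ecm_network`.
#' @return `spec`, invisibly. Throws an informative error on violation.
#' @export
validate_network <- function(spec) {
  sp <- spec$species
  if (anyDuplicated(sp$name))
    stop("duplicate species name: ",
         paste(unique(sp$name[duplicated(sp$name)]), collapse = ", "),
         call. = FALSE)
  bad_mod <- setdiff(unique(sp$module), SPECIES_MODULES)
  if (length(bad_mod))
    stop("unknown species module: ", paste(bad_mod, collapse = ", "),
         call. = FALSE)
  if (any(sp$init_lo < 0 | sp$init_hi > 1 | sp$init_lo > sp$init_hi))
    stop("species initial ranges must satisfy 0 <= lo <= hi <= 1",
         call. = FALSE)
  known <- sp$name
  for (i in seq_along(spec$edges)) {
    e <- spec$edges[[i]]
    if (is.null(e$target) || !e$target %in% known)
      stop(sprintf("edge %d targets unknown species \"%s\"", i,
                   if (is.null(e$target)) "<missing>" else e$target),
           call. = FALSE)
    if (!e$sign %in% c("production", "inhibition"))
      stop(sprintf("edge %d (-> %s) has invalid sign \"%s\"", i, e$target,
                   e$sign), call. = FALSE)
    if (length(e$activators) < 1L)
      stop(sprintf("edge %d (-> %s) names no %s", i, e$target,
                   if (e$sign == "production") "activators" else "inhibitors"),
           call. = FALSE)
    missing_sp <- setdiff(e$activators, known)
    if (length(missing_sp))
      stop(sprintf("edge %d (-> %s) references unknown species \"%s\"",
                   i, e$target, paste(missing_sp, collapse = "\", \"")),
           call. = FALSE)
    if (!is.null(e$rate) && (!is.finite(e$rate) || e$rate <= 0))
      stop(sprintf("edge %d (-> %s) has non-positive rate", i, e$target),
           call. = FALSE)
  }
  missing_in <- setdiff(spec$inputs, known)
  if (length(missing_in))
    stop("input species not declared: ", paste(missing_in, collapse = ", "),
         call. = FALSE)
  fb <- spec$feedback_fields
  if (nrow(fb)) {
    if (anyDuplicated(fb$name))
      stop("duplicate feedback field name", call. = FALSE)
    miss <- setdiff(fb$precursor, known)
    if (length(miss))
      stop("feedback field precursor not declared: ",
           paste(miss, collapse = ", "), call. = FALSE)
    tgt <- fb$target_input[!is.na(fb$target_input)]
    if (length(setdiff(tgt, spec$inputs)))
      stop("feedback field target_input must be an input species",
           call. = FALSE)
    if (any(!is.na(fb$diffusion) & fb$diffusion < 0) ||
        any(!is.na(fb$clearance) & fb$clearance < 0))
      stop("feedback field diffusion/clearance must be non-negative",
           call. = FALSE)
  }
  ec <- spec$ecm_fields
  if (nrow(ec)) {
    if (anyDuplicated(ec$name))
      stop("duplicate ECM field name", call. = FALSE)
    miss <- setdiff(ec$precursor, known)
    if (length(miss))
      stop("ECM field precursor not declared: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  validate_rates(unclass(spec$rates))
  invisible(spec)
}

#' Load a network specification from a YAML file
#'
#' Reads the structured-text network schema: top-level keys `species`,
#' `edges`, `inputs`, `feedback_fields`, `ecm_fields`, `rates`. Each
#' species entry has `name`, `module` and optional `init: [lo, hi]`; each
#' edge has `target`, `activators`, `sign` and optional `rate`; rates is a
#' mapping over any subset of the eight constant names. The packaged
#' reference network file is at [reference_network_path()].
#'
#' @param path path to a YAML network file.
#' @return A validated `ecm_network`.
#' @examples
#' net <- load_network(reference_network_path())
#' nrow(net$species)
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  for (key in c("species", "edges"))
    if (is.null(doc[[key]]))
      stop("network file missing required key: ", key, call. = FALSE)
  species <- data.frame(
    name = vapply(doc$species, function(s) as.character(s$name), ""),
    module = vapply(doc$species, function(s)
      if (is.null(s$module)) "other" else as.character(s$module), ""),
    init_lo = vapply(doc$species, function(s)
      if (is.null(s$init)) 0 else as.numeric(s$init[[1]]), 0),
    init_hi = vapply(doc$species, function(s)
      if (is.null(s$init)) 0.1 else as.numeric(s$init[[2]]), 0),
    stringsAsFactors = FALSE)
  edges <- lapply(doc$edges, function(e)
    list(target = as.character(e$target),
         activators = as.character(unlist(e$activators)),
         sign = if (is.null(e$sign)) "production" else as.character(e$sign),
         rate = if (is.null(e$rate)) NULL else as.numeric(e$rate)))
  fb <- NULL
  if (length(doc$feedback_fields))
    fb <- data.frame(
      name = vapply(doc$feedback_fields, function(f) as.character(f$name), ""),
      precursor = vapply(doc$feedback_fields,
                         function(f) as.character(f$precursor), ""),
      target_input = vapply(doc$feedback_fields, function(f)
        if (is.null(f$target_input)) NA_character_
        else as.character(f$target_input), ""),
      diffusion = vapply(doc$feedback_fields, function(f)
        if (is.null(f$diffusion)) NA_real_ else as.numeric(f$diffusion), 0),
      clearance = vapply(doc$feedback_fields, function(f)
        if (is.null(f$clearance)) NA_real_ else as.numeric(f$clearance), 0),
      stringsAsFactors = FALSE)
  ec <- NULL
  if (length(doc$ecm_fields))
    ec <- data.frame(
      name = vapply(doc$ecm_fields, function(f) as.character(f$name), ""),
      precursor = vapply(doc$ecm_fields,
                         function(f) as.character(f$precursor), ""),
      stringsAsFactors = FALSE)
  network_spec(species, edges, inputs = as.character(unlist(doc$inputs)),
               feedback_fields = fb, ecm_fields = ec,
               rates = doc$rates)
}

#' Write a network specification to a YAML file
#'
#' Inverse of [load_network()]: serializes the network in the documented
#' schema so that `load_network(write_network(spec, f))` reproduces `spec`.
#'
#' @param spec an `ecm_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(spec, path) {
  doc <- list(
    species = lapply(seq_len(nrow(spec$species)), function(i) {
      s <- spec$species[i, ]
      list(name = s$name, module = s$module,
           init = c(s$init_lo, s$init_hi))
    }),
    edges = lapply(spec$edges, function(e) {
      out <- list(target = e$target, activators = as.list(e$activators),
                  sign = e$sign)
      if (!is.null(e$rate)) out$rate <- e$rate
      if (!is.null(e$note)) out$note <- e$note
      out
    }),
    inputs = as.list(spec$inputs),
    feedback_fields = lapply(seq_len(nrow(spec$feedback_fields)), function(i) {
      f <- spec$feedback_fields[i, ]
      out <- list(name = f$name, precursor = f$precursor)
      if (!is.na(f$target_input)) out$target_input <- f$target_input
      if (!is.na(f$diffusion)) out$diffusion <- f$diffusion
      if (!is.na(f$clearance)) out$clearance <- f$clearance
      out
    }),
    ecm_fields = lapply(seq_len(nrow(spec$ecm_fields)), function(i)
      list(name = spec$ecm_fields$name[i],
           precursor = spec$ecm_fields$precursor[i])),
    rates = as.list(setNames(as.numeric(spec$rates), names(spec$rates))))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Path to the packaged reference network file
#' @return File path of the YAML reference network shipped with the package.
#' @export
reference_network_path <- function() {
  system.file("extdata", "reference_network.yaml", package = "fibrogrid",
              mustWork = TRUE)
}

#' Module census of a network
#'
#' Counts species per functional module, plus totals for edges, inputs and
#' fields. For the reference network this reproduces the model's published
#' architecture: 10 inputs, 10 receptors, 8 second messengers, 15 kinases
#' and phosphatases, 12 MAPK components, 8 transcription-factor families,
#' 18 mechanotransduction components and 20 ECM outputs, 132 species in
#' all with over 200 edges.
#'
#' @param spec an `ecm_network`.
#' @return A list with `by_module` (named integer vector), `n_species`,
#'   `n_edges`, `n_inputs`, `n_feedback_fields`, `n_ecm_fields`.
#' @export
network_census <- function(spec) {
  by_module <- vapply(SPECIES_MODULES,
                      function(m) sum(spec$species$module == m), 0L)
  list(by_module = by_module,
       n_species = nrow(spec$species),
       n_edges = length(spec$edges),
       n_inputs = length(spec$inputs),
       n_feedback_fields = nrow(spec$feedback_fields),
       n_ecm_fields = nrow(spec$ecm_fields))
}

#' Species reachable through production edges
#'
#' Breadth-first search over the directed graph whose arcs run from each
#' activator of a production edge to the edge's target. Used to check that
#' every ECM precursor is downstream of at least one input.
#'
#' @param spec an `ecm_network`.
#' @param from character vector of start species.
#' @return Character vector of all species reachable from `from`
#'   (including `from` itself).
#' @export
reachable_from <- function(spec, from) {
  adj <- list()
  for (e in spec$edges) {
    if (e$sign != "production") next
    for (a in e$activators) adj[[a]] <- c(adj[[a]], e$target)
  }
  seen <- setNames(rep(FALSE, nrow(spec$species)), spec$species$name)
  queue <- intersect(from, names(seen))
  seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[[w]]) { seen[[w]] <- TRUE; queue <- c(queue, w) }
  }
  names(seen)[seen]
}

#' @export
print.ecm_network <- function(x, ...) {
  cen <- network_census(x)
  cat(sprintf("<ecm_network> %d species, %d edges, %d inputs\n",
              cen$n_species, cen$n_edges, cen$n_inputs))
  cat(sprintf("  feedback fields: %s\n",
              if (cen$n_feedback_fields)
                paste(x$feedback_fields$name, collapse = ", ") else "none"))
  cat(sprintf("  ECM fields: %d\n", cen$n_ecm_fields))
  invisible(x)
}

#' @export
summary.ecm_network <- function(object, ...) {
  cen <- network_census(object)
  print(object)
  cat("Species by module:\n")
  print(cen$by_module[cen$by_module > 0])
  print(object$rates)
  invisible(cen)
}
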