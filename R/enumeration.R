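# Exact reachable-species enumeration (species-level closure of the initial
# mixture under all rule applications) and closed-form combinatorial
# counting of the scaffold-family state space.

#' Enumerate all reachable species of a model
#'
#' Breadth-first closure at the species level: a species is reachable when
#' some sequence of rule applications starting from the species present in
#' the initial mixture produces it, independent of copy numbers.  Every
#' complex observed in any stochastic simulation of the model is contained
#' in this set.
#'
#' @param model a `ps_model`
#' @param max_species cap on the number of species explored; exceeding it
#'   returns the partial set with `overflow = TRUE`
#' @param extra_seeds optional canonical species strings known to be
#'   reachable (e.g. observed in a simulation snapshot) used as additional
#'   starting points; the closure of a reachable set is still reachable
#' @return character vector of canonical species strings with attributes
#'   `overflow` (logical), `scaffold` (logical vector flagging
#'   scaffold-based species) and `rule_fired` (per-rule: did it ever apply)
#' @export
enumerate_species <- function(model, max_species = 10000, extra_seeds = NULL) {
  cm <- ps_compile(model)
  seeds <- list()
  for (entry in model$init) {
    st <- structure_from_pattern(model, entry$pattern)
    comps <- ps_cpp_components(cm, st, structures = TRUE)
    for (s in comps$structure) seeds[[length(seeds) + 1]] <- s
  }
  for (sp in extra_seeds)
    seeds[[length(seeds) + 1]] <- structure_from_pattern(model, sp)
  # the ligand enters the system on stimulation; seed it as well when the
  # model declares a dose
  lig <- attr(model, "ligand")
  if (!is.null(lig))
    seeds[[length(seeds) + 1]] <- structure_from_pattern(model, paste0(lig, "()"))
  res <- ps_cpp_enumerate(cm, seeds, as.integer(max_species))
  out <- as.character(res$species)
  attr(out, "overflow") <- res$overflow
  attr(out, "scaffold") <- as.logical(res$scaffold)
  rf <- as.logical(res$rule_fired)
  names(rf) <- vapply(cm$rules, `[[`, "", "name")
  attr(out, "rule_fired") <- rf
  if (res$overflow)
    warning("species cap reached; the returned set is a lower bound")
  out
}

#' Closed-form count of the scaffold-family state space
#'
#' Counts the distinct molecular structures of complexes built on the
#' scaffold: each scaffold binding site independently carries one of its
#' possible occupant subtrees (counted recursively over the signature's
#' may-bind graph, multiplying internal-state counts), the scaffold's own
#' internal states multiply in, and the homodimer contributes
#' `P * (P + 1) / 2` indistinguishable protomer pairings plus `P` monomer
#' states.  Requires the may-bind graph (away from the scaffold
#' dimerization site) to be acyclic; otherwise the count is not factorizable
#' and an error asks for capped enumeration instead.
#'
#' @param model a `ps_model` with a scaffold type
#' @return a list: `total` (numeric count of scaffold-based structures),
#'   `per_protomer` (occupancy states of one protomer), `monomer`, `dimer`
#' @export
count_scaffold_states <- function(model) {
  if (is.na(model$scaffold)) stop("model declares no scaffold type")
  cm <- ps_compile(model)
  tab <- model_tables(model)
  scaffold <- match(model$scaffold, tab$type_names)
  mb <- cm$may_bind # rows (t1, s1, t2, s2), 1-based
  partners <- function(t, s) {
    hit <- mb[, 1] == t & mb[, 2] == s
    mb[hit, c(3, 4), drop = FALSE]
  }
  nstates_of <- function(t)
    prod(vapply(tab$state_names[[t]], length, 1L))
  # occupant subtree count for type t entered via site s_in
  subtree <- function(t, s_in, path) {
    if (t %in% path)
      stop("may-bind graph is cyclic; the scaffold state space is not ",
           "factorizable - use capped enumeration", call. = FALSE)
    total <- nstates_of(t)
    for (s in seq_along(tab$site_names[[t]])) {
      if (s == s_in) next
      pp <- partners(t, s)
      opts <- 1 # free
      for (r in seq_len(nrow(pp))) {
        if (pp[r, 1] == scaffold) next # do not grow back onto a scaffold
        opts <- opts + subtree(pp[r, 1], pp[r, 2], c(path, t))
      }
      total <- total * opts
    }
    total
  }
  dim_site <- NA_integer_
  per_site <- numeric(0)
  for (s in seq_along(tab$site_names[[scaffold]])) {
    pp <- partners(scaffold, s)
    if (nrow(pp) > 0 && any(pp[, 1] == scaffold)) { dim_site <- s; next }
    opts <- 1
    for (r in seq_len(nrow(pp)))
      opts <- opts + subtree(pp[r, 1], pp[r, 2], scaffold)
    per_site <- c(per_site, opts)
  }
  P <- prod(per_site) * nstates_of(scaffold)
  monomer <- P
  dimer <- if (is.na(dim_site)) 0 else P * (P + 1) / 2
  list(total = monomer + dimer, per_protomer = P,
       monomer = monomer, dimer = dimer)
}
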