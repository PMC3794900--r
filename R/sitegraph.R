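# Site-graph complexes and mixtures.
#
# A mixture is a flat encoding of a multiset of agents: `type` (0-based type
# index per agent), `state` (internal state per site, flattened over agents)
# and `bond` (flat site-slot index of the bound partner, or -1).  Connected
# components of the bond graph are the molecular complexes; their canonical
# strings (exact up to isomorphism) are the interchange key used by every
# analysis module.

new_mixture <- function(type, state, bond) {
  structure(list(type = as.integer(type), state = as.integer(state),
                 bond = as.integer(bond)), class = "ps_mixture")
}

#' @export
print.ps_mixture <- function(x, ...) {
  cat("ps_mixture:", length(x$type), "agents,",
      sum(x$bond >= 0) / 2, "bonds\n")
  invisible(x)
}

# build the concrete structure for one pattern string (unmentioned sites are
# free in their default state); multi-complex patterns allowed
structure_from_pattern <- function(model, pattern) {
  tab <- model_tables(model)
  pp <- parse_pattern_text(pattern)
  n <- length(pp)
  types <- integer(n)
  nst <- lapply(model$agents, function(a)
    vapply(a$sites, function(s) max(1L, length(s$states)), 1L))
  for (i in seq_len(n)) {
    t <- match(pp[[i]]$type, tab$type_names)
    if (is.na(t)) stop("undeclared agent type '", pp[[i]]$type, "'", call. = FALSE)
    types[i] <- t
  }
  off <- c(0L, cumsum(vapply(types, function(t) length(tab$site_names[[t]]), 1L)))
  state <- integer(off[n + 1])
  bond <- rep(-1L, off[n + 1])
  labs <- list()
  for (i in seq_len(n)) {
    t <- types[i]
    for (sn in names(pp[[i]]$sites)) {
      s <- match(sn, tab$site_names[[t]])
      if (is.na(s)) stop("agent '", pp[[i]]$type, "' has no site '", sn, "'", call. = FALSE)
      info <- pp[[i]]$sites[[sn]]
      if (!is.na(info$state)) {
        v <- match(info$state, tab$state_names[[t]][[s]])
        if (is.na(v)) stop("'", pp[[i]]$type, ".", sn, "' has no state '", info$state, "'",
                           call. = FALSE)
        state[off[i] + s] <- v - 1L
      }
      if (info$bond$kind == "label") {
        key <- as.character(info$bond$label)
        labs[[key]] <- c(labs[[key]] %||% integer(0), off[i] + s - 1L)
      } else if (info$bond$kind != "free")
        stop("initial/concrete patterns cannot contain bond wildcards", call. = FALSE)
    }
  }
  for (key in names(labs)) {
    e <- labs[[key]]
    if (length(e) != 2) stop("bond label ", key, " must appear exactly twice", call. = FALSE)
    bond[e[1] + 1] <- e[2]
    bond[e[2] + 1] <- e[1]
  }
  new_mixture(types - 1L, state, bond)
}

#' Build the initial mixture declared by a model
#'
#' @param model a `ps_model`
#' @return a `ps_mixture` holding all `%init` declarations
#' @export
make_mixture <- function(model) {
  type <- integer(0); state <- integer(0); bond <- integer(0)
  for (entry in model$init) {
    s <- structure_from_pattern(model, entry$pattern)
    k <- entry$copies
    if (k < 0) stop("init copies must be >= 0", call. = FALSE)
    if (k == 0) next
    ns <- length(s$state)
    boff <- rep(length(state) + (seq_len(k) - 1) * ns, each = ns)
    bnd <- rep(s$bond, k)
    free <- bnd < 0
    bnd <- bnd + boff
    bnd[free] <- -1L
    type <- c(type, rep(s$type, k))
    state <- c(state, rep(s$state, k))
    bond <- c(bond, bnd)
  }
  new_mixture(type, state, bond)
}

#' Add free agents of one type to a mixture
#'
#' Used for instantaneous ligand (pheromone) addition: `n` monomeric agents
#' in their default states are appended.
#'
#' @param model a `ps_model`
#' @param mixture a `ps_mixture`
#' @param type agent type name
#' @param n number of copies
#' @return the extended mixture
#' @export
add_agents <- function(model, mixture, type, n) {
  tab <- model_tables(model)
  t <- match(type, tab$type_names)
  if (is.na(t)) stop("unknown agent type '", type, "'", call. = FALSE)
  if (n == 0) return(mixture)
  k <- length(tab$site_names[[t]])
  new_mixture(c(mixture$type, rep(t - 1L, n)),
              c(mixture$state, integer(n * k)),
              c(mixture$bond, rep(-1L, n * k)))
}

#' Canonical string of one connected complex
#'
#' Two complexes receive equal strings exactly when they are isomorphic as
#' site graphs (same agent types, bond topology and internal states); the
#' string is invariant under any permutation of the agent list.  Sites in
#' their default state and unbound are omitted, so the string parses back
#' via [species_structure()].
#'
#' @param model a `ps_model`
#' @param complex a `ps_mixture` holding exactly one connected complex
#' @return canonical string
#' @export
canonical_form <- function(model, complex) {
  ps_cpp_canonical(ps_compile(model), complex)
}

#' Are two complexes isomorphic?
#' @param model a `ps_model`
#' @param a,b single-complex mixtures
#' @return logical
#' @export
is_isomorphic <- function(model, a, b) {
  identical(canonical_form(model, a), canonical_form(model, b))
}

#' Unique complexes of a mixture
#'
#' Partitions the mixture into connected complexes and aggregates them by
#' canonical string.
#'
#' @param model a `ps_model`
#' @param mixture a `ps_mixture`
#' @param structures also return one representative structure per species
#' @return data.frame with columns `species` (canonical string), `copies`,
#'   `size` (agents per copy) and `scaffold` (TRUE for scaffold-based
#'   species: contains the scaffold or could bind a free one); when
#'   `structures` is TRUE a list column `structure` of `ps_mixture`
#' @export
mixture_components <- function(model, mixture, structures = FALSE) {
  res <- ps_cpp_components(ps_compile(model), mixture, structures)
  out <- data.frame(species = as.character(res$species),
                    copies = res$copies, size = res$size,
                    scaffold = res$scaffold, stringsAsFactors = FALSE)
  if (structures)
    out$structure <- lapply(res$structure, function(s)
      structure(s, class = "ps_mixture"))
  out
}

#' Rebuild the structure of a species from its canonical string
#'
#' Canonical strings omit free sites in default states, so they are valid
#' concrete patterns in the rule dialect and can be parsed back into a
#' single-complex mixture.
#'
#' @param model a `ps_model`
#' @param species canonical string (or vector thereof)
#' @return a `ps_mixture` (or list of them)
#' @export
species_structure <- function(model, species) {
  if (length(species) == 1) return(structure_from_pattern(model, species))
  lapply(species, structure_from_pattern, model = model)
}

#' Count agents of each type in a species string
#' @param model a `ps_model`
#' @param species character vector of canonical strings
#' @return integer matrix, rows = species, columns = agent types
#' @export
species_agent_counts <- function(model, species) {
  tn <- names(model$agents)
  out <- matrix(0L, length(species), length(tn), dimnames = list(NULL, tn))
  for (i in seq_along(species)) {
    ag <- vapply(parse_pattern_text(species[i]), `[[`, "", "type")
    tt <- table(factor(ag, levels = tn))
    out[i, ] <- as.integer(tt)
  }
  out
}

# ------------------------------------------------------------ snapshot IO --

#' Write a snapshot series to JSON-lines
#'
#' One record per time point: `{"time": t, "species": [[canonical, copies],
#' ...]}`.  Canonical strings are the interchange key across modules.
#'
#' @param series a `ps_series` (see [run_simulation()])
#' @param file output path
#' @export
write_snapshots <- function(series, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(series$times)) {
    df <- series$species[[i]]
    rec <- list(time = series$times[i],
                species = lapply(seq_len(nrow(df)), function(j)
                  list(df$species[j], df$copies[j])))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(file)
}

#' Read a JSON-lines snapshot series
#' @param file path written by [write_snapshots()]
#' @return list with `times` and `species` (data.frames)
#' @export
read_snapshots <- function(file) {
  lines <- readLines(file)
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
  times <- vapply(recs, function(r) as.numeric(r$time), 1)
  species <- lapply(recs, function(r)
    data.frame(species = vapply(r$species, function(s) as.character(s[[1]]), ""),
               copies = vapply(r$species, function(s) as.integer(s[[2]]), 1L),
               stringsAsFactors = FALSE))
  list(times = times, species = species)
}
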