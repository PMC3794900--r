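# Network-free stochastic simulation (Gillespie direct method over rule
# activities) with the replicate-branching protocol: cells are
# pre-equilibrated without ligand, pheromone is added instantaneously, and
# independent branches continue from the identical steady state, recording
# complexes at log-spaced snapshot times.

#' Simulation protocol
#'
#' @param pre_eq_time seconds of ligand-free pre-equilibration (default 1000)
#' @param post_time seconds simulated after pheromone addition (default 3600)
#' @param dose pheromone copies added at t = 0; `NULL` uses the model's
#'   builder default stored in `attr(model, "dose")`
#' @param n_parents number of independently equilibrated "cells" (N)
#' @param n_branches replicate branches per cell from its exact steady
#'   state (N')
#' @param snap_times snapshot times (seconds after stimulation); default
#'   t = 0 plus 30 log-spaced points from 1 s to `post_time`
#' @param control also simulate ligand-free control branches
#' @return a `ps_protocol` list
#' @export
make_protocol <- function(pre_eq_time = 1000, post_time = 3600, dose = NULL,
                          n_parents = 1, n_branches = 10,
                          snap_times = NULL, control = FALSE) {
  if (is.null(snap_times))
    snap_times <- c(0, logspace(1, post_time, 30))
  snap_times <- sort(snap_times)
  if (any(diff(snap_times) <= 0)) stop("snapshot times must strictly increase")
  if (n_parents < 1 || n_branches < 1) stop("n_parents and n_branches must be >= 1")
  structure(list(pre_eq_time = pre_eq_time, post_time = post_time, dose = dose,
                 n_parents = as.integer(n_parents),
                 n_branches = as.integer(n_branches),
                 snap_times = snap_times, control = control),
            class = "ps_protocol")
}

snapshots_to_series <- function(res, parent, branch, condition) {
  snaps <- lapply(res$snapshots, function(s) {
    if (is.null(s)) return(NULL) # species recording disabled
    data.frame(species = as.character(s$species), copies = s$copies,
               size = s$size, scaffold = s$scaffold, stringsAsFactors = FALSE)
  })
  obs <- as.data.frame(res$obs)
  obs$time <- as.numeric(res$snap_times)
  structure(list(parent = parent, branch = branch, condition = condition,
                 times = as.numeric(res$snap_times), species = snaps,
                 obs = obs, events = res$events), class = "ps_series")
}

#' @export
print.ps_series <- function(x, ...) {
  cat(sprintf("ps_series (parent %s, branch %s, %s): %d snapshots, %g events\n",
              x$parent, x$branch, x$condition, length(x$times), x$events))
  invisible(x)
}

pre_equilibrate <- function(model, protocol, seed) {
  cm <- ps_compile(model)
  mix <- make_mixture(model)
  res <- ps_cpp_ssa(cm, mix, 0, protocol$pre_eq_time, numeric(0), seed)
  structure(res$state, class = "ps_mixture")
}

run_branch <- function(model, state, protocol, seed, stimulate = TRUE,
                       record_species = TRUE) {
  cm <- ps_compile(model)
  if (stimulate) {
    dose <- protocol$dose %||% attr(model, "dose") %||% 0
    if (dose > 0)
      state <- add_agents(model, state, attr(model, "ligand") %||% "Pher", dose)
  }
  ps_cpp_ssa(cm, state, 0, protocol$post_time, protocol$snap_times, seed,
             FALSE, 5e8, record_species)
}

#' Run one simulation under the branching protocol
#'
#' Pre-equilibrates a single cell without pheromone, adds the ligand dose
#' and records snapshots on the protocol grid.  Identical (model, protocol,
#' seed) triples give identical output.
#'
#' @param model a `ps_model`
#' @param protocol a `ps_protocol`
#' @param seed integer seed
#' @param stimulate add pheromone (`FALSE` for the control condition)
#' @return a `ps_series`: snapshot data.frames (`species`, `copies`, `size`,
#'   `scaffold`) per time plus the observable time series in `$obs`
#' @export
run_simulation <- function(model, protocol, seed, stimulate = TRUE) {
  st <- pre_equilibrate(model, protocol, derive_seed(seed, 0, 0))
  res <- run_branch(model, st, protocol, derive_seed(seed, 1, 1), stimulate)
  snapshots_to_series(res, parent = 1L, branch = 1L,
                      condition = if (stimulate) "pheromone" else "control")
}

#' Simulate a branching population of cells
#'
#' Runs `n_parents` independent pre-equilibrations; from each steady state
#' starts `n_branches` independent stimulated trajectories (and, when the
#' protocol requests it, ligand-free control branches).  All branches of a
#' parent share its exact pre-stimulation state, so between-branch drift is
#' 0 at t = 0.  Branch seeds are derived from the master seed per
#' (parent, branch, condition), so streams are independent and the whole
#' population is reproducible.
#'
#' @param model a `ps_model`
#' @param protocol a `ps_protocol`
#' @param seed master integer seed
#' @return list of `ps_series` with attributes recording the protocol/seed
#' @export
branch_population <- function(model, protocol, seed, record_species = TRUE) {
  out <- list()
  for (p in seq_len(protocol$n_parents)) {
    st <- pre_equilibrate(model, protocol, derive_seed(seed, p, 0))
    for (b in seq_len(protocol$n_branches)) {
      res <- run_branch(model, st, protocol, derive_seed(seed, p, b), TRUE,
                        record_species)
      out[[length(out) + 1]] <- snapshots_to_series(res, p, b, "pheromone")
      if (isTRUE(protocol$control)) {
        res0 <- run_branch(model, st, protocol, derive_seed(seed, p, 1000 + b),
                           FALSE, record_species)
        out[[length(out) + 1]] <- snapshots_to_series(res0, p, b, "control")
      }
    }
  }
  attr(out, "protocol") <- protocol
  attr(out, "seed") <- seed
  out
}

#' Mean observable time course across series
#' @param series list of `ps_series`
#' @param obs observable name
#' @param condition condition filter ("pheromone"/"control"/NULL for all)
#' @return data.frame (time, mean, sd, n)
#' @export
observable_timecourse <- function(series, obs = "Fus3pp", condition = "pheromone") {
  keep <- if (is.null(condition)) series
  else Filter(function(s) s$condition == condition, series)
  times <- keep[[1]]$times
  m <- sapply(keep, function(s) s$obs[[obs]])
  if (is.null(dim(m))) m <- matrix(m, ncol = length(keep))
  data.frame(time = times, mean = rowMeans(m),
             sd = apply(m, 1, sd), n = length(keep))
}

#' Detect the peak-signaling snapshot time
#'
#' The empirical peak of the mean observable (doubly phosphorylated Fus3 by
#' default) over the post-stimulation snapshot grid; ties resolve to the
#' earliest time, and t = 0 is excluded.
#'
#' @param series list of `ps_series`
#' @param obs observable name
#' @return the snapshot time (seconds) of the maximum
#' @export
detect_peak_time <- function(series, obs = "Fus3pp") {
  tc <- observable_timecourse(series, obs, condition = "pheromone")
  tc <- tc[tc$time > 0, ]
  tc$time[which.max(tc$mean)]
}
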