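# Reproducible experiment drivers wiring the modules into the package's
# headline analyses: the drift time course, autodrift with dense lags, the
# randomized-parameter robustness sweeps, the cumulative-species curve and
# the scaffold-overexpression (combinatorial inhibition) comparison.

#' Drift time course under pheromone and control conditions
#'
#' Simulates a branching population with and without ligand and computes
#' pairwise drift at every snapshot time for both conditions.
#'
#' @param model a `ps_model`
#' @param protocol a `ps_protocol` (forced to `control = TRUE`)
#' @param seed master seed
#' @param filter `"all"` or `"scaffold"` species
#' @return list: `table` (per-pair drift rows), `summary` (mean drift per
#'   time and condition), `peak_time` (detected Fus3pp peak), `series`
#' @export
run_drift_timecourse <- function(model, protocol, seed,
                                 filter = c("all", "scaffold")) {
  filter <- match.arg(filter)
  protocol$control <- TRUE
  series <- branch_population(model, protocol, seed)
  tab <- NULL
  for (cond in c("pheromone", "control"))
    for (tm in protocol$snap_times)
      tab <- rbind(tab, pairwise_drift(series, tm, filter, cond))
  summ <- aggregate(drift ~ time + condition, tab, mean)
  list(table = tab, summary = summ,
       peak_time = detect_peak_time(series), series = series)
}

#' Scaffold overexpression and combinatorial inhibition
#'
#' Simulates the model at several Ste5 expression factors and reports the
#' peak of the mean Fus3pp time course per factor together with the
#' relative changes `dFus3pp(b-a) = (peak_b - peak_a) / peak_a` for
#' consecutive factor pairs.  A zero reference peak flags the delta as `NA`.
#'
#' @param model a `ps_model` (wild-type scaffold level)
#' @param protocol a `ps_protocol`
#' @param seed master seed
#' @param factors scaffold expression factors (default 1, 12, 60)
#' @return list: `peaks` data.frame (factor, peak, peak_time), `deltas`
#'   data.frame (from, to, dFus3pp)
#' @export
run_overexpression <- function(model, protocol, seed, factors = c(1, 12, 60)) {
  peaks <- data.frame(factor = factors, peak = NA_real_, peak_time = NA_real_)
  for (i in seq_along(factors)) {
    m <- if (factors[i] == 1) model else overexpress_ste5(model, factors[i])
    series <- branch_population(m, protocol,
                                derive_seed(seed, 7000, round(1000 * factors[i])),
                                record_species = FALSE)
    tc <- observable_timecourse(series, "Fus3pp")
    tc <- tc[tc$time > 0, ]
    peaks$peak[i] <- max(tc$mean)
    peaks$peak_time[i] <- tc$time[which.max(tc$mean)]
  }
  deltas <- NULL
  for (i in seq_len(length(factors) - 1)) {
    ref <- peaks$peak[i]
    deltas <- rbind(deltas, data.frame(
      from = factors[i], to = factors[i + 1],
      dFus3pp = if (ref > 0) (peaks$peak[i + 1] - ref) / ref else NA_real_))
  }
  list(peaks = peaks, deltas = deltas)
}

#' Robustness sweeps over randomized rate parameters
#'
#' Generates `n_models` variants of `model` with log-uniform randomized
#' rates and measures, per variant, either the mean pairwise scaffold drift
#' at that variant's detected signaling peak (`what = "drift"`) or the
#' relative change in peak Fus3pp between 12x and 60x scaffold
#' overexpression (`what = "overexpression"`).
#'
#' @param model baseline `ps_model`
#' @param n_models number of randomized variants (0 returns empty tables)
#' @param protocol a `ps_protocol` (its `n_branches` replicates per model)
#' @param seed master seed
#' @param what sweep type
#' @return data.frame with one row per model: `model`, and `mean_drift`
#'   plus `drift_values` (list column of pair values), or `dFus3pp`
#' @export
run_randomized_sweep <- function(model, n_models, protocol, seed,
                                 what = c("drift", "overexpression")) {
  what <- match.arg(what)
  if (n_models == 0)
    return(data.frame(model = integer(0), mean_drift = numeric(0),
                      dFus3pp = numeric(0)))
  out <- NULL
  for (k in seq_len(n_models)) {
    mk <- randomize_parameters(model, derive_seed(seed, 9000, k))
    if (what == "drift") {
      series <- branch_population(mk, protocol, derive_seed(seed, 9100, k))
      pk <- detect_peak_time(series)
      pd <- pairwise_drift(series, pk, "scaffold")
      out <- rbind(out, data.frame(model = k, peak_time = pk,
                                   mean_drift = mean(pd$drift),
                                   min_drift = min(pd$drift),
                                   n_pairs = nrow(pd)))
      attr(out, "drift_values") <- c(attr(out, "drift_values"), list(pd$drift))
    } else {
      ox <- run_overexpression(mk, protocol, derive_seed(seed, 9200, k),
                               factors = c(12, 60))
      out <- rbind(out, data.frame(model = k,
                                   peak12 = ox$peaks$peak[1],
                                   peak60 = ox$peaks$peak[2],
                                   dFus3pp = ox$deltas$dFus3pp[1]))
    }
  }
  out
}

#' Cumulative unique scaffold species over independent simulations
#'
#' Runs `n_sims` independently equilibrated, stimulated cells and reports
#' the cumulative number of unique scaffold-based species observed across
#' the first k cells, k = 1..n_sims (union over all snapshot times).
#'
#' @param model a `ps_model`
#' @param protocol a `ps_protocol`
#' @param seed master seed
#' @param n_sims number of independent cells
#' @return list: `curve` data.frame (k, cumulative), `species` (the final
#'   union of scaffold species)
#' @export
run_cumulative_species <- function(model, protocol, seed, n_sims = 10) {
  p1 <- protocol
  p1$n_parents <- 1L; p1$n_branches <- 1L; p1$control <- FALSE
  acc <- character(0)
  curve <- data.frame(k = seq_len(n_sims), cumulative = NA_real_)
  for (k in seq_len(n_sims)) {
    series <- branch_population(model, p1, derive_seed(seed, 8000, k))[[1]]
    sp <- unique(unlist(lapply(series$species, scaffold_species)))
    acc <- union(acc, sp)
    curve$cumulative[k] <- length(acc)
  }
  list(curve = curve, species = acc)
}

#' Autodrift experiment with dense lags from the signaling peak
#'
#' For each replicate cell, simulates to the reference time `t0` (the
#' detected peak of a pilot population when not given) and records dense
#' snapshots at `t0 + deltas`, yielding autodrift curves d(t0, t0 + delta).
#'
#' @param model a `ps_model`
#' @param protocol a `ps_protocol` (its pre-equilibration and dose apply)
#' @param seed master seed
#' @param deltas lags in seconds (default 24 log-spaced points 0.01..30 s)
#' @param n_replicates independent cells (default 10)
#' @param t0 reference time; `NULL` detects the Fus3pp peak from a pilot
#'   run with the protocol's branch count
#' @param filter species filter
#' @return list: `table` (replicate, delta, drift), `t0`
#' @export
run_autodrift <- function(model, protocol, seed,
                          deltas = logspace(0.01, 30, 24),
                          n_replicates = 10, t0 = NULL,
                          filter = c("all", "scaffold")) {
  filter <- match.arg(filter)
  if (is.null(t0)) {
    pilot <- branch_population(model, protocol, derive_seed(seed, 6000, 0))
    t0 <- detect_peak_time(pilot)
  }
  cm <- ps_compile(model)
  tab <- NULL
  for (r in seq_len(n_replicates)) {
    st <- pre_equilibrate(model, protocol, derive_seed(seed, 6100, r))
    dose <- protocol$dose %||% attr(model, "dose")
    st <- add_agents(model, st, attr(model, "ligand") %||% "Pher", dose)
    res <- ps_cpp_ssa(cm, st, 0, t0 + max(deltas), c(t0, t0 + deltas),
                      derive_seed(seed, 6200, r))
    series <- snapshots_to_series(res, r, 1L, "pheromone")
    ad <- autodrift(series, t0, deltas, filter)
    tab <- rbind(tab, cbind(replicate = r, ad))
  }
  list(table = tab, t0 = t0)
}
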