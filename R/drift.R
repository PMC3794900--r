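# Compositional drift: the Jaccard distance between the sets of unique
# complexes present in two simulated cells.  d = |A delta B| / |A union B|
# is the probability that a complex found in one cell is absent from the
# other; d = 0 for identical sets, d = 1 for disjoint ones.

#' Jaccard compositional drift between two complex sets
#'
#' @param a,b character vectors of canonical species strings (set semantics;
#'   copy numbers are ignored)
#' @return drift in `[0, 1]`; two empty sets have drift 0 by convention
#' @export
drift <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0) return(0)
  length(u) - length(intersect(a, b))
  (length(u) - length(intersect(a, b))) / length(u)
}

# complex set of one series at one snapshot time, optionally filtered
complex_set <- function(series, time, filter = c("all", "scaffold")) {
  filter <- match.arg(filter)
  i <- match(TRUE, abs(series$times - time) < 1e-9)
  if (is.na(i))
    stop("time ", time, " is not a snapshot time of this series (no interpolation)")
  df <- series$species[[i]]
  if (filter == "scaffold") df <- df[df$scaffold, ]
  unique(df$species)
}

#' Pairwise drift between replicate branches at one snapshot time
#'
#' Drift is computed for every unordered pair of branches that share a
#' parent cell (N' branches give choose(N', 2) pairs per parent).
#'
#' @param series list of `ps_series` (one condition)
#' @param time snapshot time (must be on the grid; no interpolation)
#' @param filter `"all"` complexes or `"scaffold"`-based species only
#' @param condition condition to restrict to (default "pheromone")
#' @return data.frame (time, parent, branch_i, branch_j, drift, condition,
#'   filter)
#' @export
pairwise_drift <- function(series, time, filter = c("all", "scaffold"),
                           condition = "pheromone") {
  filter <- match.arg(filter)
  keep <- Filter(function(s) s$condition == condition, series)
  if (length(keep) == 0) stop("no series in condition ", condition)
  out <- NULL
  for (par in unique(unlist(lapply(keep, `[[`, "parent")))) {
    grp <- Filter(function(s) s$parent == par, keep)
    sets <- lapply(grp, complex_set, time = time, filter = filter)
    n <- length(grp)
    if (n < 2) next
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      out <- rbind(out, data.frame(
        time = time, parent = par,
        branch_i = grp[[i]]$branch, branch_j = grp[[j]]$branch,
        drift = drift(sets[[i]], sets[[j]]),
        condition = condition, filter = filter, stringsAsFactors = FALSE))
  }
  out
}

#' Drift over unions of complexes across time points
#'
#' Compares two branches using the union of all unique complexes each
#' sampled across the given snapshot times, asking whether cells that differ
#' at each instant nevertheless visit the same overall repertoire.
#'
#' @param series_a,series_b two `ps_series` sharing a snapshot grid
#' @param times snapshot times to pool (default: all shared times)
#' @param filter species filter as in [pairwise_drift()]
#' @return drift value in `[0, 1]`
#' @export
union_drift <- function(series_a, series_b, times = NULL,
                        filter = c("all", "scaffold")) {
  filter <- match.arg(filter)
  times <- times %||% intersect(series_a$times, series_b$times)
  ua <- unique(unlist(lapply(times, complex_set, series = series_a, filter = filter)))
  ub <- unique(unlist(lapply(times, complex_set, series = series_b, filter = filter)))
  drift(ua, ub)
}

#' Autodrift: drift of one cell against its own past
#'
#' `d_i(t0, t0 + delta)` for each requested lag, measuring how fast the
#' complex repertoire of a single simulation turns over.
#'
#' @param series a `ps_series` whose snapshot grid covers `t0 + deltas`
#' @param t0 reference time (typically the detected signaling peak)
#' @param deltas numeric lags (seconds); each `t0 + delta` must be a
#'   snapshot time
#' @param filter species filter
#' @return data.frame (delta, drift)
#' @export
autodrift <- function(series, t0, deltas, filter = c("all", "scaffold")) {
  filter <- match.arg(filter)
  ref <- complex_set(series, t0, filter)
  data.frame(delta = deltas,
             drift = vapply(deltas, function(d)
               drift(ref, complex_set(series, t0 + d, filter)), 1))
}

#' Fit a saturating double exponential to autodrift curves
#'
#' Fits `d(delta) = A1 (1 - exp(-delta/tau1)) + A2 (1 - exp(-delta/tau2))`
#' by nonlinear least squares (Levenberg-Marquardt), reporting the two
#' amplitudes and timescales with `tau1 <= tau2`.  If the two-timescale fit
#' fails to converge, a single-exponential fallback is returned with
#' `fallback = TRUE`.
#'
#' @param table data.frame with columns `delta` and `drift` (pooled over
#'   replicates)
#' @return list with `A1`, `tau1`, `A2`, `tau2`, `sigma` (residual sd),
#'   `fallback`, and the fit object
#' @export
fit_autodrift <- function(table) {
  stopifnot(all(c("delta", "drift") %in% names(table)))
  tab <- table[order(table$delta), ]
  dmax <- max(tab$drift)
  t_half <- tab$delta[match(TRUE, tab$drift >= dmax / 2)] %||% median(tab$delta)
  starts <- list(A1 = dmax * 0.6, tau1 = max(t_half / 2, 1e-3),
                 A2 = dmax * 0.4, tau2 = max(t_half * 4, 1e-2))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      drift ~ A1 * (1 - exp(-delta / tau1)) + A2 * (1 - exp(-delta / tau2)),
      data = tab, start = starts,
      lower = c(0, 1e-6, 0, 1e-6), upper = c(1, 1e4, 1, 1e4),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit1 <- minpack.lm::nlsLM(drift ~ A * (1 - exp(-delta / tau)),
                              data = tab,
                              start = list(A = dmax, tau = t_half),
                              lower = c(0, 1e-6), upper = c(1, 1e4))
    cf <- coef(fit1)
    return(list(A1 = unname(cf["A"]), tau1 = unname(cf["tau"]),
                A2 = 0, tau2 = unname(cf["tau"]),
                sigma = sd(resid(fit1)), fallback = TRUE, fit = fit1))
  }
  cf <- coef(fit)
  o <- if (cf["tau1"] <= cf["tau2"]) c(1, 2) else c(2, 1)
  list(A1 = unname(cf[paste0("A", o[1])]), tau1 = unname(cf[paste0("tau", o[1])]),
       A2 = unname(cf[paste0("A", o[2])]), tau2 = unname(cf[paste0("tau", o[2])]),
       sigma = sd(resid(fit)), fallback = FALSE, fit = fit)
}

#' Permutation test for a difference of means
#'
#' @param x,y numeric samples
#' @param n_perm number of label permutations
#' @param seed integer seed
#' @return list with `observed` (mean(x) - mean(y)) and two-sided `p`
#' @export
permutation_test <- function(x, y, n_perm = 10000, seed = 1) {
  obs <- mean(x) - mean(y)
  pool <- c(x, y)
  nx <- length(x)
  stats <- with_seed(seed, replicate(n_perm, {
    idx <- sample.int(length(pool), nx)
    mean(pool[idx]) - mean(pool[-idx])
  }))
  p <- (1 + sum(abs(stats) >= abs(obs))) / (n_perm + 1)
  list(observed = obs, p = p)
}
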