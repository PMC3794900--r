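# In-silico TAP/MS: every snapshot is one purification experiment in which
# each protein type serves as bait once; every complex containing the bait
# type retrieves the other protein types in that complex as prey ("spoke"
# counts), and prey pairs co-retrieved under one bait accumulate "matrix"
# counts.  Socio-affinity scores combine the log-odds of these counts
# against a random-assortment null, and MCL on the score matrix yields
# predicted "complexes" (functional modules).

#' Extract bait-prey association counts from snapshot series
#'
#' @param model a `ps_model`
#' @param series list of `ps_series`
#' @param times snapshot times to use as experiments (default: all)
#' @param weight_by_copies weight each complex by its copy number (TRUE,
#'   emulating purification yields proportional to abundance); FALSE counts
#'   each unique complex once
#' @return a `ps_baitprey` list: `spoke` (bait x prey matrix), `matrix`
#'   (symmetric prey-pair matrix), `purifications` (per-bait experiment
#'   count), `types`
#' @export
extract_bait_prey <- function(model, series, times = NULL,
                              weight_by_copies = TRUE) {
  types <- names(model$agents)
  nt <- length(types)
  spoke <- matrix(0, nt, nt, dimnames = list(bait = types, prey = types))
  mat <- matrix(0, nt, nt, dimnames = list(types, types))
  # spoke and matrix counts are additive over experiments, so aggregate each
  # species' total weight across all snapshots first
  wtot <- new.env(parent = emptyenv())
  n_experiments <- 0L
  for (s in series) {
    use <- times %||% s$times
    for (tm in use) {
      i <- match(TRUE, abs(s$times - tm) < 1e-9)
      if (is.na(i)) next
      n_experiments <- n_experiments + 1L
      df <- s$species[[i]]
      w <- if (weight_by_copies) df$copies else rep(1L, nrow(df))
      for (r in seq_len(nrow(df))) {
        key <- df$species[r]
        wtot[[key]] <- (wtot[[key]] %||% 0) + w[r]
      }
    }
  }
  sp_names <- ls(wtot)
  counts <- species_agent_counts(model, sp_names)
  for (r in seq_along(sp_names)) {
    wr <- wtot[[sp_names[r]]]
    pres <- which(counts[r, ] > 0)
    if (length(pres) < 2) next
    for (b in pres) {
      prey <- setdiff(pres, b)
      spoke[b, prey] <- spoke[b, prey] + wr
      if (length(prey) >= 2) {
        pp <- t(combn(prey, 2))
        for (q in seq_len(nrow(pp))) {
          mat[pp[q, 1], pp[q, 2]] <- mat[pp[q, 1], pp[q, 2]] + wr
          mat[pp[q, 2], pp[q, 1]] <- mat[pp[q, 2], pp[q, 1]] + wr
        }
      }
    }
  }
  purif <- setNames(rep(as.numeric(n_experiments), nt), types)
  structure(list(spoke = spoke, matrix = mat, purifications = purif,
                 types = types), class = "ps_baitprey")
}

#' Socio-affinity scores from bait-prey counts
#'
#' For each protein pair (i, j) the score sums three log-odds terms, each
#' comparing an observed count with its expectation under random assortment
#' of prey across purifications: the spoke term with i as bait retrieving j,
#' the reciprocal spoke term, and the matrix term for co-retrieval of i and
#' j under any third bait.  Expectations come from the count marginals:
#' E[spoke(i,j)] = rowsum_i * colsum_j / total, and likewise for the matrix
#' counts.  Terms whose observed or expected count is zero are skipped and
#' flagged; pairs with no usable term are `NA` (flagged undefined).
#'
#' @param counts a `ps_baitprey`
#' @return a `ps_samatrix`: symmetric numeric matrix `sa` plus a `defined`
#'   logical matrix
#' @export
socio_affinity <- function(counts) {
  sp <- counts$spoke
  mt <- counts$matrix
  types <- counts$types
  nt <- length(types)
  logodds <- function(obs, exp) {
    if (is.na(obs) || is.na(exp) || obs <= 0 || exp <= 0) return(NA_real_)
    log(obs / exp)
  }
  e_sp <- outer(rowSums(sp), colSums(sp)) / max(sum(sp), 1)
  e_mt <- outer(rowSums(mt), colSums(mt)) / max(sum(mt), 1)
  sa <- matrix(NA_real_, nt, nt, dimnames = list(types, types))
  defined <- matrix(FALSE, nt, nt, dimnames = list(types, types))
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (i == j) next
    terms <- c(logodds(sp[i, j], e_sp[i, j]),
               logodds(sp[j, i], e_sp[j, i]),
               logodds(mt[i, j], e_mt[i, j]))
    if (all(is.na(terms))) next
    sa[i, j] <- sum(terms, na.rm = TRUE)
    defined[i, j] <- TRUE
  }
  # exact symmetry: average the (already symmetric up to float noise) halves
  sa <- (sa + t(sa)) / 2
  structure(list(sa = sa, defined = defined & t(defined), types = types),
            class = "ps_samatrix")
}

#' Markov clustering (MCL) of a similarity matrix
#'
#' Standard MCL: column-normalize the similarity matrix (with self-loops),
#' then alternate expansion (matrix squaring) and inflation (entrywise
#' power + renormalization) until (near-)idempotency; clusters are the
#' connected components of attractor support.
#'
#' @param sim a `ps_samatrix`, or a non-negative similarity matrix; SA
#'   scores are clipped at zero and unit self-loops added
#' @param inflation inflation exponent (> 1, default 2)
#' @param max_iter iteration cap; non-convergence returns the current
#'   best-effort partition with a warning
#' @param tol convergence tolerance on the max entry change
#' @return a `ps_partition` over the protein types (clusters as `members`
#'   index lists; `assign` per type)
#' @export
mcl_cluster <- function(sim, inflation = 2, max_iter = 200, tol = 1e-8) {
  if (inherits(sim, "ps_samatrix")) {
    M <- pmax(sim$sa, 0)
    M[is.na(M)] <- 0
    diag(M) <- 1
    labels <- sim$types
  } else {
    M <- as.matrix(sim)
    labels <- rownames(M) %||% as.character(seq_len(nrow(M)))
    if (any(M < 0)) stop("similarities must be non-negative")
    if (all(diag(M) == 0)) diag(M) <- 1
  }
  if (inflation <= 1) stop("inflation must exceed 1")
  norm <- function(X) sweep(X, 2, pmax(colSums(X), .Machine$double.eps), "/")
  M <- norm(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- norm(norm(M %*% M)^inflation)
    if (max(abs(M2 - M)) < tol) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  if (!converged) warning("MCL did not converge; returning best-effort partition")
  n <- nrow(M)
  # attractor-based interpretation: nodes sharing support in any row of an
  # attractor (row with positive diagonal) belong to one cluster
  adj <- matrix(FALSE, n, n)
  thr <- 1e-6
  for (i in seq_len(n)) if (M[i, i] > thr) {
    memb <- which(M[i, ] > thr)
    adj[memb, memb] <- TRUE
  }
  diag(adj) <- TRUE
  assign <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (assign[i] > 0) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (assign[u] > 0) next
      assign[u] <- cid
      queue <- c(queue, which(adj[u, ] & assign == 0))
    }
  }
  members <- lapply(seq_len(cid), function(c) which(assign == c))
  structure(list(assign = assign, members = members, species = labels,
                 clustroid = vapply(members, `[[`, 1L, 1),
                 cutoff = cid, mbcd = numeric(0)),
            class = "ps_partition")
}

#' Adjusted-for-chance-free Rand index between two partitions
#'
#' Fraction of element pairs on which two partitions agree (same/different
#' cluster).
#'
#' @param a,b partitions (`ps_partition` or integer assignment vectors over
#'   the same elements)
#' @return Rand index in `[0, 1]`
#' @export
rand_index <- function(a, b) {
  av <- if (inherits(a, "ps_partition")) a$assign else a
  bv <- if (inherits(b, "ps_partition")) b$assign else b
  stopifnot(length(av) == length(bv))
  n <- length(av)
  agree <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    agree <- agree + ((av[i] == av[j]) == (bv[i] == bv[j]))
  agree / choose(n, 2)
}
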