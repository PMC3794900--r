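# Structural analysis of scaffold-based species: pattern-conservation
# frequencies, a fixed-length vector encoding of the scaffold family, graph
# edit distance as Hamming distance on that encoding, and clustroid-based
# hierarchical clustering with conserved-pattern sizing.

#' Scaffold-based species of a snapshot
#'
#' Scaffold-based species are complexes that contain the scaffold (Ste5) or
#' that could bind a free scaffold (carry a free site whose signature may
#' bind a Ste5 site).  Snapshot data.frames already carry this flag; this
#' helper extracts the unique species strings.
#'
#' @param snapshot a snapshot data.frame (one element of `series$species`)
#' @return character vector of canonical species strings
#' @export
scaffold_species <- function(snapshot) {
  unique(snapshot$species[snapshot$scaffold])
}

#' Fraction of unique species embedding a pattern
#'
#' Set semantics: every unique species counts once, irrespective of copy
#' number.  The empty pattern embeds everywhere (frequency 1).
#'
#' @param model a `ps_model`
#' @param species character vector of canonical species strings
#' @param pattern pattern string in the rule dialect
#' @return fraction in `[0, 1]`
#' @export
pattern_frequency <- function(model, species, pattern) {
  species <- unique(species)
  if (length(species) == 0) return(NA_real_)
  if (trimws(pattern) == "") return(1.0)
  hits <- vapply(species, function(sp) {
    st <- structure_from_pattern(model, sp)
    nrow(find_embeddings(model, pattern, st)) > 0
  }, TRUE)
  mean(hits)
}

# ------------------------------------------------------ vector encoding ----

# slot layout of the scaffold-family vector (27 integer slots):
#   1  p1 present        2  p2 present (dimer partner)
#   per protomer block (p1: 3-12, p2: 13-22):
#   +0 Ste4 present  +1 Gpa1 code (0 none, 1 GDP, 2 GTP)  +2 Ste20 present
#   +3 Ste11 present +4 Ste11 phospho  +5 Ste7 present  +6 Ste7 phospho
#   +7 Fus3 present  +8 Fus3 T  +9 Fus3 Y
#   core block for Ste5-free members of the family (23-27):
#   23 core type (0 none, 1 Ste11, 2 Ste7, 3 Fus3, 4 Ste4)
#   24 core state 1 (Ste11/Ste7 phospho; Fus3 T)  25 core state 2 (Fus3 Y)
#   26 core Gpa1 code  27 core Ste20 present
ps_vector_length <- 27L

#' Vector encoding of a scaffold-family complex
#'
#' Encodes any member of the scaffold family (a Ste5-containing complex, or
#' a free kinase / G-protein subcomplex able to bind a free Ste5) as a
#' fixed-length integer vector; two complexes are equal iff their vectors
#' are equal, and the Hamming distance between vectors realizes the graph
#' edit distance in which attaching/detaching one protein or flipping one
#' internal state is a single edit.  Protomer order within a Ste5 dimer is
#' normalized lexicographically so the encoding is canonical.
#'
#' @param model a `ps_model`
#' @param complex a single-complex `ps_mixture` (or canonical string)
#' @return integer vector of length 27
#' @export
scaffold_vector <- function(model, complex) {
  if (is.character(complex)) complex <- structure_from_pattern(model, complex)
  tab <- model_tables(model)
  tn <- tab$type_names
  n <- length(complex$type)
  types <- tn[complex$type + 1]
  off <- c(0L, cumsum(vapply(complex$type + 1, function(t) length(tab$site_names[[t]]), 1L)))
  site <- function(a, name) {
    t <- complex$type[a] + 1
    s <- match(name, tab$site_names[[t]])
    off[a] + s
  }
  partner <- function(a, name) {
    b <- complex$bond[site(a, name)]
    if (b < 0) return(NA_integer_)
    # owner of flat slot b (0-based)
    findInterval(b, off[-length(off)] ) # index of agent with off <= b
  }
  stateof <- function(a, name) complex$state[site(a, name)]
  enc_err <- function() stop("complex is not a member of the scaffold family; ",
                             "use the generic multiset distance instead", call. = FALSE)
  v <- integer(ps_vector_length)
  ste5 <- which(types == "Ste5")
  protomer_block <- function(a) {
    b <- integer(10)
    s4 <- partner(a, "s4")
    if (!is.na(s4)) {
      b[1] <- 1L
      g <- partner(s4, "gpa")
      if (!is.na(g)) b[2] <- 1L + stateof(g, "nuc")
      s20 <- partner(s4, "s20")
      if (!is.na(s20)) b[3] <- 1L
    }
    s11 <- partner(a, "s11")
    if (!is.na(s11)) { b[4] <- 1L; b[5] <- stateof(s11, "st") }
    s7 <- partner(a, "s7")
    if (!is.na(s7)) { b[6] <- 1L; b[7] <- stateof(s7, "st") }
    f3 <- partner(a, "f3")
    if (!is.na(f3)) { b[8] <- 1L; b[9] <- stateof(f3, "T"); b[10] <- stateof(f3, "Y") }
    b
  }
  if (length(ste5) >= 1) {
    if (length(ste5) > 2) enc_err()
    blocks <- lapply(ste5, protomer_block)
    # every non-Ste5 agent must be reachable from the scaffold sites
    v[1] <- 1L
    if (length(ste5) == 2) {
      if (is.na(partner(ste5[1], "dim")) || partner(ste5[1], "dim") != ste5[2]) enc_err()
      v[2] <- 1L
      o <- order(vapply(blocks, paste, "", collapse = ","))
      blocks <- blocks[o]
      v[3:12] <- blocks[[1]]
      v[13:22] <- blocks[[2]]
    } else {
      if (!is.na(partner(ste5[1], "dim"))) enc_err()
      v[3:12] <- blocks[[1]]
    }
    expected <- length(ste5) + sum(vapply(blocks, function(b)
      (b[1] > 0) + (b[2] > 0) + (b[3] > 0) + (b[4] > 0) + (b[6] > 0) + (b[8] > 0), 0))
    if (expected != n) enc_err()
  } else {
    core <- if (all(types == "Ste11") && n == 1) {
      c(1L, stateof(1, "st"), 0L, 0L, 0L)
    } else if (all(types == "Ste7") && n == 1) {
      c(2L, stateof(1, "st"), 0L, 0L, 0L)
    } else if (all(types == "Fus3") && n == 1) {
      c(3L, stateof(1, "T"), stateof(1, "Y"), 0L, 0L)
    } else if ("Ste4" %in% types) {
      a <- which(types == "Ste4")
      if (length(a) != 1) enc_err()
      g <- partner(a, "gpa"); s20 <- partner(a, "s20")
      if (n != 1 + (!is.na(g)) + (!is.na(s20))) enc_err()
      c(4L, 0L, 0L, if (is.na(g)) 0L else 1L + stateof(g, "nuc"),
        if (is.na(s20)) 0L else 1L)
    } else enc_err()
    v[23:27] <- core
  }
  v
}

#' Graph edit distance between two scaffold-family complexes
#'
#' Realized as the Hamming distance between the vector encodings: each
#' differing slot is one edit (attach/detach of a protein, or one internal
#' state flip).  Symmetric, zero iff the complexes are identical, and a
#' metric on the scaffold family.  Complexes outside the family fall back to
#' a generic multiset distance over per-agent descriptors
#' (type + internal states + bound-site set).
#'
#' @param model a `ps_model`
#' @param a,b single-complex mixtures or canonical strings
#' @return non-negative integer
#' @export
ged <- function(model, a, b) {
  va <- tryCatch(scaffold_vector(model, a), error = function(e) NULL)
  vb <- tryCatch(scaffold_vector(model, b), error = function(e) NULL)
  if (is.null(va) || is.null(vb)) return(ged_generic(model, a, b))
  sum(va != vb)
}

# generic fallback: symmetric difference of per-agent descriptor multisets
ged_generic <- function(model, a, b) {
  desc <- function(x) {
    if (is.character(x)) x <- structure_from_pattern(model, x)
    tab <- model_tables(model)
    n <- length(x$type)
    off <- c(0L, cumsum(vapply(x$type + 1, function(t) length(tab$site_names[[t]]), 1L)))
    vapply(seq_len(n), function(i) {
      t <- x$type[i] + 1
      k <- length(tab$site_names[[t]])
      sl <- off[i] + seq_len(k)
      paste(tab$type_names[t],
            paste(x$state[sl], collapse = ","),
            paste(as.integer(x$bond[sl] >= 0), collapse = ","), sep = "|")
    }, "")
  }
  da <- desc(a); db <- desc(b)
  both <- intersect(unique(da), unique(db))
  common <- sum(vapply(both, function(d) min(sum(da == d), sum(db == d)), 1))
  (length(da) - common) + (length(db) - common)
}

# ------------------------------------------------------------- clustering --

#' Clustroid-based hierarchical clustering of scaffold species
#'
#' Starts with every complex in its own cluster (its own clustroid: the
#' member with the lowest average graph edit distance to the rest) and
#' repeatedly merges the two clusters whose clustroids are closest (minimum
#' between-cluster distance, MBCD), recomputing the merged cluster's
#' clustroid, until `cutoff` clusters remain.  Distance ties are broken by
#' the lexicographically smallest (clustroid string, clustroid string) pair,
#' clustroid ties by canonical-string order, so the partition is
#' deterministic and independent of input order.
#'
#' @param model a `ps_model`
#' @param species character vector of canonical species strings (the
#'   complexes to cluster); must be unique
#' @param cutoff number of clusters to return (1 <= cutoff <= n); may be a
#'   vector, in which case a named list of partitions is returned from one
#'   merge pass
#' @return a `ps_partition`: list with `assign` (cluster id per input
#'   species), `clustroid` (index of each cluster's clustroid), `members`
#'   (list of index vectors), `species`, and the merge history (`mbcd`)
#' @export
cluster_species <- function(model, species, cutoff) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("species must be unique strings")
  n <- length(species)
  if (any(cutoff < 1 | cutoff > n)) stop("cutoff must be in 1..length(species)")
  V <- t(vapply(species, function(sp) scaffold_vector(model, sp),
                integer(ps_vector_length)))
  D <- matrix(0L, n, n)
  for (k in seq_len(ncol(V))) D <- D + outer(V[, k], V[, k], "!=")
  ps_cluster_engine(D, species, sort(unique(cutoff), decreasing = TRUE))
}

# merge engine on a precomputed distance matrix; returns partitions at each
# requested cutoff (descending) from a single agglomeration pass
ps_cluster_engine <- function(D, species, cutoffs) {
  n <- length(species)
  active <- rep(TRUE, n)
  members <- lapply(seq_len(n), identity)
  clustroid <- seq_len(n)
  CD <- D * 1.0                      # clustroid-clustroid distances
  diag(CD) <- Inf
  CD[!active, ] <- Inf
  mbcd <- numeric(0)
  out <- list()
  snapshot <- function(k) {
    act <- which(active)
    assign <- integer(n)
    for (ci in seq_along(act)) assign[members[[act[ci]]]] <- ci
    structure(list(assign = assign,
                   clustroid = clustroid[act],
                   members = lapply(act, function(a) members[[a]]),
                   species = species, cutoff = k, mbcd = mbcd),
              class = "ps_partition")
  }
  k <- n
  for (cf in cutoffs) if (cf == k) out[[as.character(cf)]] <- snapshot(cf)
  while (k > min(cutoffs)) {
    m <- min(CD)
    cand <- which(CD == m, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1) {
      keys <- apply(cand, 1, function(rc) {
        ss <- sort(c(species[clustroid[rc[1]]], species[clustroid[rc[2]]]))
        paste(ss, collapse = "\r")
      })
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- integer(0)
    active[j] <- FALSE
    CD[j, ] <- Inf; CD[, j] <- Inf
    # recompute clustroid of merged cluster
    mm <- members[[i]]
    avg <- rowMeans(D[mm, mm, drop = FALSE])
    best <- which(avg == min(avg))
    if (length(best) > 1) best <- best[order(species[mm[best]])[1]]
    clustroid[i] <- mm[best]
    act <- which(active & seq_len(n) != i)
    CD[i, act] <- D[clustroid[i], clustroid[act]]
    CD[act, i] <- CD[i, act]
    mbcd <- c(mbcd, m)
    k <- k - 1
    if (as.character(k) %in% as.character(cutoffs)) out[[as.character(k)]] <- snapshot(k)
  }
  if (length(out) == 1) out[[1]] else out
}

#' @export
print.ps_partition <- function(x, ...) {
  cat("ps_partition:", length(x$members), "clusters over",
      length(x$species), "species\n")
  invisible(x)
}

# protein-node adjacency of the vector layout: node -> (presence slot,
# protein count when present, parent node)
ps_slot_nodes <- local({
  prot <- function(base, parent5) list(
    list(slot = base + 0, count = 1, parent = parent5),      # Ste4
    list(slot = base + 1, count = 1, parent = -(base + 0)),  # Gpa1 (code>0)
    list(slot = base + 2, count = 1, parent = -(base + 0)),  # Ste20
    list(slot = base + 3, count = 1, parent = parent5),      # Ste11
    list(slot = base + 5, count = 1, parent = parent5),      # Ste7
    list(slot = base + 7, count = 1, parent = parent5))      # Fus3
  function() {
    # nodes: 1 = Ste5#1 (slot 1), 2 = Ste5#2 (slot 2, parent 1)
    nodes <- list(list(slot = 1, count = 1, parent = 0),
                  list(slot = 2, count = 1, parent = 1))
    for (nd in prot(3, 1)) nodes[[length(nodes) + 1]] <- nd
    for (nd in prot(13, 2)) nodes[[length(nodes) + 1]] <- nd
    # core: one protein (slot 23 code) plus its Gpa1 / Ste20 decorations
    nodes[[length(nodes) + 1]] <- list(slot = 23, count = 1, parent = 0)
    nodes[[length(nodes) + 1]] <- list(slot = 26, count = 1, parent = -23)
    nodes[[length(nodes) + 1]] <- list(slot = 27, count = 1, parent = -23)
    nodes
  }
})

#' Average size of the largest conserved structural pattern
#'
#' For every cluster with at least `min_members` members, finds the largest
#' connected sub-structure (counted in proteins) whose presence is conserved
#' across all members: a protein counts when its presence slot in the vector
#' encoding agrees (and is occupied) in every member and it is connected to
#' the rest of the conserved pattern; internal states are ignored, matching
#' a binding-pattern notion of structural conservation.  Returns the average
#' over qualifying clusters, or `NA` when no cluster qualifies.
#'
#' @param model a `ps_model`
#' @param partition a `ps_partition` from [cluster_species()]
#' @param min_members minimum cluster size considered (default 10)
#' @return average conserved pattern size in proteins (`NA` if undefined)
#' @export
conserved_pattern_size <- function(model, partition, min_members = 10) {
  V <- t(vapply(partition$species, function(sp) scaffold_vector(model, sp),
                integer(ps_vector_length)))
  nodes <- ps_slot_nodes()
  sizes <- numeric(0)
  for (mm in partition$members) {
    if (length(mm) < min_members) next
    sub <- V[mm, , drop = FALSE]
    agree <- apply(sub, 2, function(col) all(col == col[1]))
    present <- agree & sub[1, ] > 0
    # Gpa1 slots conflate presence and nucleotide state; conservation of the
    # binding pattern ignores the state, so presence agreement suffices
    for (gs in c(4L, 14L, 26L))
      present[gs] <- all(sub[, gs] > 0)
    # node present iff its presence slot is conserved-present; connect to
    # parent (negative parent = slot index of the carrying node)
    npres <- vapply(nodes, function(nd) present[nd$slot], TRUE)
    # union-find over nodes
    parent_of <- function(i) {
      p <- nodes[[i]]$parent
      if (p == 0) return(0L)
      if (p > 0) return(p)
      match(-p, vapply(nodes, `[[`, 0, "slot"))
    }
    comp <- seq_along(nodes)
    repeat {
      changed <- FALSE
      for (i in seq_along(nodes)) {
        if (!npres[i]) next
        p <- parent_of(i)
        if (p > 0 && npres[p] && comp[i] != comp[p]) {
          newc <- min(comp[i], comp[p])
          comp[comp == comp[i] | comp == comp[p]] <- newc
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    csize <- tapply(vapply(which(npres), function(i) nodes[[i]]$count, 1),
                    comp[npres], sum)
    sizes <- c(sizes, if (length(csize)) max(csize) else 0)
  }
  if (length(sizes) == 0) return(NA_real_)
  mean(sizes)
}
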