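# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately naive (permutation search, exhaustive
# enumeration, union-find) and independent of the compiled code paths they
# check.

# --- tiny models --------------------------------------------------------

toy_ab_model <- function(kon = 1e-3, koff = 0.1, nA = 100, nB = 100) {
  parse_model(text = paste(
    "%agent: A(x)",
    "%agent: B(y)",
    "%bind: A.x B.y",
    sprintf("%%init: %d A()", nA),
    sprintf("%%init: %d B()", nB),
    "%obs: 'AB' A(x!_)",
    sprintf("'bind' A(x),B(y) -> A(x!1),B(y!1) @ %g", kon),
    sprintf("'unbind' A(x!1).B(y!1) -> A(x),B(y) @ %g", koff),
    sep = "\n"))
}

# three agent types with binding sites and states, rich enough for
# non-trivial isomorphism questions
toy_tri_model <- function() {
  parse_model(text = paste(
    "%agent: P(a,b,s~u~p)",
    "%agent: Q(a,c)",
    "%agent: R(c)",
    "%bind: P.a Q.a",
    "%bind: P.b P.b",
    "%bind: Q.c R.c",
    "%init: 5 P()",
    "'dim' P(b),P(b) -> P(b!1),P(b!1) @ 1",
    sep = "\n"))
}

# random connected complex over the tri-type signature, as a concrete
# pattern string; returns a ps_mixture
random_tri_complex <- function(model, n_agents = 4) {
  # grow a tree: start with a P, attach via legal bonds
  agents <- list() # each: list(type, sites=named chr bonds/states)
  lab <- 0
  add <- function(type) {
    agents[[length(agents) + 1]] <<- list(type = type, st = NULL, bonds = list())
    length(agents)
  }
  root <- add("P")
  free_slots <- list(c(root, "a"), c(root, "b"))
  while (length(agents) < n_agents && length(free_slots) > 0) {
    k <- sample.int(length(free_slots), 1)
    slot <- free_slots[[k]]
    free_slots[[k]] <- NULL
    i <- as.integer(slot[1]); s <- slot[2]
    ty <- agents[[i]]$type
    partner <- switch(paste0(ty, ".", s),
                      "P.a" = c("Q", "a"), "P.b" = c("P", "b"),
                      "Q.a" = c("P", "a"), "Q.c" = c("R", "c"),
                      "R.c" = c("Q", "c"))
    j <- add(partner[1])
    lab <- lab + 1
    agents[[i]]$bonds[[s]] <- lab
    agents[[j]]$bonds[[partner[2]]] <- lab
    for (s2 in setdiff(switch(partner[1], P = c("a", "b"), Q = c("a", "c"), R = "c"),
                       partner[2]))
      free_slots[[length(free_slots) + 1]] <- c(j, s2)
  }
  txt <- paste(vapply(agents, function(a) {
    parts <- character(0)
    if (a$type == "P") parts <- c(parts, paste0("s~", sample(c("u", "p"), 1)))
    for (s in names(a$bonds)) parts <- c(parts, paste0(s, "!", a$bonds[[s]]))
    paste0(a$type, "(", paste(parts, collapse = ","), ")")
  }, ""), collapse = ".")
  structure_from_pattern(model, txt)
}

# permute the agent order of a mixture (bonds remapped accordingly)
permute_mixture <- function(model, mix, perm) {
  tab <- pleioscope:::model_tables(model)
  n <- length(mix$type)
  stopifnot(length(perm) == n)
  nsites <- vapply(mix$type + 1, function(t) length(tab$site_names[[t]]), 1L)
  off <- c(0L, cumsum(nsites))
  inv <- integer(n); inv[perm] <- seq_len(n)
  newtype <- mix$type[perm]
  newnsites <- nsites[perm]
  newoff <- c(0L, cumsum(newnsites))
  state <- integer(sum(nsites)); bond <- rep(-1L, sum(nsites))
  slot_owner <- rep(seq_len(n), nsites)
  for (newi in seq_len(n)) {
    old <- perm[newi]
    for (s in seq_len(nsites[old])) {
      state[newoff[newi] + s] <- mix$state[off[old] + s]
      b <- mix$bond[off[old] + s]
      if (b >= 0) {
        oldpa <- slot_owner[b + 1]
        ps <- b - off[oldpa]
        bond[newoff[newi] + s] <- newoff[inv[oldpa]] + ps
      }
    }
  }
  pleioscope:::new_mixture(newtype, state, bond)
}

# brute-force isomorphism by permutation search over same-type agents
brute_isomorphic <- function(model, a, b) {
  tab <- pleioscope:::model_tables(model)
  n <- length(a$type)
  if (n != length(b$type)) return(FALSE)
  if (!identical(sort(a$type), sort(b$type))) return(FALSE)
  nsa <- vapply(a$type + 1, function(t) length(tab$site_names[[t]]), 1L)
  nsb <- vapply(b$type + 1, function(t) length(tab$site_names[[t]]), 1L)
  offa <- c(0L, cumsum(nsa)); offb <- c(0L, cumsum(nsb))
  owner_a <- rep(seq_len(n), nsa); owner_b <- rep(seq_len(n), nsb)
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (r in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], r)
    out
  }
  # candidate maps: match agents of equal type
  groups_a <- split(seq_len(n), a$type)
  groups_b <- split(seq_len(n), b$type)
  per_group <- lapply(names(groups_a), function(g) perms_of(groups_b[[g]]))
  grid <- expand.grid(lapply(per_group, seq_along))
  for (r in seq_len(nrow(grid))) {
    map <- integer(n)
    for (gi in seq_along(groups_a))
      map[groups_a[[gi]]] <- per_group[[gi]][[grid[r, gi]]]
    ok <- TRUE
    for (i in seq_len(n)) {
      for (s in seq_len(nsa[i])) {
        if (a$state[offa[i] + s] != b$state[offb[map[i]] + s]) { ok <- FALSE; break }
        ba <- a$bond[offa[i] + s]; bb <- b$bond[offb[map[i]] + s]
        if ((ba < 0) != (bb < 0)) { ok <- FALSE; break }
        if (ba >= 0) {
          pa <- owner_a[ba + 1]; psa <- ba - offa[pa]
          pb <- owner_b[bb + 1]; psb <- bb - offb[pb]
          if (map[pa] != pb || psa != psb) { ok <- FALSE; break }
        }
      }
      if (!ok) break
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# brute-force embedding enumeration for a (possibly multi-component)
# pattern: try all injective assignments of pattern agents to mixture agents
brute_embeddings <- function(model, pattern, mix) {
  tab <- pleioscope:::model_tables(model)
  pp <- pleioscope:::parse_pattern_text(pattern)
  np <- length(pp)
  n <- length(mix$type)
  nsm <- vapply(mix$type + 1, function(t) length(tab$site_names[[t]]), 1L)
  off <- c(0L, cumsum(nsm))
  owner <- rep(seq_len(n), nsm)
  ptype <- vapply(pp, function(a) match(a$type, tab$type_names), 1L)
  # bond label endpoints in the pattern
  labs <- list()
  for (i in seq_len(np)) for (sn in names(pp[[i]]$sites)) {
    b <- pp[[i]]$sites[[sn]]$bond
    if (b$kind == "label")
      labs[[as.character(b$label)]] <- rbind(labs[[as.character(b$label)]],
                                             c(i, match(sn, tab$site_names[[ptype[i]]])))
  }
  check <- function(map) {
    for (i in seq_len(np)) {
      mi <- map[i]
      if (mix$type[mi] + 1 != ptype[i]) return(FALSE)
      for (sn in names(pp[[i]]$sites)) {
        s <- match(sn, tab$site_names[[ptype[i]]])
        info <- pp[[i]]$sites[[sn]]
        sl <- off[mi] + s
        if (!is.na(info$state)) {
          want <- match(info$state, tab$state_names[[ptype[i]]][[s]]) - 1L
          if (mix$state[sl] != want) return(FALSE)
        }
        b <- mix$bond[sl]
        kind <- info$bond$kind
        if (kind == "free" && b >= 0) return(FALSE)
        if (kind == "bound" && b < 0) return(FALSE)
        if (kind == "label") {
          if (b < 0) return(FALSE)
          e <- labs[[as.character(info$bond$label)]]
          other <- e[e[, 1] != i | e[, 2] != s, , drop = FALSE]
          pa <- owner[b + 1]; ps <- b - off[pa] + 1
          if (map[other[1, 1]] != pa || other[1, 2] != ps) return(FALSE)
        }
        if (kind == "type") {
          if (b < 0) return(FALSE)
          pa <- owner[b + 1]; ps <- b - off[pa] + 1
          t2 <- match(info$bond$type, tab$type_names)
          s2 <- match(info$bond$site, tab$site_names[[t2]])
          if (mix$type[pa] + 1 != t2 || ps != s2) return(FALSE)
        }
      }
    }
    TRUE
  }
  res <- NULL
  rec <- function(i, map, used) {
    if (i > np) {
      if (check(map)) res <<- rbind(res, map)
      return()
    }
    for (m in seq_len(n)) {
      if (used[m]) next
      if (mix$type[m] + 1 != ptype[i]) next
      used[m] <- TRUE
      map[i] <- m
      rec(i + 1, map, used)
      used[m] <- FALSE
    }
  }
  rec(1, integer(np), logical(n))
  if (is.null(res)) matrix(integer(0), ncol = np) else unname(res)
}

# union-find component count oracle on a mixture
uf_components <- function(model, mix) {
  tab <- pleioscope:::model_tables(model)
  n <- length(mix$type)
  nsm <- vapply(mix$type + 1, function(t) length(tab$site_names[[t]]), 1L)
  off <- c(0L, cumsum(nsm))
  owner <- rep(seq_len(n), nsm)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (sl in seq_along(mix$bond)) if (mix$bond[sl] >= 0) {
    a <- owner[sl]; b <- owner[mix$bond[sl] + 1]
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}

# fast standard protocol used by simulation-level tests
short_protocol <- function(post = 120, branches = 3, parents = 1,
                           control = FALSE)
  make_protocol(pre_eq_time = 200, post_time = post, n_parents = parents,
                n_branches = branches,
                snap_times = c(0, logspace(1, post, 10)), control = control)
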