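# Rule language: agent signatures, site-graph patterns with "don't care,
# don't write" semantics, rules, a text dialect (".pka", a Kappa-style
# subset), and compilation to the integer encoding the C++ core consumes.

# ---------------------------------------------------------------- parsing --

# split "A(x!1),B(y!1).C()" into top-level agent strings ("," and "." both
# separate agents; connectivity is carried by bond labels alone)
split_agents <- function(text) {
  text <- trimws(text)
  if (text == "") return(character(0))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  out <- character(0)
  cur <- character(0)
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth == 0L && (ch == "," || ch == ".")) {
      out <- c(out, paste(cur, collapse = ""))
      cur <- character(0)
    } else cur <- c(cur, ch)
  }
  out <- c(out, paste(cur, collapse = ""))
  out <- trimws(out)
  out[out != ""]
}

# parse one agent "Name(site~state!1, site2, site3!_)" into a list
parse_agent_text <- function(txt) {
  m <- regmatches(txt, regexec("^\\s*([A-Za-z][A-Za-z0-9_]*)\\s*(\\((.*)\\))?\\s*$", txt))[[1]]
  if (length(m) == 0) stop("cannot parse agent: '", txt, "'", call. = FALSE)
  type <- m[2]
  body <- if (is.na(m[4])) "" else m[4]
  sites <- list()
  if (trimws(body) != "") {
    for (s in strsplit(body, ",", fixed = TRUE)[[1]]) {
      s <- trimws(s)
      if (s == "") next
      sm <- regmatches(s, regexec(
        "^([A-Za-z][A-Za-z0-9_]*)(~([A-Za-z0-9_]+))?(!_|![0-9]+|!([A-Za-z][A-Za-z0-9_]*)\\.([A-Za-z][A-Za-z0-9_]*)|\\?)?$", s))[[1]]
      if (length(sm) == 0) stop("cannot parse site: '", s, "' in agent '", txt, "'", call. = FALSE)
      name <- sm[2]
      state <- if (sm[4] == "") NA_character_ else sm[4]
      bt <- sm[5]
      bond <- if (bt == "") list(kind = "free")
      else if (bt == "!_") list(kind = "bound")
      else if (bt == "?") list(kind = "any")
      else if (sm[6] != "") list(kind = "type", type = sm[6], site = sm[7])
      else list(kind = "label", label = as.integer(sub("!", "", bt, fixed = TRUE)))
      if (name %in% names(sites))
        stop("site '", name, "' mentioned twice in '", txt, "'", call. = FALSE)
      sites[[name]] <- list(state = state, bond = bond)
    }
  }
  list(type = type, sites = sites)
}

parse_pattern_text <- function(text) lapply(split_agents(text), parse_agent_text)

# ------------------------------------------------------------- signatures --

#' Declare an agent signature
#'
#' @param name agent (protein) type name
#' @param sites named list; each element is `list(states = <character>,
#'   binds = <character "Type.site" vector>)`.  `states` may be omitted for
#'   a pure binding site; the first state is the default.
#' @return an agent signature list
#' @export
agent_sig <- function(name, sites = list()) {
  sites <- lapply(sites, function(s) {
    list(states = s$states %||% character(0), binds = s$binds %||% character(0))
  })
  list(name = name, sites = sites)
}

#' Assemble a rule-based model specification
#'
#' @param agents list of [agent_sig()] objects
#' @param rules list of `list(name, lhs, rhs, rate)` with `lhs`/`rhs` rule
#'   pattern strings in the package dialect and `rate` the stochastic rate
#'   constant (per second; per pair and second for bimolecular rules)
#' @param init list of `list(copies, pattern)` seeding the initial mixture
#' @param observables named character vector of single-component patterns
#' @param scaffold name of the scaffold agent type (or `NA`); used by the
#'   scaffold-species filter
#' @param vars named numeric vector of rate constants referenced by rules
#' @return an object of class `ps_model`
#' @export
model_spec <- function(agents = list(), rules = list(), init = list(),
                       observables = character(0), scaffold = NA_character_,
                       vars = numeric(0)) {
  names(agents) <- vapply(agents, `[[`, "", "name")
  m <- structure(list(agents = agents, rules = rules, init = init,
                      obs = observables, scaffold = scaffold, vars = vars,
                      uid = uid_counter()),
                 class = "ps_model")
  ps_compile(m) # validates eagerly; compilation is cached by uid
  m
}

#' @export
print.ps_model <- function(x, ...) {
  cat("ps_model:", length(x$agents), "agent types,", length(x$rules),
      "rules,", length(x$init), "init declarations,", length(x$obs),
      "observables\n")
  invisible(x)
}

#' Number of rules / agent types in a model
#' @param model a `ps_model`
#' @return integer count
#' @export
n_rules <- function(model) length(model$rules)

#' @rdname n_rules
#' @export
n_agent_types <- function(model) length(model$agents)

# ------------------------------------------------------------ compilation --

.compile_cache <- new.env(parent = emptyenv())

state_list <- function(sig, site) {
  st <- sig$sites[[site]]$states
  if (length(st) == 0) "" else st
}

# compile one parsed pattern (list of agents) against the type tables;
# returns components in C++ form plus the orig->global index map
compile_pattern <- function(pp, tab, what = "pattern") {
  n <- length(pp)
  if (n == 0) return(list(comps = list(), orig2global = integer(0), radius = 0L))
  types <- integer(n)
  for (i in seq_len(n)) {
    a <- pp[[i]]
    t <- match(a$type, tab$type_names)
    if (is.na(t)) stop(what, ": undeclared agent type '", a$type, "'", call. = FALSE)
    types[i] <- t
    for (sn in names(a$sites)) {
      s <- match(sn, tab$site_names[[t]])
      if (is.na(s)) stop(what, ": agent '", a$type, "' has no site '", sn, "'", call. = FALSE)
      st <- a$sites[[sn]]$state
      if (!is.na(st) && !(st %in% tab$state_names[[t]][[s]]))
        stop(what, ": '", a$type, ".", sn, "' has no state '", st, "'", call. = FALSE)
    }
  }
  # bond label endpoints
  labs <- list()
  for (i in seq_len(n)) for (sn in names(pp[[i]]$sites)) {
    b <- pp[[i]]$sites[[sn]]$bond
    if (b$kind == "label") {
      key <- as.character(b$label)
      labs[[key]] <- rbind(labs[[key]] %||% NULL, c(i, match(sn, tab$site_names[[types[i]]])))
    }
  }
  for (key in names(labs)) if (nrow(labs[[key]]) != 2)
    stop(what, ": bond label ", key, " must appear exactly twice", call. = FALSE)
  # adjacency and connected components
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (key in names(labs)) {
    e <- labs[[key]]
    adj[[e[1, 1]]] <- c(adj[[e[1, 1]]], e[2, 1])
    adj[[e[2, 1]]] <- c(adj[[e[2, 1]]], e[1, 1])
  }
  compid <- rep(NA_integer_, n)
  ncomp <- 0L
  for (i in seq_len(n)) {
    if (!is.na(compid[i])) next
    ncomp <- ncomp + 1L
    queue <- i
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(compid[u])) next
      compid[u] <- ncomp
      queue <- c(queue, adj[[u]])
    }
  }
  comps <- vector("list", ncomp)
  orig2global <- integer(n)
  gidx <- 0L
  radius <- 0L
  for (c in seq_len(ncomp)) {
    members <- which(compid == c)
    anchor <- members[1]
    # BFS from anchor along labelled bonds
    order <- anchor
    dist <- setNames(0L, as.character(anchor))
    attach <- list() # per new index j (>=2): c(via_new, via_site)
    k <- 1L
    while (k <= length(order)) {
      u <- order[k]
      for (key in names(labs)) {
        e <- labs[[key]]
        pos <- which(e[, 1] == u)
        for (p in pos) {
          v <- e[3 - p, 1]
          if (!(v %in% order)) {
            order <- c(order, v)
            dist[as.character(v)] <- dist[as.character(u)] + 1L
            attach[[length(order)]] <- c(match(u, order) - 1L, e[p, 2] - 1L)
          }
        }
      }
      k <- k + 1L
    }
    if (length(order) != length(members))
      stop(what, ": agents within a component must be connected by bonds", call. = FALSE)
    radius <- max(radius, max(dist))
    newpos <- setNames(seq_along(order), as.character(order))
    # conds
    rows <- NULL
    for (j in seq_along(order)) {
      i <- order[j]
      t <- types[i]
      for (sn in names(pp[[i]]$sites)) {
        s <- match(sn, tab$site_names[[t]])
        info <- pp[[i]]$sites[[sn]]
        stx <- if (is.na(info$state)) -1L
        else match(info$state, tab$state_names[[t]][[s]]) - 1L
        b <- info$bond
        row <- switch(b$kind,
          any   = if (stx >= 0) c(j - 1L, s - 1L, 0L, 0L, 0L, stx) else NULL,
          free  = c(j - 1L, s - 1L, 1L, 0L, 0L, stx),
          bound = c(j - 1L, s - 1L, 2L, 0L, 0L, stx),
          label = {
            e <- labs[[as.character(b$label)]]
            p <- which(e[, 1] == i & e[, 2] == s)
            o <- e[3 - p, ]
            c(j - 1L, s - 1L, 3L, newpos[[as.character(o[1])]] - 1L, o[2] - 1L, stx)
          },
          type  = {
            pt <- match(b$type, tab$type_names)
            if (is.na(pt)) stop(what, ": undeclared type in bond spec '", b$type, "'", call. = FALSE)
            psn <- match(b$site, tab$site_names[[pt]])
            if (is.na(psn)) stop(what, ": '", b$type, "' has no site '", b$site, "'", call. = FALSE)
            c(j - 1L, s - 1L, 4L, pt - 1L, psn - 1L, stx)
          })
        if (!is.null(row)) rows <- rbind(rows, row)
      }
    }
    if (is.null(rows)) rows <- matrix(integer(0), ncol = 6)
    am <- if (length(order) > 1)
      do.call(rbind, lapply(2:length(order), function(j) c(j - 1L, attach[[j]])))
    else matrix(integer(0), ncol = 3)
    comps[[c]] <- list(types = as.integer(types[order] - 1L),
                       conds = matrix(as.integer(rows), ncol = 6),
                       attach = matrix(as.integer(am), ncol = 3),
                       orig = as.integer(order))
    orig2global[order] <- gidx + seq_along(order)
    gidx <- gidx + length(order)
  }
  list(comps = comps, orig2global = orig2global, radius = as.integer(radius),
       types = types)
}

# automorphism count of a compiled left pattern (all components jointly)
pattern_automorphisms <- function(pp, tab, cp) {
  n <- length(pp)
  if (n <= 1) return(1)
  types <- cp$types
  # serialize conds in *original* indices for comparison
  ser <- function(perm) {
    rows <- character(0)
    for (i in seq_len(n)) {
      a <- pp[[i]]
      t <- types[i]
      for (sn in names(a$sites)) {
        info <- a$sites[[sn]]
        b <- info$bond
        bk <- b$kind
        extra <- ""
        if (bk == "type") extra <- paste0(b$type, ".", b$site)
        rows <- c(rows, paste(perm[i], sn, bk, extra, info$state %||% NA, sep = "|"))
      }
    }
    # bond edges (endpoints identified by permuted agent index + site name)
    labs <- list()
    for (i in seq_len(n)) for (sn in names(pp[[i]]$sites)) {
      b <- pp[[i]]$sites[[sn]]$bond
      if (b$kind == "label") {
        key <- as.character(b$label)
        labs[[key]] <- c(labs[[key]] %||% character(0), paste0(perm[i], ".", sn))
      }
    }
    for (key in names(labs))
      rows <- c(rows, paste("E", paste(sort(labs[[key]]), collapse = ","), sep = "|"))
    paste(sort(rows), collapse = ";")
  }
  base <- ser(seq_len(n))
  # candidate permutations: within identical-type groups
  groups <- split(seq_len(n), types)
  perms_of <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      rest <- perms_of(v[-i])
      out <- c(out, lapply(rest, function(r) c(v[i], r)))
    }
    out
  }
  gp <- lapply(groups, perms_of)
  idx <- lapply(gp, seq_along)
  grid <- expand.grid(idx, KEEP.OUT.ATTRS = FALSE)
  count <- 0
  for (r in seq_len(nrow(grid))) {
    perm <- integer(n)
    for (g in seq_along(groups))
      perm[groups[[g]]] <- gp[[g]][[grid[r, g]]]
    if (ser(perm) == base) count <- count + 1
  }
  count
}

compile_rule <- function(rule, tab) {
  nm <- rule$name %||% "<unnamed>"
  L <- parse_pattern_text(rule$lhs %||% "")
  R <- parse_pattern_text(rule$rhs %||% "")
  nL <- length(L); nR <- length(R)
  npair <- min(nL, nR)
  if (npair > 0) for (i in seq_len(npair))
    if (L[[i]]$type != R[[i]]$type)
      stop("rule '", nm, "': agent ", i, " changes type across the arrow", call. = FALSE)
  cp <- compile_pattern(L, tab, paste0("rule '", nm, "' lhs"))
  if (length(cp$comps) > 2)
    stop("rule '", nm, "': more than two reactant components are unsupported", call. = FALSE)
  # also type-check rhs mentions
  cr <- compile_pattern(R, tab, paste0("rule '", nm, "' rhs"))
  g <- cp$orig2global # orig lhs index -> 1-based global compiled index
  site_idx <- function(agent, sn) match(sn, tab$site_names[[match(agent$type, tab$type_names)]])
  state_idx <- function(agent, sn, st) {
    t <- match(agent$type, tab$type_names)
    match(st, tab$state_names[[t]][[site_idx(agent, sn)]]) - 1L
  }
  bondset <- function(agents, gmap) {
    labs <- list()
    for (i in seq_along(agents)) for (sn in names(agents[[i]]$sites)) {
      b <- agents[[i]]$sites[[sn]]$bond
      if (b$kind == "label") {
        key <- as.character(b$label)
        labs[[key]] <- rbind(labs[[key]] %||% NULL,
                             c(gmap[i], site_idx(agents[[i]], sn) - 1L))
      }
    }
    out <- list()
    for (key in names(labs)) {
      e <- labs[[key]]
      o <- order(e[, 1], e[, 2])
      e <- e[o, , drop = FALSE]
      out[[paste(e[1, 1], e[1, 2], e[2, 1], e[2, 2], sep = "_")]] <- e
    }
    out
  }
  gR <- integer(nR)
  if (npair > 0) gR[seq_len(npair)] <- g[seq_len(npair)]
  if (nR > nL) gR[(nL + 1):nR] <- nL + seq_len(nR - nL) # synthesized slots
  lb <- bondset(L, g)
  rb <- bondset(R, gR)
  degraded <- if (nL > nR) (npair + 1):nL else integer(0)
  # drop broken bonds that involve a degraded agent (freed implicitly)
  is_deg <- function(e) any(e[, 1] %in% g[degraded])
  broken <- setdiff(names(lb), names(rb))
  broken <- broken[!vapply(lb[broken], is_deg, TRUE)]
  created <- setdiff(names(rb), names(lb))
  if (length(broken) + length(created) > 1)
    stop("rule '", nm, "': at most one bond may be created or broken", call. = FALSE)
  actions <- NULL
  # synthesis first
  if (nR > nL) for (i in (nL + 1):nR) {
    t <- match(R[[i]]$type, tab$type_names)
    actions <- rbind(actions, c(4L, t - 1L, 0L, 0L, 0L, 0L))
  }
  # state changes (paired and synthesized)
  for (i in seq_len(nR)) {
    paired <- i <= npair
    for (sn in names(R[[i]]$sites)) {
      stR <- R[[i]]$sites[[sn]]$state
      if (is.na(stR)) next
      stL <- if (paired && sn %in% names(L[[i]]$sites)) L[[i]]$sites[[sn]]$state else NA
      if (paired && !(sn %in% names(L[[i]]$sites)))
        stop("rule '", nm, "': rhs mentions site '", R[[i]]$type, ".", sn,
             "' absent from lhs", call. = FALSE)
      if (!paired || is.na(stL) || stL != stR)
        actions <- rbind(actions, c(2L, gR[i] - 1L, site_idx(R[[i]], sn) - 1L, 0L, 0L,
                                    state_idx(R[[i]], sn, stR)))
    }
    # bond mention coherence for paired agents
    if (paired) for (sn in names(R[[i]]$sites)) {
      bR <- R[[i]]$sites[[sn]]$bond
      if (!(sn %in% names(L[[i]]$sites))) next # caught above if state; bonds too
      bL <- L[[i]]$sites[[sn]]$bond
      if (bR$kind %in% c("bound", "any", "type") && bR$kind != bL$kind)
        stop("rule '", nm, "': cannot transform wildcard bond on '",
             R[[i]]$type, ".", sn, "'", call. = FALSE)
    }
  }
  for (key in broken) {
    e <- lb[[key]]
    actions <- rbind(actions, c(1L, e[1, 1] - 1L, e[1, 2], 0L, 0L, 0L))
  }
  for (key in created) {
    e <- rb[[key]]
    actions <- rbind(actions, c(0L, e[1, 1] - 1L, e[1, 2], e[2, 1] - 1L, e[2, 2], 0L))
  }
  for (i in degraded)
    actions <- rbind(actions, c(3L, g[i] - 1L, 0L, 0L, 0L, 0L))
  if (is.null(actions)) actions <- matrix(integer(0), ncol = 6)
  if (is.null(rule$rate) || is.na(rule$rate) || rule$rate < 0)
    stop("rule '", nm, "': rate must be a non-negative number", call. = FALSE)
  # reorder compiled comps' conds/attach already in compiled indices; need
  # action indices in *compiled global* order: g maps orig->global already.
  list(name = nm, rate = as.numeric(rule$rate),
       aut = pattern_automorphisms(L, tab, cp),
       comps = lapply(cp$comps, function(x) x[c("types", "conds", "attach")]),
       orig = unlist(lapply(cp$comps, `[[`, "orig")),
       nleft = nL,
       actions = matrix(as.integer(actions), ncol = 6),
       radius = cp$radius)
}

# infer may-bind pairs from declared binds plus rule bond creations
model_tables <- function(model) {
  type_names <- names(model$agents)
  site_names <- lapply(model$agents, function(a) names(a$sites))
  state_names <- lapply(model$agents, function(a)
    lapply(a$sites, function(s) if (length(s$states)) s$states else ""))
  list(type_names = type_names, site_names = site_names, state_names = state_names)
}

#' Compile a model to the internal integer encoding (cached)
#' @param model a `ps_model`
#' @return the compiled representation consumed by the simulation core
#' @keywords internal
ps_compile <- function(model) {
  if (!is.null(model$uid) && !is.null(.compile_cache[[model$uid]]))
    return(.compile_cache[[model$uid]])
  tab <- model_tables(model)
  nty <- length(tab$type_names)
  nsites <- vapply(tab$site_names, length, 1L)
  nstates <- lapply(seq_len(nty), function(t)
    vapply(tab$state_names[[t]], length, 1L) %||% integer(0))
  rules <- lapply(model$rules, compile_rule, tab = tab)
  obs <- lapply(seq_along(model$obs), function(i) {
    cp <- compile_pattern(parse_pattern_text(model$obs[[i]]), tab,
                          paste0("observable '", names(model$obs)[i], "'"))
    if (length(cp$comps) != 1)
      stop("observable '", names(model$obs)[i], "' must be one connected component",
           call. = FALSE)
    c(cp$comps[[1]][c("types", "conds", "attach")], list(radius = cp$radius))
  })
  # may-bind: declared + inferred from rule bond creations
  mb <- new.env(parent = emptyenv())
  addmb <- function(t1, s1, t2, s2) {
    mb[[paste(t1, s1, t2, s2)]] <- c(t1, s1, t2, s2)
    mb[[paste(t2, s2, t1, s1)]] <- c(t2, s2, t1, s1)
  }
  for (t in seq_len(nty)) {
    a <- model$agents[[t]]
    for (s in seq_along(a$sites)) for (b in a$sites[[s]]$binds) {
      pp <- strsplit(b, ".", fixed = TRUE)[[1]]
      t2 <- match(pp[1], tab$type_names)
      if (is.na(t2)) stop("binds declaration names unknown type '", pp[1], "'", call. = FALSE)
      s2 <- match(pp[2], tab$site_names[[t2]])
      if (is.na(s2)) stop("binds declaration names unknown site '", b, "'", call. = FALSE)
      addmb(t, s, t2, s2)
    }
  }
  for (r in rules) {
    gt <- integer(0)
    for (cpn in r$comps) gt <- c(gt, cpn$types + 1L)
    am <- r$actions
    for (i in seq_len(nrow(am))) if (am[i, 1] == 0L) {
      a1 <- am[i, 2] + 1L; a2 <- am[i, 4] + 1L
      t1 <- if (a1 <= length(gt)) gt[a1] else NA
      t2 <- if (a2 <= length(gt)) gt[a2] else NA
      if (!is.na(t1) && !is.na(t2)) addmb(t1, am[i, 3] + 1L, t2, am[i, 5] + 1L)
    }
  }
  mbm <- do.call(rbind, as.list(mb)) %||% matrix(integer(0), ncol = 4)
  scaffold_type <- if (is.na(model$scaffold)) -1L
  else {
    st <- match(model$scaffold, tab$type_names)
    if (is.na(st)) stop("scaffold type '", model$scaffold, "' not declared", call. = FALSE)
    st - 1L
  }
  sb <- matrix(integer(0), ncol = 2)
  if (scaffold_type >= 0 && nrow(mbm) > 0) {
    hit <- mbm[, 3] == scaffold_type + 1L
    if (any(hit)) sb <- unique(cbind(mbm[hit, 1] - 1L, mbm[hit, 2] - 1L))
  }
  radius <- max(c(0L, vapply(rules, `[[`, 0L, "radius"),
                  vapply(obs, function(o) o$radius, 0L)))
  compiled <- list(
    nsites = as.integer(nsites),
    nstates = lapply(nstates, as.integer),
    type_names = tab$type_names,
    site_names = lapply(tab$site_names, as.character),
    state_names = lapply(tab$state_names, function(x) lapply(x, as.character)),
    rules = rules,
    obs = lapply(obs, function(o) o[c("types", "conds", "attach")]),
    obs_names = as.character(names(model$obs) %||% character(0)),
    scaffold_type = as.integer(scaffold_type),
    scaffold_binders = matrix(as.integer(sb), ncol = 2),
    radius = as.integer(radius),
    may_bind = mbm)
  if (!is.null(model$uid)) .compile_cache[[model$uid]] <- compiled
  compiled
}

# ------------------------------------------------------------ .pka parser --

#' Parse a model written in the package's rule dialect
#'
#' The dialect is a Kappa-style subset: `%agent:` signatures with `~`-listed
#' internal states, `%bind:` may-bind declarations, `%init:` seed mixtures,
#' `%var:` named rate constants, `%obs:` observables, and quoted-name rules
#' `'r' lhs -> rhs @ rate`.  Unsupported directives are collected (with line
#' numbers) in the `unsupported` attribute and reported via a warning, never
#' silently dropped.
#'
#' @param text model source (single string or character vector of lines);
#'   exactly one of `text`/`file` must be given
#' @param file path to a model file
#' @return a `ps_model`
#' @export
parse_model <- function(text = NULL, file = NULL) {
  if (is.null(text)) text <- readLines(file, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- sub("(#|//).*$", "", lines)
  agents <- list(); rules <- list(); init <- list()
  obs <- character(0); vars <- numeric(0); binds <- list()
  unsupported <- character(0)
  scaffold <- NA_character_
  for (ln in seq_along(lines)) {
    l <- trimws(lines[ln])
    if (l == "") next
    err <- function(msg) stop("line ", ln, ": ", msg, call. = FALSE)
    if (startsWith(l, "%agent:")) {
      m <- regmatches(l, regexec(
        "^%agent:\\s*([A-Za-z][A-Za-z0-9_]*)\\s*(\\((.*)\\))?\\s*$", l))[[1]]
      if (length(m) == 0) err("cannot parse %agent")
      nm <- m[2]
      body <- if (is.na(m[4])) "" else m[4]
      sites <- list()
      if (trimws(body) != "") {
        for (s in strsplit(body, ",", fixed = TRUE)[[1]]) {
          s <- trimws(s)
          if (s == "") next
          parts <- strsplit(s, "~", fixed = TRUE)[[1]]
          sites[[parts[1]]] <- list(states = if (length(parts) > 1) parts[-1] else character(0),
                                    binds = character(0))
        }
      }
      agents[[nm]] <- list(name = nm, sites = sites)
    } else if (startsWith(l, "%bind:")) {
      p <- strsplit(trimws(sub("^%bind:\\s*", "", l)), "\\s+")[[1]]
      if (length(p) != 2) err("%bind: expects 'Type.site Type.site'")
      binds[[length(binds) + 1]] <- p
    } else if (startsWith(l, "%scaffold:")) {
      scaffold <- trimws(sub("^%scaffold:\\s*", "", l))
    } else if (startsWith(l, "%init:")) {
      m <- regmatches(l, regexec("^%init:\\s*([0-9]+)\\s+(.*)$", l))[[1]]
      if (length(m) == 0) err("cannot parse %init")
      init[[length(init) + 1]] <- list(copies = as.integer(m[2]), pattern = trimws(m[3]))
    } else if (startsWith(l, "%obs:")) {
      m <- regmatches(l, regexec("^%obs:\\s*'([^']+)'\\s+(.*)$", l))[[1]]
      if (length(m) == 0) err("cannot parse %obs (expected %obs: 'name' pattern)")
      obs[[m[2]]] <- trimws(m[3])
    } else if (startsWith(l, "%var:")) {
      m <- regmatches(l, regexec("^%var:\\s*'([^']+)'\\s+([-+0-9.eE]+)\\s*$", l))[[1]]
      if (length(m) == 0) err("cannot parse %var (only numeric constants are supported)")
      vars[[m[2]]] <- as.numeric(m[3])
    } else if (startsWith(l, "%")) {
      unsupported <- c(unsupported, sprintf("line %d: %s", ln, l))
    } else {
      # rule: ['name'] lhs (-> | <->) rhs @ rate [, rate_rev]
      m <- regmatches(l, regexec("^('([^']+)'\\s+)?(.*?)\\s*(<->|->)\\s*(.*?)\\s*@\\s*(.+)$", l,
                                 perl = TRUE))[[1]]
      if (length(m) == 0) err(paste0("cannot parse rule: '", l, "'"))
      nm <- if (m[3] == "") sprintf("rule%03d", length(rules) + 1) else m[3]
      arrow <- m[5]
      rates <- trimws(strsplit(m[7], ",", fixed = TRUE)[[1]])
      getrate <- function(rr) {
        if (grepl("^'.*'$", rr)) {
          key <- gsub("'", "", rr)
          if (!(key %in% names(vars))) err(paste0("undefined rate variable ", rr))
          vars[[key]]
        } else {
          v <- suppressWarnings(as.numeric(rr))
          if (is.na(v)) err(paste0("cannot parse rate '", rr, "'"))
          v
        }
      }
      rules[[length(rules) + 1]] <- list(name = nm, lhs = m[4], rhs = m[6],
                                         rate = getrate(rates[1]))
      if (arrow == "<->") {
        if (length(rates) < 2) err("bidirectional rule needs two rates")
        rules[[length(rules) + 1]] <- list(name = paste0(nm, "_rev"), lhs = m[6],
                                           rhs = m[4], rate = getrate(rates[2]))
      }
    }
  }
  # attach binds to signatures
  tabn <- names(agents)
  for (b in binds) {
    p1 <- strsplit(b[1], ".", fixed = TRUE)[[1]]
    p2 <- strsplit(b[2], ".", fixed = TRUE)[[1]]
    for (pp in list(list(p1, b[2]), list(p2, b[1]))) {
      t <- pp[[1]][1]; s <- pp[[1]][2]
      if (!(t %in% tabn) || !(s %in% names(agents[[t]]$sites)))
        stop("%bind: unknown endpoint '", t, ".", s, "'", call. = FALSE)
      agents[[t]]$sites[[s]]$binds <- unique(c(agents[[t]]$sites[[s]]$binds, pp[[2]]))
    }
  }
  if (is.na(scaffold) && "Ste5" %in% tabn) scaffold <- "Ste5"
  agents <- lapply(agents, function(a) agent_sig(a$name, a$sites))
  m <- model_spec(agents = agents, rules = rules, init = init,
                  observables = obs, scaffold = scaffold, vars = vars)
  if (length(unsupported)) {
    attr(m, "unsupported") <- unsupported
    warning("unsupported declarations were ignored:\n  ",
            paste(unsupported, collapse = "\n  "), call. = FALSE)
  }
  m
}

#' Write a model back to its text dialect
#' @param model a `ps_model`
#' @param file optional path; when `NULL` the text is returned invisibly
#' @return the model source text, invisibly
#' @export
write_model <- function(model, file = NULL) {
  out <- character(0)
  for (a in model$agents) {
    sites <- vapply(names(a$sites), function(sn) {
      st <- a$sites[[sn]]$states
      paste0(sn, if (length(st)) paste0("~", paste(st, collapse = "~")) else "")
    }, "")
    out <- c(out, sprintf("%%agent: %s(%s)", a$name, paste(sites, collapse = ",")))
  }
  seen <- character(0)
  for (a in model$agents) for (sn in names(a$sites)) {
    for (b in a$sites[[sn]]$binds) {
      key <- paste(sort(c(paste0(a$name, ".", sn), b)), collapse = " ")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        out <- c(out, paste0("%bind: ", key))
      }
    }
  }
  if (!is.na(model$scaffold))
    out <- c(out, paste0("%scaffold: ", model$scaffold))
  for (i in model$init)
    out <- c(out, sprintf("%%init: %d %s", i$copies, i$pattern))
  for (nm in names(model$obs))
    out <- c(out, sprintf("%%obs: '%s' %s", nm, model$obs[[nm]]))
  for (r in model$rules)
    out <- c(out, sprintf("'%s' %s -> %s @ %.17g", r$name, r$lhs, r$rhs, r$rate))
  txt <- paste(out, collapse = "\n")
  if (!is.null(file)) writeLines(txt, file) else txt
  invisible(txt)
}

# ------------------------------------------------- embeddings & rule firing

#' Find all embeddings of a pattern in a mixture
#'
#' Embeddings are injective maps from pattern agents to mixture agents that
#' satisfy every site constraint.  For multi-component patterns all ordered
#' combinations of component embeddings with disjoint images are returned,
#' matching stochastic rate conventions (a symmetric homodimerization
#' pattern on n monomers yields n(n-1) ordered embeddings).
#'
#' @param model a `ps_model`
#' @param pattern pattern string in the rule dialect
#' @param mixture a mixture object (see [make_mixture()])
#' @return integer matrix, one row per embedding, columns = pattern agents
#'   in written order, entries 1-based mixture agent indices
#' @export
find_embeddings <- function(model, pattern, mixture) {
  cm <- ps_compile(model)
  tab <- model_tables(model)
  pp <- parse_pattern_text(pattern)
  cp <- compile_pattern(pp, tab)
  if (length(cp$comps) == 0)
    return(matrix(integer(0), ncol = 0))
  per <- lapply(cp$comps, function(comp)
    ps_cpp_component_embeddings(cm, mixture, comp[c("types", "conds", "attach")]))
  combos <- per[[1]]
  if (length(per) > 1) for (k in 2:length(per)) {
    new <- NULL
    for (i in seq_len(nrow(combos))) for (j in seq_len(nrow(per[[k]]))) {
      a <- combos[i, ]; b <- per[[k]][j, ]
      if (!any(b %in% a)) new <- rbind(new, c(a, b))
    }
    combos <- new %||% matrix(integer(0), ncol = ncol(combos) + ncol(per[[k]]))
  }
  orig <- unlist(lapply(cp$comps, `[[`, "orig"))
  out <- combos
  if (nrow(out) > 0) out[, orig] <- combos[, seq_along(orig)]
  else out <- matrix(integer(0), ncol = length(orig))
  out + 1L
}

#' Apply one rule at a chosen embedding
#'
#' @param model a `ps_model`
#' @param mixture mixture object
#' @param rule rule name or index
#' @param embedding integer vector over the rule's left-hand agents in
#'   written order (one row of [find_embeddings()] on the lhs pattern)
#' @return the updated mixture
#' @export
apply_rule <- function(model, mixture, rule, embedding) {
  cm <- ps_compile(model)
  ri <- if (is.character(rule)) match(rule, vapply(cm$rules, `[[`, "", "name")) else rule
  if (is.na(ri) || ri < 1 || ri > length(cm$rules)) stop("no such rule: ", rule)
  r <- cm$rules[[ri]]
  emb <- as.integer(embedding)[r$orig] # written order -> compiled order
  st <- ps_cpp_apply(cm, mixture, ri - 1L, emb - 1L)
  structure(st, class = "ps_mixture")
}
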