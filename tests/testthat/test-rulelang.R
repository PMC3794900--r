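# parser, pattern embedding semantics and rule application

test_that("empty source parses to an empty model", {
  m <- parse_model(text = "")
  expect_equal(n_rules(m), 0)
  expect_equal(n_agent_types(m), 0)
})

test_that("models round-trip through the writer", {
  m <- parse_model(text = paste(
    "%agent: A(x,s~u~p)", "%agent: B(y)",
    "%bind: A.x B.y",
    "%init: 5 A()", "%init: 7 B()",
    "%obs: 'bound' A(x!_)",
    "'bind' A(x),B(y) -> A(x!1),B(y!1) @ 0.002",
    "'mod' A(x!_,s~u) -> A(x!_,s~p) @ 0.5",
    sep = "\n"))
  m2 <- parse_model(text = write_model(m))
  expect_equal(names(m2$agents), names(m$agents))
  expect_equal(vapply(m2$rules, `[[`, "", "name"),
               vapply(m$rules, `[[`, "", "name"))
  expect_equal(vapply(m2$rules, `[[`, 1, "rate"),
               vapply(m$rules, `[[`, 1, "rate"))
  expect_equal(lapply(m2$init, `[[`, "copies"), lapply(m$init, `[[`, "copies"))
  expect_equal(unname(unlist(m2$obs)), unname(unlist(m$obs)))
  # the full pheromone fixture also round-trips
  e <- build_ensemble_model(0.1)
  e2 <- parse_model(text = write_model(e))
  expect_equal(n_rules(e2), n_rules(e))
  expect_equal(vapply(e2$rules, `[[`, 1, "rate"), vapply(e$rules, `[[`, 1, "rate"))
})

test_that("parser reports errors with context and rejects bad input", {
  expect_error(parse_model(text = "'r' A(x) -> A(x!1) @ 1"),
               "undeclared|label")
  expect_error(parse_model(text = paste("%agent: A(x)",
                                        "'r' A(z) -> A(z) @ 1", sep = "\n")),
               "site")
  expect_error(parse_model(text = paste("%agent: A(x)",
                                        "'r' A(x) -> A(x) @ -2", sep = "\n")),
               "rate")
  expect_warning(parse_model(text = paste("%agent: A(x)",
                                          "%token: weird", sep = "\n")),
                 "unsupported")
})

test_that("bidirectional rules expand into forward and reverse", {
  m <- parse_model(text = paste(
    "%agent: A(x)", "%agent: B(y)",
    "'b' A(x),B(y) <-> A(x!1),B(y!1) @ 1e-3, 0.2", sep = "\n"))
  expect_equal(n_rules(m), 2)
  expect_equal(m$rules[[2]]$rate, 0.2)
})

test_that("embedding counts follow stochastic conventions", {
  m <- build_ensemble_model(0.1)
  mix <- pleioscope:::new_mixture(integer(0), integer(0), integer(0))
  free5 <- parse_model(text = paste(
    "%agent: Ste5(s4,dim,s11,s7,f3)", "%init: 50 Ste5()", sep = "\n"))
  mix50 <- make_mixture(free5)
  emb <- find_embeddings(free5, "Ste5()", mix50)
  expect_equal(nrow(emb), 50)
  dimpat <- "Ste5(dim),Ste5(dim)"
  emb2 <- find_embeddings(free5, dimpat, mix50)
  expect_equal(nrow(emb2), 50 * 49) # ordered embeddings
})

test_that("embedding enumeration agrees with the brute-force matcher", {
  m <- toy_tri_model()
  set.seed(21)
  pats <- c("P()", "P(s~p)", "P(b!_)", "P(a!1).Q(a!1)",
            "P(b!1).P(b!1)", "Q(c!1).R(c!1)", "P(a!1).Q(a!1,c!2).R(c!2)",
            "P(),Q()", "P(b!1).P(b!1),R()")
  for (rep in 1:6) {
    pieces <- replicate(sample(2:4, 1), random_tri_complex(m, sample(1:4, 1)),
                        simplify = FALSE)
    type <- integer(0); state <- integer(0); bond <- integer(0)
    for (p in pieces) {
      shift <- length(state)
      b <- p$bond; b[b >= 0] <- b[b >= 0] + shift
      type <- c(type, p$type); state <- c(state, p$state); bond <- c(bond, b)
    }
    mix <- pleioscope:::new_mixture(type, state, bond)
    for (pat in pats) {
      got <- find_embeddings(m, pat, mix)
      want <- brute_embeddings(m, pat, mix)
      expect_equal(nrow(got), nrow(want), info = pat)
      if (nrow(got) > 0) {
        key <- function(M) sort(apply(M, 1, paste, collapse = ","))
        expect_equal(key(got), key(want), info = pat)
      }
    }
  }
})

test_that("rule application updates bonds, states and bookkeeping", {
  m <- toy_ab_model(nA = 2, nB = 1)
  mix <- make_mixture(m)
  emb <- find_embeddings(m, "A(x),B(y)", mix)
  out <- apply_rule(m, mix, "bind", emb[1, ])
  comp <- mixture_components(m, out)
  expect_setequal(comp$size, c(2, 1))
  expect_equal(sum(comp$size * comp$copies), 3)

  # stale embedding: the same bond cannot be made twice
  expect_error(apply_rule(m, out, "bind", emb[1, ]), "stale")
})

test_that("degradation frees the partner site", {
  m <- parse_model(text = paste(
    "%agent: A(x)", "%agent: B(y)", "%bind: A.x B.y",
    "%init: 1 A(x!1).B(y!1)",
    "'deg' A(x!1).B(y!1) -> A(x) @ 1", sep = "\n"))
  mix <- make_mixture(m)
  emb <- find_embeddings(m, "A(x!1).B(y!1)", mix)
  out <- apply_rule(m, mix, "deg", emb[1, ])
  comp <- mixture_components(m, out)
  expect_equal(nrow(comp), 1)
  expect_equal(comp$size, 1)
  expect_equal(comp$species, "A()")
})

test_that("state-change rules alter exactly one complex", {
  m <- toy_tri_model()
  mix <- structure_from_pattern(m, "P(a!1,s~u).Q(a!1).P()")
  before <- mixture_components(m, mix)$species
  mm <- parse_model(text = paste(
    "%agent: P(a,b,s~u~p)", "%agent: Q(a,c)", "%bind: P.a Q.a",
    "'ph' P(a!_,s~u) -> P(a!_,s~p) @ 1", sep = "\n"))
  emb <- find_embeddings(mm, "P(a!_,s~u)", mix)
  expect_equal(nrow(emb), 1)
  out <- apply_rule(mm, mix, "ph", emb[1, ])
  after <- mixture_components(mm, out)$species
  expect_equal(length(setdiff(before, after)), 1)
  expect_equal(length(setdiff(after, before)), 1)
})

test_that("agent count is conserved by rules without synthesis/degradation", {
  m <- build_ensemble_model(0.05)
  # a mid-signaling state offers embeddings for most rules
  p <- make_protocol(pre_eq_time = 150, post_time = 100, n_branches = 1,
                     snap_times = c(0, 100))
  st <- pleioscope:::pre_equilibrate(m, p, 31)
  st <- add_agents(m, st, "Pher", attr(m, "dose"))
  res <- pleioscope:::run_branch(m, st, p, 32, stimulate = FALSE)
  mix <- structure(res$state, class = "ps_mixture")
  n0 <- length(mix$type)
  cm <- pleioscope:::ps_compile(m)
  nondeg <- which(vapply(cm$rules, function(r)
    !any(r$actions[, 1] %in% c(3L, 4L)), TRUE))
  applied <- 0
  for (ri in nondeg) {
    emb <- find_embeddings(m, m$rules[[ri]]$lhs, mix)
    if (nrow(emb) == 0) next
    out <- apply_rule(m, mix, ri, emb[1, ])
    expect_equal(length(out$type), n0)
    applied <- applied + 1
  }
  expect_gte(applied, 10)
})

test_that("homodimerization carries the symmetry factor", {
  m <- build_ensemble_model(0.1)
  cm <- pleioscope:::ps_compile(m)
  auts <- vapply(cm$rules, `[[`, 1, "aut")
  names(auts) <- vapply(cm$rules, `[[`, "", "name")
  expect_equal(unname(auts["ste5_dim"]), 2)
  expect_equal(unname(auts["ste5_undim"]), 2)
  expect_equal(unname(auts["lig_bind"]), 1)
  mach <- pleioscope:::ps_compile(build_machine_model(0.1))
  mauts <- setNames(vapply(mach$rules, `[[`, 1, "aut"),
                    vapply(mach$rules, `[[`, "", "name"))
  expect_equal(unname(mauts["ste5_dim"]), 2) # swap of the two loaded halves
  expect_equal(unname(mauts["ste5_undim"]), 2)
})
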