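# canonical identity, isomorphism, and component extraction

test_that("canonical form of a free agent ignores construction details", {
  m <- build_ensemble_model(0.1)
  a <- structure_from_pattern(m, "Ste5()")
  b <- structure_from_pattern(m, "Ste5(s4,dim,s11,s7,f3)")
  expect_identical(canonical_form(m, a), canonical_form(m, b))
})

test_that("canonical form is invariant under agent permutations", {
  m <- toy_tri_model()
  set.seed(42)
  for (rep in 1:40) {
    cx <- random_tri_complex(m, n_agents = sample(2:6, 1))
    ref <- canonical_form(m, cx)
    for (k in 1:3) {
      perm <- sample(length(cx$type))
      expect_identical(canonical_form(m, permute_mixture(m, cx, perm)), ref)
    }
  }
})

test_that("canonical equality agrees with brute-force isomorphism", {
  m <- toy_tri_model()
  set.seed(7)
  pool <- replicate(25, random_tri_complex(m, n_agents = sample(3:6, 1)),
                    simplify = FALSE)
  for (i in 1:60) {
    pair <- sample(length(pool), 2, replace = TRUE)
    a <- pool[[pair[1]]]; b <- pool[[pair[2]]]
    expect_identical(is_isomorphic(m, a, b), brute_isomorphic(m, a, b))
  }
  # relabelings must always be isomorphic
  for (i in 1:20) {
    a <- pool[[sample(length(pool), 1)]]
    b <- permute_mixture(m, a, sample(length(a$type)))
    expect_true(brute_isomorphic(m, a, b))
    expect_true(is_isomorphic(m, a, b))
  }
})

test_that("canonical form rejects disconnected input", {
  m <- toy_ab_model()
  two <- structure_from_pattern(m, "A(),A()")
  expect_error(canonical_form(m, two), "disconnected")
})

test_that("isomorphism is an equivalence relation on random samples", {
  m <- toy_tri_model()
  set.seed(3)
  pool <- replicate(12, random_tri_complex(m, sample(2:5, 1)), simplify = FALSE)
  keys <- vapply(pool, function(c) canonical_form(m, c), "")
  for (i in seq_along(pool)) {
    expect_true(is_isomorphic(m, pool[[i]], pool[[i]]))
    for (j in seq_along(pool)) {
      expect_equal(is_isomorphic(m, pool[[i]], pool[[j]]),
                   is_isomorphic(m, pool[[j]], pool[[i]]))
      for (k in seq_along(pool))
        if (keys[i] == keys[j] && keys[j] == keys[k])
          expect_true(keys[i] == keys[k])
    }
  }
})

test_that("components aggregates copies and conserves agents", {
  m <- toy_ab_model(nA = 10, nB = 0)
  mix <- make_mixture(m)
  comp <- mixture_components(m, mix)
  expect_equal(nrow(comp), 1)
  expect_equal(comp$copies, 10)

  m2 <- parse_model(text = paste(
    "%agent: A(x)", "%agent: B(y)", "%bind: A.x B.y",
    "%init: 3 A(x!1).B(y!1)", "%init: 2 A()", sep = "\n"))
  comp2 <- mixture_components(m2, make_mixture(m2))
  expect_setequal(comp2$copies, c(3, 2))
  expect_equal(sum(comp2$size * comp2$copies), 8)
})

test_that("component counts match a union-find oracle on random graphs", {
  m <- toy_tri_model()
  set.seed(12)
  for (rep in 1:10) {
    # union several random complexes and free agents into one mixture
    pieces <- replicate(sample(2:5, 1), random_tri_complex(m, sample(1:5, 1)),
                        simplify = FALSE)
    type <- integer(0); state <- integer(0); bond <- integer(0)
    for (p in pieces) {
      shift <- length(state)
      b <- p$bond
      b[b >= 0] <- b[b >= 0] + shift
      type <- c(type, p$type); state <- c(state, p$state); bond <- c(bond, b)
    }
    mix <- pleioscope:::new_mixture(type, state, bond)
    comp <- mixture_components(m, mix)
    expect_equal(sum(comp$copies), uf_components(m, mix))
    expect_equal(sum(comp$size * comp$copies), length(type))
  }
})

test_that("canonical strings round-trip through species_structure", {
  m <- build_ensemble_model(0.1)
  txts <- c("Ste5(dim!1).Ste5(dim!1,s11!2).Ste11(b5!2,st~p)",
            "Fus3(T~p,Y~p)",
            "Gpa1(g4!1,nuc~gtp).Ste4(gpa!1,s20!2).Ste20(b4!2)")
  for (tx in txts) {
    cx <- structure_from_pattern(m, tx)
    key <- canonical_form(m, cx)
    back <- species_structure(m, key)
    expect_identical(canonical_form(m, back), key)
  }
})

test_that("snapshot series survive JSON-lines round trips", {
  m <- toy_ab_model(nA = 20, nB = 20)
  s <- run_simulation(m, short_protocol(post = 20, branches = 1), seed = 5)
  f <- tempfile(fileext = ".jsonl")
  write_snapshots(s, f)
  back <- read_snapshots(f)
  expect_equal(back$times, s$times)
  for (i in seq_along(s$times)) {
    expect_setequal(back$species[[i]]$species, s$species[[i]]$species)
    expect_equal(sum(back$species[[i]]$copies), sum(s$species[[i]]$copies))
  }
})
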