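# in-silico TAP/MS: bait-prey counts, socio-affinity, Markov clustering

test_that("spoke and matrix counts follow the purification semantics", {
  m <- parse_model(text = paste(
    "%agent: A(x)", "%agent: B(y,z)", "%agent: C(w)",
    "%bind: A.x B.y", "%bind: B.z C.w",
    "%init: 1 A(x!1).B(y!1)", sep = "\n"))
  s <- run_simulation(m, make_protocol(pre_eq_time = 0, post_time = 1,
                                       n_branches = 1, snap_times = 1,
                                       dose = 0),
                      seed = 1, stimulate = FALSE)
  bp <- extract_bait_prey(m, list(s))
  expect_equal(bp$spoke["A", "B"], 1)
  expect_equal(bp$spoke["B", "A"], 1)
  expect_equal(sum(bp$matrix), 0)

  m2 <- parse_model(text = paste(
    "%agent: A(x)", "%agent: B(y,z)", "%agent: C(w)",
    "%bind: A.x B.y", "%bind: B.z C.w",
    "%init: 2 A(x!1).B(y!1,z!2).C(w!2)", sep = "\n"))
  s2 <- run_simulation(m2, make_protocol(pre_eq_time = 0, post_time = 1,
                                         n_branches = 1, snap_times = 1,
                                         dose = 0),
                       seed = 1, stimulate = FALSE)
  bp2 <- extract_bait_prey(m2, list(s2))                 # copy-weighted
  expect_equal(bp2$spoke["A", "B"], 2)
  expect_equal(bp2$spoke["A", "C"], 2)
  expect_equal(bp2$matrix["B", "C"], 2)  # co-retrieved under bait A
  expect_equal(bp2$matrix["C", "B"], 2)
  bp2u <- extract_bait_prey(m2, list(s2), weight_by_copies = FALSE)
  expect_equal(bp2u$spoke["A", "B"], 1)
})

test_that("counts from a mixed snapshot match an exhaustive recount", {
  m <- toy_tri_model()
  set.seed(31)
  pieces <- replicate(6, random_tri_complex(m, sample(1:5, 1)), simplify = FALSE)
  sets <- lapply(pieces, function(p) mixture_components(m, p))
  fake <- structure(list(parent = 1L, branch = 1L, condition = "pheromone",
                         times = 1, species = list(do.call(rbind, sets)),
                         obs = data.frame(time = 1), events = 0),
                    class = "ps_series")
  bp <- extract_bait_prey(m, list(fake))
  # brute force over complexes
  spoke <- matrix(0, 3, 3, dimnames = list(names(m$agents), names(m$agents)))
  df <- do.call(rbind, sets)
  cnt <- species_agent_counts(m, df$species)
  for (r in seq_len(nrow(df))) {
    pres <- colnames(cnt)[cnt[r, ] > 0]
    for (b in pres) for (q in setdiff(pres, b))
      spoke[b, q] <- spoke[b, q] + df$copies[r]
  }
  expect_equal(bp$spoke, spoke, ignore_attr = TRUE)
})

test_that("socio-affinity is zero at the null, negative for avoidance, symmetric", {
  types <- c("A", "B", "C")
  # rank-one count matrices sit exactly at the random-assortment null
  # (observed = row-marginal * column-marginal / total for every pair)
  sp <- outer(c(2, 3, 4), c(5, 6, 7))
  dimnames(sp) <- list(types, types)
  w <- c(2, 4, 6)
  mt <- outer(w, w)
  dimnames(mt) <- list(types, types)
  bp <- structure(list(spoke = sp, matrix = mt,
                       purifications = setNames(rep(3, 3), types),
                       types = types), class = "ps_baitprey")
  sa <- socio_affinity(bp)
  expect_true(all(abs(sa$sa[upper.tri(sa$sa)]) < 1e-9))
  expect_identical(sa$sa, t(sa$sa))
  # a pair retrieved far below its expectation scores negative
  sp2 <- sp; sp2["A", "B"] <- 1; sp2["B", "A"] <- 1
  mt2 <- mt; mt2["A", "B"] <- mt2["B", "A"] <- 1
  bp2 <- structure(list(spoke = sp2, matrix = mt2,
                        purifications = setNames(rep(3, 3), types),
                        types = types), class = "ps_baitprey")
  sa2 <- socio_affinity(bp2)
  expect_lt(sa2$sa["A", "B"], 0)
})

test_that("MCL recovers block structure and boundary partitions", {
  # two disconnected 3-cliques
  M <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  M[1:3, 1:3] <- 1; M[4:6, 4:6] <- 1
  p <- mcl_cluster(M, inflation = 2)
  expect_length(p$members, 2)
  expect_setequal(lapply(p$members, sort), list(1:3, 4:6))
  # identity similarities: all singletons
  p2 <- mcl_cluster(diag(5), inflation = 2)
  expect_length(p2$members, 5)
  # planted two-block with weak cross-links, vs exhaustive best cut on 6 nodes
  set.seed(2)
  W <- matrix(runif(36, 0, 0.05), 6, 6)
  W[1:3, 1:3] <- W[1:3, 1:3] + 1
  W[4:6, 4:6] <- W[4:6, 4:6] + 1
  W <- (W + t(W)) / 2
  p3 <- mcl_cluster(W, inflation = 2)
  expect_setequal(lapply(p3$members, sort), list(1:3, 4:6))
  # brute force: among all nontrivial bipartitions of the 6 nodes, the
  # planted cut minimizes the ratio cut (between-weight / |A||B|)
  best <- NULL; best_score <- Inf
  parts <- expand.grid(rep(list(1:2), 5))
  for (r in seq_len(nrow(parts))) {
    lab <- c(1, as.integer(parts[r, ]))
    if (length(unique(lab)) < 2) next
    between <- sum(W[outer(lab, lab, "!=")]) / 2
    score <- between / (sum(lab == 1) * sum(lab == 2))
    if (score < best_score) { best_score <- score; best <- lab }
  }
  expect_equal(unname(split(1:6, best)), unname(lapply(p3$members, sort)))
})

test_that("rand index compares partitions sensibly", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(rand_index(c(1, 1, 1), c(1, 2, 3)), 0)
  expect_lt(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 1)
})
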