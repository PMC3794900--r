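# reachable-species enumeration and combinatorial state counting

test_that("a single binding rule yields exactly three species", {
  m <- parse_model(text = paste(
    "%agent: A(x)", "%agent: B(y)", "%bind: A.x B.y",
    "%init: 5 A()", "%init: 5 B()",
    "'bind' A(x),B(y) -> A(x!1),B(y!1) @ 1", sep = "\n"))
  sp <- enumerate_species(m)
  expect_length(sp, 3)
  expect_setequal(as.character(sp), c("A()", "B()", "A(x!1).B(y!1)"))
})

test_that("enumeration is independent of initial copy numbers", {
  base <- paste(
    "%agent: A(x,s~u~p)", "%agent: B(y)", "%bind: A.x B.y",
    "'bind' A(x),B(y) -> A(x!1),B(y!1) @ 1",
    "'unbind' A(x!1).B(y!1) -> A(x),B(y) @ 1",
    "'mod' A(x!_,s~u) -> A(x!_,s~p) @ 1", sep = "\n")
  m1 <- parse_model(text = paste("%init: 1 A()", "%init: 1 B()", base, sep = "\n"))
  m2 <- parse_model(text = paste("%init: 50 A()", "%init: 9 B()", base, sep = "\n"))
  expect_setequal(as.character(enumerate_species(m1)),
                  as.character(enumerate_species(m2)))
})

test_that("the species cap triggers the overflow flag", {
  m <- build_ensemble_model(0.02)
  expect_warning(sp <- enumerate_species(m, max_species = 30), "lower bound")
  expect_true(attr(sp, "overflow"))
  expect_lte(length(sp), 30)
})

test_that("closed-form scaffold counts match small cases and enumeration", {
  # one scaffold, two independent binary sites (no dimerization)
  m <- parse_model(text = paste(
    "%agent: S(a,b)", "%agent: X(s)", "%agent: Y(s)",
    "%bind: S.a X.s", "%bind: S.b Y.s",
    "%scaffold: S",
    "%init: 2 S()", "%init: 2 X()", "%init: 2 Y()",
    "'ax' S(a),X(s) -> S(a!1),X(s!1) @ 1",
    "'ax2' S(a!1).X(s!1) -> S(a),X(s) @ 1",
    "'by' S(b),Y(s) -> S(b!1),Y(s!1) @ 1",
    "'by2' S(b!1).Y(s!1) -> S(b),Y(s) @ 1", sep = "\n"))
  cnt <- count_scaffold_states(m)
  expect_equal(cnt$per_protomer, 4) # 2 x 2 occupancies
  expect_equal(cnt$total, 4)
  sp <- enumerate_species(m)
  scaffolded <- sp[grepl("S\\(", sp)]
  expect_length(scaffolded, 4)

  # homodimerizing scaffold with one k-state partner: k(k+1)/2 dimers
  m2 <- parse_model(text = paste(
    "%agent: S(d,a)", "%agent: X(s,q~a~b~c)",
    "%bind: S.d S.d", "%bind: S.a X.s",
    "%scaffold: S",
    "%init: 4 S()", "%init: 4 X()",
    "'dim' S(d),S(d) -> S(d!1),S(d!1) @ 1",
    "'undim' S(d!1).S(d!1) -> S(d),S(d) @ 1",
    "'ax' S(a),X(s) -> S(a!1),X(s!1) @ 1",
    "'axr' S(a!1).X(s!1) -> S(a),X(s) @ 1",
    "'cyc' X(q~a) -> X(q~b) @ 1",
    "'cyc2' X(q~b) -> X(q~c) @ 1",
    "'cyc3' X(q~c) -> X(q~a) @ 1", sep = "\n"))
  cnt2 <- count_scaffold_states(m2)
  P <- 1 + 3 # free or X in one of 3 states
  expect_equal(cnt2$per_protomer, P)
  expect_equal(cnt2$dimer, P * (P + 1) / 2)
  expect_equal(cnt2$total, P + P * (P + 1) / 2)
  sp2 <- enumerate_species(m2)
  expect_equal(sum(grepl("S\\(", sp2)), cnt2$total)
})

test_that("every simulated complex is contained in the enumerated set", {
  m <- build_machine_model(0.01) # complete closure is feasible here
  sp <- enumerate_species(m, max_species = 20000)
  expect_false(attr(sp, "overflow"))
  p <- make_protocol(pre_eq_time = 100, post_time = 200, n_branches = 2,
                     snap_times = c(0, 10, 100, 200))
  series <- branch_population(m, p, seed = 77)
  seen <- unique(unlist(lapply(series, function(s)
    lapply(s$species, `[[`, "species"))))
  expect_true(all(seen %in% as.character(sp)),
              info = paste(setdiff(seen, as.character(sp)), collapse = " | "))
})

test_that("machine reachability is a strict subset of the ensemble family", {
  mach <- build_machine_model(0.01)
  ens <- build_ensemble_model(0.01)
  spm <- enumerate_species(mach, max_species = 20000)
  expect_false(attr(spm, "overflow"))
  expect_true(all(attr(spm, "rule_fired")))
  n_scaffold_mach <- sum(grepl("Ste5\\(", as.character(spm)))
  total_ens <- count_scaffold_states(ens)$total
  expect_lt(n_scaffold_mach, total_ens)
  # an ensemble-reachable species the hierarchy forbids: Ste11 on a
  # monomeric, otherwise bare scaffold
  forbidden <- canonical_form(ens,
    structure_from_pattern(ens, "Ste5(s11!1).Ste11(b5!1)"))
  expect_false(forbidden %in% as.character(spm))
  # count the machine's scaffold-species set for reference: far below the
  # ensemble's combinatorial family
  expect_lt(n_scaffold_mach, total_ens / 10)
})
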