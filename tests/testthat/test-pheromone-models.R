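# fixture builders: scaling, variants, randomization, overexpression

test_that("the ensemble build matches its documented copy table and scale", {
  m <- build_ensemble_model(scale = 1)
  ct <- attr(m, "copy_table")
  expect_equal(unname(ct["Ste5"]), 650)
  m01 <- build_ensemble_model(scale = 0.1)
  expect_equal(unname(attr(m01, "copy_table")),
               unname(round(ct * 0.1)), ignore_attr = TRUE)
  # total initial agents follow the table
  mix <- make_mixture(m01)
  counts <- table(names(m01$agents)[mix$type + 1])
  expect_equal(unname(counts["Fus3"]), unname(round(ct["Fus3"] * 0.1)),
               ignore_attr = TRUE)
  expect_equal(unname(counts["Gpa1"]), unname(round(ct["Gpa1"] * 0.1)),
               ignore_attr = TRUE)
})

test_that("volume scaling divides bimolecular rates and scales the dose", {
  m1 <- build_ensemble_model(scale = 0.1)
  m2 <- build_ensemble_model(scale = 0.05)
  rate <- function(m, nm) {
    i <- match(nm, vapply(m$rules, `[[`, "", "name"))
    m$rules[[i]]$rate
  }
  expect_equal(rate(m2, "lig_bind"), rate(m1, "lig_bind") * 2)
  expect_equal(rate(m2, "lig_unbind"), rate(m1, "lig_unbind")) # unimolecular
  expect_equal(attr(m2, "dose"), as.integer(round(attr(m1, "dose") / 2)))
})

test_that("ensemble and machine rule sets differ only in the assembly block", {
  e <- build_ensemble_model(0.1)
  mc <- build_machine_model(0.1)
  en <- setNames(lapply(e$rules, function(r) r[c("lhs", "rhs", "rate")]),
                 vapply(e$rules, `[[`, "", "name"))
  mn <- setNames(lapply(mc$rules, function(r) r[c("lhs", "rhs", "rate")]),
                 vapply(mc$rules, `[[`, "", "name"))
  expect_setequal(names(en), names(mn))
  changed <- names(en)[!vapply(names(en), function(n)
    identical(en[[n]], mn[[n]]), TRUE)]
  assembly_block <- c("s4_s5_bind", "s4_s5_unbind", "s4_s20_unbind",
                      "ste5_dim", "ste5_undim", "s11_bind", "s11_unbind",
                      "s7_bind", "s7_unbind", "f3_bind")
  expect_true(all(changed %in% assembly_block))
  # agent signatures and initial copies are identical
  expect_identical(write_model(e) == write_model(mc), FALSE)
  expect_identical(names(e$agents), names(mc$agents))
  expect_identical(e$init, mc$init)
})

test_that("every ensemble rule can fire from some reachable state", {
  tiny <- build_ensemble_model(scale = 0.004) # a handful of each agent
  # seed the species-level closure with states sampled by a short
  # stimulated simulation (reachable by construction), so the enumeration
  # reaches the deep phosphorylation/feedback contexts quickly
  p <- make_protocol(pre_eq_time = 100, post_time = 150, n_branches = 1,
                     snap_times = c(50, 150))
  s <- run_simulation(tiny, p, seed = 4)
  seen <- unique(unlist(lapply(s$species, `[[`, "species")))
  sp <- suppressWarnings(
    enumerate_species(tiny, max_species = 1500, extra_seeds = seen))
  fired <- attr(sp, "rule_fired")
  expect_true(all(fired), info = paste(names(fired)[!fired], collapse = ", "))
})

test_that("parameter randomization is seeded and bounded to one decade", {
  m <- build_ensemble_model(0.1)
  r1 <- randomize_parameters(m, seed = 42)
  r2 <- randomize_parameters(m, seed = 42)
  r3 <- randomize_parameters(m, seed = 43)
  rates <- function(x) vapply(x$rules, `[[`, 1, "rate")
  expect_identical(rates(r1), rates(r2))
  expect_false(identical(rates(r1), rates(r3)))
  f <- rates(r1) / rates(m)
  expect_true(all(f >= 0.1 - 1e-12 & f <= 10 + 1e-12))
})

test_that("scaffold overexpression only rescales Ste5 copies", {
  m <- build_ensemble_model(0.1)
  expect_error(overexpress_ste5(m, 0), "factor")
  m12 <- overexpress_ste5(m, 12)
  m60 <- overexpress_ste5(overexpress_ste5(m, 12), 5)
  copies <- function(x, type) {
    mix <- make_mixture(x)
    sum(names(x$agents)[mix$type + 1] == type)
  }
  expect_equal(copies(m12, "Ste5"), copies(m, "Ste5") * 12)
  expect_equal(copies(m60, "Ste5"), copies(m, "Ste5") * 60)
  for (ty in c("Fus3", "Ste7", "Gpa1", "Ste2"))
    expect_equal(copies(m12, ty), copies(m, ty))
  expect_equal(vapply(m12$rules, `[[`, 1, "rate"),
               vapply(m$rules, `[[`, 1, "rate"))
})

test_that("the machine model produces almost no scaffold-free active Ste11", {
  p <- make_protocol(pre_eq_time = 300, post_time = 300, n_branches = 2,
                     snap_times = c(0, 50, 150, 300))
  free_act <- function(model) {
    obs2 <- c(model$obs, S11off = "Ste11(b5,st~p)")
    m2 <- model_spec(agents = model$agents, rules = model$rules,
                     init = model$init, observables = obs2,
                     scaffold = model$scaffold)
    for (a in c("variant", "scale", "ste5_factor", "dose", "ligand"))
      attr(m2, a) <- attr(model, a)
    series <- branch_population(m2, p, seed = 17)
    mean(vapply(series, function(s) mean(s$obs$S11off[s$obs$time >= 50]), 1))
  }
  e <- free_act(build_ensemble_model(0.1))
  mc <- free_act(build_machine_model(0.1))
  expect_lt(mc, 5)       # essentially none
  expect_lt(mc, e / 3)   # far below the ensemble's free active kinase pool
})
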