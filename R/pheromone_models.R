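# Programmatic builders for the scaled-down pheromone-pathway fixtures: an
# "ensemble" variant whose scaffold assembles without ordering constraints,
# and a "machine" variant whose hierarchical assembly rules funnel the
# system toward a decameric Ste5-based signaling machine.  The two rule sets
# differ only in the scaffold-assembly block.

# full-scale initial copy numbers (molecules per cell, rounded literature
# measurements for the pathway proteins; Ste5 abundance estimates span
# roughly 500 (tag-based) to 1300+ (consolidated proteome quantifications),
# so a mid-range value is used) and the saturating ligand dose
ps_copy_table <- c(Ste2 = 6000, Gpa1 = 2500, Ste4 = 2000, Ste20 = 2500,
                   Ste5 = 650, Ste11 = 2000, Ste7 = 1000, Fus3 = 8000)
ps_full_dose <- 6000

# baseline stochastic rate constants at full scale; "bimol" rates are per
# pair per second and are divided by the copy-number scale (volume scaling)
ps_base_rates <- function() {
  list(
    # ligand / receptor
    list("lig_bind",     "Pher(r),Ste2(l)",  "Pher(r!1),Ste2(l!1)", 3e-4, TRUE),
    list("lig_unbind",   "Pher(r!1),Ste2(l!1)", "Pher(r),Ste2(l)",  5e-2, FALSE),
    # G-protein cycle: occupied receptor catalyses GDP->GTP exchange on the
    # heterotrimer; GTP-loaded Gpa1 releases Ste4; hydrolysis resets it
    list("g_activate",   "Ste2(l!_),Gpa1(g4!1,nuc~gdp).Ste4(gpa!1)",
                         "Ste2(l!_),Gpa1(g4!1,nuc~gtp).Ste4(gpa!1)", 1e-4, TRUE),
    list("g_dissoc",     "Gpa1(g4!1,nuc~gtp).Ste4(gpa!1)",
                         "Gpa1(g4,nuc~gtp),Ste4(gpa)",               1,    FALSE),
    list("g_hydrolysis", "Gpa1(nuc~gtp)", "Gpa1(nuc~gdp)",           5e-2, FALSE),
    list("g_reassoc",    "Gpa1(g4,nuc~gdp),Ste4(gpa)",
                         "Gpa1(g4!1,nuc~gdp),Ste4(gpa!1)",           2e-4, TRUE),
    # Ste4-Ste20 dimer
    list("s4_s20_bind",  "Ste4(s20),Ste20(b4)", "Ste4(s20!1),Ste20(b4!1)", 1e-4, TRUE),
    list("s4_s20_unbind","Ste4(s20!1).Ste20(b4!1)", "Ste4(s20),Ste20(b4)", 1e-1, FALSE),
    # scaffold assembly block (replaced wholesale in the machine variant)
    list("s4_s5_bind",   "Ste4(gpa,s5),Ste5(s4)", "Ste4(gpa,s5!1),Ste5(s4!1)", 2e-4, TRUE),
    list("s4_s5_unbind", "Ste4(s5!1).Ste5(s4!1)", "Ste4(s5),Ste5(s4)", 1e-1, FALSE),
    list("ste5_dim",     "Ste5(dim),Ste5(dim)", "Ste5(dim!1),Ste5(dim!1)", 1e-3, TRUE),
    list("ste5_undim",   "Ste5(dim!1).Ste5(dim!1)", "Ste5(dim),Ste5(dim)", 3e-2, FALSE),
    list("s11_bind",     "Ste11(b5),Ste5(s11)", "Ste11(b5!1),Ste5(s11!1)", 1e-4, TRUE),
    list("s11_unbind",   "Ste11(b5!1).Ste5(s11!1)", "Ste11(b5),Ste5(s11)", 1e-1, FALSE),
    list("s7_bind",      "Ste7(b5),Ste5(s7)", "Ste7(b5!1),Ste5(s7!1)", 1e-4, TRUE),
    list("s7_unbind",    "Ste7(b5!1).Ste5(s7!1)", "Ste7(b5),Ste5(s7)", 1e-1, FALSE),
    list("f3_bind",      "Fus3(b5),Ste5(f3)", "Fus3(b5!1),Ste5(f3!1)", 1e-4, TRUE),
    list("f3_unbind",    "Fus3(b5!1).Ste5(f3!1)", "Fus3(b5),Ste5(f3)", 5e-1, FALSE),
    # context-dependent phosphorylation chain on the scaffold
    list("s11_act",
         "Ste5(s4!1,s11!2).Ste4(gpa,s5!1,s20!3).Ste20(b4!3).Ste11(b5!2,st~u)",
         "Ste5(s4!1,s11!2).Ste4(gpa,s5!1,s20!3).Ste20(b4!3).Ste11(b5!2,st~p)", 3, FALSE),
    list("s7_act_cis",
         "Ste5(s11!1,s7!2).Ste11(b5!1,st~p).Ste7(b5!2,st~u)",
         "Ste5(s11!1,s7!2).Ste11(b5!1,st~p).Ste7(b5!2,st~p)", 3, FALSE),
    list("s7_act_trans",
         "Ste5(s11!1,dim!2).Ste11(b5!1,st~p).Ste5(dim!2,s7!3).Ste7(b5!3,st~u)",
         "Ste5(s11!1,dim!2).Ste11(b5!1,st~p).Ste5(dim!2,s7!3).Ste7(b5!3,st~p)", 3, FALSE),
    list("f3_phos_T_cis",
         "Ste5(s7!1,f3!2).Ste7(b5!1,st~p).Fus3(b5!2,T~u)",
         "Ste5(s7!1,f3!2).Ste7(b5!1,st~p).Fus3(b5!2,T~p)", 3, FALSE),
    list("f3_phos_Y_cis",
         "Ste5(s7!1,f3!2).Ste7(b5!1,st~p).Fus3(b5!2,T~p,Y~u)",
         "Ste5(s7!1,f3!2).Ste7(b5!1,st~p).Fus3(b5!2,T~p,Y~p)", 3, FALSE),
    list("f3_phos_T_trans",
         "Ste5(s7!1,dim!2).Ste7(b5!1,st~p).Ste5(dim!2,f3!3).Fus3(b5!3,T~u)",
         "Ste5(s7!1,dim!2).Ste7(b5!1,st~p).Ste5(dim!2,f3!3).Fus3(b5!3,T~p)", 3, FALSE),
    list("f3_phos_Y_trans",
         "Ste5(s7!1,dim!2).Ste7(b5!1,st~p).Ste5(dim!2,f3!3).Fus3(b5!3,T~p,Y~u)",
         "Ste5(s7!1,dim!2).Ste7(b5!1,st~p).Ste5(dim!2,f3!3).Fus3(b5!3,T~p,Y~p)", 3, FALSE),
    # constitutive phosphatase activity
    list("s11_deact",    "Ste11(st~p)", "Ste11(st~u)", 1e-1, FALSE),
    list("s7_deact",     "Ste7(st~p)",  "Ste7(st~u)",  1e-1, FALSE),
    list("f3_T_dephos",  "Fus3(T~p)",   "Fus3(T~u)",   8e-2, FALSE),
    list("f3_Y_dephos",  "Fus3(Y~p)",   "Fus3(Y~u)",   8e-2, FALSE),
    # negative feedback: active MAPK promotes clearance of free ligand,
    # returning the network to homeostasis within the simulated hour
    list("feedback",     "Fus3(T~p,Y~p),Pher()", "Fus3(T~p,Y~p)", 5e-6, TRUE)
  )
}

# machine variant: the scaffold-assembly block is replaced by a hierarchical
# pathway.  Assembly: a Ste4-Ste20 dimer loads onto Ste5; two loaded
# protomers dimerize; Ste11 binds only to a fully loaded dimer; Ste7 binds a
# protomer only after its Ste11; Fus3 binds only the completed decamer.
# Disassembly mirrors the hierarchy in reverse (last-in-first-out): a
# protomer releases Ste4 only when it carries no kinase, the dimer opens
# only when bare, Ste11 leaves only after Ste7, Ste7 only after Fus3.  This
# context-matched reversibility realizes the hierarchical energy landscape
# that funnels the system toward (and keeps it near) the decameric machine,
# and drastically restricts the reachable species set.  Outside this block
# no rule or rate differs from the ensemble build.
ps_machine_overrides <- function() {
  loaded <- paste0("Ste5(%s,dim!91,s4!92).Ste4(s5!92,s20!93).Ste20(b4!93).",
                   "Ste5(dim!91,s4!94).Ste4(s5!94,s20!95).Ste20(b4!95)")
  decamer <- paste0(
    "Ste5(%s,dim!91,s4!92,s11!96,s7!97).Ste4(s5!92,s20!93).Ste20(b4!93).",
    "Ste11(b5!96).Ste7(b5!97).",
    "Ste5(dim!91,s4!94,s11!98,s7!99).Ste4(s5!94,s20!95).Ste20(b4!95).",
    "Ste11(b5!98).Ste7(b5!99)")
  list(
    s4_s5_bind = list(
      lhs = "Ste4(gpa,s5,s20!_),Ste5(s4)",
      rhs = "Ste4(gpa,s5!1,s20!_),Ste5(s4!1)"),
    s4_s20_unbind = list(
      lhs = "Ste4(s5,s20!1).Ste20(b4!1)",
      rhs = "Ste4(s5,s20),Ste20(b4)"),
    s4_s5_unbind = list(
      lhs = "Ste4(s5!1).Ste5(s4!1,s11,s7,f3)",
      rhs = "Ste4(s5),Ste5(s4,s11,s7,f3)", rate = 1e-2),
    ste5_dim = list(
      lhs = paste0("Ste5(dim,s4!1).Ste4(s5!1,s20!2).Ste20(b4!2),",
                   "Ste5(dim,s4!3).Ste4(s5!3,s20!4).Ste20(b4!4)"),
      rhs = paste0("Ste5(dim!5,s4!1).Ste4(s5!1,s20!2).Ste20(b4!2),",
                   "Ste5(dim!5,s4!3).Ste4(s5!3,s20!4).Ste20(b4!4)")),
    ste5_undim = list(
      lhs = "Ste5(dim!1,s11,s7,f3).Ste5(dim!1,s11,s7,f3)",
      rhs = "Ste5(dim,s11,s7,f3),Ste5(dim,s11,s7,f3)", rate = 1e-2),
    s11_bind = list(
      lhs = paste0("Ste11(b5),", sprintf(loaded, "s11")),
      rhs = paste0("Ste11(b5!2),", sprintf(loaded, "s11!2")), rate = 2e-4),
    s11_unbind = list(
      lhs = "Ste11(b5!1).Ste5(s11!1,s7,f3)",
      rhs = "Ste11(b5),Ste5(s11,s7,f3)", rate = 3e-2),
    s7_bind = list(
      lhs = "Ste7(b5),Ste5(s7,s11!_)",
      rhs = "Ste7(b5!1),Ste5(s7!1,s11!_)", rate = 1.5e-4),
    s7_unbind = list(
      lhs = "Ste7(b5!1).Ste5(s7!1,f3)",
      rhs = "Ste7(b5),Ste5(s7,f3)", rate = 5e-2),
    f3_bind = list(
      lhs = paste0("Fus3(b5),", sprintf(decamer, "f3")),
      rhs = paste0("Fus3(b5!77),", sprintf(decamer, "f3!77")),
      rate = 3e-4)
  )
}

ps_model_text <- function(rules, copies, ste5_factor) {
  agents <- c(
    "%agent: Pher(r)",
    "%agent: Ste2(l)",
    "%agent: Gpa1(g4,nuc~gdp~gtp)",
    "%agent: Ste4(gpa,s5,s20)",
    "%agent: Ste20(b4)",
    "%agent: Ste5(s4,dim,s11,s7,f3)",
    "%agent: Ste11(b5,st~u~p)",
    "%agent: Ste7(b5,st~u~p)",
    "%agent: Fus3(b5,T~u~p,Y~u~p)")
  binds <- c(
    "%bind: Pher.r Ste2.l",
    "%bind: Gpa1.g4 Ste4.gpa",
    "%bind: Ste4.s5 Ste5.s4",
    "%bind: Ste4.s20 Ste20.b4",
    "%bind: Ste5.dim Ste5.dim",
    "%bind: Ste5.s11 Ste11.b5",
    "%bind: Ste5.s7 Ste7.b5",
    "%bind: Ste5.f3 Fus3.b5")
  trimer <- min(copies["Gpa1"], copies["Ste4"])
  init <- c(
    sprintf("%%init: %d Ste2()", copies["Ste2"]),
    sprintf("%%init: %d Gpa1(g4!1,nuc~gdp).Ste4(gpa!1)", trimer),
    if (copies["Gpa1"] > trimer)
      sprintf("%%init: %d Gpa1(nuc~gdp)", copies["Gpa1"] - trimer),
    if (copies["Ste4"] > trimer)
      sprintf("%%init: %d Ste4()", copies["Ste4"] - trimer),
    sprintf("%%init: %d Ste20()", copies["Ste20"]),
    sprintf("%%init: %d Ste5()", round(copies["Ste5"] * ste5_factor)),
    sprintf("%%init: %d Ste11()", copies["Ste11"]),
    sprintf("%%init: %d Ste7()", copies["Ste7"]),
    sprintf("%%init: %d Fus3()", copies["Fus3"]))
  obs <- c(
    "%obs: 'Fus3pp' Fus3(T~p,Y~p)",
    "%obs: 'Gfree' Ste4(gpa)")
  rule_lines <- vapply(rules, function(r)
    sprintf("'%s' %s -> %s @ %.17g", r[[1]], r[[2]], r[[3]], r[[4]]), "")
  paste(c(agents, binds, "%scaffold: Ste5", init, obs, rule_lines),
        collapse = "\n")
}

ps_build <- function(variant, scale, ste5_factor, rate_overrides) {
  if (scale <= 0) stop("scale must be > 0")
  if (ste5_factor <= 0) stop("ste5_factor must be > 0")
  rules <- ps_base_rates()
  if (variant == "machine") {
    ov <- ps_machine_overrides()
    for (i in seq_along(rules)) {
      nm <- rules[[i]][[1]]
      if (nm %in% names(ov)) {
        o <- ov[[nm]]
        if (!is.null(o$lhs)) { rules[[i]][[2]] <- o$lhs; rules[[i]][[3]] <- o$rhs }
        if (!is.null(o$rate)) rules[[i]][[4]] <- o$rate
      }
    }
  }
  for (i in seq_along(rules)) {
    nm <- rules[[i]][[1]]
    if (!is.null(rate_overrides) && nm %in% names(rate_overrides))
      rules[[i]][[4]] <- rate_overrides[[nm]]
    if (rules[[i]][[5]]) rules[[i]][[4]] <- rules[[i]][[4]] / scale
  }
  copies <- round(ps_copy_table * scale)
  storage.mode(copies) <- "integer"
  text <- ps_model_text(rules, copies, ste5_factor)
  model <- parse_model(text)
  attr(model, "variant") <- variant
  attr(model, "scale") <- scale
  attr(model, "ste5_factor") <- ste5_factor
  attr(model, "dose") <- as.integer(round(ps_full_dose * scale))
  attr(model, "ligand") <- "Pher"
  attr(model, "copy_table") <- copies
  model
}

#' Build the scaled-down ensemble model of pheromone signaling
#'
#' Agents: pheromone ligand, receptor (Ste2), G-protein subunits (Gpa1,
#' Ste4), the scaffold Ste5 with five binding sites, the kinases Ste20,
#' Ste11, Ste7 and the MAPK Fus3 (two phosphosites).  Scaffold assembly is
#' unordered: Ste5 dimerizes freely and each site binds its partner
#' independently.  Phosphotransfer requires the experimentally characterized
#' molecular context (e.g. Ste11 activation needs a Ste4-Ste20 dimer on the
#' same scaffold protomer; Fus3 phosphorylation needs an active Ste7 on the
#' same or the dimer-partner protomer).  A single negative-feedback rule
#' (active Fus3 clears free ligand) returns the network to homeostasis.
#'
#' Initial copy numbers are `round(scale *` full-scale measured copies`)`
#' (see `pleioscope:::ps_copy_table`); bimolecular per-pair rates are divided
#' by `scale` so that deterministic-limit concentrations are unchanged.
#'
#' @param scale copy-number multiplier relative to measured copies
#'   (default 0.1, the package's study condition)
#' @param ste5_factor scaffold overexpression factor (1 = wild type)
#' @param rate_overrides named list of absolute full-scale rate replacements
#' @return a `ps_model` with attributes `variant`, `scale`, `dose`
#' @export
build_ensemble_model <- function(scale = 0.1, ste5_factor = 1,
                                 rate_overrides = NULL) {
  ps_build("ensemble", scale, ste5_factor, rate_overrides)
}

#' Build the machine-model counterpart
#'
#' Identical to [build_ensemble_model()] except that the scaffold-assembly
#' rules are replaced by a hierarchical pathway: a Ste4-Ste20 dimer loads
#' onto monomeric Ste5; two loaded protomers dimerize; Ste11 binds only when
#' Ste5 has dimerized and both protomers carry a Ste4-Ste20 dimer; Ste7
#' binds a protomer only after its Ste11; Fus3 binds (and is phosphorylated
#' by) only the completed decamer.  Beyond the assembly block no rule or
#' rate differs from the ensemble build, so every Ste5 dimer is
#' automatically a tetramer and hexamer (those patterns occur in identical
#' fractions of the unique species).
#'
#' @inheritParams build_ensemble_model
#' @return a `ps_model`
#' @export
build_machine_model <- function(scale = 0.1, ste5_factor = 1,
                                rate_overrides = NULL) {
  ps_build("machine", scale, ste5_factor, rate_overrides)
}

#' Randomize a model's rate parameters
#'
#' Multiplies every rule's rate constant by an independent log-uniform
#' factor spanning one order of magnitude either way (10^U, U ~
#' Uniform(-1, 1)), mirroring the plausible-range constraint used when the
#' baseline rates were set.  Deterministic per seed.
#'
#' @param model a `ps_model`
#' @param seed integer seed
#' @param decades half-width of the exponent range (default 1)
#' @return a new `ps_model` with perturbed rates
#' @export
randomize_parameters <- function(model, seed, decades = 1) {
  factors <- with_seed(seed, 10^runif(length(model$rules), -decades, decades))
  rules <- model$rules
  for (i in seq_along(rules)) rules[[i]]$rate <- rules[[i]]$rate * factors[i]
  m2 <- model_spec(agents = model$agents, rules = rules, init = model$init,
                   observables = model$obs, scaffold = model$scaffold,
                   vars = model$vars)
  for (a in c("variant", "scale", "ste5_factor", "dose", "ligand", "copy_table"))
    attr(m2, a) <- attr(model, a)
  attr(m2, "rate_factors") <- factors
  m2
}

#' Overexpress the scaffold
#'
#' Multiplies the initial Ste5 copy number by `factor`, leaving every other
#' copy number and every rate untouched.
#'
#' @param model a `ps_model`
#' @param factor positive multiplier (e.g. 12 or 60)
#' @return a new `ps_model`
#' @export
overexpress_ste5 <- function(model, factor) {
  if (factor <= 0) stop("factor must be > 0")
  init <- model$init
  hit <- FALSE
  for (i in seq_along(init)) {
    ag <- parse_pattern_text(init[[i]]$pattern)
    if (length(ag) == 1 && ag[[1]]$type == (model$scaffold %||% "Ste5")) {
      init[[i]]$copies <- as.integer(round(init[[i]]$copies * factor))
      hit <- TRUE
    }
  }
  if (!hit) stop("model has no scaffold init declaration")
  m2 <- model_spec(agents = model$agents, rules = model$rules, init = init,
                   observables = model$obs, scaffold = model$scaffold,
                   vars = model$vars)
  for (a in c("variant", "scale", "dose", "ligand", "copy_table"))
    attr(m2, a) <- attr(model, a)
  attr(m2, "ste5_factor") <- (attr(model, "ste5_factor") %||% 1) * factor
  m2
}
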