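# scaffold filtering, vector encoding, graph edit distance, clustering

ens <- build_ensemble_model(0.1)

test_that("the scaffold-species filter follows the may-bind definition", {
  species <- c("Ste5()", "Pher()", "Ste11()", "Fus3(T~p)",
               "Pher(r!1).Ste2(l!1)",
               "Gpa1(g4!1).Ste4(gpa!1)")
  flags <- vapply(species, function(s) {
    st <- structure_from_pattern(ens, s)
    comp <- mixture_components(ens, st)
    comp$scaffold[1]
  }, TRUE)
  expect_true(flags[["Ste5()"]])       # contains the scaffold
  expect_false(flags[["Pher()"]])      # cannot bind Ste5
  expect_true(flags[["Ste11()"]])      # free kinase could bind a free Ste5
  expect_true(flags[["Fus3(T~p)"]])
  expect_false(flags[["Pher(r!1).Ste2(l!1)"]])
  expect_true(flags[["Gpa1(g4!1).Ste4(gpa!1)"]]) # Ste4's s5 site is free
})

test_that("pattern frequency respects nesting monotonicity and edge cases", {
  species <- c(
    "Ste5()",
    "Ste5(dim!1).Ste5(dim!1)",
    "Ste5(dim!1,s4!2).Ste4(s5!2).Ste5(dim!1)",
    "Ste5(dim!1,s4!2).Ste4(s5!2).Ste5(dim!1,s4!3).Ste4(s5!3)",
    "Ste11()")
  dimer <- "Ste5(dim!1).Ste5(dim!1)"
  tetramer <- "Ste5(dim!1,s4!2).Ste4(s5!2).Ste5(dim!1,s4!3).Ste4(s5!3)"
  expect_equal(pattern_frequency(ens, species, ""), 1)
  f_dim <- pattern_frequency(ens, species, dimer)
  f_tet <- pattern_frequency(ens, species, tetramer)
  expect_equal(f_dim, 3 / 5)
  expect_equal(f_tet, 1 / 5)
  expect_lte(f_tet, f_dim)
})

test_that("vector encodings are canonical and faithful", {
  specs <- c("Ste5()",
             "Ste5(dim!1).Ste5(dim!1)",
             "Ste5(dim!1,s11!2).Ste11(b5!2,st~p).Ste5(dim!1)",
             "Ste5(s4!1).Ste4(s5!1,s20!2,gpa!3).Ste20(b4!2).Gpa1(g4!3,nuc~gtp)",
             "Ste11(st~p)", "Fus3(T~p,Y~u)",
             "Ste20(b4!1).Ste4(s20!1)")
  vs <- lapply(specs, function(s) scaffold_vector(ens, s))
  for (i in seq_along(specs)) for (j in seq_along(specs)) {
    same <- identical(vs[[i]], vs[[j]])
    expect_equal(same, i == j, info = paste(specs[i], specs[j]))
  }
  # protomer order normalization: the two writings of one dimer agree
  a <- scaffold_vector(ens, "Ste5(dim!1,s11!2).Ste11(b5!2).Ste5(dim!1)")
  b <- scaffold_vector(ens, "Ste5(dim!1).Ste5(dim!1,s11!2).Ste11(b5!2)")
  expect_identical(a, b)
})

test_that("graph edit distance has metric behaviour and unit edits", {
  dimer <- "Ste5(dim!1).Ste5(dim!1)"
  dimer11 <- "Ste5(dim!1,s11!2).Ste11(b5!2,st~u).Ste5(dim!1)"
  dimer11p <- "Ste5(dim!1,s11!2).Ste11(b5!2,st~p).Ste5(dim!1)"
  expect_equal(ged(ens, dimer, dimer), 0)
  expect_equal(ged(ens, dimer, dimer11), 1)  # one protein attached
  expect_equal(ged(ens, dimer11, dimer11p), 1) # one state flip
  expect_equal(ged(ens, dimer, dimer11p), 2)
  specs <- c(dimer, dimer11, dimer11p, "Ste5()", "Ste11()", "Fus3()")
  for (a in specs) for (b in specs) {
    expect_equal(ged(ens, a, b), ged(ens, b, a))
    for (cc in specs)
      expect_lte(ged(ens, a, cc), ged(ens, a, b) + ged(ens, b, cc))
  }
})

# brute-force edit-path oracle: BFS over attach/detach-protein and
# flip-state moves within the scaffold family, identified by vector states
test_that("vector distance equals a brute-force edit search on small complexes", {
  # moves operate directly on the 27-slot encoding: any single slot change
  # that yields a valid encoding is one edit; validity = decodable family
  # member (presence hierarchy respected)
  valid <- function(v) {
    # protomer 2 requires protomer 1; decorations require their presence
    # slots; the core block excludes scaffold protomers
    ok <- TRUE
    blocks <- list(v[3:12], v[13:22])
    pres <- c(v[1], v[2])
    for (k in 1:2) {
      b <- blocks[[k]]
      if (pres[k] == 0 && any(b > 0)) ok <- FALSE
      if (b[1] == 0 && (b[2] > 0 || b[3] > 0)) ok <- FALSE # Gpa1/Ste20 need Ste4
      if (b[4] == 0 && b[5] > 0) ok <- FALSE
      if (b[6] == 0 && b[7] > 0) ok <- FALSE
      if (b[8] == 0 && (b[9] > 0 || b[10] > 0)) ok <- FALSE
    }
    if (v[2] == 1 && v[1] == 0) ok <- FALSE
    if (any(v[23:27] > 0) && v[1] > 0) ok <- FALSE
    ok
  }
  ranges <- c(1, 1, rep(c(1, 2, 1, 1, 1, 1, 1, 1, 1, 1), 2), 4, 1, 1, 2, 1)
  neighbours <- function(v) {
    out <- list()
    for (s in seq_along(v)) for (val in 0:ranges[s]) {
      if (val == v[s]) next
      w <- v; w[s] <- val
      if (valid(w)) out[[length(out) + 1]] <- w
    }
    out
  }
  bfs_dist <- function(v0, v1) {
    key <- function(v) paste(v, collapse = ",")
    seen <- new.env(parent = emptyenv())
    queue <- list(list(v = v0, d = 0))
    assign(key(v0), TRUE, seen)
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      if (identical(cur$v, v1)) return(cur$d)
      if (cur$d > 4) next
      for (w in neighbours(cur$v)) {
        k <- key(w)
        if (!exists(k, seen)) {
          assign(k, TRUE, seen)
          queue[[length(queue) + 1]] <- list(v = w, d = cur$d + 1)
        }
      }
    }
    Inf
  }
  pairs <- list(
    c("Ste5()", "Ste5(dim!1).Ste5(dim!1)"),
    c("Ste5(dim!1).Ste5(dim!1)",
      "Ste5(dim!1,s11!2).Ste11(b5!2,st~u).Ste5(dim!1)"),
    c("Ste5(s4!1).Ste4(s5!1)",
      "Ste5(s4!1).Ste4(s5!1,s20!2).Ste20(b4!2)"),
    c("Ste5(dim!1).Ste5(dim!1)",
      "Ste5(dim!1,s11!2).Ste11(b5!2,st~p).Ste5(dim!1)"),
    c("Ste5()",
      "Ste5(s4!1).Ste4(s5!1,s20!2).Ste20(b4!2)"))
  for (pr in pairs) {
    va <- scaffold_vector(ens, pr[1]); vb <- scaffold_vector(ens, pr[2])
    expect_equal(ged(ens, pr[1], pr[2]), bfs_dist(va, vb), info = pr[2])
  }
})

test_that("clustroid clustering satisfies its boundary cases", {
  species <- c("Ste5()",
               "Ste5(dim!1).Ste5(dim!1)",
               "Ste5(dim!1,s11!2).Ste11(b5!2).Ste5(dim!1)",
               "Ste11()", "Ste11(st~p)", "Fus3()")
  pn <- cluster_species(ens, species, cutoff = length(species))
  expect_length(pn$members, length(species))
  expect_equal(sort(pn$clustroid), seq_along(species))
  p1 <- cluster_species(ens, species, cutoff = 1)
  expect_length(p1$members, 1)
  # exhaustive clustroid check: minimal average distance member
  V <- vapply(species, function(s) scaffold_vector(ens, s),
              integer(pleioscope:::ps_vector_length))
  D <- as.matrix(dist(t(V), method = "manhattan"))
  avg <- rowMeans(D)
  expect_equal(unname(avg[p1$clustroid]), min(avg))
})

test_that("planted families are recovered at cutoff 2", {
  fam1 <- c("Ste5()",
            "Ste5(s4!1).Ste4(s5!1)",
            "Ste5(s4!1).Ste4(s5!1,s20!2).Ste20(b4!2)")
  fam2 <- c(paste0("Ste5(dim!1,s4!2,s11!3,s7!4,f3!5).Ste4(s5!2,s20!6).Ste20(b4!6).",
                   "Ste11(b5!3,st~p).Ste7(b5!4,st~p).Fus3(b5!5,T~p,Y~p).",
                   "Ste5(dim!1,s4!7,s11!8,s7!9).Ste4(s5!7,s20!10).Ste20(b4!10).",
                   "Ste11(b5!8,st~p).Ste7(b5!9,st~p)"),
            paste0("Ste5(dim!1,s4!2,s11!3,s7!4).Ste4(s5!2,s20!6).Ste20(b4!6).",
                   "Ste11(b5!3,st~p).Ste7(b5!4,st~p).",
                   "Ste5(dim!1,s4!7,s11!8,s7!9).Ste4(s5!7,s20!10).Ste20(b4!10).",
                   "Ste11(b5!8,st~p).Ste7(b5!9,st~u)"))
  p2 <- cluster_species(ens, c(fam1, fam2), cutoff = 2)
  got <- lapply(p2$members, function(mm) sort(p2$species[mm]))
  expect_setequal(lapply(got, paste, collapse = ";"),
                  list(paste(sort(fam1), collapse = ";"),
                       paste(sort(fam2), collapse = ";")))
})

test_that("conserved pattern size counts shared connected structure", {
  # ten identical 4-protein complexes: conserved size 4
  sp4 <- paste0("Ste5(dim!1,s11!2).Ste11(b5!2,st~", c("u","p"),
                ").Ste5(dim!1,s7!3).Ste7(b5!3,st~", c("u","p"), ")")
  species <- unique(c(
    vapply(1:2, function(i) sp4[i], ""),
    "Ste5(dim!1).Ste5(dim!1)"))
  # cluster with all members containing the Ste5 dimer + Ste11 + Ste7 in
  # two members, bare dimer in one: conserved = the 2-protein dimer
  part <- structure(list(assign = rep(1L, 3), clustroid = 1L,
                         members = list(1:3), species = species,
                         cutoff = 1L, mbcd = numeric(0)),
                    class = "ps_partition")
  expect_equal(conserved_pattern_size(ens, part, min_members = 3), 2)
  # all-identical cluster: full size (4 proteins)
  part2 <- structure(list(assign = rep(1L, 2), clustroid = 1L,
                          members = list(1:2),
                          species = c(sp4[1], sp4[1]),
                          cutoff = 1L, mbcd = numeric(0)),
                     class = "ps_partition")
  expect_error(cluster_species(ens, c(sp4[1], sp4[1]), 1), "unique")
  expect_equal(conserved_pattern_size(ens, part2, min_members = 2), 4)
  # no qualifying cluster -> NA marker
  expect_true(is.na(conserved_pattern_size(ens, part, min_members = 10)))
})
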