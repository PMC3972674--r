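# Rule language: parsing, pattern matching, rule application.

test_that("molecule types, rules and parameters parse", {
  m <- parse_model("
begin molecule types
A(a,a)
B(x~u~p)
end molecule types
begin parameters
kon 0.25
end parameters
begin reaction rules
dim: A(a) + A(a) -> A(a!1).A(a!1) kon
end reaction rules")
  expect_named(m$types, c("A", "B"))
  expect_equal(m$types$A$sites, c("a", "a"))
  expect_equal(m$types$B$mods[[1]], c("u", "p"))
  r <- m$rules[[1]]
  expect_s3_class(r, "srbm_rule")
  expect_equal(r$kind, "bind")
  expect_equal(r$rate, 0.25)
  expect_equal(nrow(r$actions$form), 1L)
})

test_that("an empty rule block yields a model with zero rules", {
  m <- parse_model("
begin molecule types
A(a)
end molecule types
begin reaction rules
end reaction rules")
  expect_length(m$rules, 0L)
})

test_that("parser rejects malformed input with line information", {
  decl <- "begin molecule types\nA(a)\nend molecule types\n"
  expect_error(parse_model("A(a)"), "outside of a block")
  expect_error(parse_model(paste0(decl,
    "begin reaction rules\nA(z) + A(a) -> A(z!1).A(a!1) 1\nend reaction rules")),
    "no site 'z'")
  expect_error(parse_model(paste0(decl,
    "begin reaction rules\nA(a) -> A(a!1) 1\nend reaction rules")),
    "exactly twice")
  expect_error(parse_model(paste0(decl,
    "begin reaction rules\nA(a) + A(a) -> A(a!1).A(a!1).A(a) 1\nend reaction rules")),
    "not conserved|not connected")
  expect_error(parse_model(paste0(decl,
    "begin reaction rules\nA(a) + A(a) <-> A(a!1).A(a!1) 1\nend reaction rules")),
    "two rules")
  expect_error(parse_model(paste0(decl,
    "begin reaction rules\nA(a) + A(a) -> A(a!1).A(a!1) kon\nend reaction rules")),
    "unknown rate parameter")
  expect_error(parse_model("begin molecule types\nA(a)"),
    "unterminated")
})

test_that("switch tags gate rules and default to on", {
  m <- parse_model("
begin molecule types
A(a)
B(b)
end molecule types
begin reaction rules
AB: A(a) + B(b) -> A(a!1).B(b!1) 1.0 @SAC
end reaction rules")
  expect_equal(m$rules[[1]]$switch, "SAC")
  expect_true(m$switches[["SAC"]])
})

test_that("free sites match, bound sites do not", {
  w <- toy_world(1)
  expect_length(match_pattern(parse_pattern("A(a)"), w), 2L)  # two a slots
  rows <- which(w$sites$name == "a")
  w2 <- toy_world(2)
  r1 <- which(w2$sites$particle == 1 & w2$sites$name == "a")[1]
  r2 <- which(w2$sites$particle == 2 & w2$sites$name == "a")[1]
  w2 <- force_bond(w2, r1, r2)
  # per particle one a is bound, one free
  expect_length(match_pattern(parse_pattern("A(a)"), w2), 2L)
  expect_length(match_pattern(parse_pattern("A(a!+)"), w2), 2L)
  expect_length(match_pattern(parse_pattern("A(a!?)"), w2), 4L)
  # fully bound monomer offers no free site
  w3 <- force_bond(w2, which(w2$sites$particle == 1 & w2$sites$name == "a" &
                               is.na(w2$sites$bond)),
                   which(w2$sites$particle == 2 & w2$sites$name == "a" &
                           is.na(w2$sites$bond)))
  expect_length(match_pattern(parse_pattern("A(a)"), w3), 0L)
})

test_that("implicit rule instances: monomer + dimer expose five site pairs", {
  m <- toy_model()
  w <- toy_world(3)
  r1 <- which(w$sites$particle == 1 & w$sites$name == "a")[1]
  r2 <- which(w$sites$particle == 2 & w$sites$name == "a")[1]
  w <- force_bond(w, r1, r2)   # dimer 1-2, monomer 3
  embs <- srbm:::.match_rule_lhs(m$rules[[1]], w)
  # free-a counts 1,1,2: unordered particle pairs give 1 + 2 + 2 instances
  expect_length(embs, 5L)
})

test_that("matching equals brute-force enumeration on small worlds", {
  pats <- list(parse_pattern("A(a)"), parse_pattern("A(a,a)"),
               parse_pattern("A(a!1).A(a!1)"),
               parse_pattern("A(a,b~mod)"),
               parse_pattern("A(a!1,b~none).A(a!1)"))
  for (seed in 1:6) {
    n <- 2L + (seed %% 5L)
    w <- random_toy_world(n, seed = seed)
    for (pat in pats) {
      got <- length(match_pattern(pat, w, dedup = FALSE))
      expect_equal(got, brute_force_count(pat, w),
                   info = sprintf("seed %d n %d", seed, n))
    }
  }
})

test_that("identical-site symmetry: dedup halves the doubled embeddings", {
  w <- toy_world(1)
  pat <- parse_pattern("A(a,a)")
  raw <- match_pattern(pat, w, dedup = FALSE)
  expect_length(raw, 2L)   # the two slot orders
  expect_length(match_pattern(pat, w, dedup = TRUE), 1L)
  # symmetric dimerization does not double its propensity
  w2 <- toy_world(2)
  m <- toy_model()
  raw2 <- srbm:::.match_rule_lhs(m$rules[[1]], w2, dedup = FALSE)
  ded2 <- srbm:::.match_rule_lhs(m$rules[[1]], w2, dedup = TRUE)
  expect_equal(length(raw2), 2L * length(ded2))
})

test_that("anchored matching keeps only embeddings covering the anchor", {
  w <- toy_world(3)
  pat <- parse_pattern("A(a)")
  embs <- match_pattern(pat, w, anchor = 2L)
  expect_true(all(vapply(embs, function(e) 2L %in% e$particles, TRUE)))
  expect_length(embs, 2L)
})

test_that("bind application forms one bond, conserves molecules, logs event", {
  m <- toy_model()
  w <- toy_world(2)
  embs <- srbm:::.match_rule_lhs(m$rules[[1]], w)
  res <- apply_rule(w, m$rules[[1]], embs[[1]])
  expect_true(res$applied)
  expect_equal(nrow(res$events), 1L)
  expect_equal(res$events$action, "formed")
  expect_equal(nrow(bond_list(res$world)), 1L)
  expect_identical(res$world$particles$type, w$particles$type)
  expect_identical(nrow(res$world$particles), nrow(w$particles))
  # untouched sites keep their state
  expect_identical(res$world$sites$mod, w$sites$mod)
})

test_that("context-gated propagation rewrites the neighbour modification only", {
  m <- toy_model(with_nucleation = TRUE)
  w <- toy_world(2, model = m)
  b1 <- which(w$sites$particle == 1 & w$sites$name == "b")
  w$sites$mod[b1] <- "mod"
  a1 <- which(w$sites$particle == 1 & w$sites$name == "a")[1]
  a2 <- which(w$sites$particle == 2 & w$sites$name == "a")[1]
  w <- force_bond(w, a1, a2)
  pass <- m$rules[[2]]
  embs <- srbm:::.match_rule_lhs(pass, w)
  expect_length(embs, 1L)
  res <- apply_rule(w, pass, embs[[1]])
  expect_true(res$applied)
  b2 <- which(w$sites$particle == 2 & w$sites$name == "b")
  expect_equal(res$world$sites$mod[b2], "mod")
  expect_equal(nrow(res$events), 0L)                      # no bond change
  expect_equal(bond_pairs(res$world), bond_pairs(w))
})

test_that("stale embeddings are rejected without mutation", {
  m <- toy_model()
  w <- toy_world(3)
  embs <- srbm:::.match_rule_lhs(m$rules[[1]], w)
  res <- apply_rule(w, m$rules[[1]], embs[[1]])
  # find another embedding touching a site that has just been bound
  used <- res$events$particle_a
  stale <- Filter(function(e) any(used %in% e$particles), embs)
  stale <- Filter(function(e) !srbm:::.embedding_valid(m$rules[[1]], e,
                                                       res$world), stale)
  expect_gt(length(stale), 0L)
  res2 <- apply_rule(res$world, m$rules[[1]], stale[[1]])
  expect_false(res2$applied)
  expect_identical(res2$world$sites, res$world$sites)
})

test_that("a bind rule followed by its unbind inverse restores the site graph", {
  m <- parse_model("
begin molecule types
A(a,a,b~none~mod)
end molecule types
begin reaction rules
grow: A(a) + A(a) -> A(a!1).A(a!1) 1.0
split: A(a!1).A(a!1) -> A(a) + A(a) 1.0
end reaction rules")
  w <- random_toy_world(4, seed = 9)
  before <- w$sites
  embs <- srbm:::.match_rule_lhs(m$rules[[1]], w)
  if (length(embs)) {
    res <- apply_rule(w, m$rules[[1]], embs[[1]])
    ev <- res$events
    # undo exactly the bond just formed
    inv <- Filter(function(e) {
      v <- srbm:::.embedding_valid(m$rules[[2]], e, res$world)
      v && setequal(e$particles, c(ev$particle_a, ev$particle_b))
    }, srbm:::.match_rule_lhs(m$rules[[2]], res$world))
    hit <- FALSE
    for (e in inv) {
      back <- apply_rule(res$world, m$rules[[2]], e)
      if (back$applied && identical(back$world$sites$bond, before$bond)) {
        hit <- TRUE
        break
      }
    }
    expect_true(hit)
  } else skip("random world saturated; nothing to bind")
})

test_that("interaction tables expand to bind rules", {
  df <- data.frame(protein_a = "A", protein_b = "B", site_a = "b",
                   site_b = "a", rate_tag = "", switch_tag = "SAC",
                   stringsAsFactors = FALSE)
  rules <- interactions_to_rules(read_interaction_table(df))
  expect_length(rules, 1L)
  expect_equal(rules[[1]]$kind, "bind")
  expect_equal(rules[[1]]$id, "A-B")
  expect_equal(rules[[1]]$switch, "SAC")
  expect_error(read_interaction_table(data.frame(protein_a = "A")),
               "needs columns")
})
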