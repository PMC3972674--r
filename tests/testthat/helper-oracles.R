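# Independent oracles and small fixture builders used across the suite.

toy_model <- function(with_nucleation = FALSE) {
  rules <- if (with_nucleation) "
begin reaction rules
grow: A(a) + A(a,b~mod) -> A(a!1).A(a!1,b~mod) 1.0
pass: A(a!1,b~mod).A(a!1,b~none) -> A(a!1,b~mod).A(a!1,b~mod) 100.0
end reaction rules" else "
begin reaction rules
grow: A(a) + A(a) -> A(a!1).A(a!1) 1.0
end reaction rules"
  parse_model(paste0(
    "begin molecule types\nA(a,a,b~none~mod)\nend molecule types", rules))
}

toy_world <- function(n, seed = 1, box_half = 60, model = toy_model(),
                      params = force_params(pair = "none")) {
  geom <- geometry_spec(data.frame(type = "A", mass = 15))
  init_world(model, geom, counts = c(A = n),
             box = matrix(c(-box_half, box_half), 2, 3),
             seed = seed, params = params)
}

# directly tie two free sites together (bypasses the rule machinery)
force_bond <- function(world, row_a, row_b) {
  stopifnot(is.na(world$sites$bond[row_a]), is.na(world$sites$bond[row_b]))
  world$sites$bond[row_a] <- row_b
  world$sites$bond[row_b] <- row_a
  world
}

# a toy-polymer world with a random (valid) bond configuration and random
# b-site modifications
random_toy_world <- function(n, seed, bond_prob = 0.4) {
  set.seed(seed)
  w <- toy_world(n, seed = seed)
  a_rows <- which(w$sites$name == "a")
  free <- sample(a_rows)
  while (length(free) >= 2L) {
    r1 <- free[1]
    free <- free[-1]
    other <- free[w$sites$particle[free] != w$sites$particle[r1]]
    if (length(other) && stats::runif(1) < bond_prob) {
      r2 <- other[sample.int(length(other), 1L)]
      w <- force_bond(w, r1, r2)
      free <- setdiff(free, r2)
    }
  }
  b_rows <- which(w$sites$name == "b")
  w$sites$mod[b_rows] <- sample(c("none", "mod"), length(b_rows),
                                replace = TRUE)
  w
}

# brute-force pattern matcher: exhaustive enumeration over all injective
# particle tuples and site-slot assignments; deliberately naive and
# independent of the package's backtracking matcher
brute_force_count <- function(pattern, world) {
  mols <- pattern$mols
  nm <- length(mols)
  ids <- world$particles$id
  count <- 0L
  # all ordered injective particle tuples
  tuples <- function(chosen) {
    if (length(chosen) == nm) return(list(chosen))
    out <- list()
    for (id in setdiff(ids, chosen))
      out <- c(out, tuples(c(chosen, id)))
    out
  }
  check_tuple <- function(tuple) {
    # per molecule, enumerate all slot assignments; then check everything
    per_mol <- lapply(seq_len(nm), function(k) {
      if (world$particles$type[match(tuple[k], ids)] != mols[[k]]$type)
        return(list())
      rows <- which(world$sites$particle == tuple[k])
      sps <- mols[[k]]$sites
      if (!length(sps)) return(list(integer()))
      combos <- list(integer())
      for (sp in sps) {
        nxt <- list()
        for (cm in combos) for (r in setdiff(rows, cm)) {
          s <- world$sites[r, ]
          ok <- s$name == sp$site &&
            (is.na(sp$mod) || (!is.na(s$mod) && s$mod == sp$mod)) &&
            !(identical(sp$bond, "free") && !is.na(s$bond)) &&
            !(identical(sp$bond, "any") && is.na(s$bond))
          if (ok) nxt <- c(nxt, list(c(cm, r)))
        }
        combos <- nxt
      }
      combos
    })
    if (any(lengths(per_mol) == 0L)) return(0L)
    grids <- expand.grid(lapply(per_mol, seq_along))
    hits <- 0L
    for (g in seq_len(nrow(grids))) {
      assign <- lapply(seq_len(nm), function(k) per_mol[[k]][[grids[g, k]]])
      # bond labels must map onto actual bonds
      lab <- list()
      for (k in seq_len(nm)) for (o in seq_along(mols[[k]]$sites)) {
        b <- mols[[k]]$sites[[o]]$bond
        if (is.numeric(b))
          lab[[as.character(b)]] <- c(lab[[as.character(b)]], assign[[k]][o])
      }
      ok <- TRUE
      for (ends in lab) {
        if (length(ends) != 2L ||
            is.na(world$sites$bond[ends[1]]) ||
            world$sites$bond[ends[1]] != ends[2]) { ok <- FALSE; break }
      }
      if (ok) hits <- hits + 1L
    }
    hits
  }
  for (tp in tuples(integer())) count <- count + check_tuple(tp)
  count
}

# non-spatial exhaustive rule application until no embedding remains
exhaustive_apply <- function(world, model) {
  repeat {
    fired <- FALSE
    for (r in model$rules) {
      embs <- srbm:::.match_rule_lhs(r, world)
      if (length(embs)) {
        res <- apply_rule(world, r, embs[[1]])
        if (res$applied) {
          world <- res$world
          fired <- TRUE
          break
        }
      }
    }
    if (!fired) return(world)
  }
}

# breadth-first-search connectivity oracle over an edge list
bfs_connected <- function(edges, from, to, vertices) {
  adj <- setNames(rep(list(integer()), length(vertices)),
                  as.character(vertices))
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges$a[i])
    b <- as.character(edges$b[i])
    if (a %in% names(adj) && b %in% names(adj)) {
      adj[[a]] <- c(adj[[a]], edges$b[i])
      adj[[b]] <- c(adj[[b]], edges$a[i])
    }
  }
  seen <- as.character(from)
  queue <- from
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (nb in adj[[as.character(v)]]) {
      if (!as.character(nb) %in% seen) {
        seen <- c(seen, as.character(nb))
        queue <- c(queue, nb)
      }
    }
  }
  any(as.character(to) %in% seen)
}

# particle-pair multiset of the current bond graph
bond_pairs <- function(world) {
  bl <- bond_list(world)
  if (!nrow(bl)) return(character())
  sort(paste(pmin(bl$particle_a, bl$particle_b),
             pmax(bl$particle_a, bl$particle_b)))
}

# does a CenpA-CenpB-CenpW-H3 path span two distinct fixed nucleosomes?
has_cenpb_cenpw_bridge <- function(world, anchors) {
  bl <- bond_list(world)
  if (!nrow(bl)) return(FALSE)
  ptype <- setNames(world$particles$type, world$particles$id)
  pgroup <- setNames(world$particles$group, world$particles$id)
  partners <- function(id, type) {
    rows <- which(bl$particle_a == id | bl$particle_b == id)
    out <- setdiff(unique(c(bl$particle_a[rows], bl$particle_b[rows])), id)
    out[ptype[as.character(out)] == type]
  }
  for (ca in world$particles$id[world$particles$type == "CenpA"]) {
    for (b in partners(ca, "CenpB"))
      for (wd in partners(b, "CenpW"))
        for (h in partners(wd, "H3")) {
          ga <- pgroup[[as.character(ca)]]
          gh <- pgroup[[as.character(h)]]
          if (!is.na(ga) && !is.na(gh) && ga != gh) return(TRUE)
        }
  }
  FALSE
}

random_rotation_matrix <- function() {
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
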