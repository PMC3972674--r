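# Pattern matching against the world's site graph, and rule application
# as a graph rewrite.

# site table rows belonging to a particle id
.sites_of <- function(world, pid) which(world$sites$particle == pid)

# check one already-assigned site row against a site pattern's local
# constraints (mod + bond class); bond-label partner checks are done by the
# caller once both ends are assigned
.site_row_ok <- function(world, row, sp) {
  s <- world$sites[row, ]
  if (s$name != sp$site) return(FALSE)
  if (!is.na(sp$mod) && (is.na(s$mod) || s$mod != sp$mod)) return(FALSE)
  b <- sp$bond
  if (identical(b, "free") && !is.na(s$bond)) return(FALSE)
  if (identical(b, "any") && is.na(s$bond)) return(FALSE)
  if (is.numeric(b) && is.na(s$bond)) return(FALSE)  # labelled => bound
  TRUE
}

#' Match a complex pattern against the world
#'
#' Returns every injective embedding of the pattern's molecules and site
#' occurrences onto world particles and sites that is consistent with the
#' pattern's bond and modification constraints. Omitted sites match
#' anything; duplicate site names are matched without order preference.
#'
#' @param pattern an `srbm_pattern` (see [parse_pattern()]).
#' @param world an `srbm_world`.
#' @param anchor optional particle id; only embeddings covering it are kept.
#' @param dedup drop embeddings that are identical up to permutations of
#'   identical sites / automorphic molecule swaps (default), so a symmetric
#'   dimerization does not double its propensity.
#' @return list of embeddings, each `list(particles =, site_rows =)` with
#'   one entry per pattern molecule.
#' @export
match_pattern <- function(pattern, world, anchor = NULL, dedup = TRUE) {
  stopifnot(inherits(pattern, "srbm_pattern"))
  res <- Filter(function(e) .bonds_consistent(pattern$mols, e, world),
                .match_mols(pattern$mols, world, used = integer()))
  if (!is.null(anchor))
    res <- Filter(function(e) anchor %in% e$particles, res)
  if (dedup) res <- .dedup_embeddings(res, pattern$mols, world)
  res
}

# backtracking over pattern molecules; returns list of embeddings
.match_mols <- function(mols, world, used) {
  if (length(mols) == 0L) return(list(list(particles = integer(),
                                           site_rows = list())))
  out <- list()
  pm <- mols[[1]]
  cand <- world$particles$id[world$particles$type == pm$type]
  cand <- setdiff(cand, used)
  for (pid in cand) {
    rows <- .sites_of(world, pid)
    for (assign in .site_assignments(world, rows, pm$sites)) {
      rest <- .match_mols(mols[-1], world, c(used, pid))
      for (e in rest)
        out <- c(out, list(list(particles = c(pid, e$particles),
                                site_rows = c(list(assign), e$site_rows))))
    }
  }
  out
}

# enumerate injective assignments of pattern site occurrences to site rows
.site_assignments <- function(world, rows, sps) {
  if (length(sps) == 0L) return(list(integer()))
  out <- list()
  ok <- rows[vapply(rows, function(r) .site_row_ok(world, r, sps[[1]]), TRUE)]
  for (r in ok) {
    for (rest in .site_assignments(world, setdiff(rows, r), sps[-1]))
      out <- c(out, list(c(r, rest)))
  }
  out
}

# verify that pattern bond labels map onto actual world bonds
.bonds_consistent <- function(mols, emb, world) {
  lab <- list()
  for (k in seq_along(mols)) {
    sps <- mols[[k]]$sites
    for (o in seq_along(sps)) {
      b <- sps[[o]]$bond
      if (is.numeric(b)) {
        key <- as.character(b)
        lab[[key]] <- c(lab[[key]], emb$site_rows[[k]][o])
      }
    }
  }
  for (ends in lab) {
    if (length(ends) != 2L) return(FALSE)
    if (is.na(world$sites$bond[ends[1]]) ||
        world$sites$bond[ends[1]] != ends[2]) return(FALSE)
  }
  TRUE
}

# canonical key collapsing automorphic embeddings
.embedding_key <- function(emb, mols, world) {
  items <- vapply(seq_along(mols), function(k) {
    sps <- mols[[k]]$sites
    descs <- vapply(seq_along(sps), function(o) {
      sp <- sps[[o]]
      b <- sp$bond
      bdesc <- if (is.numeric(b)) {
        partner <- world$sites$bond[emb$site_rows[[k]][o]]
        paste0("L", partner)
      } else b
      paste(sp$site, bdesc, sp$mod, emb$site_rows[[k]][o], sep = "/")
    }, "")
    paste(mols[[k]]$type, emb$particles[k],
          paste(sort(descs), collapse = ";"), sep = "|")
  }, "")
  paste(sort(items), collapse = "||")
}

.dedup_embeddings <- function(res, mols, world) {
  if (length(res) < 2L) return(res)
  keys <- vapply(res, .embedding_key, "", mols = mols, world = world)
  res[!duplicated(keys)]
}

# match a whole rule LHS (possibly several disconnected complexes) with
# global particle injectivity; returns flattened embeddings
.match_rule_lhs <- function(rule, world, dedup = TRUE) {
  combos <- list(list(particles = integer(), site_rows = list()))
  for (cp in rule$lhs) {
    nxt <- list()
    for (base in combos) {
      embs <- Filter(function(e) .bonds_consistent(cp$mols, e, world),
                     .match_mols(cp$mols, world, used = base$particles))
      for (e in embs)
        nxt <- c(nxt, list(list(particles = c(base$particles, e$particles),
                                site_rows = c(base$site_rows, e$site_rows))))
    }
    combos <- nxt
  }
  combos <- Filter(function(e) length(e$particles) > 0L, combos)
  if (dedup) .dedup_embeddings(combos, rule$flat_lhs, world) else combos
}

# re-check that an embedding still satisfies the rule LHS (stale detection)
.embedding_valid <- function(rule, emb, world) {
  mols <- rule$flat_lhs
  for (k in seq_along(mols)) {
    pid <- emb$particles[k]
    prow <- match(pid, world$particles$id)
    if (is.na(prow) || world$particles$type[prow] != mols[[k]]$type)
      return(FALSE)
    sps <- mols[[k]]$sites
    rows <- emb$site_rows[[k]]
    if (length(rows) != length(sps)) return(FALSE)
    for (o in seq_along(sps)) {
      if (world$sites$particle[rows[o]] != pid) return(FALSE)
      if (!.site_row_ok(world, rows[o], sps[[o]])) return(FALSE)
    }
  }
  .bonds_consistent(mols, emb, world)
}

#' Apply a rule at a matched embedding
#'
#' Rewrites the world's site graph exactly as the rule's right-hand side
#' prescribes: at most one bond is formed or broken and modification labels
#' are rewritten; sites not mentioned by the rule are untouched. A stale
#' embedding (a site state changed since matching) is rejected and the
#' world is returned unmodified with `applied = FALSE`.
#'
#' @param world an `srbm_world`.
#' @param rule an `srbm_rule`.
#' @param embedding an embedding from [match_pattern()] (single-complex
#'   rules) or from the internal rule matcher.
#' @return `list(world =, events =, applied =)`; `events` is a bond-event
#'   data frame (step, rule, particle/site pair, action).
#' @export
apply_rule <- function(world, rule, embedding) {
  stopifnot(inherits(rule, "srbm_rule"))
  if (!.embedding_valid(rule, embedding, world))
    return(list(world = world, events = empty_events(), applied = FALSE))
  acts <- rule$actions
  events <- empty_events()
  ev <- function(r1, r2, action) {
    s <- world$sites
    data.frame(step = world$step, rule = rule$id,
               particle_a = s$particle[r1], site_a = s$name[r1],
               particle_b = s$particle[r2], site_b = s$name[r2],
               action = action, stringsAsFactors = FALSE)
  }
  if (!is.null(acts$form) && nrow(acts$form) > 0L) {
    f <- acts$form[1, ]
    r1 <- embedding$site_rows[[f[1]]][f[2]]
    r2 <- embedding$site_rows[[f[3]]][f[4]]
    if (!is.na(world$sites$bond[r1]) || !is.na(world$sites$bond[r2]))
      return(list(world = world, events = empty_events(), applied = FALSE))
    world$sites$bond[r1] <- r2
    world$sites$bond[r2] <- r1
    events <- rbind(events, ev(r1, r2, "formed"))
  }
  if (!is.null(acts$broken) && nrow(acts$broken) > 0L) {
    b <- acts$broken[1, ]
    r1 <- embedding$site_rows[[b[1]]][b[2]]
    r2 <- embedding$site_rows[[b[3]]][b[4]]
    world$sites$bond[r1] <- NA_integer_
    world$sites$bond[r2] <- NA_integer_
    events <- rbind(events, ev(r1, r2, "broken"))
  }
  if (!is.null(acts$mods)) {
    for (i in seq_len(nrow(acts$mods))) {
      m <- acts$mods[i, ]
      row <- embedding$site_rows[[m$mol]][m$occ]
      world$sites$mod[row] <- m$mod
    }
  }
  world$events <- rbind(world$events, events)
  list(world = world, events = events, applied = TRUE)
}

empty_events <- function() {
  data.frame(step = integer(), rule = character(),
             particle_a = integer(), site_a = character(),
             particle_b = integer(), site_b = character(),
             action = character(), stringsAsFactors = FALSE)
}
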