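# Engine: overdamped Brownian dynamics plus distance-triggered rule firing.
# The hot loop lives in src/engine.cpp; these wrappers map the world to the
# compiled core's flat arrays and back.

# integer coding tables shared between R and the compiled core
.engine_levels <- function(model) {
  types <- names(model$types)
  sites <- unique(unlist(lapply(model$types, `[[`, "sites")))
  mods <- unique(unlist(lapply(model$types, `[[`, "mods")))
  list(types = types, sites = sites, mods = mods)
}

.mod_code <- function(mod, lv) ifelse(is.na(mod), 0L, match(mod, lv$mods))

# translate site-pattern context/set lists into integer matrices
.ctx_matrix <- function(sps, skip_occ, lv, rule_id) {
  rows <- NULL
  for (o in seq_along(sps)) {
    if (o %in% skip_occ) next
    sp <- sps[[o]]
    if (!identical(sp$bond, "free") && !identical(sp$bond, "wild") &&
        !is.numeric(sp$bond))
      stop("rule '", rule_id, "': context site bond constraint '", sp$bond,
           "' is not supported by the spatial engine")
    if (!is.na(sp$mod))
      rows <- rbind(rows, c(match(sp$site, lv$sites) - 1L,
                            .mod_code(sp$mod, lv)))
  }
  rows
}

.set_matrix <- function(mods, mol, flat, lv) {
  if (is.null(mods)) return(NULL)
  m <- mods[mods$mol == mol, , drop = FALSE]
  if (!nrow(m)) return(NULL)
  site_of <- function(occ) flat[[mol]]$sites[[occ]]$site
  cbind(vapply(m$occ, function(o) match(site_of(o), lv$sites) - 1L, 0L),
        vapply(m$mod, function(x) .mod_code(x, lv), 0L))
}

# compile model rules into the engine's bimolecular / unimolecular forms
.compile_engine_rules <- function(model, switches, lv) {
  bi <- list()
  uni <- list()
  for (k in seq_along(model$rules)) {
    r <- model$rules[[k]]
    on <- is.na(r$switch) ||
      isTRUE(switches[[r$switch]])
    flat <- r$flat_lhs
    acts <- r$actions
    tcode <- function(m) match(flat[[m]]$type, lv$types) - 1L
    scode <- function(m, o) match(flat[[m]]$sites[[o]]$site, lv$sites) - 1L
    if (r$kind == "bind") {
      if (length(flat) != 2L || !is.null(.pattern_bonds(r$lhs[[1]])) ||
          length(r$lhs) != 2L)
        stop("rule '", r$id,
             "': the spatial engine supports bind rules between two ",
             "separate molecules only")
      f <- acts$form[1, ]
      bi[[length(bi) + 1L]] <- list(
        tA = tcode(f[1]), sA = scode(f[1], f[2]),
        tB = tcode(f[3]), sB = scode(f[3], f[4]),
        p = r$rate, on = on, id = k,
        ctxA = .ctx_matrix(flat[[f[1]]]$sites, f[2], lv, r$id),
        ctxB = .ctx_matrix(flat[[f[3]]]$sites, f[4], lv, r$id),
        setA = .set_matrix(acts$mods, f[1], flat, lv),
        setB = .set_matrix(acts$mods, f[3], flat, lv))
    } else if (r$kind == "unbind") {
      b <- acts$broken[1, ]
      uni[[length(uni) + 1L]] <- list(
        kind = 0L, tA = tcode(b[1]), sA = scode(b[1], b[2]),
        tB = tcode(b[3]), sB = scode(b[3], b[4]),
        k = r$rate, on = on, id = k,
        ctxA = .ctx_matrix(flat[[b[1]]]$sites, b[2], lv, r$id),
        ctxB = .ctx_matrix(flat[[b[3]]]$sites, b[4], lv, r$id),
        setA = .set_matrix(acts$mods, b[1], flat, lv),
        setB = .set_matrix(acts$mods, b[3], flat, lv))
    } else if (r$kind == "modify") {
      uni[[length(uni) + 1L]] <- list(
        kind = 1L, tA = tcode(1), sA = -1L, tB = -1L, sB = -1L,
        k = r$rate, on = on, id = k,
        ctxA = .ctx_matrix(flat[[1]]$sites, integer(), lv, r$id),
        ctxB = NULL,
        setA = .set_matrix(acts$mods, 1L, flat, lv), setB = NULL)
    } else { # modify-propagate: pattern is a bonded pair, mods rewritten
      ends <- NULL
      for (m in seq_along(flat)) for (o in seq_along(flat[[m]]$sites))
        if (is.numeric(flat[[m]]$sites[[o]]$bond))
          ends <- rbind(ends, c(m, o))
      if (is.null(ends) || nrow(ends) != 2L || length(flat) != 2L)
        stop("rule '", r$id, "': the spatial engine supports propagation ",
             "rules over one bonded pair only")
      uni[[length(uni) + 1L]] <- list(
        kind = 2L, tA = tcode(ends[1, 1]), sA = scode(ends[1, 1], ends[1, 2]),
        tB = tcode(ends[2, 1]), sB = scode(ends[2, 1], ends[2, 2]),
        k = r$rate, on = on, id = k,
        ctxA = .ctx_matrix(flat[[ends[1, 1]]]$sites, ends[1, 2], lv, r$id),
        ctxB = .ctx_matrix(flat[[ends[2, 1]]]$sites, ends[2, 2], lv, r$id),
        setA = .set_matrix(acts$mods, ends[1, 1], flat, lv),
        setB = .set_matrix(acts$mods, ends[2, 1], flat, lv))
    }
  }
  list(bi = bi, uni = uni)
}

# run the compiled core for `nsteps`; returns the updated world plus
# engine snapshots
.engine_step <- function(world, nsteps, dump_every = 0L, do_move = TRUE,
                         do_react = TRUE, step0 = world$step) {
  p <- world$particles
  n <- nrow(p)
  lv <- .engine_levels(world$model)
  if (n == 0L) return(list(world = world, snapshots = list()))
  s <- world$sites
  if (is.null(world$grot) || length(world$grot) < nrow(world$groups))
    world$grot <- c(world$grot,
                    rep(list(diag(3)), nrow(world$groups) - length(world$grot)))
  rules <- .compile_engine_rules(world$model, world$switches, lv)
  pidx <- match(s$particle, p$id)
  group <- ifelse(is.na(p$group), 0L, p$group)
  sb <- ifelse(is.na(s$bond), 0L, s$bond)
  radii <- .geom_radius(world$geometry, p$type)
  out <- .engine_run(
    as.matrix(p[, c("x", "y", "z")]),
    match(p$type, lv$types) - 1L, radii, as.integer(group),
    world$groups$rigid, world$groups$fixed, world$groups$rot_free,
    world$grot,
    as.integer(pidx), match(s$name, lv$sites) - 1L,
    .mod_code(s$mod, lv), as.integer(sb),
    s$len, s$phi * pi / 180, s$theta * pi / 180,
    as.matrix(rbind(
      setNames(data.frame(match(world$struct_bonds$p1, p$id),
                          match(world$struct_bonds$p2, p$id)), c("a", "b")))),
    world$struct_bonds$rest,
    as.matrix(setNames(data.frame(match(world$angles$p1, p$id),
                                  match(world$angles$p2, p$id),
                                  match(world$angles$p3, p$id)),
                       c("a", "b", "c"))),
    world$angles$theta0,
    rules$bi, rules$uni, world$box, world$params,
    as.integer(nsteps), as.integer(dump_every), do_move, do_react,
    as.integer(step0))
  world$particles$x <- out$pos[, 1]
  world$particles$y <- out$pos[, 2]
  world$particles$z <- out$pos[, 3]
  world$sites$bond <- ifelse(out$sbond == 0L, NA_integer_, out$sbond)
  world$sites$mod <- c(NA_character_, lv$mods)[out$smod + 1L]
  world$grot <- out$grot
  ev <- out$events
  if (length(ev$step)) {
    rid <- vapply(ev$rule, function(k) world$model$rules[[k]]$id, "")
    events <- data.frame(
      step = ev$step, rule = rid,
      particle_a = s$particle[ev$site_a], site_a = s$name[ev$site_a],
      particle_b = s$particle[ev$site_b], site_b = s$name[ev$site_b],
      action = ifelse(ev$formed == 1L, "formed", "broken"),
      stringsAsFactors = FALSE)
    world$events <- rbind(world$events, events)
  }
  list(world = world, snapshots = out$snapshots)
}

#' Advance the world by Brownian dynamics
#'
#' Overdamped Langevin update of free particles and rigid-body update of
#' template groups: deterministic forces (pair repulsion, bonds, angles,
#' centering drag) plus Gaussian noise with variance set by `kT`, `gamma`
#' and `dt`; positions leaving the box are reflected across the violated
#' face; fixed-position groups keep their centroid, rotating only if
#' rotation is free. No reactions fire.
#'
#' @param world an `srbm_world`.
#' @param nsteps number of time-steps (default 1).
#' @return the updated world (step counter advanced).
#' @export
step_dynamics <- function(world, nsteps = 1L) {
  res <- .engine_step(world, nsteps, do_move = TRUE, do_react = FALSE)
  w <- res$world
  w$step <- w$step + as.integer(nsteps)
  w
}

#' Fire reaction rules at the current configuration
#'
#' Bimolecular bind rules fire for every unordered pair of free sites whose
#' particle-centre distance is within the two site reaches (plus slack) and
#' whose enabled rule matches, with the rule's per-encounter probability;
#' candidate pairs are processed in RNG-shuffled order and a site binds at
#' most once per call. Unimolecular rules (unbind / modify) fire with
#' probability `1 - exp(-k dt)` per matched embedding. Every bond change is
#' logged as an event.
#'
#' @param world an `srbm_world`.
#' @return list with elements `world` and `events` (the new bond events).
#' @export
fire_reactions <- function(world) {
  n0 <- nrow(world$events)
  res <- .engine_step(world, 1L, do_move = FALSE, do_react = TRUE,
                      step0 = world$step - 1L)
  w <- res$world
  list(world = w, events = utils::tail(w$events, nrow(w$events) - n0))
}

#' Simulation protocol
#'
#' An ordered list of phases executed by [run_protocol()]:
#' `phase_run(steps)` advances dynamics with reactions, `phase_add(what, n)`
#' adds molecules or template instances, `phase_switch(tag, on)` flips a
#' rule-enable switch, `phase_param(name, value)` adjusts a force parameter
#' (e.g. disables the pair force).
#'
#' @param ... phases.
#' @param dump_interval snapshot period in steps (0 = final state only).
#' @return an object of class `srbm_protocol`.
#' @export
sim_protocol <- function(..., dump_interval = 5000L) {
  phases <- list(...)
  structure(list(phases = phases,
                 dump_interval = as.integer(dump_interval)),
            class = "srbm_protocol")
}

#' @rdname sim_protocol
#' @param steps number of time-steps (positive).
#' @export
phase_run <- function(steps) {
  stopifnot(steps >= 0)
  list(kind = "run", steps = as.integer(steps))
}

#' @rdname sim_protocol
#' @param what molecule type or template name.
#' @param n copies to add (positive).
#' @param ranges optional placement ranges.
#' @export
phase_add <- function(what, n, ranges = NULL) {
  stopifnot(n > 0)
  list(kind = "add", what = what, n = as.integer(n), ranges = ranges)
}

#' @rdname sim_protocol
#' @param tag switch tag.
#' @param on logical.
#' @export
phase_switch <- function(tag, on) list(kind = "switch", tag = tag, on = on)

#' @rdname sim_protocol
#' @param name force-parameter name (see [force_params()]).
#' @param value new value.
#' @export
phase_param <- function(name, value)
  list(kind = "param", name = name, value = value)

#' Execute a simulation protocol
#'
#' Runs the protocol's phases in order, dumping a trajectory record every
#' `dump_interval` steps (plus the initial and final states). With the same
#' seed the trajectory and bond log are bit-identical.
#'
#' @param world an `srbm_world` (seed it via [init_world()] or `set.seed`).
#' @param protocol an `srbm_protocol`.
#' @return list with `world` (final state), `trajectory` (list of snapshot
#'   records, see [as_record()]) and `events` (the full bond log).
#' @export
run_protocol <- function(world, protocol) {
  stopifnot(inherits(protocol, "srbm_protocol"))
  traj <- list(as_record(world))
  for (ph in protocol$phases) {
    if (ph$kind == "run") {
      if (ph$steps > 0L) {
        res <- .engine_step(world, ph$steps,
                            dump_every = protocol$dump_interval,
                            do_move = TRUE, do_react = TRUE)
        world <- res$world
        world$step <- world$step + ph$steps
        for (sn in res$snapshots)
          traj <- c(traj, list(.snapshot_record(world, sn)))
      }
    } else if (ph$kind == "add") {
      world <- add_molecules(world, ph$what, ph$n, ph$ranges)
    } else if (ph$kind == "switch") {
      world <- set_switch(world, ph$tag, ph$on)
    } else if (ph$kind == "param") {
      world$params[[ph$name]] <- ph$value
    } else stop("unknown phase kind '", ph$kind, "'")
  }
  last <- traj[[length(traj)]]
  if (last$step != world$step) traj <- c(traj, list(as_record(world)))
  list(world = world, trajectory = traj, events = world$events)
}

#' Snapshot record of a world
#'
#' @param world an `srbm_world`.
#' @return a `srbm_record`: step, per-particle table (id, type, x, y, z,
#'   group), bond list, box and seed.
#' @export
as_record <- function(world) {
  p <- world$particles
  rownames(p) <- NULL
  b <- bond_list(world)[, c("particle_a", "site_a", "particle_b", "site_b")]
  rownames(b) <- NULL
  structure(list(step = as.integer(world$step), particles = p, bonds = b,
                 box = unname(world$box),
                 seed = if (is.null(world$seed)) NULL
                        else as.integer(world$seed)),
            class = "srbm_record")
}

# record from an engine snapshot (positions + site-bond vector)
.snapshot_record <- function(world, sn) {
  p <- world$particles
  p$x <- sn$pos[, 1]
  p$y <- sn$pos[, 2]
  p$z <- sn$pos[, 3]
  rownames(p) <- NULL
  s <- world$sites
  bnd <- ifelse(sn$bond == 0L, NA_integer_, sn$bond)
  i <- which(!is.na(bnd) & seq_along(bnd) < bnd)
  structure(list(step = as.integer(sn$step), particles = p,
                 bonds = data.frame(particle_a = s$particle[i],
                                    site_a = s$name[i],
                                    particle_b = s$particle[bnd[i]],
                                    site_b = s$name[bnd[i]],
                                    stringsAsFactors = FALSE),
                 box = unname(world$box),
                 seed = if (is.null(world$seed)) NULL
                        else as.integer(world$seed)),
            class = "srbm_record")
}

#' @export
print.srbm_record <- function(x, ...) {
  cat("srbm snapshot: step", x$step, "-", nrow(x$particles), "particles,",
      nrow(x$bonds), "bonds\n")
  invisible(x)
}
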