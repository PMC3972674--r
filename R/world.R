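# World state: particle instances, positions, bonds, modification states,
# rule-enable switches and force parameters.

#' Force-field and integrator parameters
#'
#' Reduced units: kT = 1, friction gamma = 1, so the free diffusion
#' coefficient is D = kT / gamma (Angstrom^2 per time unit) and the default
#' time-step is 5e-3. Pair excluded volume is a Lennard-Jones potential cut
#' at its minimum (purely repulsive), sigma defaulting to the sum of radii;
#' bonds are harmonic springs with rest length equal to the sum of the two
#' site reaches; deterministic forces are capped at `fcap` to keep large
#' time-steps stable.
#'
#' @param pair `"lj"` or `"none"`.
#' @param epsilon Lennard-Jones well depth (kT units).
#' @param kT temperature in energy units.
#' @param gamma translational friction coefficient.
#' @param dt integration time-step.
#' @param k_bond harmonic bond stiffness.
#' @param k_angle harmonic angle stiffness (0 disables angle forces).
#' @param rot_diff rotational diffusion coefficient of rotation-free rigid
#'   groups (rad^2 per time unit).
#' @param drag optional centering drag-fix: `list(center =, radius =, k =)`;
#'   particles outside the sphere feel a harmonic pull back towards it.
#' @param bind_slack fractional slack on the binding reach (default 10%).
#' @param cone_deg angular veto half-angle for sites with declared angles.
#' @param fcap force cap (energy / Angstrom).
#' @param react_every fire reactions every this many steps.
#' @return a named list of parameters.
#' @export
force_params <- function(pair = "lj", epsilon = 1, kT = 1, gamma = 1,
                         dt = 5e-3, k_bond = 10, k_angle = 0,
                         rot_diff = 0.1, drag = NULL, bind_slack = 0.1,
                         cone_deg = 45, fcap = 100, react_every = 1L) {
  stopifnot(dt > 0, gamma > 0, kT >= 0, k_bond >= 0, k_angle >= 0)
  list(pair = pair, epsilon = epsilon, kT = kT, gamma = gamma, dt = dt,
       k_bond = k_bond, k_angle = k_angle, rot_diff = rot_diff, drag = drag,
       bind_slack = bind_slack, cone_deg = cone_deg, fcap = fcap,
       react_every = as.integer(react_every))
}

.empty_world <- function(model, geometry, templates, box, params, seed) {
  structure(list(
    model = model, geometry = geometry, templates = templates,
    particles = data.frame(id = integer(), type = character(),
                           x = numeric(), y = numeric(), z = numeric(),
                           group = integer(), stringsAsFactors = FALSE),
    groups = data.frame(id = integer(), name = character(),
                        rigid = logical(), fixed = logical(),
                        rot_free = logical(), stringsAsFactors = FALSE),
    sites = data.frame(particle = integer(), slot = integer(),
                       name = character(), len = numeric(), phi = numeric(),
                       theta = numeric(), mod = character(), bond = integer(),
                       stringsAsFactors = FALSE),
    struct_bonds = data.frame(p1 = integer(), p2 = integer(),
                              rest = numeric()),
    angles = data.frame(p1 = integer(), p2 = integer(), p3 = integer(),
                        theta0 = numeric()),
    box = box, step = 0L, seed = seed,
    switches = model$switches, params = params,
    events = empty_events()), class = "srbm_world")
}

.check_box <- function(box) {
  box <- matrix(as.numeric(box), nrow = 2)
  if (ncol(box) != 3 || any(box[2, ] <= box[1, ]))
    stop("box must be a 2x3 matrix of (lo, hi) extents")
  box
}

.random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

.runif_in <- function(ranges) {
  vapply(1:3, function(k) stats::runif(1, ranges[1, k], ranges[2, k]), 0)
}

#' Initialise a world
#'
#' Places the requested molecules and structural templates in the reactor,
#' either at explicitly given positions or randomly inside `ranges`
#' (avoiding overlap with already-placed fixed templates), and seeds the
#' random number generator.
#'
#' @param model an `srbm_model`.
#' @param geometry an `srbm_geometry`.
#' @param templates named list of `srbm_template` objects.
#' @param counts named integer vector: copies per molecule type or template
#'   name, placed randomly.
#' @param box reactor extents, 2x3 matrix of (lo, hi) per axis (Angstrom).
#' @param ranges placement ranges for random positions (defaults to `box`).
#' @param explicit optional data frame (`what`, `x`, `y`, `z`) of exact
#'   placements, honoured before random ones.
#' @param seed RNG seed (recorded in the world and in output headers).
#' @param params force parameters from [force_params()].
#' @param max_tries placement retries before giving up.
#' @return an `srbm_world`.
#' @export
init_world <- function(model, geometry, templates = list(), counts = c(),
                       box, ranges = NULL, explicit = NULL, seed = NULL,
                       params = force_params(), max_tries = 200L) {
  box <- .check_box(box)
  if (is.null(ranges)) ranges <- box else ranges <- .check_box(ranges)
  if (!is.null(seed)) set.seed(seed)
  world <- .empty_world(model, geometry, templates, box, params, seed)
  place <- function(world, what, at, rotation = NULL) {
    if (what %in% names(world$templates)) {
      build_template(world, world$templates[[what]], at = at,
                     rotation = rotation)
    } else {
      .append_particle(world, what, at)$world
    }
  }
  if (!is.null(explicit)) {
    for (i in seq_len(nrow(explicit)))
      world <- place(world, explicit$what[i],
                     c(explicit$x[i], explicit$y[i], explicit$z[i]))
  }
  for (nm in names(counts)) {
    n <- counts[[nm]]
    if (n < 0) stop("counts must be non-negative")
    for (k in seq_len(n)) {
      r <- if (nm %in% names(world$templates))
        max(.geom_radius(geometry, world$templates[[nm]]$members$type))
      else .geom_radius(geometry, nm)
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        at <- .runif_in(ranges)
        if (.placement_clear(world, at, r)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place '", nm, "' after ", max_tries,
                    " tries; box too small?")
      world <- place(world, nm, at,
                     rotation = if (nm %in% names(world$templates))
                       .random_rotation())
    }
  }
  world
}

# keep new placements clear of fixed templates (the anchored scaffold)
.placement_clear <- function(world, at, r) {
  if (!nrow(world$particles)) return(TRUE)
  fixed_groups <- world$groups$id[world$groups$fixed]
  p <- world$particles[world$particles$group %in% fixed_groups, , drop = FALSE]
  if (!nrow(p)) return(TRUE)
  radii <- .geom_radius(world$geometry, p$type)
  d <- sqrt((p$x - at[1])^2 + (p$y - at[2])^2 + (p$z - at[3])^2)
  all(d >= 0.7 * (radii + r))
}

#' Add free molecules to an existing world
#'
#' Used by protocol `add` phases.
#'
#' @param world an `srbm_world`.
#' @param what molecule type or template name.
#' @param n number of copies.
#' @param ranges placement ranges (defaults to the box).
#' @return the updated world.
#' @export
add_molecules <- function(world, what, n, ranges = NULL) {
  if (is.null(ranges)) ranges <- world$box
  for (k in seq_len(n)) {
    at <- .runif_in(ranges)
    world <- if (what %in% names(world$templates))
      build_template(world, world$templates[[what]], at = at,
                     rotation = .random_rotation())
    else .append_particle(world, what, at)$world
  }
  world
}

#' Set a rule-enable switch
#' @param world an `srbm_world`.
#' @param tag switch tag.
#' @param on logical.
#' @return the updated world.
#' @export
set_switch <- function(world, tag, on) {
  world$switches[[tag]] <- isTRUE(on)
  world
}

#' Current bond list of a world
#'
#' @param world an `srbm_world`.
#' @return data frame with one row per bond: particle/site name pairs and
#'   the site-table row indices.
#' @export
bond_list <- function(world) {
  s <- world$sites
  i <- which(!is.na(s$bond) & seq_len(nrow(s)) < s$bond)
  data.frame(particle_a = s$particle[i], site_a = s$name[i],
             particle_b = s$particle[s$bond[i]], site_b = s$name[s$bond[i]],
             row_a = i, row_b = s$bond[i], stringsAsFactors = FALSE)
}

#' @export
print.srbm_world <- function(x, ...) {
  nb <- sum(!is.na(x$sites$bond)) / 2 + nrow(x$struct_bonds)
  cat("srbm world: ", nrow(x$particles), " particles (",
      length(unique(x$particles$type)), " types), ",
      nrow(x$groups), " template groups, ", nb, " bonds, step ",
      x$step, "\n", sep = "")
  invisible(x)
}
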