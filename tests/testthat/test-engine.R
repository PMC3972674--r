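# Engine: Brownian dynamics, boundaries, reaction firing, protocols.

test_that("a free particle with T = 0 and no forces stays put", {
  w <- toy_world(1, params = force_params(kT = 0, pair = "none"))
  w2 <- step_dynamics(w, 25)
  expect_identical(w2$particles[, c("x", "y", "z")],
                   w$particles[, c("x", "y", "z")])
  expect_equal(w2$step, 25L)
})

test_that("particles crossing a reflective wall are mirrored back inside", {
  w <- toy_world(1, params = force_params(kT = 0, pair = "none"))
  w$particles$x[1] <- 65        # box is (-60, 60)
  w2 <- step_dynamics(w, 1)
  expect_equal(w2$particles$x[1], 55)
  # and under noise everything stays inside at every dump
  w3 <- toy_world(30, params = force_params(kT = 1, gamma = 0.05, dt = 0.5,
                                            pair = "none", k_bond = 0.05,
                                            fcap = 0.2))
  res <- run_protocol(w3, sim_protocol(phase_run(2000), dump_interval = 250))
  for (rec in res$trajectory) {
    p <- rec$particles
    expect_true(all(p$x >= -60 & p$x <= 60 & p$y >= -60 & p$y <= 60 &
                      p$z >= -60 & p$z <= 60))
  }
})

test_that("two bonded particles at rest length feel zero net force", {
  w <- toy_world(2, params = force_params(kT = 0, pair = "none"))
  a1 <- which(w$sites$particle == 1 & w$sites$name == "a")[1]
  a2 <- which(w$sites$particle == 2 & w$sites$name == "a")[1]
  w <- force_bond(w, a1, a2)
  # rest length = sum of site reaches = 15 + 15
  w$particles[1, c("x", "y", "z")] <- c(0, 0, 0)
  w$particles[2, c("x", "y", "z")] <- c(30, 0, 0)
  w2 <- step_dynamics(w, 10)
  expect_equal(as.numeric(w2$particles[2, c("x", "y", "z")]), c(30, 0, 0))
  # stretched bond relaxes towards rest length
  w$particles[2, c("x", "y", "z")] <- c(45, 0, 0)
  w3 <- step_dynamics(w, 200)
  gap <- w3$particles$x[2] - w3$particles$x[1]
  expect_lt(abs(gap - 30), 1)
})

test_that("free diffusion matches D = kT/gamma within 10%", {
  m <- parse_model("begin molecule types\nA(a)\nend molecule types")
  geom <- geometry_spec(data.frame(type = "A", mass = 15))
  p <- force_params(pair = "none", kT = 1, gamma = 2, dt = 0.01)
  w <- init_world(m, geom, counts = c(A = 400),
                  box = matrix(c(-1e4, 1e4), 2, 3), seed = 5, params = p)
  x0 <- as.matrix(w$particles[, c("x", "y", "z")])
  nsteps <- 400L
  w2 <- step_dynamics(w, nsteps)
  x1 <- as.matrix(w2$particles[, c("x", "y", "z")])
  msd <- mean(rowSums((x1 - x0)^2))
  expected <- 6 * (p$kT / p$gamma) * nsteps * p$dt
  expect_lt(abs(msd - expected) / expected, 0.1)
})

test_that("fire_reactions binds molecules in reach and respects distance", {
  m <- parse_model("
begin molecule types
A(c)
end molecule types
begin reaction rules
dim: A(c) + A(c) -> A(c!1).A(c!1) 1.0
end reaction rules")
  geom <- geometry_spec(data.frame(type = "A", mass = 15))
  w <- init_world(m, geom, counts = c(A = 2),
                  box = matrix(c(-60, 60), 2, 3), seed = 1,
                  params = force_params(pair = "none"))
  w$particles[1, c("x", "y", "z")] <- c(0, 0, 0)
  w$particles[2, c("x", "y", "z")] <- c(50, 0, 0)   # beyond 2*15*1.1
  res <- fire_reactions(w)
  expect_equal(nrow(res$events), 0L)
  w$particles[2, c("x", "y", "z")] <- c(25, 0, 0)   # within reach
  res2 <- fire_reactions(w)
  expect_equal(nrow(res2$events), 1L)
  expect_equal(res2$events$action, "formed")
  expect_equal(nrow(bond_list(res2$world)), 1L)
})

test_that("switched-off rules never fire regardless of proximity", {
  m <- parse_model("
begin molecule types
A(a)
B(b)
end molecule types
begin reaction rules
AB: A(a) + B(b) -> A(a!1).B(b!1) 1.0 @SAC
end reaction rules")
  geom <- geometry_spec(data.frame(type = c("A", "B"), mass = c(15, 15)))
  w <- init_world(m, geom, counts = c(A = 1, B = 1),
                  box = matrix(c(-50, 50), 2, 3), seed = 2,
                  params = force_params(pair = "none"))
  w$particles[, c("x", "y", "z")] <- matrix(c(0, 0, 0, 20, 0, 0),
                                            2, byrow = TRUE)
  w_off <- set_switch(w, "SAC", FALSE)
  expect_equal(nrow(fire_reactions(w_off)$events), 0L)
  expect_equal(nrow(fire_reactions(w)$events), 1L)
})

test_that("protocols execute phases in order and add molecules exactly", {
  m <- toy_model()
  w <- toy_world(4)
  res0 <- run_protocol(w, sim_protocol(phase_run(0), dump_interval = 0))
  expect_length(res0$trajectory, 1L)        # initial snapshot only
  expect_equal(res0$world$step, 0L)
  res <- run_protocol(w, sim_protocol(
    phase_run(100), phase_add("A", 5), phase_run(100), dump_interval = 0))
  expect_equal(nrow(res$world$particles), 9L)
  expect_equal(res$world$step, 200L)
  # per-type counts only change via add phases
  expect_equal(sum(res$world$particles$type == "A"), 9L)
})

test_that("identical seeds give bit-identical trajectories and bond logs", {
  run_once <- function() {
    fx <- toy_polymer_fixture(8, seed = 77)
    run_protocol(fx$world, sim_protocol(phase_run(1500), dump_interval = 500))
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_identical(r1$events, r2$events)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$world$particles, r2$world$particles)
})

test_that("bond bookkeeping: formed minus broken equals the standing count", {
  m <- parse_model("
begin molecule types
A(a,a,b~none~mod)
end molecule types
begin reaction rules
grow: A(a) + A(a) -> A(a!1).A(a!1) 1.0
split: A(a!1).A(a!1) -> A(a) + A(a) 0.05
end reaction rules")
  fx <- toy_polymer_fixture(10, seed = 3)
  w <- fx$world
  w$model <- m
  res <- run_protocol(w, sim_protocol(phase_run(3000), dump_interval = 0))
  formed <- sum(res$events$action == "formed")
  broken <- sum(res$events$action == "broken")
  expect_gt(broken, 0L)       # the unbinding channel is exercised
  expect_equal(formed - broken, nrow(bond_list(res$world)))
})

test_that("with p = 1 and global reach the engine saturates like exhaustive rewriting", {
  m <- toy_model()
  geom <- geometry_spec(data.frame(type = "A", mass = 15),
                        sites = data.frame(type = "A", site = "a",
                                           phi = NA, theta = NA, len = 500))
  for (n in c(2L, 4L, 6L)) {
    w0 <- init_world(m, geom, counts = c(A = n),
                     box = matrix(c(-60, 60), 2, 3), seed = n,
                     params = force_params(pair = "none"))
    oracle <- exhaustive_apply(w0, m)
    w <- w0
    for (k in 1:8) w <- fire_reactions(w)$world
    expect_length(srbm:::.match_rule_lhs(m$rules[[1]], w), 0L)
    expect_equal(nrow(bond_list(w)), nrow(bond_list(oracle)))
    # saturation: every polymerization site is bound
    expect_true(all(!is.na(w$sites$bond[w$sites$name == "a"])))
  }
})

test_that("declared site angles veto out-of-cone binding on oriented particles", {
  m <- parse_model("
begin molecule types
A(c)
B(c)
end molecule types
begin reaction rules
bindAB: A(c) + B(c) -> A(c!1).B(c!1) 1.0
end reaction rules")
  # A's site points along +z (zenith), placed on a rigid single-member
  # template so its orientation is tracked; B is isotropic
  geom <- geometry_spec(data.frame(type = c("A", "B"), mass = c(15, 15)),
                        sites = data.frame(type = "A", site = "c",
                                           phi = 0, theta = 0, len = 15))
  tp <- template_def("anchorA", data.frame(type = "A", x = 0, y = 0, z = 0),
                     rigid = TRUE, fixed = TRUE)
  build <- function(bz) {
    w <- init_world(m, geom, templates = list(anchorA = tp),
                    box = matrix(c(-60, 60), 2, 3),
                    explicit = data.frame(what = c("anchorA", "B"),
                                          x = 0, y = 0, z = c(0, bz)),
                    seed = 1, params = force_params(pair = "none"))
    w
  }
  above <- fire_reactions(build(25))    # partner inside the +z cone
  expect_equal(nrow(above$events), 1L)
  below <- fire_reactions(build(-25))   # same distance, opposite side
  expect_equal(nrow(below$events), 0L)
})

test_that("runaway time-steps abort with a diagnostic", {
  w <- toy_world(2, params = force_params(kT = 1, gamma = 1e-6, dt = 50,
                                          pair = "none"))
  expect_error(step_dynamics(w, 10), "instability")
})

test_that("zero-count initialisation leaves only explicit anchors", {
  tabs <- load_hmk_tables()
  w <- init_world(tabs$model, tabs$geometry, tabs$templates,
                  box = matrix(c(-200, 200), 2, 3),
                  explicit = data.frame(what = "NucCenpA",
                                        x = 0, y = 0, z = 0),
                  seed = 1, params = hmk_force_params())
  expect_equal(nrow(w$particles), 8L)
  expect_true(all(w$particles$group == 1L))
})

test_that("explicit placement honours coordinates exactly", {
  m <- toy_model()
  geom <- geometry_spec(data.frame(type = "A", mass = 15))
  w <- init_world(m, geom, box = matrix(c(-50, 50), 2, 3),
                  explicit = data.frame(what = "A", x = 3, y = -4, z = 5),
                  seed = 1)
  expect_equal(as.numeric(w$particles[1, c("x", "y", "z")]), c(3, -4, 5))
  # random placement respects the requested ranges
  rng <- matrix(c(-10, 10, 0, 20, -5, 5), 2)
  w2 <- init_world(m, geom, counts = c(A = 40),
                   box = matrix(c(-50, 50), 2, 3), ranges = rng, seed = 2)
  p <- w2$particles
  expect_true(all(p$x >= -10 & p$x <= 10 & p$y >= 0 & p$y <= 20 &
                    p$z >= -5 & p$z <= 5))
})
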