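# Bundled human mitotic kinetochore (HMK) model: protein geometry,
# interaction rules, structural templates, rosette initial layout, the
# four simulation variants, and a toy-polymer fixture generator.

.hmk_file <- function(name)
  system.file("extdata", "hmk", name, package = "srbm", mustWork = TRUE)

# --- fixture generation ----------------------------------------------------

# protein table: mass (kDa) and the published radius (Angstrom); the radius
# column is retained verbatim, including the internally inconsistent CenpO
# row, and is what the simulator uses
.hmk_geometry_rows <- function() {
  txt <- "
CenpA 16.00 15.33
CenpB 65.00 24.46
CenpC 107.00 28.88
CenpI 87.00 26.95
CenpK 31.50 19.21
CenpM 20.00 16.51
CenpN 39.50 20.71
CenpO 34.00 19.00
CenpP 33.00 19.51
CenpQ 30.50 19.01
CenpR 20.00 16.51
CenpS 16.00 15.33
CenpT 60.50 23.88
CenpU 47.50 22.03
CenpW 10.00 13.10
CenpX 9.00 12.65
H3 15.00 15.00
Dsn1 40.00 20.8
Mis12 24.00 17.55
Nnf1 23.50 17.42
Nsl1 32.00 19.31
Hec1 74.00 25.54
Nuf2 54.00 22.99
Spc24 22.50 17.17
Spc25 26.00 18.02
Knl1 265.00 39.07
Apc1 216.50 36.53
Apc2 94.00 27.66
Apc3 92.00 27.46
Apc4 92.00 27.46
Apc5 85.00 26.75
Apc6 71.50 25.25
Apc7 67.00 24.71
Apc8 69.00 24.95
Apc10 21.00 16.78
Apc11 10.00 13.11
Apc12 10.00 13.11
Apc13 8.50 12.41
Cdc20 55.00 23.13
Mad1 83.00 26.53
Mad2 23.50 17.42
Bub1 122.00 30.17
BubR1 120.00 30.00
Bub3 37.00 20.27
Mps1 97.00 27.95
Zwint 31.00 19.11
Zwilch 67.00 24.71
Zw10 89.00 27.16
Rod1 250.00 38.32"
  m <- do.call(rbind, strsplit(.trim(strsplit(txt, "\n")[[1]][-1]), " "))
  data.frame(type = m[, 1], mass = as.numeric(m[, 2]),
             radius = as.numeric(m[, 3]), stringsAsFactors = FALSE)
}

# members of the nucleosome octamers and of the attachment machinery whose
# masses are not in the published table; synthetic additions with radii
# from the same constant-density rule
.hmk_geometry_synthetic_rows <- function() {
  df <- data.frame(
    type = c("H4", "H2A", "H2B", "Ska1", "Ska2", "Ska3", "MT"),
    mass = c(11.4, 14.0, 13.8, 29.5, 14.0, 46.0, 110.0),
    stringsAsFactors = FALSE)
  df$radius <- round(radius_from_mass(df$mass), 2)
  df
}

# interaction pairs (deduplicated partner listing); SAC-internal pairs are
# gated by the "SAC" switch
.hmk_interaction_rows <- function() {
  pairs <- list(
    c("CenpA", "CenpB"), c("CenpA", "CenpN"), c("CenpA", "CenpC"),
    c("CenpB", "CenpW"), c("CenpB", "CenpQ"), c("CenpB", "CenpU"),
    c("CenpB", "CenpC"),
    c("CenpI", "CenpU"),
    c("CenpK", "CenpO"), c("CenpK", "CenpR"), c("CenpK", "CenpU"),
    c("CenpK", "CenpN"),
    c("CenpM", "CenpS"), c("CenpM", "CenpU"), c("CenpM", "CenpT"),
    c("CenpM", "H3"),
    c("CenpO", "CenpP"), c("CenpO", "CenpU"), c("CenpO", "CenpQ"),
    c("CenpP", "CenpU"), c("CenpP", "CenpQ"),
    c("CenpQ", "CenpU"),
    c("CenpR", "CenpU"),
    c("CenpS", "H3"), c("CenpS", "CenpT"), c("CenpS", "CenpX"),
    c("CenpT", "H3"),
    c("CenpW", "H3"),
    c("Dsn1", "Mis12"), c("Dsn1", "Nsl1"),
    c("Nnf1", "Mis12"), c("Nnf1", "CenpC"),
    c("Nsl1", "Spc24"), c("Nsl1", "Spc25"),
    c("Hec1", "Nuf2"),
    c("Nuf2", "Spc25"),
    c("Spc24", "Spc25"), c("Spc24", "CenpT"),
    c("Cdc20", "Mad2"), c("Cdc20", "BubR1"), c("Cdc20", "Apc2"),
    c("Mad2", "Mad1"), c("Mad2", "Rod1"), c("Mad2", "Zw10"),
    c("Mad1", "Bub1"), c("Mad1", "Rod1"), c("Mad1", "Zw10"),
    c("Bub3", "Bub1"), c("Bub3", "BubR1"),
    c("BubR1", "Bub1"), c("BubR1", "Knl1"), c("BubR1", "Apc3"),
    c("BubR1", "Apc4"), c("BubR1", "Apc5"), c("BubR1", "Mps1"),
    c("BubR1", "Rod1"), c("BubR1", "Zw10"),
    c("Bub1", "Knl1"),
    c("Mps1", "Mis12"), c("Mps1", "Hec1"),
    c("Zwint", "Zw10"), c("Zwint", "Knl1"), c("Zwint", "Mis12"),
    c("Zwilch", "Rod1"), c("Zwilch", "Zw10"),
    c("Zw10", "Rod1"), c("Zw10", "Knl1"))
  sac_set <- c("Mad1", "Mad2", "Cdc20", "Bub1", "Bub3", "BubR1", "Mps1",
               "Rod1", "Zw10", "Zwilch", "Zwint",
               paste0("Apc", c(1:8, 10:13)))
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(protein_a = p[1], protein_b = p[2],
               site_a = tolower(p[2]), site_b = tolower(p[1]),
               rate_tag = "",
               switch_tag = if (all(p %in% sac_set)) "SAC" else "",
               stringsAsFactors = FALSE)
  }))
}

# microtubule attachment rules are not part of the published pair list
.hmk_interaction_synthetic_rows <- function() {
  data.frame(protein_a = c("Hec1", "Ska3"), protein_b = c("MT", "MT"),
             site_a = c("mt", "mt"), site_b = c("hec1", "ska3"),
             rate_tag = "", switch_tag = "", stringsAsFactors = FALSE)
}

# histone-octamer bead layout: two staggered rings of four
.octamer_members <- function(types, active, ring_r = 20, half_h = 12) {
  ang_top <- (0:3) * 90 * pi / 180
  ang_bot <- ((0:3) * 90 + 45) * pi / 180
  data.frame(type = types,
             x = c(ring_r * cos(ang_top), ring_r * cos(ang_bot)),
             y = c(ring_r * sin(ang_top), ring_r * sin(ang_bot)),
             z = c(rep(half_h, 4), rep(-half_h, 4)),
             active = active, stringsAsFactors = FALSE)
}

# linear chain of touching beads along x, centred
.chain_members <- function(types, geometry, zigzag = 0) {
  r <- .geom_radius(geometry, types)
  n <- length(types)
  x <- numeric(n)
  for (k in seq_len(n)[-1]) x[k] <- x[k - 1] + r[k - 1] + r[k]
  z <- if (zigzag > 0) rep_len(c(0, zigzag), n) else rep(0, n)
  data.frame(type = types, x = x - mean(x), y = 0, z = z - mean(z),
             active = TRUE, stringsAsFactors = FALSE)
}

# rigid microtubule: rings of tubulin beads forming a ~25 nm cylinder
.mt_members <- function(geometry, n_ring = 8, n_len = 3, outer_d = 250) {
  r <- .geom_radius(geometry, "MT")
  ring_r <- outer_d / 2 - r
  ang <- (seq_len(n_ring) - 1) * 2 * pi / n_ring
  out <- NULL
  for (k in seq_len(n_len)) {
    out <- rbind(out, data.frame(
      type = "MT", x = ring_r * cos(ang), y = ring_r * sin(ang),
      z = (k - (n_len + 1) / 2) * 2 * r, active = TRUE,
      stringsAsFactors = FALSE))
  }
  out
}

# all HMK structural templates (coordinates are package modelling choices;
# the published model names the compositions but no internal geometry)
.hmk_templates <- function(geometry) {
  oct_cenpa <- .octamer_members(
    c("CenpA", "H4", "CenpA", "H4", "H2A", "H2B", "H2A", "H2B"),
    active = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
  oct_h3 <- .octamer_members(
    c("H3", "H4", "H3", "H4", "H2A", "H2B", "H2A", "H2B"),
    active = rep(TRUE, 8))
  list(
    NucCenpA = template_def("NucCenpA", oct_cenpa, rigid = TRUE,
                            fixed = TRUE, rot_free = TRUE),
    NucH3 = template_def("NucH3", oct_h3, rigid = TRUE, fixed = TRUE,
                         rot_free = TRUE),
    Mis12C = template_def("Mis12C",
      .chain_members(c("Nnf1", "Mis12", "Dsn1", "Nsl1"), geometry)),
    Ndc80C = template_def("Ndc80C",
      .chain_members(c("Spc24", "Spc25", "Nuf2", "Hec1"), geometry)),
    MadMad2 = template_def("MadMad2",
      .chain_members(c("Mad1", "Mad2"), geometry)),
    RZZ = template_def("RZZ",
      .chain_members(c("Rod1", "Zw10", "Zwilch"), geometry)),
    APC = template_def("APC",
      .chain_members(paste0("Apc", c(1:8, 10:13)), geometry)),
    Ska = template_def("Ska",
      .chain_members(c("Ska3", "Ska2", "Ska1", "Ska1", "Ska2", "Ska3"),
                     geometry, zigzag = 25)),
    MT = template_def("MT", .mt_members(geometry), rigid = TRUE,
                      fixed = TRUE))
}

#' Regenerate the packaged HMK fixture files
#'
#' Writes the geometry, interaction and template tables to `dir` in the
#' package's TSV formats. Files with `_synthetic` in the name contain
#' quantities that are package modelling choices, not published values.
#'
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
hmk_write_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  w(.hmk_geometry_rows(), "hmk_geometry.tsv")
  w(.hmk_geometry_synthetic_rows(), "hmk_geometry_synthetic.tsv")
  w(.hmk_interaction_rows(), "hmk_interactions.tsv")
  w(.hmk_interaction_synthetic_rows(), "hmk_interactions_synthetic.tsv")
  geom <- geometry_spec(rbind(.hmk_geometry_rows(),
                              .hmk_geometry_synthetic_rows()))
  write_template_table(.hmk_templates(geom), file.path(dir,
    "hmk_templates_synthetic.tsv"))
  invisible(dir)
}

#' Load the bundled kinetochore tables
#'
#' Builds the geometry specification (one entry per protein of the
#' published table, mass and printed radius both retained, plus the
#' synthetic octamer/attachment additions), the molecule types (one
#' specific binding site per listed partner) and one bind rule per
#' deduplicated interaction pair; SAC-internal rules carry the `SAC`
#' switch tag.
#'
#' @return list with `geometry` (`srbm_geometry`), `model` (`srbm_model`),
#'   `interactions` (the pair table), and `templates`.
#' @export
load_hmk_tables <- function() {
  geo_df <- rbind(
    read.delim(.hmk_file("hmk_geometry.tsv"), stringsAsFactors = FALSE),
    read.delim(.hmk_file("hmk_geometry_synthetic.tsv"),
               stringsAsFactors = FALSE))
  if (anyDuplicated(geo_df$type)) stop("duplicate geometry rows")
  inter <- rbind(
    read_interaction_table(.hmk_file("hmk_interactions.tsv")),
    read_interaction_table(.hmk_file("hmk_interactions_synthetic.tsv")))
  key <- apply(inter[, c("protein_a", "protein_b")], 1,
               function(r) paste(sort(r), collapse = "-"))
  if (anyDuplicated(key)) stop("duplicate interaction rows")
  geometry <- geometry_spec(geo_df)
  # molecule types: one site per interaction partner
  types <- list()
  for (ty in geo_df$type) {
    sa <- inter$site_a[inter$protein_a == ty]
    sb <- inter$site_b[inter$protein_b == ty]
    types[[ty]] <- molecule_type(ty, c(sa, sb))
  }
  rules <- interactions_to_rules(inter)
  model <- structure(list(types = types, rules = rules, params = numeric(),
                          switches = .default_switches(rules)),
                     class = "srbm_model")
  .validate_model(model)
  templates <- read_template_table(.hmk_file("hmk_templates_synthetic.tsv"))
  list(geometry = geometry, model = model, interactions = inter,
       templates = templates)
}

#' Kinetochore simulation variants
#'
#' The four studied conditions: an unattached kinetochore (SAC signaling
#' on, no microtubule) and kinetochores attached to one, two or three
#' microtubules (SAC off, Ska complex present; two or more microtubules
#' come with a three-fold increase of protein copies).
#'
#' @param name one of `"unattached"`, `"attached_1MT"`, `"attached_2MT"`,
#'   `"attached_3MT"`.
#' @return an object of class `srbm_hmk_variant`.
#' @export
hmk_variant <- function(name = c("unattached", "attached_1MT",
                                 "attached_2MT", "attached_3MT")) {
  name <- match.arg(name)
  mt <- c(unattached = 0L, attached_1MT = 1L, attached_2MT = 2L,
          attached_3MT = 3L)[[name]]
  structure(list(name = name, sac_on = mt == 0L, microtubules = mt,
                 multiplier = if (mt >= 2L) 3L else 1L,
                 templates = c("NucCenpA", "NucH3", "Mis12C", "Ndc80C",
                               "MadMad2", "RZZ", "APC",
                               if (mt > 0L) c("Ska", "MT"))),
            class = "srbm_hmk_variant")
}

#' @export
print.srbm_hmk_variant <- function(x, ...) {
  cat("HMK variant '", x$name, "': ", x$microtubules, " microtubule(s), SAC ",
      if (x$sac_on) "on" else "off", ", copy multiplier x", x$multiplier,
      "\n", sep = "")
  invisible(x)
}

#' Copy numbers per molecule type for one variant
#'
#' Every protein occurs six times per simulation, except CenpA (one
#' binding-competent copy) and CenpN (two); two or more microtubules imply
#' a three-fold increase. Used for bond-frequency capacities.
#'
#' @param variant an [hmk_variant()].
#' @return named integer vector of copy numbers.
#' @export
hmk_copies <- function(variant = hmk_variant("unattached")) {
  tabs <- load_hmk_tables()
  copies <- setNames(rep(6L, length(tabs$model$types)),
                     names(tabs$model$types))
  copies["CenpA"] <- 1L
  copies["CenpN"] <- 2L
  copies["H3"] <- 12L       # two H3 beads in each of the six petals
  copies[c("H4", "H2A", "H2B")] <- 0L
  copies[c("Ska1", "Ska2", "Ska3")] <-
    if (variant$microtubules > 0L) 12L else 0L
  copies["MT"] <- 24L * variant$microtubules
  mult <- variant$multiplier
  if (mult > 1L) {
    scale <- setdiff(names(copies),
                     c("CenpA", "H3", "H4", "H2A", "H2B", "MT"))
    copies[scale] <- copies[scale] * mult
  }
  copies
}

#' Reduced-scale HMK dynamics parameters
#'
#' The published runs use reduced units kT = 1, gamma = 1, dt = 5e-3 over
#' millions of steps. The reduced preset rescales the time-step and
#' friction (dt = 0.5, gamma = 0.05, so the per-step diffusive displacement
#' is about 4.5 Angstrom, still well below any binding reach) so the
#' reactor is explored within tens of thousands of steps; see the methods
#' vignette.
#'
#' @param scaled use the reduced preset (default) or the slow published
#'   regime.
#' @return a [force_params()] list with the centering drag enabled.
#' @export
hmk_force_params <- function(scaled = TRUE) {
  if (scaled)
    force_params(dt = 0.5, gamma = 0.05, k_bond = 0.05, epsilon = 1,
                 fcap = 0.2, rot_diff = 1e-3, react_every = 5L,
                 drag = list(center = c(0, 0, 0), radius = 250, k = 0.01))
  else
    force_params(dt = 5e-3, gamma = 1, k_bond = 10, epsilon = 1,
                 fcap = 100, rot_diff = 0.1, react_every = 1L,
                 drag = list(center = c(0, 0, 0), radius = 250, k = 1))
}

#' Build a kinetochore world and protocol for one variant
#'
#' The CenpA nucleosome (eight-bead rigid octamer) is fixed at the reactor
#' centre; six H3 nucleosomes are fixed on a regular hexagon 14 nm from the
#' centre, free to rotate about their centres; all other molecules and
#' templates are placed randomly in the ranges x (-400, 400), y (-400,
#' 800), z (-400, 400) Angstrom with copy number 6 (times the variant
#' multiplier), except one binding-competent CenpA and two CenpN; a
#' centering drag keeps diffusing molecules near the rosette; the SAC
#' switch is set by the variant. Attached variants add the Ska complex and
#' fixed microtubule cylinders.
#'
#' @param variant an [hmk_variant()] (or its name).
#' @param seed RNG seed.
#' @param steps protocol length in time-steps.
#' @param dump_interval snapshot period.
#' @param params dynamics parameters, see [hmk_force_params()].
#' @return list with `world`, `protocol`, `tables` and the nucleosome
#'   particle-id groups (`anchors`).
#' @export
build_variant_world <- function(variant = hmk_variant("unattached"),
                                seed = NULL, steps = 50000L,
                                dump_interval = 5000L,
                                params = hmk_force_params()) {
  if (is.character(variant)) variant <- hmk_variant(variant)
  tabs <- load_hmk_tables()
  box <- matrix(c(-400, 400, -400, 800, -400, 400), nrow = 2)
  hex <- 0:5 * 60 * pi / 180
  explicit <- data.frame(
    what = c("NucCenpA", rep("NucH3", 6),
             if (variant$microtubules > 0L)
               rep("MT", variant$microtubules)),
    x = c(0, 140 * cos(hex),
          if (variant$microtubules > 0L)
            300 * (seq_len(variant$microtubules) -
                     (variant$microtubules + 1) / 2)),
    y = c(0, rep(0, 6), rep(500, variant$microtubules)),
    z = c(0, 140 * sin(hex), rep(0, variant$microtubules)),
    stringsAsFactors = FALSE)
  mult <- variant$multiplier
  counts <- c(
    CenpB = 6, CenpC = 6, CenpI = 6, CenpK = 6, CenpM = 6, CenpN = 2,
    CenpO = 6, CenpP = 6, CenpQ = 6, CenpR = 6, CenpS = 6, CenpT = 6,
    CenpU = 6, CenpW = 6, CenpX = 6, Knl1 = 6, Cdc20 = 6, Bub1 = 6,
    Bub3 = 6, BubR1 = 6, Mps1 = 6, Zwint = 6,
    Mis12C = 6, Ndc80C = 6, MadMad2 = 6, RZZ = 6, APC = 6,
    if (variant$microtubules > 0L) c(Ska = 6))
  counts <- round(counts * mult)
  world <- init_world(tabs$model, tabs$geometry, tabs$templates,
                      counts = counts, box = box, explicit = explicit,
                      seed = seed, params = params)
  world <- set_switch(world, "SAC", variant$sac_on)
  anchors <- lapply(seq_len(7L), function(g)
    world$particles$id[!is.na(world$particles$group) &
                         world$particles$group == g])
  protocol <- sim_protocol(phase_run(steps), dump_interval = dump_interval)
  list(world = world, protocol = protocol, tables = tabs, anchors = anchors,
       variant = variant)
}

#' Run a replicate campaign of one HMK variant
#'
#' Builds and simulates `n_runs` independent replicates (seeds
#' `seed + 1 .. seed + n_runs`) and collects the final worlds, the bond
#' logs and the nucleosome anchor groups.
#'
#' @param variant an [hmk_variant()] or its name.
#' @param n_runs number of replicate simulations.
#' @param steps time-steps per run.
#' @param seed base seed.
#' @param params dynamics parameters.
#' @return list with `worlds`, `events`, `anchors`, `copies`, `model`.
#' @export
hmk_campaign <- function(variant = "unattached", n_runs = 20L,
                         steps = 50000L, seed = 1L,
                         params = hmk_force_params()) {
  if (is.character(variant)) variant <- hmk_variant(variant)
  worlds <- list()
  events <- list()
  anchors <- NULL
  model <- NULL
  for (r in seq_len(n_runs)) {
    bv <- build_variant_world(variant, seed = seed + r, steps = steps,
                              dump_interval = 0L, params = params)
    res <- run_protocol(bv$world, bv$protocol)
    worlds[[r]] <- res$world
    events[[r]] <- res$events
    anchors <- bv$anchors
    model <- bv$tables$model
  }
  list(worlds = worlds, events = events, anchors = anchors,
       copies = hmk_copies(variant), model = model)
}

# --- toy polymer fixture ---------------------------------------------------

#' Toy polymer model for tests
#'
#' A single monomer type `A(a, a, b~none~mod)` with two interchangeable
#' polymerization sites. The plain variant polymerizes unconditionally;
#' the nucleation variant gates polymerization on the `b~mod` label and
#' adds a propagation rule that passes the modification across each new
#' bond, so chains can only grow from a pre-modified seed monomer.
#'
#' @param n_monomers number of monomers placed randomly.
#' @param with_nucleation use the context-gated rule pair.
#' @param seeded pre-modify one monomer (default: `with_nucleation`).
#' @param seed RNG seed.
#' @param box_half half-extent of the cubic reactor (Angstrom).
#' @param params dynamics parameters (defaults to the reduced preset
#'   without drag).
#' @return list with `model`, `geometry`, `world`.
#' @export
toy_polymer_fixture <- function(n_monomers, with_nucleation = FALSE,
                                seeded = with_nucleation, seed = NULL,
                                box_half = 80,
                                params = NULL) {
  stopifnot(n_monomers >= 1)
  rules <- if (with_nucleation) "
begin reaction rules
grow: A(a) + A(a,b~mod) -> A(a!1).A(a!1,b~mod) 1.0
pass: A(a!1,b~mod).A(a!1,b~none) -> A(a!1,b~mod).A(a!1,b~mod) 100.0
end reaction rules" else "
begin reaction rules
grow: A(a) + A(a) -> A(a!1).A(a!1) 1.0
end reaction rules"
  model <- parse_model(paste0("
begin molecule types
A(a,a,b~none~mod)
end molecule types", rules))
  geometry <- geometry_spec(data.frame(type = "A", mass = 15,
                                       radius = NA_real_))
  if (is.null(params))
    params <- force_params(dt = 0.5, gamma = 0.05, k_bond = 0.05,
                           fcap = 0.2, react_every = 2L)
  box <- matrix(c(-box_half, box_half), 2, 3)
  world <- init_world(model, geometry, counts = c(A = n_monomers),
                      box = box, seed = seed, params = params)
  if (seeded) {
    first <- world$particles$id[1]
    brow <- which(world$sites$particle == first & world$sites$name == "b")
    world$sites$mod[brow] <- "mod"
  }
  list(model = model, geometry = geometry, world = world)
}
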