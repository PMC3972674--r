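# Molecular geometry: sphere radii from mass, site placement in spherical
# coordinates, and multi-particle structural templates.

#' Sphere radius from molecular mass
#'
#' Coarse constant-density approximation: all molecules are spheres of the
#' same density, so the radius scales with the cube root of the mass. The
#' reference pair defaults to histone H3 (15 kDa, 15.00 Angstrom).
#'
#' @param mass molecular mass in kDa (vectorised).
#' @param ref_mass,ref_radius calibration point (kDa, Angstrom).
#' @return radius in Angstrom.
#' @examples
#' radius_from_mass(120)  # 8x the reference mass => twice the radius: 30
#' @export
radius_from_mass <- function(mass, ref_mass = 15, ref_radius = 15) {
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("mass must be positive")
  ref_radius * (mass / ref_mass)^(1 / 3)
}

#' Cartesian offset of a binding site
#'
#' Converts a site placement in spherical coordinates to a Cartesian offset
#' in the molecule's body frame: `phi` is the angle from the zenith (+z)
#' axis, `theta` the azimuth around it, `length` the bond reach.
#'
#' @param phi degrees from the zenith axis, in `[0, 180]`.
#' @param theta degrees of azimuth, in `[0, 360)`.
#' @param length bond reach in Angstrom (> 0); typically the molecule
#'   radius, so reactions occur on the surface.
#' @return numeric 3-vector (Angstrom).
#' @export
site_to_cartesian <- function(phi, theta, length) {
  if (phi < 0 || phi > 180) stop("phi must be in [0, 180] degrees")
  if (theta < 0 || theta >= 360) stop("theta must be in [0, 360) degrees")
  if (length <= 0) stop("length must be positive")
  p <- phi * pi / 180
  t <- theta * pi / 180
  c(length * sin(p) * cos(t), length * sin(p) * sin(t), length * cos(p))
}

#' Build a geometry specification table
#'
#' A geometry spec records, per molecule type, the mass, the sphere radius
#' (computed from mass via [radius_from_mass()] when absent) and optional
#' per-site placements. Sites without placements are isotropic: the whole
#' surface is equally reactive and the reach defaults to the radius.
#'
#' @param types data frame with columns `type`, `mass` (kDa) and optionally
#'   `radius` (Angstrom; `NA` = derive from mass).
#' @param sites optional data frame with columns `type`, `site`, `phi`,
#'   `theta` (degrees, `NA` = isotropic) and `len` (Angstrom, `NA` = radius).
#' @param ref_mass,ref_radius calibration passed to [radius_from_mass()].
#' @return an object of class `srbm_geometry`.
#' @export
geometry_spec <- function(types, sites = NULL, ref_mass = 15, ref_radius = 15) {
  stopifnot(is.data.frame(types), all(c("type", "mass") %in% names(types)))
  if (anyDuplicated(types$type)) stop("duplicate geometry rows")
  if (is.null(types$radius)) types$radius <- NA_real_
  miss <- is.na(types$radius)
  types$radius[miss] <- radius_from_mass(types$mass[miss], ref_mass, ref_radius)
  if (any(types$radius <= 0)) stop("radius must be positive")
  if (is.null(sites))
    sites <- data.frame(type = character(), site = character(),
                        phi = numeric(), theta = numeric(), len = numeric(),
                        stringsAsFactors = FALSE)
  structure(list(types = types, sites = sites), class = "srbm_geometry")
}

.geom_radius <- function(geometry, type) {
  i <- match(type, geometry$types$type)
  if (anyNA(i)) stop("no geometry for type(s): ",
                     paste(unique(type[is.na(i)]), collapse = ", "))
  geometry$types$radius[i]
}

# reach, phi, theta for one site occurrence of a type (NA angles = isotropic)
.geom_site <- function(geometry, type, site) {
  r <- .geom_radius(geometry, type)
  g <- geometry$sites
  hit <- which(g$type == type & g$site == site)
  if (length(hit)) {
    len <- g$len[hit[1]]
    if (is.na(len)) len <- r
    list(len = len, phi = g$phi[hit[1]], theta = g$theta[hit[1]])
  } else list(len = r, phi = NA_real_, theta = NA_real_)
}

#' Read / write a tab-separated geometry table
#'
#' Columns: `type`, `mass` (kDa), optional `radius` (Angstrom), and optional
#' site placement columns `site`, `phi`, `theta`, `len` on additional rows.
#' Rows with an empty `site` declare the type; rows with a site name add a
#' placement.
#'
#' @param file TSV path.
#' @param ... passed to [geometry_spec()].
#' @return an `srbm_geometry`.
#' @export
read_geometry_table <- function(file, ...) {
  df <- read.delim(file, stringsAsFactors = FALSE, comment.char = "#")
  if (!"site" %in% names(df)) df$site <- ""
  df$site[is.na(df$site)] <- ""
  tys <- df[df$site == "", intersect(c("type", "mass", "radius"), names(df))]
  st <- df[df$site != "", , drop = FALSE]
  sites <- if (nrow(st)) {
    for (col in c("phi", "theta", "len")) if (is.null(st[[col]])) st[[col]] <- NA_real_
    st[, c("type", "site", "phi", "theta", "len")]
  } else NULL
  geometry_spec(tys, sites, ...)
}

#' @export
print.srbm_geometry <- function(x, ...) {
  cat("srbm geometry:", nrow(x$types), "molecule types")
  if (nrow(x$sites)) cat(",", nrow(x$sites), "site placements")
  cat("\n")
  print(utils::head(x$types, 10))
  if (nrow(x$types) > 10) cat("...\n")
  invisible(x)
}

#' Define a structural template
#'
#' A template is a predefined multi-particle assembly: member molecule types
#' at relative coordinates, optionally rigid (all pairwise member distances
#' preserved), anchored in space (`fixed`), and/or free to rotate about its
#' centroid (`rot_free`).
#'
#' @param name template name.
#' @param members data frame with columns `type`, `x`, `y`, `z` (Angstrom)
#'   and optionally `active` (logical; inactive members carry no binding
#'   sites).
#' @param rigid,fixed,rot_free flags.
#' @return an object of class `srbm_template`.
#' @export
template_def <- function(name, members, rigid = FALSE, fixed = FALSE,
                         rot_free = FALSE) {
  stopifnot(is.data.frame(members),
            all(c("type", "x", "y", "z") %in% names(members)))
  if (is.null(members$active)) members$active <- TRUE
  structure(list(name = name, members = members, rigid = rigid,
                 fixed = fixed, rot_free = rot_free),
            class = "srbm_template")
}

#' Read a tab-separated template table
#'
#' Columns: `template`, `member`, `type`, `x`, `y`, `z`, `rigid`, `fixed`,
#' and optionally `rot_free` and `active`.
#'
#' @param file TSV path.
#' @return named list of `srbm_template` objects.
#' @export
read_template_table <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE, comment.char = "#")
  out <- list()
  for (nm in unique(df$template)) {
    d <- df[df$template == nm, ]
    d <- d[order(d$member), ]
    mem <- data.frame(type = d$type, x = d$x, y = d$y, z = d$z,
                      active = if (is.null(d$active)) TRUE else as.logical(d$active),
                      stringsAsFactors = FALSE)
    out[[nm]] <- template_def(nm, mem,
                              rigid = as.logical(d$rigid[1]),
                              fixed = as.logical(d$fixed[1]),
                              rot_free = if (is.null(d$rot_free)) FALSE
                                         else as.logical(d$rot_free[1]))
  }
  out
}

#' Write templates to a tab-separated table
#' @param templates named list of `srbm_template`.
#' @param file output TSV path.
#' @export
write_template_table <- function(templates, file) {
  rows <- do.call(rbind, lapply(templates, function(tp) {
    data.frame(template = tp$name, member = seq_len(nrow(tp$members)),
               type = tp$members$type, x = tp$members$x, y = tp$members$y,
               z = tp$members$z, rigid = tp$rigid, fixed = tp$fixed,
               rot_free = tp$rot_free, active = tp$members$active,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Instantiate a structural template
#'
#' Creates particle instances at the template's relative coordinates
#' (translated to `at`, optionally rotated), registers the rigid constraint
#' group and fixed-position anchor as requested, pre-forms internal bonds
#' between touching members (site bonds where matching free partner sites
#' exist, structural springs otherwise), and warns about overlapping
#' members (pair distance below half the sum of radii).
#'
#' @param world an `srbm_world`.
#' @param template an `srbm_template` (or name of a template registered in
#'   `world$templates`).
#' @param at centroid position (Angstrom 3-vector).
#' @param rotation optional 3x3 rotation matrix applied to member offsets.
#' @return the updated world.
#' @export
build_template <- function(world, template, at = c(0, 0, 0), rotation = NULL) {
  if (is.character(template)) {
    template <- world$templates[[template]]
    if (is.null(template)) stop("unknown template")
  }
  mem <- template$members
  xyz <- as.matrix(mem[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(xyz))
  if (!is.null(rotation)) xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, at, "+")
  radii <- .geom_radius(world$geometry, mem$type)
  gid <- nrow(world$groups) + 1L
  world$groups <- rbind(world$groups,
    data.frame(id = gid, name = template$name, rigid = template$rigid,
               fixed = template$fixed, rot_free = template$rot_free,
               stringsAsFactors = FALSE))
  ids <- integer(nrow(mem))
  for (i in seq_len(nrow(mem))) {
    res <- .append_particle(world, mem$type[i], xyz[i, ], group = gid,
                            with_sites = isTRUE(mem$active[i]))
    world <- res$world
    ids[i] <- res$id
  }
  # internal bonds between touching members; overlap check
  n <- nrow(mem)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d < 0.5 * (radii[i] + radii[j]))
      warning(sprintf("template '%s': members %d and %d overlap (%.1f A)",
                      template$name, i, j, d))
    if (d <= 1.05 * (radii[i] + radii[j])) {
      bonded <- FALSE
      # prefer a site bond when both members expose matching free partner
      # sites named after each other's type (lowercased)
      ri <- which(world$sites$particle == ids[i] &
                    world$sites$name == tolower(mem$type[j]) &
                    is.na(world$sites$bond))
      rj <- which(world$sites$particle == ids[j] &
                    world$sites$name == tolower(mem$type[i]) &
                    is.na(world$sites$bond))
      if (length(ri) && length(rj)) {
        world$sites$bond[ri[1]] <- rj[1]
        world$sites$bond[rj[1]] <- ri[1]
        bonded <- TRUE
        rid <- .find_bind_rule_id(world$model, mem$type[i],
                                  tolower(mem$type[j]), mem$type[j],
                                  tolower(mem$type[i]))
        world$events <- rbind(world$events,
          data.frame(step = world$step, rule = rid,
                     particle_a = ids[i], site_a = tolower(mem$type[j]),
                     particle_b = ids[j], site_b = tolower(mem$type[i]),
                     action = "formed", stringsAsFactors = FALSE))
      }
      if (!bonded)
        world$struct_bonds <- rbind(world$struct_bonds,
          data.frame(p1 = ids[i], p2 = ids[j], rest = d))
    }
  }
  # harmonic angle triples for flexible chains: equilibrium from the
  # template's own geometry (rigid groups need none)
  if (!template$rigid && n > 2L) {
    adj <- .template_adjacency(world, ids)
    for (m in seq_len(n)) {
      nb <- adj[[m]]
      if (length(nb) == 2L) {
        v1 <- xyz[nb[1], ] - xyz[m, ]
        v2 <- xyz[nb[2], ] - xyz[m, ]
        th <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2)))))
        world$angles <- rbind(world$angles,
          data.frame(p1 = ids[nb[1]], p2 = ids[m], p3 = ids[nb[2]],
                     theta0 = th))
      }
    }
  }
  world
}

# adjacency (by member index) among a freshly built template's particles
.template_adjacency <- function(world, ids) {
  n <- length(ids)
  adj <- rep(list(integer()), n)
  link <- function(i, j) {
    if (!is.na(i) && !is.na(j) && i != j) {
      adj[[i]] <<- union(adj[[i]], j)
      adj[[j]] <<- union(adj[[j]], i)
    }
  }
  s <- world$sites
  for (r in which(!is.na(s$bond)))
    link(match(s$particle[r], ids), match(s$particle[s$bond[r]], ids))
  for (r in seq_len(nrow(world$struct_bonds)))
    link(match(world$struct_bonds$p1[r], ids),
         match(world$struct_bonds$p2[r], ids))
  adj
}

# id of the bind rule joining (tA.sA, tB.sB), either orientation; NA if none
.find_bind_rule_id <- function(model, tA, sA, tB, sB) {
  for (r in model$rules) {
    if (r$kind != "bind") next
    f <- r$actions$form[1, ]
    m1 <- r$flat_lhs[[f[1]]]; o1 <- m1$sites[[f[2]]]
    m2 <- r$flat_lhs[[f[3]]]; o2 <- m2$sites[[f[4]]]
    if ((m1$type == tA && o1$site == sA && m2$type == tB && o2$site == sB) ||
        (m1$type == tB && o1$site == sB && m2$type == tA && o2$site == sA))
      return(r$id)
  }
  NA_character_
}

# internal pure helper: add one particle (and its sites unless suppressed)
.append_particle <- function(world, type, pos, group = NA_integer_,
                             with_sites = TRUE) {
  id <- if (nrow(world$particles)) max(world$particles$id) + 1L else 1L
  world$particles <- rbind(world$particles,
    data.frame(id = id, type = type, x = pos[1], y = pos[2], z = pos[3],
               group = group, stringsAsFactors = FALSE))
  if (with_sites) {
    ty <- world$model$types[[type]]
    if (is.null(ty)) stop("type '", type, "' not in model")
    if (length(ty$sites)) {
      g <- lapply(ty$sites, function(s) .geom_site(world$geometry, type, s))
      world$sites <- rbind(world$sites,
        data.frame(particle = id, slot = seq_along(ty$sites),
                   name = ty$sites,
                   len = vapply(g, `[[`, 0, "len"),
                   phi = vapply(g, `[[`, 0, "phi"),
                   theta = vapply(g, `[[`, 0, "theta"),
                   mod = vapply(ty$mods, function(m)
                     if (length(m)) m[1] else NA_character_, ""),
                   bond = NA_integer_, stringsAsFactors = FALSE))
    }
  }
  list(world = world, id = id)
}
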