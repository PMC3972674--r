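# Structure comparison across replicate runs (positional / paired / local
# RMSD), UPGMA dendrograms, bond-frequency and connectivity statistics.

.positions_of <- function(s) {
  if (inherits(s, "srbm_record")) as.matrix(s$particles[, c("x", "y", "z")])
  else if (inherits(s, "srbm_world"))
    as.matrix(s$particles[, c("x", "y", "z")])
  else as.matrix(s)
}

.check_same_particles <- function(a, b) {
  get_sig <- function(s) {
    if (inherits(s, "srbm_record") || inherits(s, "srbm_world"))
      paste(s$particles$id, s$particles$type)
    else NULL
  }
  sa <- get_sig(a)
  sb <- get_sig(b)
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb))
    stop("snapshots do not share the same particle id/type sequence")
}

#' Positional RMSD after two-ray anchor alignment
#'
#' Rigid-motion degrees of freedom are removed by construction: the first
#' anchor particle is fixed at the origin in both structures and rotation
#' is fixed by aligning the rays to the second and third anchor particles;
#' the root mean square deviation of all particle positions is then taken.
#' Only useful for small, rigid structures.
#'
#' @param p,q n x 3 position matrices (Angstrom), `srbm_record`s or worlds,
#'   with identical particle ordering.
#' @param anchor indices of three non-collinear anchor particles.
#' @return RMSD in Angstrom.
#' @export
rmsd_positions <- function(p, q, anchor = 1:3) {
  .check_same_particles(p, q)
  p <- .positions_of(p)
  q <- .positions_of(q)
  if (nrow(p) != nrow(q)) stop("structures differ in particle count")
  if (length(anchor) != 3L) stop("anchor must index three particles")
  frame_of <- function(x) {
    v1 <- x[anchor[2], ] - x[anchor[1], ]
    v2 <- x[anchor[3], ] - x[anchor[1], ]
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    scale <- sqrt(sum(v1^2)) * sqrt(sum(v2^2))
    if (scale < 1e-12 || sqrt(sum(cr^2)) < 1e-9 * scale)
      stop("anchor particles are collinear or coincident")
    e1 <- v1 / sqrt(sum(v1^2))
    e3 <- cr / sqrt(sum(cr^2))
    e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
            e3[3] * e1[1] - e3[1] * e1[3],
            e3[1] * e1[2] - e3[2] * e1[1])
    rbind(e1, e2, e3)
  }
  tp <- sweep(p, 2, p[anchor[1], ]) %*% t(frame_of(p))
  tq <- sweep(q, 2, q[anchor[1], ]) %*% t(frame_of(q))
  sqrt(mean(rowSums((tp - tq)^2)))
}

#' Paired RMSD: RMSD of all pairwise inter-particle distances
#'
#' `sqrt( 2/(n^2+n) * sum_{i<=j} (|p_i-p_j| - |q_i-q_j|)^2 )`; the diagonal
#' terms are zero, so the average runs over the n(n+1)/2 pairs. Invariant
#' under rigid rotation and translation of either structure.
#'
#' @inheritParams rmsd_positions
#' @return paired RMSD in Angstrom.
#' @export
paired_rmsd <- function(p, q) {
  .check_same_particles(p, q)
  p <- .positions_of(p)
  q <- .positions_of(q)
  n <- nrow(p)
  if (n != nrow(q)) stop("structures differ in particle count")
  if (n == 0L) stop("empty structure")
  dp <- stats::dist(p)
  dq <- stats::dist(q)
  sqrt(2 / (n^2 + n) * sum((dp - dq)^2))
}

#' Local RMSD: paired RMSD of cutoff-clipped distances
#'
#' Each inter-particle distance is replaced by `min(C, distance)` before the
#' paired RMSD is taken, so only the local structure within the cutoff
#' contributes and macrostructural shape is ignored.
#'
#' @inheritParams rmsd_positions
#' @param C cutoff distance in Angstrom (>= 0).
#' @return local RMSD in Angstrom.
#' @export
local_rmsd <- function(p, q, C) {
  .check_same_particles(p, q)
  p <- .positions_of(p)
  q <- .positions_of(q)
  n <- nrow(p)
  if (n != nrow(q)) stop("structures differ in particle count")
  if (C < 0) stop("C must be non-negative")
  dp <- pmin(C, stats::dist(p))
  dq <- pmin(C, stats::dist(q))
  sqrt(2 / (n^2 + n) * sum((dp - dq)^2))
}

#' Pairwise structure-distance matrix
#'
#' @param snapshots list (>= 2) of position matrices / records with
#'   consistent particle sets.
#' @param metric `"paired"` (default), `"rmsd"` or `"local"`.
#' @param C cutoff for the local metric.
#' @param anchor anchors for the positional metric.
#' @param labels optional run labels (default names or indices).
#' @return symmetric matrix of class `srbm_distmat`.
#' @export
distance_matrix <- function(snapshots, metric = c("paired", "rmsd", "local"),
                            C = NULL, anchor = 1:3, labels = NULL) {
  metric <- match.arg(metric)
  n <- length(snapshots)
  if (n < 2L) stop("need at least two snapshots")
  if (is.null(labels))
    labels <- if (!is.null(names(snapshots))) names(snapshots)
              else as.character(seq_len(n))
  fun <- switch(metric,
    paired = paired_rmsd,
    rmsd = function(a, b) rmsd_positions(a, b, anchor),
    local = function(a, b) {
      if (is.null(C)) stop("local metric needs a cutoff C")
      local_rmsd(a, b, C)
    })
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- fun(snapshots[[i]], snapshots[[j]])
  }
  structure(m, class = c("srbm_distmat", "matrix"))
}

#' UPGMA dendrogram
#'
#' Unweighted pair-group agglomeration with arithmetic-mean linkage: the
#' distance between clusters is the cluster-size-weighted average of member
#' distances, the merge height is that average distance, and ties are
#' broken deterministically towards the smallest pair of leaf labels.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @return object of class `srbm_dendrogram` with the nested node tree
#'   (`$node`: children / height / leaf label) and an `stats::hclust`
#'   representation (`$hclust`).
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < 2L) stop("distance matrix must be at least 2x2")
  if (any(abs(m - t(m)) > 1e-9) || any(diag(m) != 0) || any(m < 0))
    stop("not a valid distance matrix")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  active <- seq_len(n)
  size <- rep(1L, n)
  node <- lapply(seq_len(n), function(i)
    list(leaf = labels[i], height = 0, children = NULL))
  minleaf <- seq_len(n)           # smallest original leaf per cluster
  merge_idx <- rep(NA_integer_, n)  # hclust code: -leaf or +merge row
  for (i in seq_len(n)) merge_idx[i] <- -i
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  cur <- m
  for (s in seq_len(n - 1L)) {
    k <- length(active)
    best <- NULL
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      ca <- active[a]; cb <- active[b]
      dd <- cur[a, b]
      key <- c(dd, sort(c(minleaf[ca], minleaf[cb])))
      if (is.null(best) || dd < best$key[1] - 1e-12 ||
          (abs(dd - best$key[1]) <= 1e-12 &&
           (key[2] < best$key[2] ||
            (key[2] == best$key[2] && key[3] < best$key[3])))) {
        best <- list(a = a, b = b, key = key)
      }
    }
    a <- best$a; b <- best$b
    ca <- active[a]; cb <- active[b]
    h <- cur[a, b]
    newid <- n + s
    node[[newid]] <- list(leaf = NULL, height = h,
                          children = list(node[[ca]], node[[cb]]))
    minleaf[newid] <- min(minleaf[ca], minleaf[cb])
    size[newid] <- size[ca] + size[cb]
    merge[s, ] <- sort(c(merge_idx[ca], merge_idx[cb]))
    height[s] <- h
    merge_idx[newid] <- s
    # size-weighted average linkage update
    newrow <- (size[ca] * cur[a, ] + size[cb] * cur[b, ]) /
      (size[ca] + size[cb])
    keep <- setdiff(seq_len(k), c(a, b))
    cur <- cur[keep, keep, drop = FALSE]
    nr <- newrow[keep]
    cur <- rbind(cbind(cur, nr), c(nr, 0))
    active <- c(active[keep], newid)
  }
  leaf_order <- function(nd) {
    if (!is.null(nd$leaf)) return(match(nd$leaf, labels))
    c(leaf_order(nd$children[[1]]), leaf_order(nd$children[[2]]))
  }
  hc <- structure(list(merge = merge, height = height,
                       order = leaf_order(node[[2 * n - 1L]]),
                       labels = labels, method = "upgma",
                       call = match.call(), dist.method = "euclidean"),
                  class = "hclust")
  structure(list(node = node[[2 * n - 1L]], hclust = hc, labels = labels),
            class = "srbm_dendrogram")
}

#' @export
print.srbm_dendrogram <- function(x, ...) {
  cat("srbm UPGMA dendrogram over", length(x$labels), "structures; root at",
      format(x$node$height, digits = 4), "\n")
  invisible(x)
}

#' @export
as.hclust.srbm_dendrogram <- function(x, ...) x$hclust

#' @export
plot.srbm_dendrogram <- function(x, ...) plot(x$hclust, ...)

#' Write a dendrogram as Newick text
#' @param x an `srbm_dendrogram`.
#' @param file output path; `NULL` returns the string.
#' @return Newick text.
#' @export
write_newick <- function(x, file = NULL) {
  phy <- ape::as.phylo(x$hclust)
  # as.phylo halves hclust heights; restore merge-height branch lengths
  phy$edge.length <- phy$edge.length * 2
  txt <- ape::write.tree(phy)
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

# count bonds per bind rule in a final world or an event log
.bond_counts <- function(run, model, at_step = Inf) {
  ids <- vapply(model$rules, `[[`, "", "id")
  counts <- setNames(numeric(length(ids)), ids)
  if (inherits(run, "srbm_world")) {
    bl <- bond_list(run)
    ptype <- setNames(run$particles$type, run$particles$id)
    for (i in seq_len(nrow(bl))) {
      rid <- .find_bind_rule_id(model, ptype[[as.character(bl$particle_a[i])]],
                                bl$site_a[i],
                                ptype[[as.character(bl$particle_b[i])]],
                                bl$site_b[i])
      if (!is.na(rid)) counts[rid] <- counts[rid] + 1
    }
  } else {
    ev <- run
    if (!all(ev$rule %in% c(ids, NA)))
      stop("unknown rule in bond log: ",
           paste(setdiff(unique(ev$rule), ids), collapse = ", "))
    ev <- ev[ev$step <= at_step, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      r <- ev$rule[i]
      if (is.na(r)) next
      counts[r] <- counts[r] + if (ev$action[i] == "formed") 1 else -1
    }
  }
  counts
}

# per-run bond capacity of one bind rule: min over the two partners of
# (copy count x site multiplicity)
.rule_capacity <- function(rule, model, copies) {
  f <- rule$actions$form[1, ]
  cap_side <- function(m, o) {
    ty <- rule$flat_lhs[[m]]$type
    site <- rule$flat_lhs[[m]]$sites[[o]]$site
    mult <- sum(model$types[[ty]]$sites == site)
    cp <- copies[[ty]]
    if (is.null(cp) || is.na(cp)) stop("no copy number for type '", ty, "'")
    cp * mult
  }
  min(cap_side(f[1], f[2]), cap_side(f[3], f[4]))
}

#' Realized bond frequency per rule
#'
#' For each bind rule, the number of bonds present at the final step,
#' summed over replicate runs, divided by the maximum possible over those
#' runs. The per-run maximum is the smaller of the two partners'
#' capacities (copy count times matching-site multiplicity).
#'
#' @param runs list of final `srbm_world`s or of bond-event logs.
#' @param model the shared `srbm_model`.
#' @param copies named vector of copy numbers per molecule type.
#' @param at_step count bonds present at this step (event-log runs only;
#'   default final).
#' @return data frame: rule, realized, possible, pct.
#' @export
bond_frequency <- function(runs, model, copies, at_step = Inf) {
  bind_rules <- Filter(function(r) r$kind == "bind", model$rules)
  tot <- Reduce(`+`, lapply(runs, .bond_counts, model = model,
                            at_step = at_step))
  out <- do.call(rbind, lapply(bind_rules, function(r) {
    cap <- .rule_capacity(r, model, copies) * length(runs)
    data.frame(rule = r$id, realized = unname(tot[r$id]), possible = cap,
               pct = 100 * unname(tot[r$id]) / cap,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Distribution of per-run bond counts for one rule
#'
#' @param counts integer vector: final bond count of the rule in each run.
#' @param max maximum possible count per run.
#' @return named numeric over `0:max`; fractions summing to 1.
#' @export
bond_count_histogram <- function(counts, max) {
  if (any(counts > max)) stop("count exceeds the per-run maximum")
  if (any(counts < 0)) stop("negative count")
  tab <- tabulate(counts + 1L, nbins = max + 1L) / length(counts)
  setNames(tab, 0:max)
}

#' Connectivity between anchor groups
#'
#' Builds the bond graph of the world and reports, for each unordered pair
#' of anchor groups, whether a path connects them through non-anchor
#' particles.
#'
#' @param world an `srbm_world`.
#' @param groups list of disjoint particle-id vectors (the anchors, e.g.
#'   the nucleosomes of a rosette).
#' @return list with `count` (number of connected pairs) and `pairs`
#'   (data frame `a`, `b`, `connected`).
#' @export
bridge_count <- function(world, groups) {
  ids <- unlist(groups)
  if (anyDuplicated(ids)) stop("anchor groups must be disjoint")
  bl <- bond_list(world)
  edges <- rbind(data.frame(a = bl$particle_a, b = bl$particle_b),
                 data.frame(a = world$struct_bonds$p1,
                            b = world$struct_bonds$p2))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = as.character(world$particles$id)))
  ng <- length(groups)
  pairs <- NULL
  count <- 0L
  anchors <- lapply(groups, as.character)
  all_anchor <- unlist(anchors)
  for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
    keep <- setdiff(igraph::V(g)$name, setdiff(all_anchor,
                                               c(anchors[[i]], anchors[[j]])))
    sub <- igraph::induced_subgraph(g, keep)
    comp <- igraph::components(sub)$membership
    conn <- length(intersect(comp[anchors[[i]]], comp[anchors[[j]]])) > 0
    pairs <- rbind(pairs, data.frame(a = i, b = j, connected = conn))
    if (conn) count <- count + 1L
  }
  list(count = count, pairs = pairs)
}
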