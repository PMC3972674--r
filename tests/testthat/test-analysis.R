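# Structure metrics, clustering and bond statistics.

random_structure <- function(n, seed) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = 10), n, 3)
}

test_that("positional RMSD is zero for identical or translated structures", {
  p <- random_structure(6, 1)
  expect_equal(rmsd_positions(p, p), 0)
  expect_equal(rmsd_positions(p, sweep(p, 2, c(5, -3, 11), "+")), 0)
  # and for rotations about the anchor frame
  R <- random_rotation_matrix()
  expect_equal(rmsd_positions(p, p %*% t(R)), 0, tolerance = 1e-9)
  expect_error(rmsd_positions(p, p, anchor = c(1, 2, 2)), "collinear|three")
  collinear <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0, 5, 5, 5), 4, 3,
                      byrow = TRUE)
  expect_error(rmsd_positions(collinear, collinear), "collinear")
})

test_that("positional RMSD reports post-alignment displacements", {
  p <- random_structure(4, 2)
  q <- p
  q[4, ] <- q[4, ] + c(3, 0, 0)   # anchors 1:3 untouched
  expect_equal(rmsd_positions(p, q), sqrt(9 / 4))
})

test_that("paired RMSD matches hand-computed two-particle cases", {
  p <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  q <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(paired_rmsd(p, p), 0)
  expect_equal(paired_rmsd(p, q), sqrt(2 / 6), tolerance = 1e-12)  # 0.577
  expect_equal(local_rmsd(p, q, 1.5), sqrt(2 / 6 * 0.25))          # 0.289
  expect_error(paired_rmsd(p[0, , drop = FALSE], q[0, , drop = FALSE]),
               "empty")
})

test_that("paired RMSD is rigid-motion invariant and symmetric", {
  set.seed(33)
  for (i in 1:25) {
    p <- random_structure(7, 100 + i)
    q <- random_structure(7, 200 + i)
    R <- random_rotation_matrix()
    t <- stats::rnorm(3, sd = 50)
    q_moved <- sweep(q %*% t(R), 2, t, "+")
    expect_lt(abs(paired_rmsd(p, q_moved) - paired_rmsd(p, q)), 1e-9)
    expect_equal(paired_rmsd(p, q), paired_rmsd(q, p))
    expect_gte(paired_rmsd(p, q), 0)
  }
})

test_that("paired RMSD vanishes iff all pairwise distances agree", {
  # exhaustive over tiny perturbation cases
  p <- matrix(c(0, 0, 0, 2, 0, 0, 0, 3, 0), 3, 3, byrow = TRUE)
  R <- random_rotation_matrix()
  mirrored <- p %*% diag(c(-1, 1, 1))
  expect_equal(paired_rmsd(p, mirrored), 0)     # distances preserved
  expect_equal(paired_rmsd(p, p %*% t(R)), 0, tolerance = 1e-12)
  for (i in 1:3) for (k in 1:3) {
    q <- p
    q[i, k] <- q[i, k] + 0.5
    expect_gt(paired_rmsd(p, q), 0)
  }
})

test_that("local RMSD is monotone in the cutoff and converges to paired", {
  p <- random_structure(8, 3)
  q <- random_structure(8, 4)
  expect_equal(local_rmsd(p, q, 0), 0)
  cs <- seq(0, 100, by = 5)
  vals <- vapply(cs, function(C) local_rmsd(p, q, C), 0)
  expect_true(all(diff(vals) >= -1e-12))
  big <- max(stats::dist(p), stats::dist(q)) + 1
  expect_equal(local_rmsd(p, q, big), paired_rmsd(p, q))
})

test_that("distance matrices agree with per-pair metric calls", {
  snaps <- lapply(1:4, random_structure, n = 5)
  m <- distance_matrix(snaps, metric = "paired")
  expect_equal(unclass(m)[1, 1], 0)
  expect_equal(m, t(m))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(unclass(m)[i, j], paired_rmsd(snaps[[i]], snaps[[j]]))
  # identical snapshots give the zero matrix
  z <- distance_matrix(list(snaps[[1]], snaps[[1]]))
  expect_true(all(z == 0))
  # rigidly moving one snapshot leaves the paired matrix unchanged
  moved <- snaps
  moved[[2]] <- sweep(moved[[2]] %*% t(random_rotation_matrix()), 2,
                      c(9, 9, 9), "+")
  expect_equal(distance_matrix(moved), m, tolerance = 1e-9)
  expect_error(distance_matrix(snaps[1]), "at least two")
})

test_that("UPGMA merges by average linkage with deterministic ties", {
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  u2 <- upgma(d2)
  expect_equal(u2$node$height, 3)
  d3 <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  u3 <- upgma(d3)
  expect_equal(u3$hclust$height, c(2, 8))
  expect_setequal(unlist(lapply(u3$node$children, function(ch)
    if (is.null(ch$leaf)) vapply(ch$children, `[[`, "", "leaf") else ch$leaf)),
    c("A", "B", "C"))
  z <- upgma(matrix(0, 3, 3))
  expect_true(all(z$hclust$height == 0))
  expect_error(upgma(matrix(0, 1, 1)), "2x2")
  expect_error(upgma(matrix(c(0, 1, 2, 0), 2)), "valid")
})

test_that("UPGMA cophenetic matrices match stats::hclust average linkage", {
  for (i in 1:10) {
    set.seed(400 + i)
    x <- matrix(stats::rnorm(36), 6)
    d <- as.matrix(stats::dist(x))
    mine <- stats::cophenetic(as.hclust(upgma(d)))
    ref <- stats::cophenetic(stats::hclust(stats::as.dist(d),
                                           method = "average"))
    expect_equal(as.matrix(mine)[order(rownames(as.matrix(mine))),
                                 order(colnames(as.matrix(mine)))],
                 as.matrix(ref)[order(rownames(as.matrix(ref))),
                                order(colnames(as.matrix(ref)))],
                 tolerance = 1e-12)
  }
})

test_that("Newick export writes merge-height branch lengths", {
  d3 <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  txt <- write_newick(upgma(d3))
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  expect_equal(max(ape::node.depth.edgelength(phy)), 8)
})

test_that("bond frequencies follow the min-capacity convention", {
  df <- data.frame(protein_a = "X", protein_b = "Y", site_a = "y",
                   site_b = "x", stringsAsFactors = FALSE)
  rules <- interactions_to_rules(df)
  model <- structure(list(
    types = list(X = molecule_type("X", "y"), Y = molecule_type("Y", "x")),
    rules = rules, params = numeric(),
    switches = logical()), class = "srbm_model")
  copies <- c(X = 6, Y = 6)
  log_with <- function(k) data.frame(
    step = seq_len(k), rule = rep("X-Y", k), particle_a = seq_len(k),
    site_a = rep("y", k), particle_b = seq_len(k) + 10,
    site_b = rep("x", k), action = rep("formed", k),
    stringsAsFactors = FALSE)
  # 2 runs x 3 bonds of 6 possible -> 50%
  bf <- bond_frequency(list(log_with(3), log_with(3)), model, copies)
  expect_equal(bf$pct, 50)
  expect_equal(bf$possible, 12)
  expect_equal(bond_frequency(list(log_with(6), log_with(6)), model,
                              copies)$pct, 100)
  expect_equal(bond_frequency(list(log_with(0), log_with(0)), model,
                              copies)$pct, 0)
  # asymmetric copy numbers limit via the scarcer partner
  bf2 <- bond_frequency(list(log_with(1)), model, c(X = 1, Y = 6))
  expect_equal(bf2$possible, 1)
  expect_error(bond_frequency(list({
    e <- log_with(1); e$rule <- "bogus"; e
  }), model, copies), "unknown rule")
})

test_that("time-resolved bond frequency is cumulative-consistent", {
  fx <- toy_polymer_fixture(8, seed = 91)
  res <- run_protocol(fx$world, sim_protocol(phase_run(2000),
                                             dump_interval = 0))
  copies <- c(A = 8)
  final_from_log <- bond_frequency(list(res$events), fx$model, copies)
  static <- bond_frequency(list(res$world), fx$model, copies)
  expect_equal(final_from_log$realized, static$realized)
  # early time points never exceed the final cumulative count
  half <- bond_frequency(list(res$events), fx$model, copies, at_step = 1000)
  expect_lte(half$realized, final_from_log$realized)
})

test_that("bond count histograms tally runs exactly", {
  h <- bond_count_histogram(c(0, 0, 0, 6), max = 6)
  expect_equal(unname(h[c("0", "6")]), c(0.75, 0.25))
  expect_equal(sum(h), 1)
  expect_equal(unname(bond_count_histogram(rep(2, 5), max = 4)["2"]), 1)
  set.seed(77)
  counts <- sample(0:6, 200, replace = TRUE)
  h2 <- bond_count_histogram(counts, max = 6)
  expect_equal(unname(h2), as.numeric(table(factor(counts, 0:6))) / 200)
  expect_error(bond_count_histogram(c(1, 9), max = 6), "maximum")
})

test_that("bridge_count agrees with a breadth-first-search oracle", {
  w <- toy_world(6)
  groups <- list(1L, 2L)
  expect_equal(bridge_count(w, groups)$count, 0L)
  # chain 1-3-4-2: anchors 1 and 2 joined through intermediates
  chain <- list(c(1L, 3L), c(3L, 4L), c(4L, 2L))
  for (pr in chain) {
    ra <- which(w$sites$particle == pr[1] & w$sites$name == "a" &
                  is.na(w$sites$bond))[1]
    rb <- which(w$sites$particle == pr[2] & w$sites$name == "a" &
                  is.na(w$sites$bond))[1]
    w <- force_bond(w, ra, rb)
  }
  bc <- bridge_count(w, groups)
  expect_equal(bc$count, 1L)
  expect_error(bridge_count(w, list(1L, 1L)), "disjoint")
  # random worlds against the independent BFS
  for (seed in 1:8) {
    wr <- random_toy_world(7, seed = 50 + seed)
    bl <- bond_list(wr)
    edges <- data.frame(a = bl$particle_a, b = bl$particle_b)
    groups <- list(1L, 2L, 3L)
    bcr <- bridge_count(wr, groups)
    for (k in seq_len(nrow(bcr$pairs))) {
      pr <- bcr$pairs[k, ]
      allowed <- c(setdiff(wr$particles$id, unlist(groups)),
                   groups[[pr$a]], groups[[pr$b]])
      expect_equal(pr$connected,
                   bfs_connected(edges[edges$a %in% allowed &
                                         edges$b %in% allowed, , drop = FALSE],
                                 groups[[pr$a]], groups[[pr$b]], allowed),
                   info = sprintf("seed %d pair %d-%d", seed, pr$a, pr$b))
    }
  }
})
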