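# Shorthand typed-graph constructors for motif tests.
ffl_adj <- function() {
  a <- matrix(0L, 3, 3); a[1, 2] <- a[1, 3] <- a[2, 3] <- 1L; a
}
chain_adj <- function() {
  a <- matrix(0L, 3, 3); a[1, 2] <- a[2, 3] <- 1L; a
}
double_target_adj <- function() {
  a <- matrix(0L, 3, 3); a[1, 3] <- a[2, 3] <- 1L; a
}

test_that("canonical classes respect typed isomorphism", {
  tt <- c(TRUE, TRUE, FALSE)
  # any relabeling of the FFL maps to the same key
  key <- canonical_class(ffl_adj(), tt)
  perm <- c(2, 1, 3)
  expect_equal(canonical_class(ffl_adj()[perm, perm], tt[perm]), key)
  # chain vs double-target: different classes (exhaustive-permutation check)
  expect_false(canonical_class(chain_adj(), tt) ==
                 canonical_class(double_target_adj(), tt))
  # retyping the target as TF changes the class
  expect_false(canonical_class(ffl_adj(), c(TRUE, TRUE, TRUE)) == key)
  # equal keys <=> typed isomorphic, spot-checked against igraph VF2
  set.seed(111)
  for (i in 1:40) {
    n <- sample(3:4, 1)
    ntf <- sample(1:(n - 1), 1)
    types <- c(rep(TRUE, ntf), rep(FALSE, n - ntf))
    mk <- function() {
      a <- matrix(0L, n, n)
      for (r in seq_len(ntf)) for (cc in seq_len(n))
        if (r != cc && runif(1) < 0.5) a[r, cc] <- 1L
      a
    }
    a1 <- mk(); a2 <- mk()
    g1 <- igraph::graph_from_adjacency_matrix(a1)
    g2 <- igraph::graph_from_adjacency_matrix(a2)
    iso <- igraph::isomorphic(g1, g2, method = "vf2",
                              vertex.color1 = as.integer(types),
                              vertex.color2 = as.integer(types))
    expect_equal(canonical_class(a1, types) == canonical_class(a2, types),
                 iso)
  }
})

test_that("active networks apply the expression and binding conditions", {
  f <- planted_toy()
  expr <- run_differentiation(f$genome, f$cond)
  net1 <- build_active_network(f$genome, expr$final, 1, f$cond)
  # merged roster: 3 TFs + terminal-all + 2 specific groups = 6 nodes
  expect_equal(nrow(net1$nodes), 6L)
  expect_equal(sum(net1$nodes$is_tf), 3L)
  expect_equal(net1$nodes$role[1:3],
               c("lineage-this-cell", "lineage-other-cell", "inhibitor"))
  # only TFs expressed in the cell contribute edges
  silent <- which(expr$final[1:3, 1] == 0)
  for (s in silent) expect_equal(sum(net1$adjacency[s, ]), 0L)
  # an edge needs at least one binding site on the target's members
  for (i in 1:3) for (j in seq_len(6)) {
    if (i == j) next
    members <- net1$nodes$members[[j]]
    has_site <- any(vapply(members, function(g)
      any(f$genome$sites[[g]]$tf_id == i), TRUE))
    expressed <- expr$final[i, 1] > 0
    expect_equal(net1$adjacency[i, j] == 1L, has_site && expressed)
  }
  # no self-loops
  expect_true(all(diag(net1$adjacency) == 0))
  # the two cells of the organism give different networks
  net2 <- build_active_network(f$genome, expr$final, 2, f$cond)
  expect_false(identical(net1$adjacency, net2$adjacency))
})

test_that("subgraph enumeration matches a naive all-subsets oracle", {
  mk_net <- function(n, ntf, nlin, p, seed) {
    set.seed(seed)
    adj <- matrix(0L, n, n)
    for (r in seq_len(ntf)) for (cc in seq_len(n))
      if (r != cc && runif(1) < p) adj[r, cc] <- 1L
    dimnames(adj) <- list(paste0("n", 1:n), paste0("n", 1:n))
    nodes <- data.frame(node_id = 1:n, label = paste0("n", 1:n),
                        is_tf = seq_len(n) <= ntf,
                        is_lineage = seq_len(n) <= nlin,
                        role = "x", stringsAsFactors = FALSE)
    nodes$members <- I(as.list(1:n))
    structure(list(nodes = nodes, adjacency = adj, cell = 1),
              class = "grn_network")
  }
  for (seed in 1:6) {
    net <- mk_net(8, 5, 2, 0.35, seed)
    fast <- enumerate_subgraphs(net, 3:5)
    slow <- oracle_enumerate(net, 3:5)
    expect_equal(fast[order(names(fast))], slow[order(names(slow))])
  }
  # a single FFL over (lineage TF, activator TF, terminal) is found once
  net <- mk_net(3, 2, 1, 0, 1)
  net$adjacency <- ffl_adj()
  dimnames(net$adjacency) <- list(paste0("n", 1:3), paste0("n", 1:3))
  cnt <- enumerate_subgraphs(net, 3)
  expect_equal(length(cnt), 1L)
  expect_equal(unname(cnt), 1L)
  expect_equal(names(cnt), canonical_class(ffl_adj(), c(TRUE, TRUE, FALSE)))
  # a non-lineage TF with no input edge disqualifies the subset
  net_nl <- mk_net(3, 2, 1, 0, 1)
  net_nl$adjacency <- double_target_adj()  # T2 (non-lineage) has no input
  dimnames(net_nl$adjacency) <- list(paste0("n", 1:3), paste0("n", 1:3))
  expect_equal(length(enumerate_subgraphs(net_nl, 3)), 0L)
})

test_that("the admissible class inventory is exact", {
  expect_equal(length(enumerate_possible_classes(2)), 1L)
  cls3 <- enumerate_possible_classes(3)
  expect_equal(length(cls3), 6L)
  # the six documented size-3 classes, built by hand
  tt <- c(TRUE, TRUE, FALSE)
  two_cycle_one <- matrix(0L, 3, 3)
  two_cycle_one[1, 2] <- two_cycle_one[2, 1] <- two_cycle_one[1, 3] <- 1L
  two_cycle_both <- two_cycle_one; two_cycle_both[2, 3] <- 1L
  fanout <- matrix(0L, 3, 3); fanout[1, 2] <- fanout[1, 3] <- 1L
  hand <- c(
    canonical_class(double_target_adj(), tt),
    canonical_class(chain_adj(), tt),
    canonical_class(ffl_adj(), tt),
    canonical_class(two_cycle_one, tt),
    canonical_class(two_cycle_both, tt),
    canonical_class(fanout, c(TRUE, FALSE, FALSE)))
  expect_setequal(cls3, hand)
  expect_equal(length(enumerate_possible_classes(4)), 75L)
  # under a strict global-connectivity reading one disjoint-union class
  # (two independent TF->target pairs) drops out
  expect_equal(length(enumerate_possible_classes(4, connected = TRUE)), 74L)
  expect_equal(length(enumerate_possible_classes(3, connected = TRUE)), 6L)
})

test_that("output shuffling preserves degrees and avoids self-loops", {
  f <- planted_toy()
  expr <- run_differentiation(f$genome, f$cond)
  nets <- lapply(1:2, function(cc)
    build_active_network(f$genome, expr$final, cc, f$cond))
  set.seed(121)
  # make a denser synthetic network for a stronger check
  n <- 10
  adj <- matrix(0L, n, n)
  for (r in 1:6) for (cc in 1:n) if (r != cc && runif(1) < 0.5) adj[r, cc] <- 1L
  nodes <- data.frame(node_id = 1:n, label = paste0("n", 1:n),
                      is_tf = 1:n <= 6, is_lineage = 1:n <= 2, role = "x")
  nodes$members <- I(as.list(1:n))
  dense <- structure(list(nodes = nodes, adjacency = adj, cell = 1),
                     class = "grn_network")
  for (net in c(nets, list(dense))) {
    shuf <- shuffle_outputs(list(net))[[1]]
    expect_equal(rowSums(shuf$adjacency), rowSums(net$adjacency))
    expect_equal(sort(colSums(shuf$adjacency)), sort(colSums(net$adjacency)))
    expect_true(all(diag(shuf$adjacency) == 0))
    expect_true(all(shuf$adjacency %in% c(0L, 1L)))
  }
  # shuffling actually moves edges on the dense network
  set.seed(122)
  shuf <- shuffle_outputs(list(dense))[[1]]
  expect_false(identical(shuf$adjacency, dense$adjacency))
})

test_that("Z-scores follow the population-sd formula", {
  nulls <- lapply(c(10, 12, 8, 11, 9, 10, 13, 10, 9, 8), function(v)
    c("s3.t2.a1" = v))
  zs <- motif_zscores(c("s3.t2.a1" = 20), nulls)
  expect_equal(zs$null_mean, 10)
  expect_equal(zs$z, (20 - 10) / sqrt(mean((c(10, 12, 8, 11, 9, 10, 13, 10,
                                              9, 8) - 10)^2)))
  expect_equal(zs$z, 6.455, tolerance = 1e-3)
  expect_true(zs$is_motif)
  # equal to the null mean: z = 0, not a motif
  zs0 <- motif_zscores(c("s3.t2.a1" = 10), nulls)
  expect_equal(zs0$z, 0)
  expect_false(zs0$is_motif)
  # zero null spread: infinite sentinel, flagged degenerate
  zsd <- motif_zscores(c("s3.t2.a1" = 5), lapply(1:10, function(i) c("s3.t2.a1" = 3)))
  expect_true(is.infinite(zsd$z) && zsd$z > 0)
  expect_true(zsd$degenerate)
  expect_error(motif_zscores(c("s3.t2.a1" = 5), list(c("s3.t2.a1" = 3))), "at least 2")
})

test_that("position orbits separate unique and symmetric positions", {
  tt <- c(TRUE, TRUE, FALSE)
  # FFL: trivial automorphism group, three unique positions
  orb <- position_orbits(canonical_class(ffl_adj(), tt))
  expect_equal(sort(orb$name), c("p0", "p1", "p2"))
  # double target: the two TFs are symmetric
  orb2 <- position_orbits(canonical_class(double_target_adj(), tt))
  expect_setequal(orb2$name, c("set0", "set0", "p0"))
  expect_true(all(orb2$is_tf[orb2$name == "set0"]))
})

test_that("the occupancy matrix conserves motif-position incidences", {
  set.seed(131)
  cond <- make_toy_condition(n_cells = 2, n_other_activators = 1,
                             n_inhibitors = 1, n_terminal_all = 1,
                             n_terminal_specific = 2)
  pwms <- sample_pwm_set(4)
  genome <- scan_genome(random_genome(cond), pwms)
  expr <- run_differentiation(genome, cond)
  run <- structure(list(condition = cond, best = genome,
                        best_final = expr$final), class = "grn_run")
  set.seed(132)
  ma <- motif_analysis(list(run), sizes = 3:4, n_null = 4, z_threshold = -Inf)
  # every instance of every class contributes size-many position incidences,
  # expanded over merged members
  expected_total <- 0
  for (net in ma$networks) {
    inst <- grnevolve:::motif_instances(net, 3:4)
    keep <- inst$key %in% ma$motifs
    expected_total <- expected_total +
      sum(vapply(which(keep), function(q)
        sum(lengths(net$nodes$members[inst$nodes[[q]]])), 0))
  }
  expect_equal(sum(ma$occupancy), expected_total)
  expect_equal(nrow(ma$occupancy), 1 * 2 * nrow(cond$genes))
})
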