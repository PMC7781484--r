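test_that("organism MSE averages squared deviations over terminal genes and cells", {
  expect_equal(organism_mse(matrix(1:6, 2), matrix(1:6, 2)), 0)
  # 2 cells x 2 genes, deviations (0.1, 0 | 0, 0.2)
  final <- matrix(c(0.1, 0, 0, 0.2), 2, 2)
  expect_equal(organism_mse(final, matrix(0, 2, 2)), 0.0125)
  expect_error(organism_mse(matrix(0, 2, 2), matrix(0, 3, 2)), "shape")
  # TF rows are excluded when a full-roster matrix is passed
  cond <- make_toy_condition(n_cells = 1)
  full <- matrix(c(9, 4, 4), 3, 1,
                 dimnames = list(cond$genes$name, "cell1"))
  expect_equal(organism_mse(full, cond$optimal_pattern, cond), 0)
})

test_that("tournament selection picks the fittest of each independent draw", {
  set.seed(91)
  mse <- c(5, 1, 3, 7, 2, 8, 4, 6, 9, 10)
  # k = N forces the global best in both draws (selfing)
  expect_equal(tournament_round(mse, k = 10), c(2L, 2L))
  # k = 1: degenerate uniform choice
  picks <- replicate(2000, tournament_round(mse, 1)[1])
  expect_gt(min(table(factor(picks, levels = 1:10))), 100)
  # winner-rank distribution matches the order-statistic law:
  # P(winner is rank r) = C(N-r, k-1)/C(N, k)
  N <- 10; k <- 4
  rank_of <- rank(mse)
  wins <- replicate(10000, rank_of[tournament_round(mse, k)[1]])
  emp <- tabulate(wins, N) / 10000
  theo <- choose(N - seq_len(N), k - 1) / choose(N, k)
  expect_lt(max(abs(emp - theo)), 0.02)
  # ties break deterministically by lower index
  expect_equal(tournament_round(c(1, 1, 1), 3), c(1L, 1L))
})

test_that("reproduction segregates, recombines and mutates promoters", {
  set.seed(92)
  cond <- make_toy_condition(n_cells = 2, n_terminal_specific = 6,
                             n_terminal_all = 2)
  A <- random_genome(cond)$promoters
  B <- random_genome(cond)$promoters
  # r = 0, m = 0: every promoter identical to one parent, roughly half from A
  kids <- replicate(60, reproduce(A, B, r = 0, m = 0))
  from_a <- mean(kids == matrix(A, nrow = length(A), ncol = 60))
  expect_true(all(kids == matrix(A, length(A), 60) |
                    kids == matrix(B, length(B), 60)))
  expect_gt(from_a, 0.4); expect_lt(from_a, 0.6)
  # identical parents: child identical regardless of recombination rate
  expect_identical(reproduce(A, A, r = 50, m = 0), A)
  # crossover mosaics: every base comes from one of the parents
  child <- reproduce(A, B, r = 50, m = 0)
  for (g in seq_along(A)) {
    a <- strsplit(A[[g]], "")[[1]]
    b <- strsplit(B[[g]], "")[[1]]
    ch <- strsplit(child[[g]], "")[[1]]
    expect_true(all(ch == a | ch == b))
  }
  # substitution count: m = 5/kb on a 40 x 150 bp genome ~ 30 per child
  cond40 <- build_condition("mce0fix")
  P40 <- random_genome(cond40)$promoters
  nmut <- replicate(40, {
    kid <- reproduce(P40, P40, r = 0, m = 5)
    sum(mapply(function(x, y)
      sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]), kid, P40))
  })
  expect_gt(mean(nmut), 25); expect_lt(mean(nmut), 35)
  # alphabet and length conserved
  expect_true(all(nchar(child) == 150))
  expect_false(any(grepl("[^ACGT]", child)))
})

test_that("the mutation and tournament schedule follows the generation rules", {
  evo <- evo_params()
  kb <- 40 * 150 / 1000
  s <- mutation_schedule(50, 1, 1, kb, evo)
  expect_equal(s$m_per_kb, 5); expect_equal(s$k, 12L)
  s <- mutation_schedule(150, 1, 1, kb, evo)
  expect_equal(s$m_per_kb, 1)
  s <- mutation_schedule(400, 0.4, 0.4, kb, evo)
  expect_equal(s$m_per_kb, 1.5 / kb)  # 1.5 substitutions per genome
  expect_equal(s$k, 18L)
  s <- mutation_schedule(600, 0.6, 0.6, kb, evo)
  expect_equal(s$m_per_kb, 1.25 / kb)
  expect_equal(s$k, 12L)  # mean MSE still above 0.5
  # individual scaling: equal to the mean leaves the rate unchanged,
  # extremes are clipped to [0.5, 2]
  expect_equal(mutation_schedule(50, 2, 2, kb, evo)$m_per_kb, 5)
  expect_equal(mutation_schedule(50, 2, 100, kb, evo)$m_per_kb, 10)
  expect_equal(mutation_schedule(50, 2, 1e-6, kb, evo)$m_per_kb, 2.5)
})

test_that("toy evolution converges and is bit-identical under one seed", {
  cond <- make_toy_condition(n_cells = 1, n_terminal_all = 1,
                             n_terminal_specific = 0)
  run <- run_evolution(cond, evo = evo_params(max_generations = 2000),
                       seed = 3)
  expect_true(run$converged)
  expect_lt(tail(run$mse_mean, 1), 0.01)
  # stopping rule bounds the best organism's deviation from the optimum
  G <- 1; C <- 1
  dev <- abs(run$best_final["g2", 1] - cond$optimal_pattern["g2", 1])
  expect_lt(dev, sqrt(0.01 * G * C) + 0.05)
  run2 <- run_evolution(cond, evo = evo_params(max_generations = 2000),
                        seed = 3)
  expect_identical(run$best$promoters, run2$best$promoters)
  expect_identical(run$mse_mean, run2$mse_mean)
  expect_identical(run$population, run2$population)
  # a different seed gives a different trajectory
  run3 <- run_evolution(cond, evo = evo_params(max_generations = 2000),
                        seed = 4)
  expect_false(identical(run$best$promoters, run3$best$promoters))
  # the best-ever MSE is non-increasing as a running minimum
  expect_true(all(diff(cummin(run$mse_best)) <= 0))
})

test_that("site-event tracking satisfies its accounting invariants", {
  cond <- make_toy_condition(n_cells = 2, n_inhibitors = 1)
  run <- run_evolution(cond, evo = evo_params(max_generations = 120),
                       seed = 5, track_sites = TRUE)
  ev <- run$site_events
  expect_gt(nrow(ev), 0)
  died <- !ev$persisted
  expect_true(all(ev$death_gen[died] > ev$birth_gen[died]))
  expect_true(all(is.na(ev$death_gen[!died])))
  expect_true(all(ev$death_gen[died] - ev$birth_gen[died] >= 1))
  # persisted sites are present in the final population's site caches
  final_keys <- unique(unlist(lapply(seq_len(ncol(run$population)), function(i) {
    g <- scan_genome(new_genome(run$population[, i]), run$pwms)
    s <- grnevolve:::genome_sites(g)
    paste(s$gene_id, s$tf_id, s$position, s$strand)
  })))
  pers <- ev[ev$persisted, ]
  expect_true(all(paste(pers$gene_id, pers$tf_id, pers$position,
                        pers$strand) %in% final_keys))
  # tracking disabled: explicit error from the statistics
  run0 <- run_evolution(cond, evo = evo_params(max_generations = 5), seed = 5)
  expect_error(persistence_stats(run0), "without site tracking")
})

test_that("persistence statistics follow their definitions", {
  ev <- data.frame(
    gene_id = c(10, 10, 11, 12), tf_id = 1, position = c(5, 9, 2, 4),
    strand = "+",
    birth_gen = c(0, 380, 400, 360),
    death_gen = c(100, NA, 450, NA),
    persisted = c(FALSE, TRUE, FALSE, TRUE),
    gene_class = c("specific", "specific", "all", "all"))
  st <- persistence_stats(ev, min_birth_gen = 0)
  expect_equal(st$persistence_prob[st$gene_class == "specific"], 0.5)
  expect_equal(st$mean_lifespan[st$gene_class == "specific"], 100)
  expect_equal(st$mean_lifespan[st$gene_class == "all"], 50)
  # a site present only at the end persists, counted from its birth
  st2 <- persistence_stats(ev, min_birth_gen = 350, count_persisted = TRUE,
                           final_generation = 500)
  expect_equal(st2$n_emerged, c(2L, 1L))  # classes sorted: all, specific
  expect_equal(st2$mean_lifespan[st2$gene_class == "specific"], 120)
  expect_equal(st2$mean_lifespan[st2$gene_class == "all"], (50 + 140) / 2)
})
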