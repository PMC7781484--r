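# A hand-built organism where every regulatory edge is known exactly:
# 1 cell; g1 = lineage activator, g2 = inhibitor, g3/g4 = terminal genes.
# g1 autoactivates, activates g3 (its only input) and g4; g2 is silent.
fixture_org <- function() {
  cond <- make_toy_condition(n_cells = 1, n_inhibitors = 1,
                             n_terminal_all = 1, n_terminal_specific = 1)
  set.seed(7)
  pwms <- sample_pwm_set(2)
  genome <- new_genome(setNames(replicate(4, random_dna(150)),
                                cond$genes$name))
  site <- function(g, tf, pos) data.frame(gene_id = g, tf_id = tf,
                                          position = pos, strand = "+",
                                          llr = pwms[[tf]]$llr_max,
                                          q_base = 1)
  genome$sites <- list(site(1, 1, 5), grnevolve:::empty_sites(),
                       site(3, 1, 20), site(4, 1, 40))
  names(genome$sites) <- cond$genes$name
  genome$pwms <- pwms
  list(cond = cond, genome = genome)
}

test_that("binding-site knockout removes direct activation only", {
  f <- fixture_org()
  wt <- run_differentiation(f$genome, f$cond)
  # the inhibitor has no sites anywhere: both knockout flavours are no-ops
  expect_equal(knockout_tf_sites(f$genome, f$cond, 2)$final, wt$final)
  expect_equal(knockout_tf(f$genome, f$cond, 2)$final, wt$final)
  # removing the activator's terminal sites silences g3 and g4 completely
  mut <- knockout_tf_sites(f$genome, f$cond, 1)
  expect_gt(wt$final["g3", 1], 0)
  expect_equal(mut$final["g3", 1], 0)
  expect_equal(mut$final["g4", 1], 0)
  # phenotype = mutant - wildtype = -wildtype for a fully silenced gene
  expect_equal(mut$final["g3", 1] - wt$final["g3", 1], -wt$final["g3", 1])
  # scope excludes TF promoters: the TF's own trajectory is untouched
  expect_equal(mut$x["g1", , ], wt$x["g1", , ])
  expect_error(knockout_tf_sites(f$genome, f$cond, 99), "unknown tf_id")
})

test_that("TF knockout captures indirect effects and equals TFBS knockout without them", {
  f <- fixture_org()
  # without sites on any TF promoter there are no indirect paths, so the
  # two knockout flavours must agree exactly; drop g1's autoregulatory site
  f$genome$sites[[1]] <- grnevolve:::empty_sites()
  wt <- run_differentiation(f$genome, f$cond)
  tfbs <- knockout_tf_sites(f$genome, f$cond, 1)
  tfko <- knockout_tf(f$genome, f$cond, 1)
  expect_equal(tfbs$final, tfko$final, tolerance = 1e-12)
  # with autoregulation present, full TF knockout is at least as severe
  f2 <- fixture_org()
  tfbs2 <- knockout_tf_sites(f2$genome, f2$cond, 1)
  tfko2 <- knockout_tf(f2$genome, f2$cond, 1)
  expect_lte(tfko2$final["g3", 1], tfbs2$final["g3", 1] + 1e-12)
})

test_that("regulator counting follows the site+expression definition", {
  cond <- make_toy_condition(n_cells = 1, n_other_activators = 2,
                             n_terminal_all = 1, n_terminal_specific = 0)
  # genes: g1 lineage, g2/g3 other activators, g4 terminal
  genome <- new_genome(setNames(replicate(4, random_dna(150)),
                                cond$genes$name))
  genome$sites <- list(grnevolve:::empty_sites(), grnevolve:::empty_sites(),
                       grnevolve:::empty_sites(),
                       data.frame(gene_id = 4L, tf_id = c(1L, 3L),
                                  position = c(5L, 30L), strand = "+",
                                  llr = 1, q_base = 1))
  names(genome$sites) <- cond$genes$name
  final <- matrix(c(1.2, 0.8, 0, 2), 4, 1,
                  dimnames = list(cond$genes$name, "cell1"))
  # g1 expressed with a site -> counts; g2 expressed without a site -> no;
  # g3 has a site but is silent -> no
  expect_equal(count_regulators(genome, final, 1, 4, cond), 1L)
  expect_equal(count_regulators(genome, final, 1, 4, cond,
                                role = "inhibitor"), 0L)
  # empty promoter: zero regulators
  expect_equal(count_regulators(genome, final, 1, 2, cond), 0L)
})

test_that("expression breadth uses an inclusive threshold", {
  final <- matrix(c(0, 0, 0, 0,
                    0.5, 0.2, 0.1, 0,
                    4, 3, 2, 1), 3, 4, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(expression_breadth(final),
               c(a = 0L, b = 1L, c = 4L))
  expect_equal(expression_breadth(final, threshold = 2),
               c(a = 0L, b = 0L, c = 3L))
})

test_that("phenotype records are restricted to optimally expressing cells", {
  f <- fixture_org()
  run <- list(condition = f$cond, best = f$genome,
              best_final = run_differentiation(f$genome, f$cond)$final,
              dyn = dynamics_params(), tfp = tf_params(f$cond))
  class(run) <- "grn_run"
  ph <- phenotype_table(run, mode = "tfbs")
  # only the activator TF is perturbed by default; g3, g4 in their one cell
  expect_setequal(ph$gene_id, c(3L, 4L))
  expect_true(all(ph$tf_id == 1L))
  expect_equal(ph$phenotype, ph$mutant - ph$wildtype)
  expect_true(all(ph$phenotype <= 0))
  expect_equal(ph$gene_breadth_class[order(ph$gene_id)],
               c("all", "specific"))
})

test_that("repression summaries flag active inhibitors in off-cells", {
  # no inhibitors: nothing can be repressed
  f <- fixture_org()
  run <- list(condition = make_toy_condition(n_cells = 1),
              best = f$genome,
              best_final = matrix(1, 4, 1,
                                  dimnames = list(f$cond$genes$name, "cell1")))
  class(run) <- "grn_run"
  expect_equal(repression_summary(run)$fraction_genes_repressed, 0)

  # 2 cells, inhibitor expressed in cell 2 with a site on g5 (specific to
  # cell 1): flagged as repressed in its off-cell
  cond <- make_toy_condition(n_cells = 2, n_inhibitors = 1,
                             n_terminal_all = 1, n_terminal_specific = 2)
  genome <- new_genome(setNames(replicate(6, random_dna(150)),
                                cond$genes$name))
  genome$sites <- replicate(6, grnevolve:::empty_sites(), simplify = FALSE)
  genome$sites[[5]] <- data.frame(gene_id = 5L, tf_id = 3L, position = 10L,
                                  strand = "+", llr = 1, q_base = 1)
  names(genome$sites) <- cond$genes$name
  final <- matrix(0, 6, 2, dimnames = list(cond$genes$name,
                                           c("cell1", "cell2")))
  final[3, 2] <- 0.9  # inhibitor g3 expressed in cell 2
  run2 <- list(condition = cond, best = genome, best_final = final)
  class(run2) <- "grn_run"
  rs <- repression_summary(run2)
  expect_equal(rs$fraction_genes_repressed, 0.5)  # g5 yes, g6 no
  flagged <- rs$pairs[rs$pairs$repressed, ]
  expect_equal(flagged$gene_id, 5)
  expect_equal(flagged$cell, 2)
})

test_that("derepression matrices are zero when inhibitors have no sites", {
  f <- fixture_org()
  run <- list(condition = f$cond, best = f$genome,
              best_final = run_differentiation(f$genome, f$cond)$final,
              dyn = dynamics_params(), tfp = tf_params(f$cond))
  class(run) <- "grn_run"
  dm <- derepression_matrices(run)
  expect_named(dm, "g2")
  expect_true(all(dm$g2 == 0))
  expect_equal(dim(dm$g2), c(2L, 1L))
})
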