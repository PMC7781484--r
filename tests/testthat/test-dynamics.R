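test_that("site weights follow the Boltzmann form", {
  expect_equal(site_weight(1.0, tf_conc = 0), 0)
  expect_equal(site_weight(1.0, tf_conc = 1, k_max = 1, accessibility = 1), 1)
  # a site one bit below consensus: q = e^-1 under the literal base-e
  # exponentiation of the bits-valued LLR deficit
  expect_equal(site_weight(exp(-1), tf_conc = 1), exp(-1))
  expect_equal(site_weight(exp(-1), tf_conc = 1), 0.36788, tolerance = 1e-4)
  expect_equal(site_weight(1.0, tf_conc = 2, k_max = 0.5,
                           accessibility = 0.5), 0.5)
  expect_equal(site_weight(0.8, tf_conc = 0.7, accessibility = 0), 0)
})

test_that("promoter activation reproduces hand-enumerated configurations", {
  # no sites under exclude-empty: silent promoter
  expect_equal(promoter_activation(numeric(0), numeric(0)), 0)
  # one activator site q=1, alpha=2: Z_ON = (1+2)-1 = 2, Z_OFF = 2
  expect_equal(promoter_activation(1, 2), 0.5)
  # activator + repressor: Z_ON = 3*1.005 - 1 = 2.015, Z_OFF = 4
  expect_equal(promoter_activation(c(1, 1), c(2, 0.005)), 2.015 / 6.015)
  expect_equal(promoter_activation(c(1, 1), c(2, 0.005)), 0.3350,
               tolerance = 1e-4)
  # include-empty: empty promoter transcribes at 0.5
  expect_equal(promoter_activation(numeric(0), numeric(0), "include-empty"),
               0.5)
  # btm-weight: empty promoter at q_btm/(q_btm + 1)
  expect_equal(promoter_activation(numeric(0), numeric(0), "btm-weight",
                                   q_btm = 0.01), 0.01 / 1.01)
})

test_that("factorized activation equals 2^n enumeration in every basal mode", {
  set.seed(71)
  for (i in 1:150) {
    n <- sample(1:10, 1)
    q <- runif(n, 0, 3)
    alpha <- sample(c(2.0, 0.005), n, replace = TRUE)
    for (mode in c("exclude-empty", "include-empty", "btm-weight")) {
      expect_equal(promoter_activation(q, alpha, mode, q_btm = 0.001),
                   oracle_activation(q, alpha, mode, q_btm = 0.001),
                   tolerance = 1e-12)
    }
  }
  # log-space path stays finite and sane for many sites
  E <- promoter_activation(rep(2, 400), rep(2, 400))
  expect_true(is.finite(E) && E > 0.99 && E <= 1)
})

test_that("activation is monotone in activator and repressor occupancy", {
  set.seed(72)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    q <- runif(n, 0, 2)
    alpha <- sample(c(2.0, 0.005), n, replace = TRUE)
    j <- sample(n, 1)
    q2 <- q
    q2[j] <- q[j] + runif(1, 0.1, 1)
    dE <- promoter_activation(q2, alpha) - promoter_activation(q, alpha)
    if (alpha[j] > 1) expect_gte(dE, 0) else expect_lte(dE, 0)
  }
})

test_that("expression step closed forms hold", {
  expect_equal(step_expression(0, 0, 0.2), 0)
  # fixed point x = E/b
  expect_equal(step_expression(3.5, 0.7, 0.2), 3.5)
  # 10-step ceiling from 0 at E = 1
  x <- 0
  for (t in 1:10) x <- step_expression(x, 1, 0.2)
  expect_equal(x, (1 - 0.8^10) / 0.2, tolerance = 1e-12)
  expect_equal(x, 4.46313, tolerance = 1e-5)
  # pure decay
  x <- 0.5
  for (t in 1:10) x <- step_expression(x, 0, 0.2)
  expect_equal(x, 0.5 * 0.8^10, tolerance = 1e-12)
})

test_that("chromatin step matches its closed forms", {
  cond <- make_toy_condition(n_cells = 1, n_inhibitors = 1)
  tfp <- tf_params(cond)
  empty <- data.frame(tf_id = integer(0), position = integer(0),
                      q_base = numeric(0))
  phi <- runif(50, 0.2, 1.5)
  # H = 0: phi shrinks by the factor 1 + beta*delta = 0.84
  expect_equal(step_chromatin(phi, empty, c(1, 1), tfp), 0.84 * phi,
               tolerance = 1e-12)
  # single consensus activator site, concentration c, at the site position
  sites <- data.frame(tf_id = 1L, position = 10L, q_base = 1)
  conc <- c(0.7, 0)
  phi1 <- rep(1, 50)
  out <- step_chromatin(phi1, sites, conc, tfp)
  expect_equal(out[11], 0.84 * 1 + 0.8 * 0.7 * 1.0 * 1.0, tolerance = 1e-12)
  # 25 bp away the TF contribution falls to exp(-0.5) of the at-site value
  at <- out[11] - 0.84
  away <- out[36] - 0.84
  expect_equal(away / at, exp(-0.5), tolerance = 1e-12)
  # clamping at zero: strong repressor closes chromatin, never below 0
  sites_r <- data.frame(tf_id = 2L, position = 10L, q_base = 1)
  out_r <- step_chromatin(rep(0.01, 50), sites_r, c(0, 5), tfp)
  expect_true(all(out_r >= 0))
  expect_equal(out_r[11], 0)
})

test_that("run_differentiation equals the stepwise R oracle", {
  toy <- planted_toy()
  fast <- run_differentiation(toy$genome, toy$cond)
  slow <- oracle_trajectory(toy$genome, toy$cond)
  expect_equal(as.vector(fast$x), as.vector(slow$x), tolerance = 1e-12)
  expect_equal(unname(fast$final), unname(slow$final), tolerance = 1e-12)
  # expression stays within the Euler ceiling
  expect_true(all(fast$x >= 0))
  expect_true(all(fast$x <= (1 - 0.8^10) / 0.2 + 1e-9))
})

test_that("chromatin-enabled dynamics equal the stepwise R oracle", {
  set.seed(81)
  cond <- make_toy_condition(n_cells = 2, n_inhibitors = 1,
                             promoter_length = 60,
                             chromatin_enabled = TRUE)
  pwms <- sample_pwm_set(3)
  genome <- scan_genome(random_genome(cond), pwms)
  fast <- run_differentiation(genome, cond)
  slow <- oracle_trajectory(genome, cond)
  expect_equal(as.vector(fast$x), as.vector(slow$x), tolerance = 1e-10)
  for (g in seq_along(slow$phi))
    expect_equal(unname(fast$phi[, g, ]), unname(slow$phi[[g]]),
                 tolerance = 1e-10)
})

test_that("degenerate dynamics reduce to closed forms", {
  # zero binding sites: lineage TF decays geometrically, others stay 0
  cond <- make_toy_condition(n_cells = 2, n_terminal_all = 1,
                             n_terminal_specific = 2)
  genome <- new_genome(setNames(replicate(5, random_dna(150)),
                                cond$genes$name))
  genome$sites <- replicate(5, grnevolve:::empty_sites(), simplify = FALSE)
  names(genome$sites) <- cond$genes$name
  expr <- run_differentiation(genome, cond)
  expect_equal(expr$final["g1", "cell1"], 0.5 * 0.8^10, tolerance = 1e-12)
  expect_equal(expr$final["g1", "cell1"], 0.05369, tolerance = 1e-4)
  expect_true(all(expr$final[-(1:2), ] == 0))
  expect_true(all(expr$final[cbind(c(1, 2), c(2, 1))] == 0))

  # all k_max = 0: whole initial pattern decays by (1-b)^T
  toy <- planted_toy()
  tfp0 <- tf_params(toy$cond)
  tfp0$k_max[] <- 0
  expr0 <- run_differentiation(toy$genome, toy$cond, tfp = tfp0)
  expect_equal(unname(expr0$final),
               unname(toy$cond$initial_pattern * 0.8^10), tolerance = 1e-12)

  # chromatin layer with phi frozen at 1 equals the plain model
  set.seed(82)
  condc <- make_toy_condition(n_cells = 1, promoter_length = 60,
                              chromatin_enabled = TRUE)
  pwms <- sample_pwm_set(1)
  genome <- scan_genome(random_genome(condc), pwms)
  dyn_frozen <- dynamics_params(beta = 0, delta = 0)
  fastc <- run_differentiation(genome, condc, dyn_frozen)
  condp <- condc
  condp$chromatin_enabled <- FALSE
  plain <- run_differentiation(genome, condp)
  expect_equal(as.vector(fastc$x), as.vector(plain$x), tolerance = 1e-12)
})
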