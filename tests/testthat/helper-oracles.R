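# Independent slow-path oracles used to validate the fast implementations.

# Uniform PWM: every window scores 0 bits.
uniform_pwm <- function(L = 8L) {
  grnevolve:::new_pwm(matrix(0.25, 4, L,
                             dimnames = list(c("A", "C", "G", "T"), NULL)))
}

# PWM from an explicit probability matrix.
pwm_from_probs <- function(probs, threshold_frac = 0.7, tf_id = NA_integer_) {
  rownames(probs) <- c("A", "C", "G", "T")
  grnevolve:::new_pwm(probs, threshold_frac = threshold_frac, tf_id = tf_id)
}

# Near-deterministic PWM whose consensus is `word`.
pwm_for_word <- function(word, eps = 1e-4, threshold_frac = 0.7,
                         tf_id = NA_integer_) {
  chars <- strsplit(word, "")[[1]]
  probs <- vapply(chars, function(ch) {
    p <- rep(eps, 4)
    p[match(ch, c("A", "C", "G", "T"))] <- 1 - 3 * eps
    p
  }, numeric(4))
  pwm_from_probs(probs, threshold_frac, tf_id)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Brute-force double-strand scan written independently of the C++ kernel.
oracle_scan <- function(seq, pwm) {
  n <- nchar(seq)
  L <- pwm$L
  out <- list()
  if (n >= L) {
    rc <- revcomp(seq)
    for (pos in 0:(n - L)) {
      wf <- substr(seq, pos + 1, pos + L)
      sf <- llr_score(wf, pwm)
      if (sf >= pwm$min_llr)
        out[[length(out) + 1]] <- data.frame(position = pos, strand = "+",
                                             llr = sf)
      # reverse-strand site occupying the same forward window
      wr <- substr(rc, n - L - pos + 1, n - pos)
      sr <- llr_score(wr, pwm)
      if (sr >= pwm$min_llr)
        out[[length(out) + 1]] <- data.frame(position = pos, strand = "-",
                                             llr = sr)
    }
  }
  if (!length(out))
    return(data.frame(position = integer(0), strand = character(0),
                      llr = numeric(0)))
  df <- do.call(rbind, out)
  df[order(df$position, df$strand), ]
}

# Full 2^n configuration enumeration of the promoter partition function.
oracle_activation <- function(q, alpha, basal_mode = "exclude-empty",
                              q_btm = 0.001) {
  n <- length(q)
  zon <- 0; zoff <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    W <- prod(q[sel])
    Q <- prod(alpha[sel])
    zoff <- zoff + W
    empty <- !any(sel)
    zon <- zon + switch(basal_mode,
      "exclude-empty" = if (empty) 0 else W * Q,
      "include-empty" = W * Q,
      "btm-weight" = q_btm * W * Q)
  }
  if (zon == 0) 0 else zon / (zon + zoff)
}

# Naive trajectory: repeated application of the exported step functions.
oracle_trajectory <- function(genome, condition, dyn = dynamics_params(),
                              tfp = tf_params(condition)) {
  G <- nrow(condition$genes)
  C <- condition$n_cells
  P <- condition$promoter_length
  x <- condition$initial_pattern
  chrom <- condition$chromatin_enabled
  phi <- if (chrom)
    lapply(seq_len(G), function(g) matrix(1, P, C)) else NULL
  traj <- array(0, c(G, C, dyn$T + 1))
  traj[, , 1] <- x
  for (t in seq_len(dyn$T)) {
    xn <- x
    for (cc in seq_len(C)) {
      for (g in seq_len(G)) {
        s <- genome$sites[[g]]
        qv <- numeric(0); av <- numeric(0)
        if (nrow(s) > 0) {
          ti <- match(s$tf_id, tfp$tf_id)
          acc <- if (chrom) phi[[g]][s$position + 1, cc] else 1
          qv <- site_weight(s$q_base, x[s$tf_id, cc], tfp$k_max[ti], acc)
          av <- tfp$alpha_btm[ti]
        }
        E <- promoter_activation(qv, av, dyn$basal_mode, dyn$q_btm)
        xn[g, cc] <- step_expression(x[g, cc], E, dyn$b)
      }
    }
    if (chrom) {
      for (cc in seq_len(C)) for (g in seq_len(G)) {
        phi[[g]][, cc] <- step_chromatin(phi[[g]][, cc], genome$sites[[g]],
                                         x[, cc], tfp, dyn$beta, dyn$delta)
      }
    }
    x <- xn
    traj[, , t + 1] <- x
  }
  list(x = traj, final = x, phi = phi)
}

# Naive retained-subgraph counter over all node subsets.
oracle_enumerate <- function(network, sizes = 3:5) {
  adj <- network$adjacency != 0
  n <- nrow(adj)
  tf <- network$nodes$is_tf
  lin <- network$nodes$is_lineage
  counts <- list()
  for (k in sizes) {
    if (k > n) next
    subsets <- utils::combn(n, k)
    for (ci in seq_len(ncol(subsets))) {
      sub <- subsets[, ci]
      a <- adj[sub, sub, drop = FALSE]
      u <- a | t(a)
      # weak connectivity
      seen <- rep(FALSE, k); seen[1] <- TRUE; q <- 1
      while (length(q)) {
        v <- q[1]; q <- q[-1]
        nb <- which(u[v, ] & !seen); seen[nb] <- TRUE; q <- c(q, nb)
      }
      if (!all(seen)) next
      outd <- rowSums(a); ind <- colSums(a)
      stf <- tf[sub]; slin <- lin[sub]
      if (any(stf & outd == 0)) next
      if (any(stf & !slin & ind == 0)) next
      if (!any(stf & slin)) next
      if (!any(!stf & ind >= 1)) next
      key <- canonical_class(a * 1L, stf)
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A 2-cell toy genome with planted sites: lineage TF of each cell
# autoactivates (site on its own... not allowed: self-sites are fine for
# expression, only networks ignore them) and drives one terminal gene.
planted_toy <- function(seed = 42) {
  set.seed(seed)
  cond <- make_toy_condition(n_cells = 2, n_inhibitors = 1,
                             n_terminal_all = 1, n_terminal_specific = 2)
  pwms <- sample_pwm_set(3)  # 2 lineage activators + 1 inhibitor
  genome <- random_genome(cond)
  # wipe incidental sites by rebuilding promoters from a low-scoring base
  plan <- data.frame(gene_id = c(4, 5, 6, 4),
                     tf_id   = c(1, 1, 2, 2),
                     position = c(10, 40, 80, 120),
                     strand = c("+", "+", "-", "+"))
  genome <- plant_sites(genome, pwms, plan)
  genome <- scan_genome(genome, pwms)
  list(cond = cond, pwms = pwms, genome = genome, plan = plan)
}
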