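# Population-level evolutionary loop: fitness, tournament selection with
# sex, segregation, recombination, scheduled mutation, convergence
# detection, binding-site birth/death tracking.

#' Evolutionary parameters
#'
#' @param N population size.
#' @param k tournament size (two tournaments of `k` organisms are drawn per
#'   offspring; the fittest of each is a parent).
#' @param k_late tournament size after generation 300 once the population
#'   mean MSE has dropped below 0.5 (increased selection pressure).
#' @param r recombination rate, crossover events per kilobase of promoter.
#' @param epsilon convergence threshold: the run stops when the population
#'   mean MSE falls below it.
#' @param max_generations hard cap; a run reaching it is flagged
#'   non-converged.
#' @param m_schedule mutation-rate schedule: substitutions per kb before
#'   generation 100 and from 100 to 299, then substitutions *per genome*
#'   from 300 to 499 and from 500 on.
#' @param m_breaks the three generation breakpoints of the schedule.
#' @param m_clip bounds on the per-individual scaling of the substitution
#'   rate (an individual's rate is the scheduled rate times its MSE
#'   relative to the population mean, clipped to this interval).
#' @return a list of class `grn_evo_params`.
#' @export
evo_params <- function(N = 24L, k = 12L, k_late = 18L, r = 0.2,
                       epsilon = 0.01, max_generations = 5000L,
                       m_schedule = c(5, 1, 1.5, 1.25),
                       m_breaks = c(100L, 300L, 500L),
                       m_clip = c(0.5, 2.0)) {
  stopifnot(k > 1, k <= N, k_late <= N, epsilon > 0,
            length(m_schedule) == 4L, length(m_breaks) == 3L)
  structure(list(N = as.integer(N), k = as.integer(k),
                 k_late = as.integer(k_late), r = r, epsilon = epsilon,
                 max_generations = as.integer(max_generations),
                 m_schedule = m_schedule, m_breaks = as.integer(m_breaks),
                 m_clip = m_clip),
            class = "grn_evo_params")
}

#' Mean squared error of an organism's adult expression pattern
#'
#' Fitness statistic: the mean over cells of the mean over non-TF
#' (terminal) genes of the squared deviation between adult and optimal
#' expression. TFs are excluded from fitness; organisms are ranked by
#' ascending MSE (fitness is its inverse, with MSE 0 strictly best).
#'
#' @param final_pattern terminal-genes x cells matrix (or a full genes x
#'   cells matrix together with `condition`, from which terminal rows are
#'   taken).
#' @param optimal_pattern terminal-genes x cells matrix of target levels.
#' @param condition optional `grn_condition` used to subset a full-roster
#'   `final_pattern`.
#' @return the MSE (non-negative scalar).
#' @export
#' @examples
#' organism_mse(matrix(c(0.1, 0, 0, 0.2), 2), matrix(0, 2, 2))  # 0.0125
organism_mse <- function(final_pattern, optimal_pattern, condition = NULL) {
  if (!is.null(condition) && nrow(final_pattern) == n_genes(condition))
    final_pattern <- final_pattern[terminal_ids(condition), , drop = FALSE]
  if (!all(dim(final_pattern) == dim(optimal_pattern)))
    stop("shape mismatch between final and optimal pattern")
  mean(colMeans((final_pattern - optimal_pattern)^2))
}

#' One round of tournament selection with sex
#'
#' Two sets of `k` organisms are drawn from the population, each without
#' replacement within itself but independently of the other (so the same
#' organism can win both tournaments: selfing is possible). The fittest
#' organism of each set — lowest MSE, ties broken by lower population index
#' — is returned as a parent.
#'
#' @param mse numeric vector of organism MSEs (the population).
#' @param k tournament size.
#' @return integer vector of two parent indices.
#' @export
tournament_round <- function(mse, k) {
  N <- length(mse)
  stopifnot(k >= 1, k <= N)
  pick <- function() {
    set <- sample.int(N, k)
    set[order(mse[set], set)[1L]]
  }
  c(pick(), pick())
}

#' Produce one offspring genome from two parents
#'
#' Genes segregate independently: each promoter starts from one parent
#' chosen with probability 1/2. Homologous promoters then recombine with
#' `Poisson(r * length/1000)` crossover points at uniform positions
#' (segments alternate between the parents, starting from the chosen one),
#' and accumulate `Poisson(m * length/1000)` random substitutions, each to
#' one of the other three bases uniformly.
#'
#' @param parentA,parentB `grn_genome` objects (or named character vectors
#'   of promoters) over the same roster.
#' @param r recombination rate per kb.
#' @param m substitution rate per kb.
#' @return a named character vector of offspring promoters.
#' @export
reproduce <- function(parentA, parentB, r = 0.2, m = 5) {
  pa <- if (inherits(parentA, "grn_genome")) parentA$promoters else parentA
  pb <- if (inherits(parentB, "grn_genome")) parentB$promoters else parentB
  stopifnot(length(pa) == length(pb))
  P <- nchar(pa[[1]])
  child <- character(length(pa))
  names(child) <- names(pa)
  for (g in seq_along(pa)) {
    first <- runif(1) < 0.5
    s <- if (first) pa[[g]] else pb[[g]]
    ncross <- rpois(1, r * P / 1000)
    if (ncross > 0 && pa[[g]] != pb[[g]]) {
      pts <- sort(sample.int(P - 1L, ncross, replace = TRUE))
      a <- strsplit(pa[[g]], "")[[1]]
      b <- strsplit(pb[[g]], "")[[1]]
      src <- if (first) a else b
      other <- if (first) b else a
      out <- src
      take_other <- FALSE
      bounds <- c(pts, P)
      prev <- 0L
      for (bi in seq_along(bounds)) {
        if (take_other && bounds[bi] > prev)
          out[(prev + 1L):bounds[bi]] <- other[(prev + 1L):bounds[bi]]
        prev <- bounds[bi]
        take_other <- !take_other
      }
      s <- paste(out, collapse = "")
    }
    nsub <- rpois(1, m * P / 1000)
    if (nsub > 0) {
      chars <- strsplit(s, "")[[1]]
      for (j in seq_len(nsub)) {
        pos <- sample.int(P, 1L)
        chars[pos] <- sample(setdiff(DNA_BASES, chars[pos]), 1L)
      }
      s <- paste(chars, collapse = "")
    }
    child[g] <- s
  }
  child
}

#' Mutation-rate and tournament-size schedule
#'
#' The substitution rate starts high to explore sequence space and drops as
#' evolution proceeds: 5/kb before generation 100, 1/kb from 100, then 1.5
#' substitutions per genome from generation 300 and 1.25 from generation
#' 500. Each individual's rate is additionally scaled by its MSE relative
#' to the population mean (clipped), so offspring of less fit parents
#' mutate more. Tournament size is `k`, raised to `k_late` after generation
#' 300 once mean MSE < 0.5.
#'
#' @param generation generation being produced (1-based).
#' @param mean_mse current population mean MSE.
#' @param individual_mse MSE of the (mid-parent of the) individual.
#' @param genome_kb genome length in kilobases (to convert per-genome rates
#'   to per-kb).
#' @param evo a `grn_evo_params`.
#' @return list with `m_per_kb` (individually scaled substitution rate) and
#'   `k` (tournament size).
#' @export
mutation_schedule <- function(generation, mean_mse, individual_mse,
                              genome_kb, evo = evo_params()) {
  sc <- evo$m_schedule
  br <- evo$m_breaks
  m_base <- if (generation < br[1]) sc[1]
    else if (generation < br[2]) sc[2]
    else if (generation < br[3]) sc[3] / genome_kb
    else sc[4] / genome_kb
  scale <- min(max(individual_mse / mean_mse, evo$m_clip[1]), evo$m_clip[2])
  k <- if (generation > br[2] && mean_mse < 0.5) evo$k_late else evo$k
  list(m_per_kb = m_base * scale, k = k)
}

#' Evolve a population toward a condition's optimal expression pattern
#'
#' Runs one complete evolutionary simulation: PWMs are sampled once and
#' held fixed; `N` genomes with uniform random promoters form generation 0;
#' each generation `N` offspring are produced by tournament selection,
#' independent segregation, recombination and scheduled mutation; the run
#' stops when the population mean MSE drops below `epsilon` or at the
#' generation cap (flagged non-converged). All randomness flows from
#' `seed`; identical seeds give bit-identical runs.
#'
#' @param condition a `grn_condition`.
#' @param evo a `grn_evo_params`.
#' @param dyn a `grn_dynamics_params`.
#' @param tfp per-TF parameters (defaults to [tf_params()] of the
#'   condition).
#' @param seed integer seed driving the whole run.
#' @param track_sites record the birth and death generation of every
#'   population-level binding site (identified by gene, TF, position and
#'   strand)?
#' @param pwms optional pre-sampled PWM list (sampled from `seed` if
#'   omitted).
#' @param progress print mean/best MSE every this many generations (0:
#'   silent).
#' @return an object of class `grn_run`: the condition, PWM set, final
#'   population (promoters and MSEs), best genome (with site cache and
#'   expression trajectory), MSE trajectories, generations used,
#'   convergence flag, site-event table (if tracked) and the seed.
#' @export
run_evolution <- function(condition, evo = evo_params(),
                          dyn = dynamics_params(),
                          tfp = tf_params(condition), seed = 1L,
                          track_sites = FALSE, pwms = NULL,
                          progress = 0L) {
  set.seed(seed)
  nTF <- length(tf_ids(condition))
  if (is.null(pwms)) pwms <- sample_pwm_set(nTF)
  stopifnot(length(pwms) == nTF)
  if (condition$chromatin_enabled && dyn$T < 1)
    stop("chromatin dynamics need at least one step")

  res <- cpp_evolve(
    n_genes(condition), condition$n_cells, condition$promoter_length, nTF,
    condition$initial_pattern, full_optimal(condition),
    terminal_ids(condition) - 1L,
    lapply(pwms, `[[`, "logodds"),
    vapply(pwms, `[[`, 0, "llr_max"), vapply(pwms, `[[`, 0, "min_llr"),
    dyn$llr_scale,
    tfp$alpha_btm, tfp$k_max, tfp$rho, tfp$sigma_chrom,
    dyn$b, dyn$T, basal_mode_code(dyn$basal_mode), dyn$q_btm,
    condition$chromatin_enabled, dyn$beta, dyn$delta,
    evo$N, evo$k, evo$k_late, evo$r, evo$epsilon, evo$max_generations,
    evo$m_schedule, evo$m_breaks, evo$m_clip[1], evo$m_clip[2],
    track_sites, as.integer(progress))

  gene_names <- condition$genes$name
  cell_names <- colnames(condition$initial_pattern)
  rownames(res$population) <- gene_names

  best_prom <- res$population[, res$best_index]
  names(best_prom) <- gene_names
  sites <- res$best_sites
  sites$strand <- c("+", "-")[sites$strand + 1L]
  best <- structure(list(promoters = best_prom,
                         sites = split(sites, factor(sites$gene_id,
                                                     levels = seq_along(gene_names))),
                         pwms = pwms),
                    class = "grn_genome")
  names(best$sites) <- gene_names
  dimnames(res$best_trajectory) <- list(gene_names, cell_names,
                                        paste0("t", 0:dyn$T))
  final <- res$best_trajectory[, , dyn$T + 1L, drop = FALSE]
  dim(final) <- c(n_genes(condition), condition$n_cells)
  dimnames(final) <- list(gene_names, cell_names)

  events <- NULL
  if (track_sites) {
    events <- res$site_events
    events$strand <- c("+", "-")[events$strand + 1L]
    events$gene_class <- gene_breadth_class(condition)[events$gene_id]
    events$gene_class[is.na(events$gene_class)] <- "tf"
  }

  structure(list(
    condition = condition, pwms = pwms, evo = evo, dyn = dyn, tfp = tfp,
    population = res$population, population_mse = res$mse,
    best_index = res$best_index, best = best,
    best_final = final, best_trajectory = res$best_trajectory,
    best_mse = res$mse[res$best_index],
    mse_mean = res$mse_mean, mse_best = res$mse_best,
    generations = res$generations, converged = res$converged,
    site_events = events, seed = seed), class = "grn_run")
}

#' @export
print.grn_run <- function(x, ...) {
  cat("grn_run [", x$condition$name, "] seed ", x$seed, ": ",
      x$generations, " generations, ",
      if (x$converged) "converged" else "NOT converged",
      " (mean MSE ", format(tail(x$mse_mean, 1), digits = 4),
      ", best ", format(x$best_mse, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Persistence statistics of population-level binding sites
#'
#' A site key (gene, TF, position, strand) *emerges* at the first
#' generation any individual carries it and *dies* at the first subsequent
#' generation no individual carries it; it *persists* if it is alive in the
#' final generation. Statistics are computed per terminal-gene breadth
#' class over keys with `birth_gen >= min_birth_gen`. Lifespans (death
#' minus birth generation) are averaged over died sites; persisted sites
#' are censored at the final generation and excluded from the mean unless
#' `count_persisted` is set.
#'
#' @param run a `grn_run` produced with `track_sites = TRUE` (or its
#'   `site_events` table).
#' @param min_birth_gen only sites born at or after this generation count.
#' @param tf_role restrict to sites of activator or inhibitor TFs
#'   (`"any"`: all).
#' @param count_persisted include persisted sites (censored at the final
#'   generation) in the mean lifespan?
#' @param final_generation needed with `count_persisted` when passing a raw
#'   event table.
#' @return data.frame with one row per gene class: sites emerged, emerged
#'   per promoter, persistence probability, mean lifespan.
#' @export
persistence_stats <- function(run, min_birth_gen = 0,
                              tf_role = c("any", "activator", "inhibitor"),
                              count_persisted = FALSE,
                              final_generation = NULL) {
  tf_role <- match.arg(tf_role)
  if (inherits(run, "grn_run")) {
    if (is.null(run$site_events))
      stop("run was produced without site tracking; ",
           "use run_evolution(track_sites = TRUE)")
    ev <- run$site_events
    final_generation <- run$generations
    n_prom <- table(gene_breadth_class(run$condition), useNA = "no")
    if (tf_role != "any") {
      roles <- setNames(run$tfp$role, run$tfp$tf_id)
      ev <- ev[roles[as.character(ev$tf_id)] == tf_role, , drop = FALSE]
    }
  } else {
    ev <- run
    n_prom <- NULL
  }
  ev <- ev[ev$birth_gen >= min_birth_gen, , drop = FALSE]
  cls <- sort(unique(ev$gene_class))
  out <- do.call(rbind, lapply(cls, function(cl) {
    e <- ev[ev$gene_class == cl, , drop = FALSE]
    died <- !e$persisted
    life <- e$death_gen[died] - e$birth_gen[died]
    if (count_persisted) {
      if (is.null(final_generation))
        stop("final_generation needed to censor persisted sites")
      life <- c(life, final_generation - e$birth_gen[!died])
    }
    data.frame(gene_class = cl, n_emerged = nrow(e),
               emerged_per_promoter =
                 if (!is.null(n_prom) && cl %in% names(n_prom))
                   nrow(e) / as.integer(n_prom[[cl]]) else NA_real_,
               persistence_prob = mean(e$persisted),
               mean_lifespan = if (length(life)) mean(life) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
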