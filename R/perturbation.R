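# In-silico mutagenesis of evolved networks: binding-site removal, TF
# knockout, phenotype quantification, regulator counting, expression
# breadth and repression summaries.

#' Remove all binding sites of one TF from terminal-gene promoters
#'
#' Deletes every cached binding site of `tf_id` on terminal-feature
#' promoters (the DNA sequence is untouched, so no new sites can be created
#' by the deletion) and re-runs differentiation. TF-gene promoters are not
#' touched, so only the direct regulatory contribution of the TF on
#' terminal features is removed.
#'
#' @param genome an evolved `grn_genome` with site cache.
#' @param condition the `grn_condition` of the run.
#' @param tf_id TF to mutate.
#' @param dyn,tfp dynamics and per-TF parameters.
#' @param scope `"terminal-only"` (default) removes sites on terminal
#'   promoters only; `"all"` removes them everywhere.
#' @return a `grn_expression` for the mutant.
#' @export
knockout_tf_sites <- function(genome, condition, tf_id,
                              dyn = dynamics_params(),
                              tfp = tf_params(condition),
                              scope = c("terminal-only", "all")) {
  scope <- match.arg(scope)
  check_tf(condition, tf_id)
  term <- terminal_ids(condition)
  mut <- genome
  mut$sites <- lapply(seq_along(genome$sites), function(g) {
    s <- genome$sites[[g]]
    if (scope == "all" || g %in% term) s[s$tf_id != tf_id, , drop = FALSE]
    else s
  })
  names(mut$sites) <- names(genome$sites)
  run_differentiation(mut, condition, dyn, tfp)
}

#' Knock out a TF by nullifying its association constant
#'
#' Sets the TF's consensus association constant to zero and re-runs
#' differentiation, so the TF can no longer bind anywhere: direct and
#' indirect effects (through other TFs it regulates) both contribute to the
#' phenotype.
#'
#' @inheritParams knockout_tf_sites
#' @return a `grn_expression` for the mutant.
#' @export
knockout_tf <- function(genome, condition, tf_id, dyn = dynamics_params(),
                        tfp = tf_params(condition)) {
  check_tf(condition, tf_id)
  tfp$k_max[tfp$tf_id == tf_id] <- 0
  run_differentiation(genome, condition, dyn, tfp)
}

check_tf <- function(condition, tf_id) {
  if (length(tf_id) != 1L || !tf_id %in% tf_ids(condition))
    stop("unknown tf_id: ", tf_id)
  invisible(tf_id)
}

#' Number of cells in which each gene is expressed
#'
#' A gene counts as expressed in a cell when its final expression is at or
#' above `threshold` (inclusive, default 0.5; maximal attainable levels are
#' around 4).
#'
#' @param final_expression genes x cells matrix of adult expression.
#' @param threshold inclusive expression threshold.
#' @return named integer vector, cells expressed per gene.
#' @export
expression_breadth <- function(final_expression, threshold = 0.5) {
  apply(final_expression >= threshold, 1, sum)
}

#' Count the active regulators of a gene in a cell
#'
#' A TF counts as a regulator of a gene in a cell if (i) it has at least
#' one binding site on the gene's promoter and (ii) its own expression in
#' that cell is greater than `floor`.
#'
#' @param genome `grn_genome` with site cache.
#' @param final_expression genes x cells adult pattern.
#' @param cell cell index.
#' @param gene gene index.
#' @param condition the `grn_condition`.
#' @param role `"any"`, `"activator"` or `"inhibitor"`.
#' @param floor expression floor for "expressed" (default literal 0; a
#'   small epsilon can be supplied because repressor-only promoters can
#'   carry tiny nonzero expression).
#' @return integer count.
#' @export
count_regulators <- function(genome, final_expression, cell, gene, condition,
                             role = c("any", "activator", "inhibitor"),
                             floor = 0) {
  role <- match.arg(role)
  sites <- genome$sites[[gene]]
  tfs <- unique(sites$tf_id)
  if (role != "any") {
    keep <- condition$genes$kind[tfs] == role
    tfs <- tfs[keep]
  }
  sum(final_expression[tfs, cell] > floor)
}

#' Phenotypes of all single-TF perturbations of an evolved organism
#'
#' For every activator (or requested) TF, removes either its terminal-gene
#' binding sites (`mode = "tfbs"`, direct effects only) or the TF itself
#' (`mode = "tf"`, direct plus indirect effects), re-computes the adult
#' pattern, and records `phenotype = mutant - wildtype` expression for
#' every terminal feature in the cells where it is optimally expressed.
#'
#' @param run a `grn_run` (or a list with `best`, `condition`, `dyn`,
#'   `tfp`).
#' @param mode `"tfbs"` or `"tf"`.
#' @param tfs TF ids to perturb (default: all activators).
#' @param breadth_threshold threshold for the TF-breadth annotation.
#' @param regulators_only keep only records where the perturbed TF actually
#'   regulates the gene in that cell in the wildtype — at least one binding
#'   site on the gene's promoter and TF expression above `floor` (default).
#'   With `FALSE`, every (TF, gene, cell) triple is recorded, most with a
#'   phenotype of exactly zero.
#' @param floor expression floor for the regulator condition.
#' @return data.frame with columns `tf_id`, `gene_id`, `cell`, `wildtype`,
#'   `mutant`, `phenotype`, `tf_breadth` (cells where the TF is expressed
#'   at or above `breadth_threshold` in the wildtype), `gene_breadth_class`
#'   (`"specific"`, `"two-cell"` or `"all"`).
#' @export
phenotype_table <- function(run, mode = c("tfbs", "tf"), tfs = NULL,
                            breadth_threshold = 0.5, regulators_only = TRUE,
                            floor = 0) {
  mode <- match.arg(mode)
  cond <- run$condition
  wt <- run$best_final
  if (is.null(tfs)) tfs <- activator_ids(cond)
  term <- terminal_ids(cond)
  breadth <- expression_breadth(wt, breadth_threshold)
  gclass <- gene_breadth_class(cond)
  opt <- full_optimal(cond)
  rows <- lapply(tfs, function(h) {
    idx <- which(opt[term, , drop = FALSE] > 0, arr.ind = TRUE)
    if (regulators_only) {
      has_site <- vapply(term[idx[, 1]], function(g)
        any(run$best$sites[[g]]$tf_id == h), TRUE)
      expressed <- wt[h, idx[, 2]] > floor
      idx <- idx[has_site & expressed, , drop = FALSE]
    }
    if (nrow(idx) == 0) return(NULL)
    mut <- if (mode == "tfbs")
      knockout_tf_sites(run$best, cond, h, run$dyn, run$tfp)
    else knockout_tf(run$best, cond, h, run$dyn, run$tfp)
    data.frame(tf_id = h,
               gene_id = term[idx[, 1]],
               cell = idx[, 2],
               wildtype = wt[cbind(term[idx[, 1]], idx[, 2])],
               mutant = mut$final[cbind(term[idx[, 1]], idx[, 2])],
               tf_breadth = breadth[[h]],
               gene_breadth_class = gclass[term[idx[, 1]]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$phenotype <- out$mutant - out$wildtype
  out
}

#' Active repression of cell-specific terminal features in their off-cells
#'
#' An inhibitor TF counts as repressing a gene in a cell if (i) it has at
#' least one binding site on the gene's promoter and (ii) its expression in
#' that cell is greater than `floor`. For every cell-specific terminal
#' feature and every cell where it should be off, the presence of at least
#' one active inhibitor is flagged; results are aggregated per gene
#' (repressed in at least one off-cell) and per (gene, off-cell) pair.
#'
#' @param run a `grn_run`.
#' @param floor expression floor for "expressed".
#' @return list with `fraction_genes_repressed`, `fraction_pairs_repressed`
#'   and the per-pair table `pairs`.
#' @export
repression_summary <- function(run, floor = 0) {
  cond <- run$condition
  wt <- run$best_final
  inh <- inhibitor_ids(cond)
  spec <- which(cond$genes$pattern_class == "terminal-specific")
  if (length(inh) == 0L || length(spec) == 0L)
    return(list(fraction_genes_repressed = 0, fraction_pairs_repressed = 0,
                pairs = data.frame()))
  opt <- full_optimal(cond)
  rows <- list()
  for (g in spec) {
    off_cells <- which(opt[g, ] == 0)
    has_site <- inh[vapply(inh, function(h)
      any(run$best$sites[[g]]$tf_id == h), TRUE)]
    for (cc in off_cells) {
      active <- has_site[wt[has_site, cc] > floor]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, cell = cc, n_active_inhibitors = length(active),
        repressed = length(active) > 0)
    }
  }
  pairs <- do.call(rbind, rows)
  by_gene <- tapply(pairs$repressed, pairs$gene_id, any)
  list(fraction_genes_repressed = mean(by_gene),
       fraction_pairs_repressed = mean(pairs$repressed),
       pairs = pairs)
}

#' De-repression matrices under inhibitor knockout
#'
#' For each inhibitor, knocks the TF out and returns the phenotype
#' (mutant minus wildtype adult expression) of every terminal feature in
#' every cell: positive entries are de-repression.
#'
#' @param run a `grn_run`.
#' @param inhibitors inhibitor TF ids (default all).
#' @return named list of terminal-genes x cells phenotype matrices.
#' @export
derepression_matrices <- function(run, inhibitors = NULL) {
  cond <- run$condition
  if (is.null(inhibitors)) inhibitors <- inhibitor_ids(cond)
  term <- terminal_ids(cond)
  out <- lapply(inhibitors, function(h) {
    mut <- knockout_tf(run$best, cond, h, run$dyn, run$tfp)
    (mut$final - run$best_final)[term, , drop = FALSE]
  })
  names(out) <- cond$genes$name[inhibitors]
  out
}
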