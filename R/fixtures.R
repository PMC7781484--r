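# Deterministic toy generators: every stage of the pipeline is testable in
# milliseconds without running a full evolutionary simulation.

#' Build a miniature condition for testing and demonstration
#'
#' Assembles a minimal valid condition: `n_cells` cells each seeded by its
#' own lineage activator TF, plus optional extra activators, inhibitors and
#' terminal features. Terminal features are split between broadly
#' expressed (optimally on in all cells) and cell-specific (assigned to
#' cells round-robin).
#'
#' @param n_cells number of cells (lineage TFs match it).
#' @param n_other_activators,n_inhibitors extra TFs.
#' @param n_terminal_all broadly expressed terminal features.
#' @param n_terminal_specific cell-specific terminal features.
#' @param promoter_length promoter length in bases.
#' @param chromatin_enabled enable the chromatin-accessibility layer?
#' @param levels named vector with `low`, `high`, `off` expression levels.
#' @return a `grn_condition` named `"toy"`.
#' @export
#' @examples
#' make_toy_condition(1, n_terminal_specific = 0, n_terminal_all = 1)
make_toy_condition <- function(n_cells = 2L, n_other_activators = 0L,
                               n_inhibitors = 0L, n_terminal_all = 1L,
                               n_terminal_specific = n_cells,
                               promoter_length = 150L,
                               chromatin_enabled = FALSE,
                               levels = c(low = 0.5, high = 4.0, off = 0.0)) {
  C <- as.integer(n_cells)
  if (C < 1) stop("infeasible toy configuration: need at least one cell")
  if (n_terminal_all + n_terminal_specific < 1)
    stop("infeasible toy configuration: need at least one terminal gene")
  rows <- list()
  add <- function(kind, class, cells)
    rows[[length(rows) + 1L]] <<- list(kind = kind, class = class,
                                       cells = cells)
  for (c in seq_len(C)) add("activator", "lineage", c)
  for (i in seq_len(n_other_activators))
    add("activator", "other-activator", integer(0))
  for (i in seq_len(n_inhibitors)) add("inhibitor", "inhibitor", integer(0))
  for (i in seq_len(n_terminal_all)) add("terminal", "terminal-all",
                                         seq_len(C))
  for (i in seq_len(n_terminal_specific))
    add("terminal", "terminal-specific", ((i - 1L) %% C) + 1L)

  G <- length(rows)
  genes <- data.frame(gene_id = seq_len(G), name = paste0("g", seq_len(G)),
                      kind = vapply(rows, `[[`, "", "kind"),
                      pattern_class = vapply(rows, `[[`, "", "class"),
                      stringsAsFactors = FALSE)
  genes$cells <- I(lapply(rows, `[[`, "cells"))
  initial <- matrix(0, G, C, dimnames = list(genes$name,
                                             paste0("cell", seq_len(C))))
  for (g in which(genes$pattern_class == "lineage"))
    initial[g, genes$cells[[g]]] <- levels[["low"]]
  term <- which(genes$kind == "terminal")
  optimal <- matrix(levels[["off"]], length(term), C,
                    dimnames = list(genes$name[term],
                                    paste0("cell", seq_len(C))))
  for (i in seq_along(term))
    optimal[i, genes$cells[[term[i]]]] <- levels[["high"]]
  cond <- structure(
    list(name = "toy", n_cells = C, genes = genes,
         initial_pattern = initial, optimal_pattern = optimal,
         promoter_length = as.integer(promoter_length),
         n_inhibitors = as.integer(n_inhibitors),
         chromatin_enabled = isTRUE(chromatin_enabled),
         levels = levels),
    class = "grn_condition")
  validate_condition(cond)
  cond
}

#' Write PWM consensus words into promoters at planned positions
#'
#' Each plan row places the consensus site of one TF's PWM on a promoter at
#' a given offset, on the forward or reverse strand. Planted windows on
#' the same promoter must not overlap. Scanning the planted genome
#' recovers (at least) the planned sites at the consensus LLR.
#'
#' @param genome a `grn_genome`.
#' @param pwms list of `grn_pwm`.
#' @param plan data.frame with columns `gene_id`, `tf_id`, `position`
#'   (0-based window start) and optionally `strand` ("+"/"-", default "+").
#' @return the genome with planted promoters (site cache rebuilt when PWMs
#'   are attached).
#' @export
plant_sites <- function(genome, pwms, plan) {
  if (is.null(plan$strand)) plan$strand <- "+"
  for (g in unique(plan$gene_id)) {
    rows <- plan[plan$gene_id == g, , drop = FALSE]
    L <- vapply(rows$tf_id, function(h) pwms[[h]]$L, 0L)
    start <- rows$position
    end <- start + L
    ord <- order(start)
    if (any(start[ord][-1] < end[ord][-length(ord)]))
      stop("overlap conflict between planted sites on gene ", g)
    prom <- strsplit(genome$promoters[[g]], "")[[1]]
    if (any(end > length(prom)))
      stop("planted site extends past promoter end on gene ", g)
    for (r in seq_len(nrow(rows))) {
      word <- pwms[[rows$tf_id[r]]]$consensus
      if (rows$strand[r] == "-") word <- revcomp(word)
      prom[(start[r] + 1L):end[r]] <- strsplit(word, "")[[1]]
    }
    genome$promoters[[g]] <- paste(prom, collapse = "")
  }
  genome$sites <- NULL
  if (!is.null(genome$pwms)) genome <- scan_genome(genome, pwms)
  genome
}

#' Emit a complete miniature run directory
#'
#' Runs a short toy evolution and saves it with [save_run()]; used by the
#' command-line `fixtures` subcommand and by tests that need a run
#' directory on disk.
#'
#' @param dir output directory.
#' @param seed seed for the toy run.
#' @param max_generations cap for the toy run.
#' @return the directory, invisibly.
#' @export
make_toy_run <- function(dir, seed = 1L, max_generations = 200L) {
  cond <- make_toy_condition(n_cells = 1L, n_terminal_all = 1L,
                             n_terminal_specific = 0L)
  run <- run_evolution(cond,
                       evo = evo_params(max_generations = max_generations),
                       seed = seed)
  save_run(run, dir)
  invisible(dir)
}
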