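# Simulation conditions: gene rosters, initial and optimal expression patterns.

#' Numeric expression levels used to populate condition patterns
#'
#' Returns the three concentrations used when building initial and optimal
#' expression matrices: the low level at which lineage TFs are seeded before
#' differentiation, the high level at which terminal features should end up
#' in the cells where they belong, and the off level elsewhere. The high
#' level defaults to 4.0, just below the ceiling `(1 - (1-b)^T)/b ~ 4.463`
#' that the Euler dynamics can reach at maximal activation, so that a
#' converged organism can actually attain it.
#'
#' @param condition a `grn_condition`, or `NULL` for the package defaults.
#' @return a list with components `low_init`, `high_opt`, `off_opt`.
#' @export
#' @examples
#' pattern_levels()
pattern_levels <- function(condition = NULL) {
  lv <- if (is.null(condition)) default_levels() else condition$levels
  list(low_init = lv[["low"]], high_opt = lv[["high"]], off_opt = lv[["off"]])
}

default_levels <- function() c(low = 0.5, high = 4.0, off = 0.0)

gene_kinds <- c("activator", "inhibitor", "terminal")
pattern_classes <- c("lineage", "other-activator", "inhibitor",
                     "terminal-all", "terminal-specific", "terminal-2")

# Registered presets. The "fix" suffix is treated as a configuration label
# (the presets differ only in the number of repressor TFs); `Xss` is the
# long-promoter chromatin-accessibility variant; `mini` is a reduced roster
# with the same architecture, intended for replicated desk-scale experiments.
condition_presets <- function() {
  list(
    mce0    = list(model = "mce0", n_inhibitors = 5),
    mce0fix = list(model = "mce0", n_inhibitors = 4),
    mce1    = list(model = "mce1", n_inhibitors = 4),
    mce1fix = list(model = "mce1", n_inhibitors = 4),
    mce2    = list(model = "mce2", n_inhibitors = 5),
    mce2fix = list(model = "mce2", n_inhibitors = 4),
    mce0Xss = list(model = "mce0", n_inhibitors = 5,
                   promoter_length = 600, chromatin_enabled = TRUE),
    mce0mini = list(model = "mce0", n_inhibitors = 3, n_tfs = 10,
                    n_terminal_all = 3, n_specific_per_cell = 2),
    mce2mini = list(model = "mce2", n_inhibitors = 3, n_tfs = 10,
                    n_terminal_all = 3, n_specific_per_cell = 2)
  )
}

#' Build a simulation condition
#'
#' A condition defines the organisms of one evolutionary experiment: the
#' gene roster (which genes are activator TFs, repressor TFs or terminal
#' features, and which TFs are lineage TFs), the number of cells, the
#' initial expression pattern (lineage TFs at a low level, everything else
#' silent) and the optimal expression pattern over terminal features only.
#'
#' Built-in labels: `mce0`/`mce0fix` (40 genes: 15 TFs of which 4 are
#' cell-specific lineage TFs, plus 5 broadly expressed and 20 cell-specific
#' terminal features over 4 cells), `mce1`/`mce1fix` (10 extra terminal
#' features expressed in cell pairs), `mce2`/`mce2fix` (as mce0 plus one
#' extra lineage TF expressed in every cell), `mce0Xss` (mce0 with 600 bp
#' promoters and the chromatin-accessibility layer enabled), and
#' `mce0mini`/`mce2mini` (reduced rosters with the same architecture for
#' replicated desk-scale experiments).
#'
#' @param name one of the built-in labels above.
#' @param overrides named list of condition fields to override
#'   (`n_inhibitors`, `promoter_length`, `chromatin_enabled`, `levels`,
#'   `n_tfs`, `n_terminal_all`, `n_specific_per_cell`, `n_cells`).
#' @return an object of class `grn_condition`.
#' @export
#' @examples
#' cond <- build_condition("mce0fix")
#' nrow(cond$genes)  # 40
build_condition <- function(name, overrides = list()) {
  presets <- condition_presets()
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets))
    stop("unknown condition label '", paste(name, collapse = ","),
         "'; known labels: ", paste(names(presets), collapse = ", "))
  cfg <- modifyList(presets[[name]], overrides)
  cfg$name <- name
  defaults <- list(n_cells = 4L, n_tfs = 15L, promoter_length = 150L,
                   chromatin_enabled = FALSE, n_terminal_all = 5L,
                   n_specific_per_cell = 5L, n_terminal2 = 10L,
                   levels = default_levels())
  cfg <- modifyList(defaults, cfg)
  if (is.list(cfg$levels)) cfg$levels <- unlist(cfg$levels)
  cond <- build_mce_condition(cfg)
  validate_condition(cond)
  cond
}

# Assemble the gene roster and patterns for the mce0/mce1/mce2 family.
build_mce_condition <- function(cfg) {
  C <- as.integer(cfg$n_cells)
  lv <- cfg$levels
  if (!is.numeric(lv["high"]) || lv[["high"]] <= 0)
    stop("invalid levels: high optimal level must be positive")
  n_lineage <- if (cfg$model == "mce2") C + 1L else C
  n_inh <- as.integer(cfg$n_inhibitors)
  n_tfs <- as.integer(cfg$n_tfs)
  n_other <- n_tfs - n_lineage - n_inh
  if (n_other < 0)
    stop("roster inconsistency: fewer TFs (", n_tfs,
         ") than lineage TFs plus inhibitors (", n_lineage + n_inh, ")")

  rows <- list()
  add <- function(kind, class, cells) {
    rows[[length(rows) + 1L]] <<- list(kind = kind, class = class, cells = cells)
  }
  for (c in seq_len(C)) add("activator", "lineage", c)
  if (cfg$model == "mce2") add("activator", "lineage", seq_len(C))
  for (i in seq_len(n_other)) add("activator", "other-activator", integer(0))
  for (i in seq_len(n_inh)) add("inhibitor", "inhibitor", integer(0))
  for (i in seq_len(cfg$n_terminal_all)) add("terminal", "terminal-all", seq_len(C))
  for (c in seq_len(C))
    for (i in seq_len(cfg$n_specific_per_cell))
      add("terminal", "terminal-specific", c)
  if (cfg$model == "mce1") {
    half <- cfg$n_terminal2 %/% 2L
    lo <- seq_len(ceiling(C / 2))
    hi <- setdiff(seq_len(C), lo)
    for (i in seq_len(half)) add("terminal", "terminal-2", lo)
    for (i in seq_len(cfg$n_terminal2 - half)) add("terminal", "terminal-2", hi)
  }

  G <- length(rows)
  genes <- data.frame(
    gene_id = seq_len(G),
    name = paste0("g", seq_len(G)),
    kind = vapply(rows, `[[`, "", "kind"),
    pattern_class = vapply(rows, `[[`, "", "class"),
    stringsAsFactors = FALSE
  )
  genes$cells <- I(lapply(rows, `[[`, "cells"))

  initial <- matrix(0, nrow = G, ncol = C,
                    dimnames = list(genes$name, paste0("cell", seq_len(C))))
  for (g in which(genes$pattern_class == "lineage"))
    initial[g, genes$cells[[g]]] <- lv[["low"]]

  term <- which(genes$kind == "terminal")
  optimal <- matrix(lv[["off"]], nrow = length(term), ncol = C,
                    dimnames = list(genes$name[term], paste0("cell", seq_len(C))))
  for (i in seq_along(term))
    optimal[i, genes$cells[[term[i]]]] <- lv[["high"]]

  structure(
    list(name = cfg$name, n_cells = C, genes = genes,
         initial_pattern = initial, optimal_pattern = optimal,
         promoter_length = as.integer(cfg$promoter_length),
         n_inhibitors = n_inh,
         chromatin_enabled = isTRUE(cfg$chromatin_enabled),
         levels = lv),
    class = "grn_condition")
}

#' @export
print.grn_condition <- function(x, ...) {
  kinds <- table(x$genes$kind)
  cat("grn_condition '", x$name, "': ", nrow(x$genes), " genes (",
      paste(paste0(as.integer(kinds), " ", names(kinds)), collapse = ", "),
      ") in ", x$n_cells, " cells\n", sep = "")
  cat("  promoters ", x$promoter_length, " bp; chromatin ",
      if (x$chromatin_enabled) "enabled" else "disabled",
      "; levels low=", x$levels[["low"]], " high=", x$levels[["high"]], "\n",
      sep = "")
  invisible(x)
}

# Check every structural invariant of a condition; errors name the violated
# invariant.
validate_condition <- function(cond) {
  genes <- cond$genes
  C <- cond$n_cells
  if (!all(genes$kind %in% gene_kinds))
    stop("invariant violated: unknown gene kind")
  if (!all(genes$pattern_class %in% pattern_classes))
    stop("invariant violated: unknown pattern class")
  lin <- which(genes$pattern_class == "lineage")
  if (!all(genes$kind[lin] == "activator"))
    stop("invariant violated: lineage genes must be activator TFs")
  if (length(lin) < C)
    stop("invariant violated: fewer lineage TFs than cells")
  term <- which(genes$kind == "terminal")
  if (length(term) == 0L)
    stop("invariant violated: roster has no terminal genes")
  if (!identical(rownames(cond$optimal_pattern), genes$name[term]))
    stop("invariant violated: optimal pattern must cover exactly the non-TF genes")
  if (ncol(cond$initial_pattern) != C || ncol(cond$optimal_pattern) != C)
    stop("invariant violated: pattern column count must equal n_cells")
  if (nrow(cond$initial_pattern) != nrow(genes))
    stop("invariant violated: initial pattern row count must equal the roster")
  nz <- which(rowSums(cond$initial_pattern != 0) > 0)
  if (!all(genes$pattern_class[nz] == "lineage"))
    stop("invariant violated: initial pattern nonzero for a non-lineage gene")
  per_cell <- colSums(cond$initial_pattern[lin, , drop = FALSE] != 0)
  if (any(per_cell < 1))
    stop("invariant violated: some cell has no lineage TF in the initial pattern")
  invisible(cond)
}

# Convenience accessors used throughout.
tf_ids <- function(cond) which(cond$genes$kind != "terminal")
terminal_ids <- function(cond) which(cond$genes$kind == "terminal")
activator_ids <- function(cond) which(cond$genes$kind == "activator")
inhibitor_ids <- function(cond) which(cond$genes$kind == "inhibitor")
lineage_ids <- function(cond) which(cond$genes$pattern_class == "lineage")
n_genes <- function(cond) nrow(cond$genes)

# Optimal pattern expanded to the full roster (TF rows zero); used by the
# fitness kernel, which only reads the terminal rows.
full_optimal <- function(cond) {
  out <- matrix(0, nrow = n_genes(cond), ncol = cond$n_cells,
                dimnames = list(cond$genes$name, colnames(cond$initial_pattern)))
  out[terminal_ids(cond), ] <- cond$optimal_pattern
  out
}

# Breadth class of each terminal gene: broadly expressed ("all"),
# expressed in a pair of cells ("two-cell"), or cell-specific ("specific").
gene_breadth_class <- function(cond) {
  cls <- cond$genes$pattern_class
  out <- rep(NA_character_, n_genes(cond))
  out[cls == "terminal-all"] <- "all"
  out[cls == "terminal-2"] <- "two-cell"
  out[cls == "terminal-specific"] <- "specific"
  out
}

#' Serialize a condition to a YAML-compatible list (and back)
#'
#' @param cond a `grn_condition`.
#' @return `condition_to_config()`: a plain list; `condition_from_config()`:
#'   a `grn_condition`.
#' @export
condition_to_config <- function(cond) {
  list(
    name = cond$name, n_cells = cond$n_cells,
    genes = lapply(seq_len(n_genes(cond)), function(g) list(
      gene_id = cond$genes$gene_id[g], name = cond$genes$name[g],
      kind = cond$genes$kind[g], pattern_class = cond$genes$pattern_class[g],
      cells = as.integer(cond$genes$cells[[g]]))),
    initial_pattern = apply(cond$initial_pattern, 1, as.numeric, simplify = FALSE),
    optimal_pattern = apply(cond$optimal_pattern, 1, as.numeric, simplify = FALSE),
    promoter_length = cond$promoter_length,
    n_inhibitors = cond$n_inhibitors,
    chromatin_enabled = cond$chromatin_enabled,
    levels = as.list(cond$levels)
  )
}

#' @rdname condition_to_config
#' @param config a list as produced by `condition_to_config()`.
#' @export
condition_from_config <- function(config) {
  G <- length(config$genes)
  genes <- data.frame(
    gene_id = vapply(config$genes, function(g) as.integer(g$gene_id), 0L),
    name = vapply(config$genes, function(g) g$name, ""),
    kind = vapply(config$genes, function(g) g$kind, ""),
    pattern_class = vapply(config$genes, function(g) g$pattern_class, ""),
    stringsAsFactors = FALSE
  )
  genes$cells <- I(lapply(config$genes, function(g) as.integer(unlist(g$cells))))
  C <- as.integer(config$n_cells)
  cellnames <- paste0("cell", seq_len(C))
  initial <- do.call(rbind, lapply(config$initial_pattern, as.numeric))
  dimnames(initial) <- list(names(config$initial_pattern), cellnames)
  optimal <- do.call(rbind, lapply(config$optimal_pattern, as.numeric))
  dimnames(optimal) <- list(names(config$optimal_pattern), cellnames)
  cond <- structure(
    list(name = config$name, n_cells = C, genes = genes,
         initial_pattern = initial, optimal_pattern = optimal,
         promoter_length = as.integer(config$promoter_length),
         n_inhibitors = as.integer(config$n_inhibitors),
         chromatin_enabled = isTRUE(config$chromatin_enabled),
         levels = unlist(config$levels)),
    class = "grn_condition")
  validate_condition(cond)
  cond
}

#' @rdname condition_to_config
#' @param path file path for the YAML serialization.
#' @export
write_condition_yaml <- function(cond, path) {
  yaml::write_yaml(condition_to_config(cond), path)
  invisible(path)
}

#' @rdname condition_to_config
#' @export
read_condition_yaml <- function(path) {
  condition_from_config(yaml::read_yaml(path))
}
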