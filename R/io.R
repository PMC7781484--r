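# File-format plumbing: run directories, tables, networks, matrices.

#' Export an expression trajectory as a long-format table
#'
#' @param expr a `grn_expression`.
#' @param simulation,generation optional identifiers recorded per row.
#' @return data.frame with columns `simulation`, `generation`, `cell`,
#'   `gene`, `t`, `x`.
#' @export
expression_long <- function(expr, simulation = 1L, generation = NA_integer_) {
  d <- dim(expr$x)
  dn <- dimnames(expr$x)
  out <- expand.grid(gene = dn[[1]], cell = dn[[2]], t = seq_len(d[3]) - 1L,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$x <- as.vector(expr$x)
  cbind(simulation = simulation, generation = generation, out)
}

#' Export chromatin accessibility profiles as a long-format table
#'
#' @param expr a `grn_expression` from a chromatin-enabled condition.
#' @param simulation optional identifier recorded per row.
#' @return data.frame with columns `simulation`, `gene`, `cell`, `position`
#'   (0-based) and `phi` (final accessibility).
#' @export
chromatin_long <- function(expr, simulation = 1L) {
  if (is.null(expr$phi))
    stop("expression object has no chromatin profile; ",
         "run a chromatin-enabled condition")
  d <- dim(expr$phi)  # positions x genes x cells
  out <- expand.grid(position = seq_len(d[1]) - 1L,
                     gene = rownames(expr$final),
                     cell = colnames(expr$final),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$phi <- as.vector(expr$phi)
  cbind(simulation = simulation, out[, c("gene", "cell", "position", "phi")])
}

#' Bin knockout phenotypes into fixed-width intervals
#'
#' Summarizes a phenotype table as relative frequencies of phenotype
#' intervals (width 0.5 by default), split by gene breadth class —
#' the bar-chart representation of mutational robustness.
#'
#' @param phenotypes data.frame from [phenotype_table()].
#' @param width bin width in expression units.
#' @return data.frame with `gene_breadth_class`, `bin` (interval label),
#'   `lower`, `n` and `freq` (relative frequency within the class).
#' @export
phenotype_bins <- function(phenotypes, width = 0.5) {
  lo <- floor(min(phenotypes$phenotype) / width) * width
  hi <- ceiling(max(phenotypes$phenotype) / width) * width
  if (hi <= lo) hi <- lo + width
  breaks <- seq(lo, hi, by = width)
  out <- do.call(rbind, lapply(split(phenotypes,
                                     phenotypes$gene_breadth_class),
    function(d) {
      cut_ <- cut(d$phenotype, breaks, right = FALSE, include.lowest = TRUE)
      tab <- table(cut_)
      data.frame(gene_breadth_class = d$gene_breadth_class[1],
                 bin = names(tab), lower = head(breaks, -1),
                 n = as.integer(tab),
                 freq = as.integer(tab) / nrow(d),
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Convert an active network to igraph
#'
#' @param network a `grn_network`.
#' @return an igraph directed graph with node attributes `label`, `is_tf`,
#'   `is_lineage`, `role`.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_adjacency_matrix(network$adjacency,
                                           mode = "directed")
  igraph::V(g)$label <- network$nodes$label
  igraph::V(g)$is_tf <- network$nodes$is_tf
  igraph::V(g)$is_lineage <- network$nodes$is_lineage
  igraph::V(g)$role <- network$nodes$role
  g
}

#' Write / read an active network as edge-list TSV or GraphML
#'
#' @param network a `grn_network`.
#' @param path output file.
#' @return the path, invisibly (writers); for `read_network_edgelist()` a
#'   data.frame of edges.
#' @export
write_network_edgelist <- function(network, path) {
  edges <- which(network$adjacency != 0, arr.ind = TRUE)
  df <- data.frame(source = rownames(network$adjacency)[edges[, 1]],
                   target = colnames(network$adjacency)[edges[, 2]],
                   source_role = network$nodes$role[edges[, 1]],
                   target_role = network$nodes$role[edges[, 2]],
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_edgelist
#' @export
read_network_edgelist <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_network_edgelist
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Write the occupancy matrix in MatrixMarket format with label sidecars
#'
#' @param occupancy sparse matrix from [motif_analysis()].
#' @param path base path; writes `<path>.mtx`, `<path>.rows.txt`,
#'   `<path>.cols.txt`.
#' @return the `.mtx` path, invisibly.
#' @export
write_occupancy_mtx <- function(occupancy, path) {
  mtx <- paste0(path, ".mtx")
  Matrix::writeMM(occupancy, mtx)
  chr0 <- function(x) if (is.null(x)) character(0) else as.character(x)
  writeLines(chr0(rownames(occupancy)), paste0(path, ".rows.txt"))
  writeLines(chr0(colnames(occupancy)), paste0(path, ".cols.txt"))
  invisible(mtx)
}

#' @rdname write_occupancy_mtx
#' @export
read_occupancy_mtx <- function(path) {
  m <- methods::as(Matrix::readMM(paste0(path, ".mtx")), "CsparseMatrix")
  dimnames(m) <- list(readLines(paste0(path, ".rows.txt")),
                      readLines(paste0(path, ".cols.txt")))
  m
}

#' Save an evolutionary run to a directory / load it back
#'
#' The directory holds plain-text artifacts: the best genome's promoters
#' (FASTA), the PWM set (MEME), the MSE trajectory and final expression
#' (TSV), the site-event table if tracked (TSV), the condition (YAML) and
#' a JSON manifest with all resolved parameters, the seed and per-file
#' checksums. `load_run()` reconstructs a `grn_run` sufficient for
#' perturbation and motif analysis (the full population is not persisted).
#'
#' @param run a `grn_run`.
#' @param dir output directory (created if needed).
#' @return `save_run()`: `dir`, invisibly; `load_run()`: a `grn_run`.
#' @export
save_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_promoters_fasta(run$best, fp("best_promoters.fasta"))
  write_meme(run$pwms, fp("pwms.meme"))
  write.table(data.frame(generation = seq_along(run$mse_mean) - 1L,
                         mean_mse = run$mse_mean, best_mse = run$mse_best),
              fp("mse_trajectory.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  fin <- data.frame(gene = rownames(run$best_final), run$best_final,
                    check.names = FALSE)
  write.table(fin, fp("final_expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(run$site_events))
    write.table(run$site_events, fp("site_events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write_condition_yaml(run$condition, fp("condition.yaml"))
  files <- setdiff(list.files(dir), "manifest.json")
  manifest <- list(
    condition = run$condition$name, seed = run$seed,
    generations = run$generations, converged = run$converged,
    best_mse = run$best_mse,
    parameters = list(
      evo = unclass(run$evo), dyn = unclass(run$dyn),
      tf = run$tfp, levels = as.list(run$condition$levels),
      promoter_length = run$condition$promoter_length,
      chromatin_enabled = run$condition$chromatin_enabled),
    files = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(fp(f)))))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_run
#' @export
load_run <- function(dir) {
  fp <- function(f) file.path(dir, f)
  need <- c("best_promoters.fasta", "pwms.meme", "condition.yaml",
            "manifest.json")
  missing <- need[!file.exists(fp(need))]
  if (length(missing))
    stop("run directory ", dir, " is missing artifact(s): ",
         paste(missing, collapse = ", "))
  manifest <- jsonlite::read_json(fp("manifest.json"))
  condition <- read_condition_yaml(fp("condition.yaml"))
  pwms <- read_meme(fp("pwms.meme"))
  genome <- read_promoters_fasta(fp("best_promoters.fasta"))
  genome <- scan_genome(genome, pwms)
  dynp <- manifest$parameters$dyn
  dyn <- dynamics_params(b = dynp$b, basal_mode = dynp$basal_mode,
                         q_btm = dynp$q_btm, beta = dynp$beta,
                         delta = dynp$delta, T = dynp$T,
                         llr_scale = dynp$llr_scale)
  tfp <- tf_params(condition)
  expr <- run_differentiation(genome, condition, dyn, tfp)
  traj <- read.delim(fp("mse_trajectory.tsv"))
  events <- if (file.exists(fp("site_events.tsv")))
    read.delim(fp("site_events.tsv"), stringsAsFactors = FALSE) else NULL
  structure(list(
    condition = condition, pwms = pwms,
    evo = do.call(evo_params, lapply(manifest$parameters$evo, unlist)),
    dyn = dyn, tfp = tfp,
    best = genome, best_final = expr$final, best_trajectory = expr$x,
    best_mse = manifest$best_mse,
    mse_mean = traj$mean_mse, mse_best = traj$best_mse,
    generations = manifest$generations, converged = manifest$converged,
    site_events = events, seed = manifest$seed), class = "grn_run")
}
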