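# Per-cell active networks, typed induced-subgraph enumeration, Z-scores
# against output-shuffled nulls, orbit naming, and the gene x motif-position
# occupancy matrix.

#' Build the active regulatory network of one cell
#'
#' Nodes are TF genes plus terminal features, with terminal features that
#' share an identical optimal-expression row merged into a single vertex.
#' A directed edge A -> B is present iff (i) A is expressed above `floor`
#' in the cell and (ii) at least one promoter of B's member genes carries a
#' binding site for A. Self-regulation is ignored. Nodes are labelled with
#' cell-relative roles (lineage-this-cell, lineage-other-cell,
#' other-activator, inhibitor, terminal-all, terminal-specific-this/other,
#' terminal-2-this/other).
#'
#' @param genome evolved `grn_genome` with site cache.
#' @param final_expression genes x cells adult pattern.
#' @param cell cell index.
#' @param condition the `grn_condition`.
#' @param floor expression floor for condition (i).
#' @return object of class `grn_network`: list with `nodes` (data.frame:
#'   `node_id`, `label`, `is_tf`, `is_lineage`, `role`, `members`),
#'   `adjacency` (binary matrix) and `cell`.
#' @export
build_active_network <- function(genome, final_expression, cell, condition,
                                 floor = 0) {
  tfs <- tf_ids(condition)
  term <- terminal_ids(condition)
  # merge terminal features with identical optimal rows
  patkey <- apply(condition$optimal_pattern, 1, paste, collapse = ",")
  groups <- split(term, factor(patkey, levels = unique(patkey)))
  members <- c(as.list(tfs), unname(groups))
  n <- length(members)
  is_tf <- c(rep(TRUE, length(tfs)), rep(FALSE, length(groups)))
  is_lineage <- c(condition$genes$pattern_class[tfs] == "lineage",
                  rep(FALSE, length(groups)))
  role <- character(n)
  for (i in seq_len(n)) {
    g1 <- members[[i]][1]
    cls <- condition$genes$pattern_class[g1]
    this <- cell %in% condition$genes$cells[[g1]]
    role[i] <- switch(cls,
      "lineage" = if (this) "lineage-this-cell" else "lineage-other-cell",
      "other-activator" = "other-activator",
      "inhibitor" = "inhibitor",
      "terminal-all" = "terminal-all",
      "terminal-specific" = if (this) "terminal-specific-this" else
        "terminal-specific-other",
      "terminal-2" = if (this) "terminal-2-this" else "terminal-2-other")
  }
  label <- vapply(seq_len(n), function(i) {
    m <- members[[i]]
    if (length(m) == 1L) condition$genes$name[m]
    else paste0(condition$genes$name[m[1]], "+", length(m) - 1L)
  }, "")

  adj <- matrix(0L, n, n, dimnames = list(label, label))
  expressed <- final_expression[tfs, cell] > floor
  for (ti in seq_along(tfs)) {
    if (!expressed[ti]) next
    h <- tfs[ti]
    for (j in seq_len(n)) {
      if (j == ti) next  # self-regulation ignored
      tgt <- members[[j]]
      hit <- any(vapply(tgt, function(g)
        any(genome$sites[[g]]$tf_id == h), TRUE))
      if (hit) adj[ti, j] <- 1L
    }
  }
  nodes <- data.frame(node_id = seq_len(n), label = label, is_tf = is_tf,
                      is_lineage = is_lineage, role = role,
                      stringsAsFactors = FALSE)
  nodes$members <- I(members)
  structure(list(nodes = nodes, adjacency = adj, cell = cell),
            class = "grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  cat("grn_network (cell ", x$cell, "): ", nrow(x$nodes), " nodes, ",
      sum(x$adjacency), " edges\n", sep = "")
  invisible(x)
}

#' Canonical class of a typed digraph
#'
#' Two subgraphs are equivalent when some node ordering makes both their
#' adjacency matrices and their node type sequences (TF vs non-TF) equal.
#' The canonical key is the minimal adjacency bit-encoding over all
#' type-respecting orderings (brute force over at most 120 permutations for
#' sizes up to 5).
#'
#' @param adjacency binary adjacency matrix (size up to 6).
#' @param is_tf logical vector of node types.
#' @return a canonical key string (`"s<k>.t<ntf>.a<bits>"`).
#' @export
canonical_class <- function(adjacency, is_tf) {
  cpp_canonical_key(adjacency_int(adjacency), as.logical(is_tf))
}

adjacency_int <- function(adj) {
  m <- matrix(as.integer(adj != 0), nrow(adj), ncol(adj))
  m
}

# Decode a canonical key back into adjacency + types.
decode_class_key <- function(key) {
  parts <- as.numeric(strsplit(sub("^s", "", gsub("[ta]", "", key)), "\\.")[[1]])
  k <- as.integer(parts[1]); ntf <- as.integer(parts[2]); bits <- parts[3]
  adj <- matrix(0L, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    b <- (i - 1L) * k + (j - 1L)
    if (bits %% 2^(b + 1) >= 2^b) adj[i, j] <- 1L
  }
  list(size = k, n_tf = ntf, adjacency = adj,
       is_tf = c(rep(TRUE, ntf), rep(FALSE, k - ntf)))
}

#' Enumerate retained induced subgraphs of an active network
#'
#' Every weakly connected induced subgraph of the requested sizes is
#' enumerated (ESU algorithm, each subset exactly once) and kept when it
#' passes the retention filter: every TF node has an output edge, every
#' non-lineage TF also has an input edge, at least one lineage TF is
#' present, and at least one non-TF node with an input edge is present.
#' Counts are accumulated per canonical typed class.
#'
#' @param network a `grn_network`.
#' @param sizes subgraph sizes (3 to 5).
#' @return named integer vector of counts per canonical key.
#' @export
enumerate_subgraphs <- function(network, sizes = 3:5) {
  res <- cpp_enumerate_subgraphs(adjacency_int(network$adjacency),
                                 network$nodes$is_tf,
                                 network$nodes$is_lineage,
                                 as.integer(sizes), FALSE)
  setNames(as.integer(res$count), as.character(res$key))
}

# Retained subgraph instances with their nodes in canonical order.
motif_instances <- function(network, sizes = 3:5) {
  res <- cpp_enumerate_subgraphs(adjacency_int(network$adjacency),
                                 network$nodes$is_tf,
                                 network$nodes$is_lineage,
                                 as.integer(sizes), TRUE)
  nodes <- split(res$instance_nodes,
                 rep(seq_along(res$instance_size), res$instance_size))
  list(key = as.character(res$instance_key), nodes = unname(nodes))
}

#' Enumerate all admissible typed subgraph classes of a given size
#'
#' Brute-force inventory of every typed digraph (nodes typed TF or non-TF,
#' non-TF nodes with out-degree 0, no self-loops) admissible under the
#' retention criteria with free lineage designation: every TF node has an
#' output edge, every non-TF node has an input edge, and at least one
#' non-TF node is present. With `connected = FALSE` (default) the graph
#' may be any disjoint union of such pieces — each weakly connected
#' component must carry a regulated non-TF node — which reproduces the
#' full observable class inventory (6 classes at size 3, 75 at size 4);
#' `connected = TRUE` restricts to weakly connected classes (74 at size 4).
#'
#' @param size subgraph size, 2 to 5.
#' @param connected require global weak connectivity?
#' @return character vector of canonical class keys.
#' @export
#' @examples
#' length(enumerate_possible_classes(3))  # 6
enumerate_possible_classes <- function(size, connected = FALSE) {
  if (!size %in% 2:5) stop("size must be between 2 and 5")
  as.character(cpp_possible_classes(as.integer(size), isTRUE(connected)))
}

#' Randomize a set of networks by shuffling edge targets
#'
#' Within each network, the target endpoints of all edges are randomly
#' permuted among the edges (self-loops and duplicate edges are resolved
#' by further local swaps). Every node's out-degree and the global
#' in-degree multiset are preserved exactly; per-node in-degrees are
#' redistributed.
#'
#' @param networks list of `grn_network`.
#' @param max_tries permutation redraws before giving up on a network
#'   (returned unshuffled with a warning).
#' @return list of randomized `grn_network`.
#' @export
shuffle_outputs <- function(networks, max_tries = 50) {
  lapply(networks, function(net) {
    adj <- net$adjacency
    edges <- which(adj != 0, arr.ind = TRUE)
    E <- nrow(edges)
    if (E >= 2) {
      tgt <- shuffled_targets(edges[, 1], edges[, 2], max_tries)
      if (is.null(tgt)) {
        warning("could not shuffle a network without conflicts; ",
                "returning it unchanged")
      } else {
        adj[] <- 0L
        adj[cbind(edges[, 1], tgt)] <- 1L
      }
    }
    net$adjacency <- adj
    net
  })
}

# Random permutation of edge targets with conflict resolution: self-loops
# and duplicate edges are repaired by swapping the offending target with a
# random other edge's target.
shuffled_targets <- function(from, tgt0, max_tries = 50) {
  E <- length(from)
  for (try in seq_len(max_tries)) {
    tgt <- tgt0[sample.int(E)]
    for (pass in 1:200) {
      key <- paste(from, tgt)
      bad <- which(from == tgt | duplicated(key))
      if (!length(bad)) return(tgt)
      for (b in bad) {
        j <- sample.int(E, 1L)
        tmp <- tgt[b]; tgt[b] <- tgt[j]; tgt[j] <- tmp
      }
    }
  }
  NULL
}

#' Z-scores of subgraph classes against randomized networks
#'
#' `z = (N_real - mean(N_random)) / sd(N_random)` with the population
#' (divide-by-n) standard deviation. Classes whose null counts have zero
#' spread get an infinite sentinel and are flagged degenerate.
#'
#' @param real_counts named count vector (pooled over a condition's
#'   networks).
#' @param null_counts list of named count vectors, one per randomized set.
#' @param z_threshold classes at or above this Z are flagged as motifs.
#' @return data.frame: `key`, `size`, `n_real`, `null_mean`, `null_sd`,
#'   `z`, `degenerate`, `is_motif`.
#' @export
motif_zscores <- function(real_counts, null_counts, z_threshold = 2) {
  if (length(null_counts) < 2) stop("need at least 2 randomized sets")
  keys <- sort(unique(c(names(real_counts),
                        unlist(lapply(null_counts, names)))))
  nulls <- vapply(null_counts, function(nc) {
    v <- nc[keys]
    v[is.na(v)] <- 0
    as.numeric(v)
  }, numeric(length(keys)))
  if (length(keys) == 1L) nulls <- matrix(nulls, nrow = 1L)
  nreal <- as.numeric(real_counts[keys])
  nreal[is.na(nreal)] <- 0
  mu <- rowMeans(nulls)
  sdev <- sqrt(rowMeans(nulls^2) - mu^2)  # population sd
  z <- ifelse(sdev > 0, (nreal - mu) / sdev,
              ifelse(nreal > mu, Inf, ifelse(nreal < mu, -Inf, 0)))
  data.frame(key = keys,
             size = as.integer(sub("^s(\\d+)\\..*$", "\\1", keys)),
             n_real = nreal, null_mean = mu, null_sd = sdev, z = z,
             degenerate = sdev == 0,
             is_motif = z >= z_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Named node orbits of a subgraph class
#'
#' Nodes of a motif share a name when a type-respecting automorphism of
#' the motif maps one onto the other. Orbits are named in canonical node
#' order: `p0, p1, ...` for singleton (unique) positions and
#' `set0, set1, ...` for symmetric multi-node positions.
#'
#' @param key canonical class key (from [canonical_class()] or an
#'   enumeration).
#' @return data.frame: `position` (canonical node index), `is_tf`,
#'   `orbit` (orbit id), `name`.
#' @export
#' @examples
#' # feed-forward loop: three unique positions
#' adj <- matrix(0, 3, 3); adj[1, 2] <- adj[1, 3] <- adj[2, 3] <- 1
#' key <- canonical_class(adj, c(TRUE, TRUE, FALSE))
#' position_orbits(key)$name
position_orbits <- function(key) {
  cls <- decode_class_key(key)
  k <- cls$size
  perms <- all_permutations(k)
  orbit <- seq_len(k)
  for (p in seq_len(nrow(perms))) {
    pp <- perms[p, ]
    if (!all(cls$is_tf[pp] == cls$is_tf)) next
    if (!all(cls$adjacency[pp, pp] == cls$adjacency)) next
    # automorphism: union the orbits it connects
    for (i in seq_len(k)) {
      a <- orbit[i]; b <- orbit[pp[i]]
      if (a != b) orbit[orbit == max(a, b)] <- min(a, b)
    }
  }
  uniq <- unique(orbit)
  name <- character(k)
  np <- ns <- 0L
  for (o in uniq) {
    idx <- which(orbit == o)
    if (length(idx) == 1L) {
      name[idx] <- paste0("p", np); np <- np + 1L
    } else {
      name[idx] <- paste0("set", ns); ns <- ns + 1L
    }
  }
  data.frame(position = seq_len(k), is_tf = cls$is_tf,
             orbit = match(orbit, uniq), name = name,
             stringsAsFactors = FALSE)
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Full motif analysis of a set of evolved runs
#'
#' Builds the per-cell active networks of every run, pools retained
#' subgraph counts, compares them with `n_null` output-shuffled network
#' sets, names the positions of every motif (class with `z >=
#' z_threshold`), and assembles the sparse gene x motif-position occupancy
#' matrix: one row per (simulation, cell, gene), one column per named
#' position of a motif, counting how often the gene occupies that position.
#'
#' @param runs list of `grn_run` (one per simulation).
#' @param sizes subgraph sizes.
#' @param n_null number of randomized network sets.
#' @param z_threshold motif threshold on the Z-score.
#' @param floor expression floor for the active-network edges.
#' @return list with `zscores` (see [motif_zscores()]), `motifs` (keys with
#'   `z >= z_threshold`), `networks`, and `occupancy`
#'   (a `Matrix::sparseMatrix` with labelled rows and columns).
#' @export
motif_analysis <- function(runs, sizes = 3:5, n_null = 10, z_threshold = 2,
                           floor = 0) {
  if (inherits(runs, "grn_run")) runs <- list(runs)
  nets <- list()
  net_tag <- list()
  for (si in seq_along(runs)) {
    run <- runs[[si]]
    for (cc in seq_len(run$condition$n_cells)) {
      nets[[length(nets) + 1L]] <-
        build_active_network(run$best, run$best_final, cc, run$condition,
                             floor = floor)
      net_tag[[length(net_tag) + 1L]] <- c(si, cc)
    }
  }
  count_all <- function(networks) {
    tot <- list()
    for (net in networks) {
      cnt <- enumerate_subgraphs(net, sizes)
      for (k in names(cnt)) tot[[k]] <- (tot[[k]] %||% 0L) + cnt[[k]]
    }
    unlist(tot)
  }
  real <- count_all(nets)
  nulls <- lapply(seq_len(n_null), function(i) count_all(shuffle_outputs(nets)))
  zs <- motif_zscores(real, nulls, z_threshold)
  motifs <- zs$key[zs$is_motif]

  orbits <- lapply(motifs, position_orbits)
  names(orbits) <- motifs

  # occupancy: rows = (simulation, cell, gene); cols = motif positions
  cond <- runs[[1]]$condition
  G <- n_genes(cond)
  C <- cond$n_cells
  row_of <- function(si, cc, g) ((si - 1L) * C + (cc - 1L)) * G + g
  col_names <- as.character(unlist(lapply(motifs, function(k)
    paste0(k, ":", unique(orbits[[k]]$name)))))
  col_index <- setNames(seq_along(col_names), col_names)
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  acc <- new.env(parent = emptyenv())
  for (ni in seq_along(nets)) {
    net <- nets[[ni]]
    tag <- net_tag[[ni]]
    inst <- motif_instances(net, sizes)
    keep <- inst$key %in% motifs
    for (q in which(keep)) {
      k <- inst$key[q]
      orb <- orbits[[k]]
      nd <- inst$nodes[[q]]
      for (p in seq_along(nd)) {
        col <- col_index[[paste0(k, ":", orb$name[p])]]
        for (g in net$nodes$members[[nd[p]]]) {
          key <- paste0(row_of(tag[1], tag[2], g), ".", col)
          acc[[key]] <- (if (is.null(acc[[key]])) 0L else acc[[key]]) + 1L
        }
      }
    }
  }
  ks <- ls(acc)
  if (length(ks)) {
    parts <- matrix(as.integer(unlist(strsplit(ks, ".", fixed = TRUE))),
                    ncol = 2, byrow = TRUE)
    ii <- parts[, 1]; jj <- parts[, 2]
    xx <- vapply(ks, function(k) acc[[k]], 0L, USE.NAMES = FALSE)
  }
  row_names <- as.vector(vapply(seq_along(runs), function(si)
    vapply(seq_len(C), function(cc)
      paste0("sim", si, ".cell", cc, ".", cond$genes$name), character(G)),
    matrix("", G, C)))
  occupancy <- Matrix::sparseMatrix(
    i = ii, j = jj, x = xx,
    dims = c(length(runs) * C * G, length(col_names)),
    dimnames = list(row_names, col_names))
  list(zscores = zs, motifs = motifs, orbits = orbits,
       networks = nets, occupancy = occupancy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
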