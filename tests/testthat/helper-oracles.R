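# Independent oracles and fixture builders.  Everything here is written
# from first principles (loops, exhaustive enumeration) and deliberately
# avoids the package's own code paths and igraph.

# Brute-force Benjamini-Hochberg step-up: for ascending p, the adjusted
# value at rank k is min over j >= k of m*p(j)/j, clipped to 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (k in seq_len(m)) {
    adj[k] <- min(1, min(m * sorted[k:m] / (k:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Mean-ratio fold change computed with explicit loops.
oracle_log2fc <- function(values, groups, pseudocount) {
  out <- numeric(nrow(values))
  for (i in seq_len(nrow(values))) {
    ca <- mean(values[i, groups == "cancer"])
    co <- mean(values[i, groups == "control"])
    out[i] <- log2((ca + pseudocount) / (co + pseudocount))
  }
  names(out) <- rownames(values)
  out
}

# Exhaustive DFS: does `node` have a directed path to any sink?
oracle_reaches_sink <- function(edges, node, sinks) {
  if (node %in% sinks) return(TRUE)
  seen <- character(0)
  frontier <- node
  while (length(frontier)) {
    cur <- frontier[[1]]
    frontier <- frontier[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    nxt <- edges$target[edges$source == cur]
    if (any(nxt %in% sinks)) return(TRUE)
    frontier <- c(frontier, setdiff(nxt, seen))
  }
  FALSE
}

# Enumerate ALL simple directed paths from `from` to `to` by recursive
# DFS, then keep the minimum-length ones.  Returns NULL when unreachable,
# otherwise list(L, signs, paths) with paths sorted lexicographically by
# their node-id sequences.
oracle_shortest_paths <- function(edges, from, to) {
  paths <- list()
  recurse <- function(node, visited, sgn) {
    if (node == to) {
      paths[[length(paths) + 1]] <<- list(path = visited, sign = sgn)
      return()
    }
    rows <- which(edges$source == node)
    for (r in rows) {
      nxt <- edges$target[r]
      if (nxt %in% visited) next
      recurse(nxt, c(visited, nxt), sgn * edges$sign[r])
    }
  }
  recurse(from, from, 1L)
  if (!length(paths)) return(NULL)
  lens <- vapply(paths, function(p) length(p$path) - 1L, integer(1))
  keep <- paths[lens == min(lens)]
  keys <- vapply(keep, function(p) paste(p$path, collapse = "\r"),
                 character(1))
  keep <- keep[order(keys)]
  list(L = min(lens),
       signs = vapply(keep, function(p) p$sign, integer(1)),
       paths = lapply(keep, function(p) p$path))
}

oracle_resolve_sign <- function(signs, policy) {
  if (policy == "lexicographic") return(signs[[1]])
  s <- if (policy == "majority") sum(signs) else mean(signs)
  if (s > 0) 1L else if (s < 0) -1L else 0L
}

# Build a migrn object directly from edge tables, bypassing
# trace_upstream's pruning, so oracle tests see exactly the generated
# topology.
make_migrn <- function(gene_edges, target_edges, cell_fate) {
  all_edges <- rbind(gene_edges, target_edges)
  mirna_ids <- unique(target_edges$source)
  nodes <- unique(c(all_edges$source, all_edges$target,
                    cell_fate$gene_id))
  g <- igraph::graph_from_data_frame(
    all_edges[, c("source", "target", "sign", "kind")],
    directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  igraph::V(g)$kind <- ifelse(igraph::V(g)$name %in% mirna_ids,
                              "miRNA", "gene")
  fate <- stats::setNames(cell_fate$fate_class, cell_fate$gene_id)
  igraph::V(g)$fate <- unname(fate[igraph::V(g)$name])
  structure(list(graph = g, cell_fate = cell_fate,
                 diagnostics = list()), class = "migrn")
}

edge_df <- function(source, target, sign,
                    kind = rep("gene_gene", length(source))) {
  data.frame(source = source, target = target, sign = as.integer(sign),
             kind = kind, stringsAsFactors = FALSE)
}

# Random signed digraph over n gene nodes plus a few miRNA sources;
# guaranteed self-loop free, possibly cyclic.
random_signed_graph <- function(n_genes, n_mirnas, density = 0.25,
                                inhibition = 0.4) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  mirnas <- sprintf("m%02d", seq_len(n_mirnas))
  grid <- expand.grid(source = genes, target = genes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, ]
  pick <- runif(nrow(grid)) < density
  ge <- edge_df(grid$source[pick], grid$target[pick],
                ifelse(runif(sum(pick)) < inhibition, -1L, 1L))
  hits <- lapply(mirnas, function(m)
    sample(genes, max(1, rbinom(1, n_genes, 0.3))))
  te <- edge_df(rep(mirnas, lengths(hits)), unlist(hits),
                rep(-1L, sum(lengths(hits))),
                kind = rep("mirna_gene", sum(lengths(hits))))
  n_cf <- max(1, round(n_genes / 3))
  cf <- data.frame(gene_id = sample(genes, n_cf),
                   fate_class = sample(c("proliferation", "apoptosis"),
                                       n_cf, replace = TRUE),
                   stringsAsFactors = FALSE)
  list(gene_edges = ge, target_edges = te, cell_fate = cf,
       mirnas = mirnas, genes = genes)
}

# The worked toy example: mir-5 -(-1)-> Gene1 -(+1)-> Gene*
toy_network <- function() {
  ge <- edge_df("Gene1", "Gene*", 1L)
  te <- edge_df("mir-5", "Gene1", -1L, kind = "mirna_gene")
  cf <- data.frame(gene_id = "Gene*", fate_class = "proliferation",
                   stringsAsFactors = FALSE)
  make_migrn(ge, te, cf)
}

toy_de <- function(log2fc = 2.25) {
  data.frame(feature_id = "mir-5", log2fc = log2fc, p_value = 1e-6,
             fdr = 1e-5, significant = TRUE, untestable = FALSE,
             stringsAsFactors = FALSE)
}

# Write the toy topology as the TSV files the readers consume.
write_toy_fixture_files <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines("Gene1\tGene*\tactivation",
             file.path(dir, "gene_edges.tsv"))
  writeLines("mir-5\tGene1", file.path(dir, "mirna_targets.tsv"))
  writeLines("Gene*\tproliferation", file.path(dir, "cell_fate.tsv"))
  invisible(dir)
}
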