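#' Default vocabulary mapping interaction strings to edge signs
#'
#' Activation-like terms map to +1, inhibition-like terms to -1.  Strings
#' are matched case-insensitively after trimming.
#'
#' @return Named integer vector, names are interaction strings.
#' @export
default_sign_vocabulary <- function() {
  c(activation = 1L, activate = 1L, activates = 1L, promote = 1L,
    promotes = 1L, promotion = 1L, "+1" = 1L, "1" = 1L, "+" = 1L,
    up = 1L, positive = 1L,
    inhibition = -1L, inhibit = -1L, inhibits = -1L, repress = -1L,
    represses = -1L, repression = -1L, "-1" = -1L, "-" = -1L,
    down = -1L, negative = -1L)
}

new_signed_edges <- function(source, target, sign, kind) {
  data.frame(source = as.character(source), target = as.character(target),
             sign = as.integer(sign), kind = as.character(kind),
             stringsAsFactors = FALSE)
}

#' Load a signed edge list from TSV
#'
#' Gene-gene files have three columns `source<TAB>target<TAB>interaction`;
#' the interaction string is mapped to a sign through `vocabulary`.
#' miRNA-target files have two columns `mirna<TAB>gene` (a third column is
#' ignored) and every edge sign is forced to -1: miRNAs are assumed to
#' repress their target genes.
#'
#' Self-loops are dropped with a warning.  Duplicate (source, target)
#' pairs keep the first occurrence; a sign conflict among duplicates is an
#' error under `strict = TRUE` and a logged warning otherwise.  Interaction
#' strings missing from the vocabulary map to `unknown_sign` (default +1,
#' a sign-preserving pass-through) in lenient mode and error in strict
#' mode.
#'
#' @param path TSV file path.
#' @param kind `"gene_gene"` or `"mirna_gene"`.
#' @param vocabulary Named integer vector mapping interaction strings to
#'   +1/-1; see [default_sign_vocabulary()].
#' @param strict If `TRUE`, unmappable interaction strings and sign
#'   conflicts abort with an error listing the offending line numbers.
#' @param unknown_sign Sign assigned to unmappable interaction strings in
#'   lenient mode: `1`, `-1`, or `NA` to drop such rows.
#' @return Data frame of edges with columns `source`, `target`, `sign`,
#'   `kind`, plus a `diagnostics` attribute counting dropped/defaulted
#'   rows.
#' @export
load_edges <- function(path, kind = c("gene_gene", "mirna_gene"),
                       vocabulary = default_sign_vocabulary(),
                       strict = FALSE, unknown_sign = 1L) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop("edge file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(new_signed_edges(character(), character(),
                                              integer(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # tolerate a header row
  first <- tolower(trimws(fields[[1]]))
  has_header <- any(first %in% c("source", "mirna", "regulator", "from"))
  rows <- seq_along(fields)
  if (has_header) rows <- rows[-1]

  min_cols <- if (kind == "gene_gene") 3L else 2L
  src <- tgt <- character(0); sgn <- integer(0)
  bad_lines <- integer(0); unknown_lines <- integer(0)
  names(vocabulary) <- tolower(names(vocabulary))
  for (i in rows) {
    f <- trimws(fields[[i]])
    if (length(f) < min_cols || any(!nzchar(f[1:2]))) {
      bad_lines <- c(bad_lines, i)
      next
    }
    if (kind == "mirna_gene") {
      s <- -1L
    } else {
      key <- tolower(f[3])
      if (key %in% names(vocabulary)) {
        s <- vocabulary[[key]]
      } else {
        unknown_lines <- c(unknown_lines, i)
        if (is.na(unknown_sign)) next
        s <- as.integer(unknown_sign)
      }
    }
    src <- c(src, f[1]); tgt <- c(tgt, f[2]); sgn <- c(sgn, s)
  }
  if (strict && length(unknown_lines))
    stop("unmappable interaction string(s) at line(s): ",
         paste(unknown_lines, collapse = ", "), " in ", path, call. = FALSE)
  if (strict && length(bad_lines))
    stop("malformed row(s) at line(s): ",
         paste(bad_lines, collapse = ", "), " in ", path, call. = FALSE)
  if (length(bad_lines))
    warning(length(bad_lines), " malformed row(s) skipped in ", path,
            " (lines ", paste(bad_lines, collapse = ", "), ")",
            call. = FALSE)

  edges <- new_signed_edges(src, tgt, sgn, kind)
  edges <- resolve_edges(edges, strict = strict)
  attr(edges, "diagnostics") <- list(
    rows_read = length(rows), malformed = length(bad_lines),
    unknown_interaction = length(unknown_lines),
    edges_kept = nrow(edges))
  edges
}

# Drop self-loops and duplicate (source, target) pairs.  Conflicting signs
# among duplicates: error in strict mode, keep-first with a warning
# otherwise.
resolve_edges <- function(edges, strict = FALSE) {
  loops <- edges$source == edges$target
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    conflict <- tapply(edges$sign, key, function(s) length(unique(s)) > 1)
    if (any(conflict)) {
      who <- gsub("\r", " -> ", names(conflict)[conflict])
      if (strict)
        stop("conflicting signs for duplicated edge(s): ",
             paste(who, collapse = "; "), call. = FALSE)
      warning("conflicting signs for duplicated edge(s), keeping first: ",
              paste(who, collapse = "; "), call. = FALSE)
    }
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  rownames(edges) <- NULL
  edges
}

#' Read a cell-fate gene list (TSV or GMT)
#'
#' TSV form: two columns `gene<TAB>fate_class` with fate_class one of
#' proliferation/apoptosis.  GMT form: gene-set lines named
#' `proliferation` and `apoptosis` (set name, description, then genes).
#'
#' @param path File path; GMT is detected by the `.gmt` extension.
#' @return Data frame with columns `gene_id`, `fate_class`.
#' @export
read_cell_fate <- function(path) {
  if (!file.exists(path))
    stop("cell-fate file not found: ", path, call. = FALSE)
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    out <- do.call(rbind, lapply(lines, function(l) {
      f <- trimws(strsplit(l, "\t", fixed = TRUE)[[1]])
      cls <- tolower(f[1])
      if (!cls %in% c("proliferation", "apoptosis"))
        stop("GMT set name must be proliferation or apoptosis, got: ",
             f[1], call. = FALSE)
      genes <- f[-(1:2)]
      genes <- genes[nzchar(genes)]
      data.frame(gene_id = genes, fate_class = cls,
                 stringsAsFactors = FALSE)
    }))
  } else {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (tolower(df[1, 2]) %in% c("fate_class", "class", "fate"))
      df <- df[-1, , drop = FALSE]
    out <- data.frame(gene_id = as.character(df[[1]]),
                      fate_class = tolower(as.character(df[[2]])),
                      stringsAsFactors = FALSE)
  }
  bad <- setdiff(unique(out$fate_class), c("proliferation", "apoptosis"))
  if (length(bad))
    stop("unknown fate class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(out$gene_id))
    stop("duplicated gene id(s) in cell-fate list", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Back-trace the regulatory network upstream of the cell-fate genes
#'
#' Starting from the designated cell-fate (proliferation/apoptosis) sink
#' genes, keeps exactly those nodes that can reach at least one sink along
#' directed edges (reverse breadth-first reachability), and returns the
#' vertex-induced subgraph.  Cycles are permitted and retained.  Cell-fate
#' genes absent from the edge universe are kept as isolated annotated
#' nodes with a warning.
#'
#' @param edges Data frame of gene-gene edges from [load_edges()].
#' @param cell_fate Data frame from [read_cell_fate()].
#' @param max_depth Optional cap on the back-trace depth (edges); default
#'   unlimited.
#' @return A `migrn` object: a signed directed graph whose nodes all reach
#'   a cell-fate gene.
#' @export
trace_upstream <- function(edges, cell_fate, max_depth = Inf) {
  if (!nrow(cell_fate))
    stop("cell-fate gene set must be non-empty", call. = FALSE)
  if (nrow(edges) && any(edges$kind != "gene_gene"))
    stop("trace_upstream expects gene_gene edges only", call. = FALSE)

  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "sign", "kind")],
    directed = TRUE,
    vertices = data.frame(
      name = union(unique(c(edges$source, edges$target)),
                   cell_fate$gene_id),
      stringsAsFactors = FALSE))
  missing <- setdiff(cell_fate$gene_id,
                     unique(c(edges$source, edges$target)))
  if (length(missing))
    warning(length(missing), " cell-fate gene(s) absent from the edge ",
            "universe, kept isolated: ",
            paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)

  d <- igraph::distances(g, to = cell_fate$gene_id, mode = "out")
  mins <- apply(d, 1, min)
  reach <- is.finite(mins) & mins <= max_depth
  keep <- rownames(d)[reach]
  sub <- igraph::induced_subgraph(g, keep)

  fate <- stats::setNames(cell_fate$fate_class, cell_fate$gene_id)
  igraph::V(sub)$kind <- "gene"
  igraph::V(sub)$fate <- unname(fate[igraph::V(sub)$name])

  structure(list(graph = sub,
                 cell_fate = cell_fate,
                 diagnostics = list(
                   genes_in_universe = igraph::vcount(g),
                   genes_traced = igraph::vcount(sub),
                   edges_traced = igraph::ecount(sub),
                   cell_fate_missing = length(missing),
                   mirnas_attached = 0L,
                   mirnas_skipped = 0L)),
            class = "migrn")
}

#' Attach significantly differentially expressed miRNAs to the network
#'
#' For each miRNA flagged significant in `de`, adds a miRNA node and a
#' repressive (sign -1) edge to each of its targets already present in the
#' gene network.  miRNAs with no in-network target are omitted and counted
#' in the diagnostics.  Non-significant miRNAs are never attached.
#'
#' @param net A `migrn` from [trace_upstream()].
#' @param targets Data frame of miRNA-target edges (`kind == "mirna_gene"`)
#'   from [load_edges()].
#' @param de Data frame with columns `feature_id` and `significant`
#'   (typically from [differential_expression()] on the miRNA matrix).
#' @return The `migrn` with miRNA nodes and edges added.
#' @export
attach_mirnas <- function(net, targets, de) {
  stopifnot(inherits(net, "migrn"))
  if (nrow(targets) && any(targets$kind != "mirna_gene"))
    stop("`targets` must all have kind mirna_gene", call. = FALSE)
  sig <- de$feature_id[de$significant]
  if (!length(sig)) {
    warning("no significant miRNAs to attach; gene network returned ",
            "unchanged", call. = FALSE)
    return(net)
  }
  genes <- igraph::V(net$graph)$name
  hits <- targets[targets$source %in% sig & targets$target %in% genes, ,
                  drop = FALSE]
  attach_ids <- unique(hits$source)
  skipped <- setdiff(sig, attach_ids)

  g <- net$graph
  if (length(attach_ids)) {
    g <- igraph::add_vertices(g, length(attach_ids), name = attach_ids,
                              kind = "miRNA", fate = NA_character_)
    idx <- match(c(rbind(hits$source, hits$target)),
                 igraph::V(g)$name)
    g <- igraph::add_edges(g, idx, sign = -1L, kind = "mirna_gene")
  }
  net$graph <- g
  net$diagnostics$mirnas_attached <- length(attach_ids)
  net$diagnostics$mirnas_skipped <- length(skipped)
  net$diagnostics$mirna_edges <- nrow(hits)
  net
}

#' @export
print.migrn <- function(x, ...) {
  k <- igraph::V(x$graph)$kind
  cat(sprintf(
    "miGRN: %d gene nodes, %d miRNA nodes, %d edges, %d cell-fate sinks\n",
    sum(k == "gene"), sum(k == "miRNA"), igraph::ecount(x$graph),
    sum(igraph::V(x$graph)$name %in% x$cell_fate$gene_id)))
  invisible(x)
}

#' Cell-fate genes actually present in a miGRN
#' @param net A `migrn`.
#' @return Data frame `gene_id`, `fate_class`, restricted to graph nodes.
#' @export
network_cell_fate <- function(net) {
  cf <- net$cell_fate
  cf[cf$gene_id %in% igraph::V(net$graph)$name, , drop = FALSE]
}

#' miRNA node ids of a miGRN
#' @param net A `migrn`.
#' @return Character vector.
#' @export
network_mirnas <- function(net) {
  igraph::V(net$graph)$name[igraph::V(net$graph)$kind == "miRNA"]
}

#' Export a miGRN as edge-list and node-annotation TSVs
#'
#' @param net A `migrn`.
#' @param edge_path,node_path Output TSV paths.
#' @return Invisibly, a list with the two data frames written.
#' @export
write_network <- function(net, edge_path, node_path) {
  el <- igraph::as_data_frame(net$graph, what = "edges")
  edges <- data.frame(source = el$from, target = el$to,
                      sign = el$sign, kind = el$kind,
                      stringsAsFactors = FALSE)
  nodes <- data.frame(node = igraph::V(net$graph)$name,
                      kind = igraph::V(net$graph)$kind,
                      fate_class = ifelse(is.na(igraph::V(net$graph)$fate),
                                          "none", igraph::V(net$graph)$fate),
                      stringsAsFactors = FALSE)
  write_tsv(edges, edge_path)
  write_tsv(nodes, node_path)
  invisible(list(edges = edges, nodes = nodes))
}

#' Rebuild a miGRN from exported edge and node TSVs
#'
#' Round-trip counterpart of [write_network()].
#'
#' @param edge_path,node_path TSV paths written by [write_network()].
#' @param cell_fate Optional cell-fate data frame; reconstructed from the
#'   node annotations when omitted.
#' @return A `migrn`.
#' @export
read_network <- function(edge_path, node_path, cell_fate = NULL) {
  edges <- utils::read.delim(edge_path, stringsAsFactors = FALSE)
  nodes <- utils::read.delim(node_path, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "sign", "kind")],
    directed = TRUE, vertices = nodes["node"])
  igraph::V(g)$kind <- nodes$kind
  igraph::V(g)$fate <- ifelse(nodes$fate_class == "none", NA_character_,
                              nodes$fate_class)
  if (is.null(cell_fate)) {
    cf <- nodes[nodes$fate_class != "none", , drop = FALSE]
    cell_fate <- data.frame(gene_id = cf$node, fate_class = cf$fate_class,
                            stringsAsFactors = FALSE)
  }
  structure(list(graph = g, cell_fate = cell_fate,
                 diagnostics = list()), class = "migrn")
}
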