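#' Shortest directed path length from a miRNA to a cell-fate gene
#'
#' Number of edges on a minimum-edge directed path in the unweighted
#' miGRN, by breadth-first search.  Unreachable pairs return `NA` (never 0
#' or a numeric infinity).
#'
#' @param net A `migrn`.
#' @param source miRNA node id.
#' @param target Cell-fate gene node id.
#' @return Positive integer path length, or `NA_integer_` if unreachable.
#' @export
shortest_path_length <- function(net, source, target) {
  stopifnot(inherits(net, "migrn"))
  nm <- igraph::V(net$graph)$name
  if (!source %in% nm) stop("unknown node id: ", source, call. = FALSE)
  if (!target %in% nm) stop("unknown node id: ", target, call. = FALSE)
  d <- igraph::distances(net$graph, v = source, to = target, mode = "out")
  d <- d[1, 1]
  if (!is.finite(d) || d == 0) return(NA_integer_)
  as.integer(d)
}

#' Sign of a regulatory path
#'
#' The product of edge signs (+1 activation, -1 inhibition) along an
#' ordered node sequence that must be a path of the network.
#'
#' @param net A `migrn`.
#' @param path Character vector of node ids, consecutive pairs being
#'   directed edges of the network.
#' @return +1 or -1.
#' @export
path_sign <- function(net, path) {
  stopifnot(inherits(net, "migrn"))
  if (length(path) < 2)
    stop("a path needs at least two nodes", call. = FALSE)
  ids <- match(path, igraph::V(net$graph)$name)
  if (anyNA(ids))
    stop("unknown node id(s): ",
         paste(path[is.na(ids)], collapse = ", "), call. = FALSE)
  eids <- igraph::get_edge_ids(net$graph,
                               c(rbind(ids[-length(ids)], ids[-1])))
  if (any(eids == 0))
    stop("input is not a path of the network (missing edge)",
         call. = FALSE)
  as.integer(prod(igraph::E(net$graph)$sign[eids]))
}

# Enumerate every minimum-length directed path from `source` to `target`
# and return the vector of their sign products, with paths ordered
# lexicographically by node ids.  Enumeration is bounded to the shortest
# length, so it terminates even on cyclic graphs.
shortest_path_signs <- function(net, source, target) {
  asp <- igraph::all_shortest_paths(net$graph, from = source, to = target,
                                    mode = "out")
  paths <- asp$vpaths
  if (!length(paths)) return(integer(0))
  names_mat <- t(vapply(paths, function(p) igraph::V(net$graph)$name[p],
                        character(length(paths[[1]]))))
  ord <- do.call(order, as.data.frame(names_mat, stringsAsFactors = FALSE))
  vapply(paths[ord], function(p)
    path_sign(net, igraph::V(net$graph)$name[p]), integer(1))
}

#' Net regulatory sign of a (miRNA, gene) pair
#'
#' When several minimum-length paths exist they may disagree in sign; the
#' resolution policy is configurable:
#' \describe{
#'   \item{majority}{sign held by the strict majority of shortest paths;
#'     0 on a tie (the pair is then ambiguous and contributes no impact).}
#'   \item{lexicographic}{sign of the path whose node-id sequence is
#'     minimal in lexicographic order.}
#'   \item{all_paths_mean}{sign of the mean of path signs (0 if the mean
#'     is 0).}
#' }
#'
#' @param net A `migrn`.
#' @param source miRNA node id.
#' @param target Gene node id, reachable from `source`.
#' @param policy Sign resolution policy.
#' @return Integer in `{-1, 0, +1}`.
#' @export
pair_sign <- function(net, source, target,
                      policy = c("majority", "lexicographic",
                                 "all_paths_mean")) {
  policy <- match.arg(policy)
  signs <- shortest_path_signs(net, source, target)
  if (!length(signs))
    stop("target ", target, " is unreachable from ", source,
         "; callers must pre-filter unreachable pairs", call. = FALSE)
  resolve_sign(signs, policy)
}

resolve_sign <- function(signs, policy) {
  switch(policy,
         majority = {
           s <- sum(signs)
           if (s > 0) 1L else if (s < 0) -1L else 0L
         },
         lexicographic = signs[[1]],
         all_paths_mean = {
           m <- mean(signs)
           if (m > 0) 1L else if (m < 0) -1L else 0L
         })
}

#' Impact of one miRNA on one cell-fate gene
#'
#' The pair impact is `I = S * log2fc / L`: the miRNA's log2 fold change,
#' signed by the product of regulatory signs along the shortest path and
#' attenuated linearly by the path length.  Returns `NULL` when the gene
#' is unreachable from the miRNA.  Sign-ambiguous pairs (S = 0 under the
#' majority or mean policy) carry I = 0 and are flagged.
#'
#' @param net A `migrn`.
#' @param mirna miRNA node id.
#' @param gene Cell-fate gene node id.
#' @param log2fc The miRNA's log2 fold change (cancer over control).
#' @param policy Sign policy, see [pair_sign()].
#' @return One-row data frame with columns `mirna`, `gene`, `L`, `S`,
#'   `log2fc`, `I`, `ambiguous`, or `NULL` if unreachable.
#' @export
pair_impact <- function(net, mirna, gene, log2fc,
                        policy = c("majority", "lexicographic",
                                   "all_paths_mean")) {
  policy <- match.arg(policy)
  L <- shortest_path_length(net, mirna, gene)
  if (is.na(L)) return(NULL)
  S <- pair_sign(net, mirna, gene, policy)
  data.frame(mirna = mirna, gene = gene, L = L, S = S,
             log2fc = log2fc, I = S * log2fc / L,
             ambiguous = S == 0L, stringsAsFactors = FALSE)
}

#' Pair impact table over all (miRNA, cell-fate gene) pairs
#'
#' Evaluates the pair impact for every attached miRNA against every
#' cell-fate gene of the network.  Unreachable pairs are excluded (they
#' contribute to no sum).  Rows are ordered by miRNA id then gene id, so
#' the table is byte-stable across runs.
#'
#' @param net A `migrn` with miRNAs attached.
#' @param de Differential expression table for the miRNAs, providing
#'   `feature_id` and `log2fc`.
#' @param policy Sign policy, see [pair_sign()].
#' @return Data frame with columns `mirna`, `gene`, `fate_class`, `L`,
#'   `S`, `log2fc`, `I`, `ambiguous`.
#' @export
pair_impacts <- function(net, de,
                         policy = c("majority", "lexicographic",
                                    "all_paths_mean")) {
  stopifnot(inherits(net, "migrn"))
  policy <- match.arg(policy)
  mirnas <- sort(network_mirnas(net))
  cf <- network_cell_fate(net)
  cf <- cf[order(cf$gene_id), , drop = FALSE]
  empty <- data.frame(mirna = character(), gene = character(),
                      fate_class = character(), L = integer(),
                      S = integer(), log2fc = numeric(), I = numeric(),
                      ambiguous = logical(), stringsAsFactors = FALSE)
  if (!length(mirnas) || !nrow(cf)) return(empty)
  lfc <- stats::setNames(de$log2fc, de$feature_id)
  if (any(!mirnas %in% names(lfc)))
    stop("missing log2fc for miRNA(s): ",
         paste(setdiff(mirnas, names(lfc)), collapse = ", "),
         call. = FALSE)

  out <- vector("list", length(mirnas))
  for (k in seq_along(mirnas)) {
    mi <- mirnas[k]
    d <- igraph::distances(net$graph, v = mi, to = cf$gene_id,
                           mode = "out")[1, ]
    reach <- which(is.finite(d) & d > 0)
    if (!length(reach)) next
    rows <- lapply(reach, function(j) {
      g <- cf$gene_id[j]
      S <- resolve_sign(shortest_path_signs(net, mi, g), policy)
      data.frame(mirna = mi, gene = g, fate_class = cf$fate_class[j],
                 L = as.integer(d[j]), S = S, log2fc = unname(lfc[mi]),
                 I = S * unname(lfc[mi]) / d[j], ambiguous = S == 0L,
                 stringsAsFactors = FALSE)
    })
    out[[k]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Total impact received by one cell-fate gene
#'
#' Sum of pair impacts over the gene's upstream miRNAs.  Positive means
#' the gene is promoted by its upstream miRNAs, negative repressed.
#' A gene with no upstream miRNA scores 0 (flagged via attribute
#' `no_upstream`).
#'
#' @param pairs Pair impact table from [pair_impacts()].
#' @param gene Gene id.
#' @return Numeric total.
#' @export
gene_impact <- function(pairs, gene) {
  rows <- pairs$gene == gene
  out <- sum(pairs$I[rows])
  attr(out, "no_upstream") <- !any(rows)
  out
}

#' Total impact exerted by one miRNA
#'
#' Sum of pair impacts over the cell-fate genes the miRNA reaches.
#' A miRNA reaching no cell-fate gene scores 0 (flagged via attribute
#' `no_downstream`).
#'
#' @param pairs Pair impact table from [pair_impacts()].
#' @param mirna miRNA id.
#' @return Numeric total.
#' @export
mirna_impact <- function(pairs, mirna) {
  rows <- pairs$mirna == mirna
  out <- sum(pairs$I[rows])
  attr(out, "no_downstream") <- !any(rows)
  out
}

#' Summarise pair impacts into per-gene and per-miRNA tables
#'
#' Produces the per-gene totals, the per-miRNA totals with class-wise
#' average impacts on proliferation and apoptosis genes, and the
#' critical-miRNA ranking by absolute total impact (ties broken by id).
#' Class averages are reported under two denominators: genes of the class
#' the miRNA actually reaches (`avg_I_*`) and all genes of the class
#' present in the network (`avg_I_*_all`).
#'
#' @param pairs Pair impact table from [pair_impacts()].
#' @param net The `migrn` the pairs were computed on.
#' @return A list of class `impact_summary` with elements `genes` (data
#'   frame `gene`, `fate_class`, `n_upstream`, `I_gene`), `mirnas` (data
#'   frame `mirna`, `log2fc`, `n_reached`, `I_miR`, class averages,
#'   `rank`), and `ranking` (character vector of miRNA ids, strongest
#'   first).
#' @export
impact_summary <- function(pairs, net) {
  stopifnot(inherits(net, "migrn"))
  cf <- network_cell_fate(net)
  cf <- cf[order(cf$gene_id), , drop = FALSE]
  mirnas <- sort(network_mirnas(net))

  genes <- data.frame(
    gene = cf$gene_id, fate_class = cf$fate_class,
    n_upstream = vapply(cf$gene_id,
                        function(g) sum(pairs$gene == g), integer(1)),
    I_gene = vapply(cf$gene_id,
                    function(g) sum(pairs$I[pairs$gene == g]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(genes) <- NULL

  n_class_all <- table(factor(cf$fate_class,
                              levels = c("proliferation", "apoptosis")))
  class_avg <- function(mi, cls, denom_all) {
    rows <- pairs$mirna == mi & pairs$fate_class == cls
    n <- sum(rows)
    denom <- if (denom_all) n_class_all[[cls]] else n
    if (denom == 0) return(NA_real_)
    sum(pairs$I[rows]) / denom
  }
  lfc <- stats::setNames(pairs$log2fc, pairs$mirna)
  mir <- data.frame(
    mirna = mirnas,
    log2fc = vapply(mirnas, function(m)
      if (m %in% names(lfc)) unname(lfc[m]) else NA_real_, numeric(1)),
    n_reached = vapply(mirnas, function(m)
      sum(pairs$mirna == m), integer(1)),
    I_miR = vapply(mirnas, function(m)
      sum(pairs$I[pairs$mirna == m]), numeric(1)),
    avg_I_proliferation = vapply(mirnas, class_avg, numeric(1),
                                 cls = "proliferation", denom_all = FALSE),
    avg_I_apoptosis = vapply(mirnas, class_avg, numeric(1),
                             cls = "apoptosis", denom_all = FALSE),
    avg_I_proliferation_all = vapply(mirnas, class_avg, numeric(1),
                                     cls = "proliferation",
                                     denom_all = TRUE),
    avg_I_apoptosis_all = vapply(mirnas, class_avg, numeric(1),
                                 cls = "apoptosis", denom_all = TRUE),
    stringsAsFactors = FALSE)
  ord <- order(-abs(mir$I_miR), mir$mirna)
  mir$rank <- integer(nrow(mir))
  mir$rank[ord] <- seq_len(nrow(mir))
  mir <- mir[order(mir$rank), , drop = FALSE]
  rownames(mir) <- NULL

  structure(list(genes = genes, mirnas = mir, ranking = mir$mirna),
            class = "impact_summary")
}

#' @export
print.impact_summary <- function(x, ...) {
  cat(sprintf("impact_summary: %d cell-fate genes, %d miRNAs\n",
              nrow(x$genes), nrow(x$mirnas)))
  cat("top miRNAs: ",
      paste(utils::head(x$ranking, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Top-k critical miRNAs
#'
#' miRNAs sorted by absolute total impact `|I_miR|` descending, ties
#' broken lexicographically by id; a "top 50" list containing both up-
#' and down-regulated miRNAs is only produced by an absolute-magnitude
#' key.
#'
#' @param summary An `impact_summary`.
#' @param k Number of miRNAs to return (capped at the number available).
#' @return Character vector of at most `k` miRNA ids.
#' @export
rank_mirnas <- function(summary, k = 50) {
  stopifnot(inherits(summary, "impact_summary"))
  if (!is.numeric(k) || length(k) != 1 || k < 1)
    stop("`k` must be a positive integer", call. = FALSE)
  utils::head(summary$ranking, k)
}
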