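# Deterministic TSV writer: floats serialized with 6 significant digits
# so repeated runs are byte-identical.
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- formatC(signif(out[[j]], 6), format = "g",
                          digits = 6)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

config_defaults <- function() {
  list(mirna = NULL, mrna = NULL, groups = NULL, edges = NULL,
       targets = NULL, cellfate = NULL,
       alpha = 0.05, fc_threshold = 1.5, pseudocount = 1.0,
       method = "welch", policy = "majority", strict = FALSE,
       readjust_cellfate = FALSE, max_depth = Inf, top_k = 50,
       out_dir = ".", seed = 1L)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file holding the input paths and analysis parameters,
#' fills defaults (alpha 0.05, fold-change threshold 1.5, pseudocount 1,
#' Welch test, majority sign policy, top 50), and rejects unknown keys
#' and out-of-range values.  An empty file yields all defaults.
#'
#' @param path YAML file path.
#' @return A validated named list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, raw)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
      "config: alpha must lie in (0, 1)")
  chk(is.numeric(cfg$fc_threshold) && cfg$fc_threshold > 1,
      "config: fc_threshold must exceed 1")
  chk(is.numeric(cfg$pseudocount) && cfg$pseudocount >= 0,
      "config: pseudocount must be nonnegative")
  chk(cfg$method %in% c("welch", "moderated"),
      "config: method must be welch or moderated")
  chk(cfg$policy %in% c("majority", "lexicographic", "all_paths_mean"),
      "config: policy must be majority, lexicographic or all_paths_mean")
  chk(is.numeric(cfg$top_k) && cfg$top_k >= 1,
      "config: top_k must be a positive integer")
  chk(is.numeric(cfg$max_depth) && cfg$max_depth >= 1,
      "config: max_depth must be >= 1 (use .inf for unlimited)")
  chk(is.logical(cfg$strict) || cfg$strict %in% c(0, 1),
      "config: strict must be logical")
  structure(cfg, class = "run_config")
}

# Canonical YAML rendering of a config (keys sorted, defaults filled);
# used both for the round-trip property and the manifest hash.  YAML
# serializes Inf as `.inf` natively, so max_depth needs no special case.
normalize_config <- function(cfg) {
  cfg <- unclass(cfg)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]  # unset paths
  cfg[order(names(cfg))]
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(normalize_config(cfg), tmp)
  unname(tools::md5sum(tmp))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage:", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline: differential expression, network build, impact
#'
#' Executes the three analysis stages in sequence on the inputs named in
#' the config and writes every result table plus a run manifest into
#' `out_dir`:
#' \itemize{
#'   \item `de_mirna.tsv`, `de_mrna.tsv`, `de_cellfate.tsv` — differential
#'     expression tables (the cell-fate table gates the mRNA results to
#'     the cell-fate list, FDR adjusted over all mRNAs unless
#'     `readjust_cellfate`).
#'   \item `network_edges.tsv`, `network_nodes.tsv` — the traced miGRN
#'     with miRNAs attached.
#'   \item `pair_impacts.tsv` — one row per reachable (miRNA, cell-fate
#'     gene) pair: shortest-path length L, path sign S, log2FC, impact I.
#'   \item `gene_impacts.tsv`, `mirna_impacts.tsv` — per-gene and
#'     per-miRNA totals with class-wise averages and ranks.
#'   \item `ranking.json` — the top-k critical miRNAs for machine
#'     consumption.
#'   \item `manifest.json` — package version, normalized config, config
#'     hash, and per-stage diagnostic counts.
#' }
#'
#' @param config A `run_config` from [load_config()], or a named list
#'   accepted by it.
#' @return Invisibly, a list with the in-memory results (`de_mirna`,
#'   `de_cellfate`, `network`, `pairs`, `summary`, `ranking`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    config <- validate_config(utils::modifyList(config_defaults(), config))
  for (key in c("mirna", "mrna", "groups", "edges", "targets", "cellfate"))
    if (is.null(config[[key]]))
      stop("[stage:config] missing required input path: ", key,
           call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logmsg <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message(msg)
    logmsg <<- c(logmsg, msg)
  }

  groups <- stage("io", read_groups(config$groups))
  mirna <- stage("io", read_expression(config$mirna, groups))
  mrna <- stage("io", read_expression(config$mrna, groups))
  cell_fate <- stage("io", read_cell_fate(config$cellfate))

  de_mirna <- stage("de", differential_expression(
    mirna, config$alpha, config$fc_threshold, config$method,
    config$pseudocount))
  de_mrna <- stage("de", differential_expression(
    mrna, config$alpha, config$fc_threshold, config$method,
    config$pseudocount))
  de_cellfate <- stage("de", subset_de(
    de_mrna, cell_fate$gene_id, readjust = isTRUE(config$readjust_cellfate),
    alpha = config$alpha, fc_threshold = config$fc_threshold))
  note("de: %d/%d miRNAs and %d/%d cell-fate genes significant",
       sum(de_mirna$significant), nrow(de_mirna),
       sum(de_cellfate$significant), nrow(de_cellfate))

  edges <- stage("build", load_edges(config$edges, "gene_gene",
                                     strict = isTRUE(config$strict)))
  targets <- stage("build", load_edges(config$targets, "mirna_gene",
                                       strict = isTRUE(config$strict)))
  net <- stage("build", trace_upstream(edges, cell_fate,
                                       max_depth = config$max_depth))
  net <- stage("build", attach_mirnas(net, targets, de_mirna))
  note("build: %d edges read, %d nodes traced, %d miRNAs attached (%d skipped)",
       nrow(edges), net$diagnostics$genes_traced,
       net$diagnostics$mirnas_attached, net$diagnostics$mirnas_skipped)

  pairs <- stage("impact", pair_impacts(net, de_mirna, config$policy))
  summ <- stage("impact", impact_summary(pairs, net))
  ranking <- rank_mirnas(summ, config$top_k)
  note("impact: %d pairs scored, %d ambiguous",
       nrow(pairs), sum(pairs$ambiguous))

  out <- config$out_dir
  write_tsv(de_mirna, file.path(out, "de_mirna.tsv"))
  write_tsv(de_mrna, file.path(out, "de_mrna.tsv"))
  write_tsv(de_cellfate, file.path(out, "de_cellfate.tsv"))
  write_network(net, file.path(out, "network_edges.tsv"),
                file.path(out, "network_nodes.tsv"))
  write_tsv(pairs, file.path(out, "pair_impacts.tsv"))
  write_tsv(summ$genes, file.path(out, "gene_impacts.tsv"))
  write_tsv(summ$mirnas, file.path(out, "mirna_impacts.tsv"))
  jsonlite::write_json(
    list(top_k = config$top_k, ranking = ranking),
    file.path(out, "ranking.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  manifest <- list(
    package = "mignet",
    version = as.character(utils::packageVersion("mignet")),
    config = normalize_config(config),
    config_hash = config_hash(config),
    counts = list(
      mirnas_tested = nrow(de_mirna),
      mirnas_significant = sum(de_mirna$significant),
      cellfate_significant = sum(de_cellfate$significant),
      edges_read = nrow(edges),
      nodes_traced = net$diagnostics$genes_traced,
      mirnas_attached = net$diagnostics$mirnas_attached,
      mirnas_skipped = net$diagnostics$mirnas_skipped,
      pairs_scored = nrow(pairs),
      pairs_ambiguous = sum(pairs$ambiguous)),
    log = logmsg)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(de_mirna = de_mirna, de_mrna = de_mrna,
                 de_cellfate = de_cellfate, network = net, pairs = pairs,
                 summary = summ, ranking = ranking, manifest = manifest))
}
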