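# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards: no global RNG state leaks out.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic miGRN benchmark world
#'
#' Describes a layered signed regulatory graph (genes arranged in layers,
#' edges only from layer t to layer t+1, the final layer being the
#' cell-fate genes), a set of miRNAs with repressive target edges, and a
#' group-structured expression design with planted fold changes.  All
#' randomness flows from the single integer `seed`.
#'
#' @param n_genes Total number of genes, including the cell-fate layer.
#' @param n_layers Number of gene layers; the last layer is the cell-fate
#'   set.  With `n_layers = 1` the miRNAs hit cell-fate genes directly.
#' @param n_mirnas Number of miRNAs.
#' @param n_cellfate Number of cell-fate genes (last layer).
#' @param prolif_fraction Fraction of cell-fate genes labelled
#'   proliferation (the rest apoptosis); default 0.776 mirrors a curated
#'   97 proliferation / 28 apoptosis split.
#' @param edge_density Probability of each possible layer-(t, t+1) edge;
#'   every gene additionally keeps at least one outgoing edge so the
#'   graph stays connected to the sinks.
#' @param inhibition_fraction Probability that a gene-gene edge is
#'   inhibitory (sign -1).
#' @param planted_drivers Data frame with columns `mirna` (1-based miRNA
#'   index) and `log2fc` (planted log2 fold change), or `NULL` for none.
#' @param driver_target_fraction Fraction of first-layer genes each
#'   planted driver targets (default 0.3).
#' @param targets_per_mirna Number of target genes per background miRNA,
#'   sampled uniformly across all layers.
#' @param background_log2fc_max Background miRNAs receive a true log2
#'   fold change drawn uniformly from
#'   `[-background_log2fc_max, background_log2fc_max]`; set 0 for a pure
#'   null.
#' @param noise_sd Standard deviation of per-sample noise on the log2
#'   scale.
#' @param n_cancer,n_control Samples per group.
#' @param cyclic If `TRUE`, adds sparse back-edges (layer t+1 to t) to
#'   exercise cycle handling.
#' @param seed Integer seed; identical specs generate byte-identical
#'   outputs.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 40, n_layers = 3, n_mirnas = 15,
                           n_cellfate = 12, prolif_fraction = 97 / 125,
                           edge_density = 0.3, inhibition_fraction = 0.3,
                           planted_drivers = NULL,
                           driver_target_fraction = 0.3,
                           targets_per_mirna = 3,
                           background_log2fc_max = 0.5,
                           noise_sd = 0.5, n_cancer = 20, n_control = 20,
                           cyclic = FALSE, seed = 1) {
  spec <- list(n_genes = as.integer(n_genes),
               n_layers = as.integer(n_layers),
               n_mirnas = as.integer(n_mirnas),
               n_cellfate = as.integer(n_cellfate),
               prolif_fraction = prolif_fraction,
               edge_density = edge_density,
               inhibition_fraction = inhibition_fraction,
               planted_drivers = planted_drivers,
               driver_target_fraction = driver_target_fraction,
               targets_per_mirna = as.integer(targets_per_mirna),
               background_log2fc_max = background_log2fc_max,
               noise_sd = noise_sd,
               n_cancer = as.integer(n_cancer),
               n_control = as.integer(n_control),
               cyclic = isTRUE(cyclic),
               seed = as.integer(seed))
  with(spec, {
    if (n_genes < 1 || n_mirnas < 1 || n_layers < 1 || n_cellfate < 1)
      stop("counts must be positive", call. = FALSE)
    if (n_cellfate > n_genes)
      stop("n_cellfate cannot exceed n_genes", call. = FALSE)
    if (n_layers > 1 && n_genes == n_cellfate)
      stop("n_layers > 1 needs upstream genes (n_genes > n_cellfate)",
           call. = FALSE)
    if (n_layers > 1 && n_genes - n_cellfate < n_layers - 1)
      stop("too few upstream genes for ", n_layers - 1,
           " upstream layer(s)", call. = FALSE)
    if (edge_density <= 0 || edge_density > 1)
      stop("edge_density must lie in (0, 1]", call. = FALSE)
    if (inhibition_fraction < 0 || inhibition_fraction > 1)
      stop("inhibition_fraction must lie in [0, 1]", call. = FALSE)
    if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
    if (n_cancer < 2 || n_control < 2)
      stop("need >=2 samples per group", call. = FALSE)
  })
  if (!is.null(spec$planted_drivers)) {
    pd <- spec$planted_drivers
    if (!is.data.frame(pd) || !all(c("mirna", "log2fc") %in% names(pd)))
      stop("planted_drivers needs columns `mirna` (index) and `log2fc`",
           call. = FALSE)
    if (any(pd$mirna < 1 | pd$mirna > spec$n_mirnas))
      stop("planted driver index out of range", call. = FALSE)
    if (anyDuplicated(pd$mirna))
      stop("duplicated planted driver index", call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate the synthetic regulatory network and miRNA target map
#'
#' Genes are arranged in `n_layers` layers with edges only from each layer
#' to the next (plus sparse back-edges when `cyclic`); the final layer is
#' the cell-fate sink set, split into proliferation and apoptosis classes.
#' Each edge is inhibitory with probability `inhibition_fraction`.
#' Background miRNAs target uniformly sampled genes; planted drivers
#' target a fixed fraction of first-layer genes so their signal must
#' traverse the full depth of the graph.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `edges` (gene-gene signed edge data frame),
#'   `targets` (miRNA-target edge data frame, all signs -1), `cell_fate`
#'   (data frame `gene_id`, `fate_class`), `mirna_ids`, `layers` (list of
#'   gene-id vectors), and `truth` (planted driver table).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    gene_ids <- sprintf("G%03d", seq_len(spec$n_genes))
    mirna_ids <- sprintf("mir-%02d", seq_len(spec$n_mirnas))

    n_up <- spec$n_genes - spec$n_cellfate
    if (spec$n_layers == 1) {
      layers <- list(gene_ids)
    } else {
      sizes <- rep(n_up %/% (spec$n_layers - 1), spec$n_layers - 1)
      extra <- n_up %% (spec$n_layers - 1)
      if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      bounds <- cumsum(c(0L, sizes))
      layers <- lapply(seq_len(spec$n_layers - 1), function(t)
        gene_ids[(bounds[t] + 1):bounds[t + 1]])
      layers <- c(layers, list(gene_ids[(n_up + 1):spec$n_genes]))
    }
    cf_ids <- layers[[spec$n_layers]]
    n_prolif <- max(1L, round(spec$prolif_fraction * spec$n_cellfate))
    n_prolif <- min(n_prolif, spec$n_cellfate)
    cell_fate <- data.frame(
      gene_id = cf_ids,
      fate_class = c(rep("proliferation", n_prolif),
                     rep("apoptosis", spec$n_cellfate - n_prolif)),
      stringsAsFactors = FALSE)

    src <- tgt <- character(0)
    if (spec$n_layers > 1) {
      for (t in seq_len(spec$n_layers - 1)) {
        a <- layers[[t]]; b <- layers[[t + 1]]
        grid <- expand.grid(s = a, g = b, stringsAsFactors = FALSE)
        pick <- stats::runif(nrow(grid)) < spec$edge_density
        # guarantee every upstream gene keeps a route to the sinks
        for (s in a) {
          rows <- which(grid$s == s)
          if (!any(pick[rows]))
            pick[rows[sample.int(length(rows), 1)]] <- TRUE
        }
        src <- c(src, grid$s[pick]); tgt <- c(tgt, grid$g[pick])
        if (spec$cyclic) {
          back <- stats::runif(nrow(grid)) < spec$edge_density / 5
          src <- c(src, grid$g[back]); tgt <- c(tgt, grid$s[back])
        }
      }
    }
    sgn <- ifelse(stats::runif(length(src)) < spec$inhibition_fraction,
                  -1L, 1L)
    edges <- new_signed_edges(src, tgt, sgn, rep("gene_gene", length(src)))
    edges <- resolve_edges(edges)

    drivers <- spec$planted_drivers
    driver_idx <- if (is.null(drivers)) integer(0) else drivers$mirna
    t_src <- t_tgt <- character(0)
    first_layer <- layers[[1]]
    for (m in seq_len(spec$n_mirnas)) {
      if (m %in% driver_idx) {
        n_hit <- max(1L, round(spec$driver_target_fraction *
                                 length(first_layer)))
        hits <- sample(first_layer, n_hit)
      } else {
        hits <- sample(gene_ids, min(spec$targets_per_mirna,
                                     length(gene_ids)))
      }
      t_src <- c(t_src, rep(mirna_ids[m], length(hits)))
      t_tgt <- c(t_tgt, hits)
    }
    targets <- new_signed_edges(t_src, t_tgt, rep(-1L, length(t_src)),
                                rep("mirna_gene", length(t_src)))

    truth <- if (is.null(drivers)) {
      data.frame(mirna = character(), log2fc = numeric(),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(mirna = mirna_ids[drivers$mirna],
                 log2fc = drivers$log2fc, stringsAsFactors = FALSE)
    }
    list(edges = edges, targets = targets, cell_fate = cell_fate,
         mirna_ids = mirna_ids, gene_ids = gene_ids, layers = layers,
         truth = truth)
  })
}

#' Generate group-structured expression matrices for a synthetic network
#'
#' Baseline abundances are log-normal (per-feature log2 baseline drawn
#' from N(6, 1)).  Planted driver miRNAs have their cancer-group mean
#' multiplied by `2^log2fc`; background miRNAs receive a uniform true
#' log2 fold change bounded by `background_log2fc_max`.  Genes directly
#' targeted by a planted driver are shifted in the cancer group by
#' `-log2fc / 2` (repression, attenuated), so cell-fate gene differential
#' expression is also exercised.  Per-sample noise is N(0, `noise_sd`) on
#' the log2 scale.
#'
#' @param spec A [synthetic_spec()].
#' @param network Output of [generate_network()] on the same spec.
#' @return A list with `mirna` and `mrna` [expression_matrix()] objects,
#'   `groups` (named character vector), and `true_log2fc` (named vector
#'   of planted miRNA effects).
#' @export
generate_expression <- function(spec, network) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed + 1L, {
    n <- spec$n_cancer + spec$n_control
    sample_ids <- c(sprintf("T%02d", seq_len(spec$n_cancer)),
                    sprintf("N%02d", seq_len(spec$n_control)))
    groups <- stats::setNames(c(rep("cancer", spec$n_cancer),
                                rep("control", spec$n_control)),
                              sample_ids)
    is_cancer <- groups == "cancer"

    effect <- stats::runif(spec$n_mirnas, -spec$background_log2fc_max,
                           spec$background_log2fc_max)
    names(effect) <- network$mirna_ids
    if (nrow(network$truth))
      effect[network$truth$mirna] <- network$truth$log2fc

    sim_matrix <- function(ids, eff) {
      base <- stats::rnorm(length(ids), mean = 6, sd = 1)
      logx <- outer(base, rep(0, n), `+`) +
        outer(eff, as.numeric(is_cancer)) +
        matrix(stats::rnorm(length(ids) * n, 0, spec$noise_sd),
               nrow = length(ids))
      m <- 2^logx
      dimnames(m) <- list(ids, sample_ids)
      m
    }
    mirna_m <- sim_matrix(network$mirna_ids, unname(effect))

    gene_eff <- stats::setNames(rep(0, length(network$gene_ids)),
                                network$gene_ids)
    if (nrow(network$truth)) {
      for (r in seq_len(nrow(network$truth))) {
        hit <- network$targets$target[
          network$targets$source == network$truth$mirna[r]]
        gene_eff[hit] <- gene_eff[hit] - network$truth$log2fc[r] / 2
      }
    }
    mrna_m <- sim_matrix(network$gene_ids, unname(gene_eff))

    list(mirna = expression_matrix(mirna_m, groups),
         mrna = expression_matrix(mrna_m, groups),
         groups = groups,
         true_log2fc = effect)
  })
}

#' Write a complete synthetic input set to disk
#'
#' Emits the four pipeline inputs in exactly the formats the readers
#' consume — miRNA and mRNA expression TSVs, a groups TSV, a gene-gene
#' edge TSV, a miRNA-target TSV and a cell-fate TSV — plus a ground-truth
#' YAML recording the planted drivers.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
simulate_migrn <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  net <- generate_network(spec)
  ex <- generate_expression(spec, net)

  paths <- list(
    mirna_expression = file.path(out_dir, "mirna_expression.tsv"),
    mrna_expression = file.path(out_dir, "mrna_expression.tsv"),
    groups = file.path(out_dir, "groups.tsv"),
    gene_edges = file.path(out_dir, "gene_edges.tsv"),
    mirna_targets = file.path(out_dir, "mirna_targets.tsv"),
    cell_fate = file.path(out_dir, "cell_fate.tsv"),
    truth = file.path(out_dir, "truth.yaml"))

  write_expression_tsv(ex$mirna, paths$mirna_expression)
  write_expression_tsv(ex$mrna, paths$mrna_expression)
  utils::write.table(
    data.frame(sample_id = names(ex$groups), group = unname(ex$groups)),
    paths$groups, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  write_tsv(data.frame(source = net$edges$source,
                       target = net$edges$target,
                       interaction = ifelse(net$edges$sign > 0,
                                            "activation", "inhibition")),
            paths$gene_edges)
  write_tsv(data.frame(mirna = net$targets$source,
                       gene = net$targets$target), paths$mirna_targets)
  utils::write.table(net$cell_fate, paths$cell_fate, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(seed = spec$seed,
                        planted_drivers = if (nrow(net$truth))
                          lapply(seq_len(nrow(net$truth)), function(i)
                            list(mirna = net$truth$mirna[i],
                                 log2fc = net$truth$log2fc[i]))
                        else list(),
                        true_log2fc = as.list(ex$true_log2fc)),
                   paths$truth)
  invisible(paths)
}

write_expression_tsv <- function(expr, path) {
  df <- data.frame(feature_id = rownames(expr$values),
                   expr$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
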