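#' Pipeline configuration
#'
#' Collects input paths and stage thresholds for [run_pipeline()]. Inputs
#' are either file paths (counts + conditions required; annotation, hub
#' gene list and Ct table optional) or, when `simulate` is a [sim_config()],
#' generated in-memory by the synthetic-data module.
#'
#' @param outdir Output directory (created if missing).
#' @param counts,conditions,annotation,gene_list,ct_table Input file paths
#'   (TSV / GMT); ignored when `simulate` is given, except `gene_list`.
#' @param simulate Optional [sim_config()]: generate all inputs instead of
#'   reading them.
#' @param fc_hi,fc_lo,max_fdr DE selection thresholds.
#' @param enrich_min_term_size Minimum term size for enrichment.
#' @param network_mode,network_cutoff Edge rule for [build_network()].
#' @param n_network_genes When no `gene_list` is given, the top DE genes
#'   (by p-value) used for the network stage (study scale: 72).
#' @param calibrator qPCR calibrator condition.
#' @param seed Seed recorded in the manifest (the generators use the seed in
#'   `simulate`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, counts = NULL, conditions = NULL,
                            annotation = NULL, gene_list = NULL,
                            ct_table = NULL, simulate = NULL,
                            fc_hi = 2, fc_lo = 0.5, max_fdr = 0.05,
                            enrich_min_term_size = 2,
                            network_mode = "abs_r", network_cutoff = 0.95,
                            n_network_genes = 72, calibrator = "F",
                            seed = 1) {
  if (is.null(simulate) && (is.null(counts) || is.null(conditions))) {
    stop("either 'simulate' or both 'counts' and 'conditions' are required")
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  stopifnot(fc_hi > 0, fc_lo > 0, fc_lo < fc_hi,
            max_fdr > 0, max_fdr <= 1, n_network_genes >= 2)
  structure(list(outdir = outdir, counts = counts, conditions = conditions,
                 annotation = annotation, gene_list = gene_list,
                 ct_table = ct_table, simulate = simulate,
                 fc_hi = fc_hi, fc_lo = fc_lo, max_fdr = max_fdr,
                 enrich_min_term_size = enrich_min_term_size,
                 network_mode = network_mode,
                 network_cutoff = network_cutoff,
                 n_network_genes = n_network_genes,
                 calibrator = calibrator, seed = as.integer(seed)),
            class = "pipeline_config")
}

# internal: run one stage; on error, abort naming the stage and leave a
# FAILED marker next to any partial outputs
run_stage <- function(name, outdir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", name,
                       conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the analysis pipeline end to end
#'
#' Stages, in order: load or simulate inputs; differential expression
#' ([run_de()] + [filter_de()]); direction-split enrichment; per-condition
#' co-expression networks on the selected gene panel; degree/k-core and the
#' dif-k-core ranking; optional qPCR ddCt and concordance. Every stage's
#' table is persisted as TSV under `config$outdir`, and a JSON manifest
#' records thresholds, the seed, per-stage row counts and md5 checksums of
#' all outputs — rerunning with the same config reproduces the checksums.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with the in-memory results (`de`, `de_selected`,
#'   `enrichment`, `graphs`, `kcore_table`, `qpcr`, `concordance`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(outdir, "FAILED"))
  counts_n <- 0L

  inputs <- run_stage("load", outdir, {
    if (!is.null(config$simulate)) {
      sim <- simulate_counts(config$simulate)
      ann <- simulate_annotations(rownames(sim$cm$counts), sim$truth,
                                  config$simulate)
      sim$truth$enriched_terms <- attr(ann, "enriched_terms")
      ct <- simulate_qpcr(names(sim$truth$de_genes),
                          unname(sim$truth$de_genes),
                          seed = config$simulate$seed + 2000L)
      list(cm = sim$cm, ann = ann, ct = ct, truth = sim$truth)
    } else {
      cm <- count_matrix(read_counts(config$counts),
                         read_conditions(config$conditions))
      ann <- if (!is.null(config$annotation)) {
        if (!file.exists(config$annotation)) {
          stop("annotation file not found: ", config$annotation)
        }
        read_gmt(config$annotation)
      }
      ct <- if (!is.null(config$ct_table)) read_ct_table(config$ct_table)
      list(cm = cm, ann = ann, ct = ct, truth = NULL)
    }
  })
  counts_n <- nrow(inputs$cm$counts)

  de <- run_stage("de", outdir, {
    res <- run_de(inputs$cm, config$fc_hi, config$fc_lo, config$max_fdr)
    write_tsv(res, file.path(outdir, "de_results.tsv"))
    sel <- filter_de(res, config$fc_hi, config$fc_lo, config$max_fdr)
    write_tsv(sel$table, file.path(outdir, "de_selected.tsv"))
    list(res = res, sel = sel)
  })

  enr <- if (!is.null(inputs$ann)) run_stage("enrichment", outdir, {
    universe <- intersect(rownames(inputs$cm$counts),
                          unique(unlist(inputs$ann$sets)))
    de_tab <- de$sel$table[de$sel$table$gene %in% universe, , drop = FALSE]
    e <- enrich_by_direction(de_tab, universe, inputs$ann,
                             config$enrich_min_term_size)
    write_tsv(e$up, file.path(outdir, "enrichment_up.tsv"))
    write_tsv(e$down, file.path(outdir, "enrichment_down.tsv"))
    e
  })

  net <- run_stage("network", outdir, {
    panel <- if (!is.null(config$gene_list)) {
      if (is.character(config$gene_list) && length(config$gene_list) == 1L &&
          file.exists(config$gene_list)) {
        readLines(config$gene_list, warn = FALSE)
      } else {
        as.character(config$gene_list)
      }
    } else {
      sel <- de$sel$table
      sel$gene[order(sel$p_value)][seq_len(min(config$n_network_genes,
                                               nrow(sel)))]
    }
    panel <- intersect(panel, rownames(inputs$cm$counts))
    if (length(panel) < 2) stop("network gene panel has fewer than 2 genes")
    sf <- size_factors(inputs$cm)
    expr <- normalize_expression(inputs$cm, sf)
    graphs <- lapply(unique(inputs$cm$conditions), function(cond) {
      cols <- names(inputs$cm$conditions)[inputs$cm$conditions == cond]
      co <- suppressWarnings(
        pairwise_correlation(expr[, cols, drop = FALSE], genes = panel))
      g <- build_network(co, condition = cond, mode = config$network_mode,
                         cutoff = config$network_cutoff)
      write_edges(g, file.path(outdir, sprintf("edges_%s.tsv", cond)))
      g
    })
    names(graphs) <- unique(inputs$cm$conditions)
    graphs
  })

  kcore_tab <- run_stage("kcore", outdir, {
    labels <- names(net)
    ref <- if ("F" %in% labels) "F" else labels[1]
    other <- setdiff(labels, ref)[1]
    tab <- dif_kcore(net[[ref]], net[[other]], de$res)
    write_tsv(tab, file.path(outdir, "kcore_table.tsv"))
    tab
  })

  qp <- if (!is.null(inputs$ct)) run_stage("qpcr", outdir, {
    rec <- delta_delta_ct(inputs$ct, calibrator = config$calibrator)
    write_tsv(rec, file.path(outdir, "qpcr_table.tsv"))
    conc <- qpcr_concordance(rec, de$res)
    list(records = rec, concordance = conc)
  })

  manifest <- run_stage("manifest", outdir, {
    outputs <- list.files(outdir, pattern = "\\.tsv$")
    man <- list(
      package_version = as.character(utils::packageVersion("difcore")),
      seed = config$seed,
      thresholds = list(fc_hi = config$fc_hi, fc_lo = config$fc_lo,
                        max_fdr = config$max_fdr,
                        network_mode = config$network_mode,
                        network_cutoff = config$network_cutoff),
      rows = list(genes = counts_n, de_selected = de$sel$n_total,
                  de_up = de$sel$n_up, de_down = de$sel$n_down,
                  kcore = nrow(kcore_tab)),
      checksums = as.list(tools::md5sum(file.path(outdir, outputs))) |>
        stats::setNames(outputs))
    jsonlite::write_json(man, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    man
  })

  invisible(list(de = de$res, de_selected = de$sel, enrichment = enr,
                 graphs = net, kcore_table = kcore_tab, qpcr = qp,
                 truth = inputs$truth, manifest = manifest))
}
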