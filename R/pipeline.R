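# Top-level pipeline: inference with all three methods, structural
# comparison, enrichment, reference comparison, manifest.

pipeline_defaults <- function() {
  list(expression = NULL, probe_mapping = NULL, gene_sets = NULL,
       references = NULL, out_dir = NULL,
       copula = TRUE, alpha = 0.05, B = 50L, epsilon = 0.15,
       n_null_c3net = 100000L, n_null_aracne = 100000L,
       R_degree = 1000L, R_overlap = 1000L,
       step = 25L, window_alpha = 0.05, min_size = 2L, seed = 1L)
}

# Format numbers at 6 significant digits for report tables.
write_report <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full inference-and-comparison pipeline
#'
#' Reads an expression matrix (optionally summarizing probes and
#' applying the copula transform), infers C3Net, BC3Net and
#' ARACNE-style networks, and writes to the output directory: the 3
#' networks (TSV + SIF), a global summary table, the pairwise
#' edge-overlap table, GPEA and degree-centrality pathway tables per
#' network (when a gene-set collection is supplied), reference-overlap
#' reports and sliding-window degree-correlation profiles per
#' reference network (when references are supplied), and a YAML run
#' manifest echoing the configuration, package version, per-stage
#' counts and durations, and every seed and threshold used.
#'
#' @param config named list, or path to a YAML file with the same
#'   keys.  Required: `expression` (TSV path), `out_dir`.  Optional:
#'   `probe_mapping`, `gene_sets` (GMT path), `references` (named list
#'   of edge-list TSV paths), `copula`, `alpha`, `B`, `epsilon`,
#'   `n_null_c3net`, `n_null_aracne`, `R_degree`, `R_overlap`, `step`,
#'   `window_alpha`, `min_size`, `seed`.  Unknown keys are rejected.
#' @return the run manifest, invisibly (also written to
#'   `out_dir/manifest.yaml`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$expression) || is.null(cfg$out_dir))
    stop("config must provide 'expression' and 'out_dir'")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "migrn",
                   version = as.character(utils::packageVersion("migrn")),
                   config = cfg[!vapply(cfg, is.null, TRUE)],
                   stages = list())
  t_stage <- function(name, f) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(f(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- c(list(seconds = round(proc.time()[["elapsed"]] - t0, 3)),
                                  attr(out, "manifest_info"))
    out
  }
  info <- function(x, ...) { attr(x, "manifest_info") <- list(...); x }

  expr <- t_stage("read_expression", function() {
    e <- read_expression(cfg$expression)
    if (!is.null(cfg$probe_mapping))
      e <- summarize_probes_median(e, read_probe_mapping(cfg$probe_mapping))
    if (isTRUE(cfg$copula)) e <- copula_transform(e)
    info(e, n_genes = nrow(e), n_samples = ncol(e))
  })

  seeds <- derive_seeds(cfg$seed, 8L)
  nets <- list()
  nets$c3net <- t_stage("c3net", function() {
    g <- c3net(expr, alpha = cfg$alpha, n_null = cfg$n_null_c3net,
               seed = seeds[1L])
    info(g, n_edges = igraph::gsize(g), mi_threshold = g$mi_threshold,
         seed = seeds[1L])
  })
  nets$bc3net <- t_stage("bc3net", function() {
    g <- bc3net(expr, B = cfg$B, alpha_c3net = cfg$alpha,
                alpha_binomial = cfg$alpha, n_null = cfg$n_null_c3net,
                seed = seeds[2L])
    info(g, n_edges = igraph::gsize(g), B = cfg$B, seed = seeds[2L])
  })
  nets$aracne <- t_stage("aracne", function() {
    g <- aracne(expr, epsilon = cfg$epsilon, alpha = cfg$alpha,
                n_null = cfg$n_null_aracne, seed = seeds[3L])
    info(g, n_edges = igraph::gsize(g), mi_threshold = g$mi_threshold,
         epsilon = cfg$epsilon, seed = seeds[3L])
  })
  for (nm in names(nets)) {
    write_network(nets[[nm]], file.path(cfg$out_dir, paste0(nm, ".tsv")), "tsv")
    write_network(nets[[nm]], file.path(cfg$out_dir, paste0(nm, ".sif")), "sif")
  }

  t_stage("global_summary", function() {
    gs <- do.call(rbind, lapply(nets, global_summary))
    gs <- cbind(network = names(nets), gs)
    write_report(gs, file.path(cfg$out_dir, "global_summary.tsv"))
    info(gs)
  })
  t_stage("edge_overlap", function() {
    ov <- edge_overlap_table(nets)
    df <- data.frame(network = rownames(ov$shared), ov$shared,
                     check.names = FALSE)
    pf <- data.frame(network = rownames(ov$pct), ov$pct, check.names = FALSE)
    write_report(df, file.path(cfg$out_dir, "edge_overlap_counts.tsv"))
    write_report(pf, file.path(cfg$out_dir, "edge_overlap_pct.tsv"))
    info(ov)
  })

  if (!is.null(cfg$gene_sets)) {
    sets <- read_gmt(cfg$gene_sets)
    for (nm in names(nets)) {
      local({
        nm <- nm
        t_stage(paste0("gpea_", nm), function() {
          res <- gpea(nets[[nm]], sets, min_size = cfg$min_size)
          write_report(res, file.path(cfg$out_dir, paste0("gpea_", nm, ".tsv")))
          info(res, n_terms = nrow(res),
               n_significant = sum(res$q <= 0.05))
        })
        t_stage(paste0("degtest_", nm), function() {
          res <- degree_pathway_test(nets[[nm]], sets, R = cfg$R_degree,
                                     seed = seeds[4L])
          write_report(res, file.path(cfg$out_dir, paste0("degtest_", nm, ".tsv")))
          info(res, R = cfg$R_degree, seed = seeds[4L])
        })
      })
    }
  }

  if (!is.null(cfg$references)) {
    for (ref_nm in names(cfg$references)) {
      ref <- read_network(cfg$references[[ref_nm]], "tsv")
      local({
        ref_nm <- ref_nm; ref <- ref
        t_stage(paste0("refcompare_", ref_nm), function() {
          rows <- lapply(names(nets), function(nm) {
            rep_row <- shared_edge_overlap(nets[[nm]], ref)
            rep_row$p <- overlap_significance(nets[[nm]], ref,
                                              R = cfg$R_overlap,
                                              seed = seeds[5L])
            cbind(network = nm, rep_row, R = cfg$R_overlap)
          })
          res <- do.call(rbind, rows)
          write_report(res, file.path(cfg$out_dir,
                                      paste0("refcompare_", ref_nm, ".tsv")))
          info(res, R = cfg$R_overlap, seed = seeds[5L])
        })
        t_stage(paste0("windowcorr_", ref_nm), function() {
          rows <- lapply(names(nets), function(nm) {
            cbind(network = nm,
                  window_degree_correlation(nets[[nm]], ref, step = cfg$step,
                                            alpha = cfg$window_alpha))
          })
          res <- do.call(rbind, rows)
          write_report(res, file.path(cfg$out_dir,
                                      paste0("windowcorr_", ref_nm, ".tsv")))
          info(res)
        })
      })
    }
  }

  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  invisible(manifest)
}
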