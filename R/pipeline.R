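#' Read a pipeline run configuration
#'
#' YAML with the keys used by [run_full()] / [run_stage()]: `out_dir`,
#' `seed`, `inputs` (paths: `expr` or `coexpr`, `promoters`, `pwm`,
#' `annotations`, `obo`, optional `population`, `ct`, `segregation`,
#' `alignment`, `anchors`), `queries` (named lists of query gene ids),
#' `thresholds` (`r_min`, `p_max`, `top_k`, `motif_p_max`,
#' `enrichment_q_max`), `strand_policy`, `background`, `keywords`.
#'
#' @param path Path to a YAML file.
#' @return A validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' Validate (and default-fill) a pipeline configuration
#'
#' @param cfg A config list.
#' @return The completed config.
#' @export
validate_run_config <- function(cfg) {
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$thresholds <- utils::modifyList(
    list(r_min = 0.7, p_max = 0.05, top_k = 20000L, motif_p_max = 1e-4,
         enrichment_q_max = 0.05),
    cfg$thresholds %||% list())
  th <- cfg$thresholds
  for (nm in c("r_min", "p_max", "motif_p_max", "enrichment_q_max")) {
    if (!(th[[nm]] > 0 && th[[nm]] <= 1)) {
      stop("threshold '", nm, "' must lie in (0, 1]")
    }
  }
  cfg$strand_policy <- cfg$strand_policy %||% "both"
  cfg$background <- cfg$background %||% "from-input"
  cfg$keywords <- cfg$keywords %||% "root"
  cfg$out_dir <- cfg$out_dir %||% "arfnet_out"
  cfg
}

.require_inputs <- function(cfg, keys) {
  for (k in keys) {
    p <- cfg$inputs[[k]]
    if (is.null(p)) stop("config is missing required input '", k, "'")
    if (!file.exists(p)) stop("input '", k, "' not found: ", p)
  }
  invisible(TRUE)
}

.manifest_entry <- function(stage, inputs, params, outputs) {
  list(stage = stage,
       inputs = as.list(tools::md5sum(unlist(inputs))),
       params = params,
       outputs = as.list(tools::md5sum(unlist(outputs))))
}

#' Run the full target-inference and map-building workflow
#'
#' Executes, per configured query set, the stage order co-expression
#' filter -> promoter motif scan -> motif filter -> enrichment map ->
#' keyword node count, writes every intermediate as a file under
#' `out_dir`, and writes the cross-map comparison table when two or more
#' query sets are configured. A manifest (stage, parameter, input/output
#' checksums) makes reruns verifiable: identical inputs and seed give
#' identical output hashes.
#'
#' @param cfg A config list (see [read_run_config()]).
#' @return A `pipeline_run`: list with `maps` (per query set), `comparison`
#'   (or NULL), `manifest`, and `out_dir`.
#' @export
run_full <- function(cfg) {
  cfg <- validate_run_config(cfg)
  .require_inputs(cfg, c(if (is.null(cfg$inputs$coexpr)) "expr" else "coexpr",
                         "promoters", "pwm", "annotations", "obo"))
  if (is.null(cfg$queries) || !length(cfg$queries)) {
    stop("config must define at least one query set under 'queries'")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$thresholds
  promoters <- read_fasta(cfg$inputs$promoters)
  pwms <- read_pwm(cfg$inputs$pwm)
  annotations <- read_annotation_table(cfg$inputs$annotations)
  dag <- read_obo(cfg$inputs$obo)
  population <- if (!is.null(cfg$inputs$population)) {
    gene_set("population", readLines(cfg$inputs$population))
  } else NULL
  source <- if (!is.null(cfg$inputs$coexpr)) {
    read.delim(cfg$inputs$coexpr, stringsAsFactors = FALSE)
  } else {
    .read_expr_matrix(cfg$inputs$expr)
  }
  manifest <- list()
  maps <- list()
  for (lbl in names(cfg$queries)) {
    queries <- unlist(cfg$queries[[lbl]])
    coex <- coexpression_filter(source, queries, r_min = th$r_min,
                                p_max = th$p_max, top_k = th$top_k)
    scanned <- promoters[promoters$id %in% coex$genes, , drop = FALSE]
    hits <- scan_promoters(scanned, pwms, background = cfg$background,
                           p_max = th$motif_p_max,
                           strand_policy = cfg$strand_policy)
    targets <- filter_by_motif(coex, hits, scanned_ids = scanned$id)
    net <- build_map(targets, annotations, dag, population = population,
                     q_max = th$enrichment_q_max)
    net$label <- lbl
    maps[[lbl]] <- net
    hp <- file.path(cfg$out_dir, paste0(lbl, "_hits.tsv"))
    tp <- file.path(cfg$out_dir, paste0(lbl, "_targets.tsv"))
    ep <- file.path(cfg$out_dir, paste0(lbl, "_enrichment.tsv"))
    gp <- file.path(cfg$out_dir, paste0(lbl, "_map.graphml"))
    sp <- file.path(cfg$out_dir, paste0(lbl, "_map.sif"))
    write.table(hits, hp, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(targets$provenance, tp, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(net$results, ep, sep = "\t", quote = FALSE, row.names = FALSE)
    write_network(net, gp, "GraphML")
    write_network(net, sp, "SIF")
    manifest[[lbl]] <- .manifest_entry(
      paste0("map:", lbl), cfg$inputs,
      c(th, list(queries = queries, strand_policy = cfg$strand_policy)),
      list(hp, tp, ep, gp, sp))
  }
  comparison <- NULL
  if (length(maps) >= 2L) {
    comparison <- compare_maps(maps, keywords = cfg$keywords)
    cp <- file.path(cfg$out_dir, "comparison.tsv")
    write.table(comparison, cp, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$comparison <- .manifest_entry("compare", cfg$inputs,
                                           list(keywords = cfg$keywords),
                                           list(cp))
  }
  mp <- file.path(cfg$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  structure(list(maps = maps, comparison = comparison, manifest = manifest,
                 out_dir = cfg$out_dir),
            class = "pipeline_run")
}

.read_expr_matrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' Run a single pipeline stage in isolation
#'
#' @param name One of `"simulate"`, `"mine-go"`, `"cluster-tf"`,
#'   `"infer-targets"`, `"enrich"`, `"compare"`, `"qpcr"`,
#'   `"segregation"`.
#' @param cfg A config list (see [read_run_config()]); each stage reads
#'   only the inputs it needs and writes its outputs under `out_dir`.
#' @return Stage-specific result, invisibly where the result is a file set.
#' @export
run_stage <- function(name, cfg) {
  cfg <- validate_run_config(cfg)
  stages <- c("simulate", "mine-go", "cluster-tf", "infer-targets", "enrich",
              "compare", "qpcr", "segregation")
  if (!name %in% stages) {
    stop("unknown stage '", name, "'; available stages: ",
         paste(stages, collapse = ", "))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(name,
    "simulate" = {
      args <- cfg$simulation %||% list()
      args$seed <- cfg$seed
      spec <- do.call(simulation_spec, args)
      simulate_dataset(spec, cfg$out_dir)
    },
    "mine-go" = {
      .require_inputs(cfg, "annotations")
      tab <- read_annotation_table(cfg$inputs$annotations)
      a <- keyword_filter(tab, cfg$keywords_a %||% "transcription factor")
      b <- keyword_filter(tab, cfg$keywords_b %||% "root")
      both <- intersect_gene_sets(a, b)
      export_gene_report(list(a, b, both), cfg$out_dir)
      invisible(list(a = a, b = b, intersection = both))
    },
    "cluster-tf" = {
      .require_inputs(cfg, "alignment")
      aln <- read_fasta(cfg$inputs$alignment)
      tree <- bootstrap_support(aln, replicates = cfg$bootstrap %||% 100L,
                                seed = cfg$seed)
      ape::write.tree(tree, file.path(cfg$out_dir, "tree.nwk"))
      groups <- NULL
      if (!is.null(cfg$inputs$anchors)) {
        an <- read.delim(cfg$inputs$anchors, stringsAsFactors = FALSE)
        anchors <- setNames(an$family, an$gene_id)
        groups <- extract_family_groups(tree, anchors)
        export_gene_report(groups, cfg$out_dir, prefix = "family_")
      }
      invisible(list(tree = tree, groups = groups))
    },
    "infer-targets" = , "enrich" = , "compare" = {
      run <- run_full(cfg)
      invisible(run)
    },
    "qpcr" = {
      .require_inputs(cfg, "ct")
      ct <- read.delim(cfg$inputs$ct, stringsAsFactors = FALSE)
      res <- delta_delta_ct(ct, cfg$target %||% "NtARF7",
                            cfg$reference %||% "L25",
                            cfg$calibrator %||% "EV2")
      res$significant <- res$p < 0.05
      write.table(res, file.path(cfg$out_dir, "rfc.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      res
    },
    "segregation" = {
      .require_inputs(cfg, "segregation")
      counts <- read.delim(cfg$inputs$segregation, stringsAsFactors = FALSE)
      res <- segregation_analysis(counts, alpha = cfg$alpha %||% 0.05)
      write.table(res, file.path(cfg$out_dir, "segregation_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      res
    })
}
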