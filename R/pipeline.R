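#' Default pipeline configuration
#'
#' One flat key-value set holding every threshold of the analysis, each
#' defaulting to its conventional value, so a standard run needs no
#' overrides: fold-change and p cuts for DEG calling, the 0.4 interaction
#' confidence filter, the hub score cut of 12, the module-detection knobs
#' (degree cutoff 2, node score cutoff 0.2, k-core 2, max depth 100,
#' module score 5), the enrichment cuts (p 0.05, count 2) and the 50%
#' survival split.
#'
#' @param ... overrides for any config key.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    expr_path = NA_character_, probe_map_path = NA_character_,
    edges_path = NA_character_, gmt_path = NA_character_,
    survival_path = NA_character_,
    logfc_threshold = 1, p_threshold = 0.05,
    min_confidence = 0.4, hcm_threshold = 12,
    degree_cutoff = 2, node_score_cutoff = 0.2, kcore = 2,
    max_depth = 100, min_module_score = 5,
    min_count = 2, enrich_p = 0.05,
    survival_cutoff = 0.5,
    normalization_mode = "default",
    focus_generation = 4,
    seed = 1,
    out_dir = NA_character_)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration file
#'
#' Flat `key = value` text; `#` starts a comment; values are coerced to
#' numeric where possible. Unknown keys are an error.
#'
#' @param path file to read.
#' @return a [pipeline_config()] list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) stop("unparseable config line: ", lines[bad][1])
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- vapply(kv, `[[`, "", 3L)
  vals <- gsub('^"|"$', "", trimws(vals))
  parsed <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(parsed) <- keys
  do.call(pipeline_config, parsed)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full hub-gene discovery pipeline
#'
#' Orchestrates: input loading (with optional probe collapsing) ->
#' per-generation DEG calling -> cross-generation partition -> network
#' construction on the focus generation's DEGs -> hybrid-centrality hub
#' selection -> dense-module detection -> enrichment of DEGs, modules and
#' hubs -> survival screen of the hub genes. Inputs may be given as paths
#' in the config or passed directly as objects (which takes precedence).
#' When `out_dir` is set, every stage table is written there along with a
#' `manifest.json` recording the seed, all thresholds, the normalization
#' mode and per-stage row counts; a failed run moves partial outputs to
#' `<out_dir>/failed/`. Reruns with the same config and inputs reproduce
#' the tables byte for byte.
#'
#' @param config a [pipeline_config()] list or path to a config file.
#' @param expr,edges,gmt,surv_table optional pre-loaded inputs
#'   ([expr_matrix], edge data.frame, [gene_sets], survival data.frame).
#' @return list with `degs` (per generation), `partition`, `network`,
#'   `metrics`, `hubs`, `modules`, `enrichment` (list: degs, modules,
#'   hubs), `survival_screen`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), expr = NULL,
                         edges = NULL, gmt = NULL, surv_table = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  writing <- !is.na(out_dir)
  if (writing) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(x, file) {
    if (!writing) return(invisible(NULL))
    path <- file.path(out_dir, file)
    if (grepl("\\.json$", file)) {
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    } else {
      write_report(x, path, "tsv")
    }
    written <<- c(written, path)
  }
  on_failure <- function(e) {
    if (writing && length(written)) {
      fdir <- file.path(out_dir, "failed")
      dir.create(fdir, showWarnings = FALSE)
      file.rename(written, file.path(fdir, basename(written)))
    }
    stop(e)
  }
  tryCatch({
    counts <- list()

    expr <- stage("io_formats", {
      if (is.null(expr)) {
        if (is.na(config$expr_path)) stop("no expression input supplied")
        expr <- read_expression_table(config$expr_path)
      }
      if (!is.na(config$probe_map_path))
        expr <- collapse_probes(expr,
                                read_probe_annotation(config$probe_map_path))
      expr
    })
    counts$genes <- nrow(expr$values)

    gens <- sort(unique(stats::na.omit(expr$samples$generation)))
    degs <- stage("deg_analysis", {
      out <- lapply(gens, function(g)
        call_degs(test_differential(expr, g),
                  logfc_threshold = config$logfc_threshold,
                  p_threshold = config$p_threshold))
      names(out) <- paste0("gen", gens)
      out
    })
    for (nm in names(degs)) emit(degs[[nm]], paste0("degs_", nm, ".tsv"))
    counts$degs_per_generation <-
      vapply(degs, function(d) sum(d$direction != "none"), 0L)

    part <- stage("deg_analysis", partition_common(degs))
    emit(part[c("up", "down", "both", "per_generation_counts")],
         "partition.json")
    counts$common_degs <- length(part$common)

    focus <- paste0("gen", config$focus_generation)
    if (!focus %in% names(degs)) focus <- names(degs)[1]
    focus_deg <- degs[[focus]]
    deg_genes <- focus_deg$gene[focus_deg$direction != "none"]

    net <- stage("network_analysis", {
      if (is.null(edges)) {
        if (is.na(config$edges_path)) stop("no edges input supplied")
        edges <- read_edge_list(config$edges_path)
      }
      build_network(edges, min_confidence = config$min_confidence,
                    restrict_to = if (length(deg_genes)) deg_genes)
    })
    counts$network <- c(nodes = igraph::vcount(net),
                        edges = igraph::ecount(net))

    metrics <- stage("network_analysis",
                     hybrid_centrality(net,
                                       mode = config$normalization_mode))
    hubs <- stage("network_analysis",
                  select_hubs(metrics, threshold = config$hcm_threshold,
                              deg = focus_deg))
    emit(metrics, "node_metrics.tsv")
    emit(hubs, "hubs.tsv")
    counts$hubs <- nrow(hubs)

    modules <- stage("module_detection",
                     find_modules(net,
                                  degree_cutoff = config$degree_cutoff,
                                  node_score_cutoff =
                                    config$node_score_cutoff,
                                  k_core = config$kcore,
                                  max_depth = config$max_depth,
                                  min_score = config$min_module_score))
    emit(modules, "modules.json")
    counts$modules <- length(modules)

    enr <- stage("enrichment", {
      if (is.null(gmt) && !is.na(config$gmt_path))
        gmt <- read_gmt(config$gmt_path)
      if (is.null(gmt)) NULL else {
        run1 <- function(q) {
          if (!length(q)) return(NULL)
          tally_directions(
            enrich(q, gmt, min_count = config$min_count,
                   p_threshold = config$enrich_p), focus_deg)
        }
        list(degs = run1(deg_genes),
             modules = lapply(modules, function(m) run1(m$nodes)),
             hubs = run1(hubs$gene))
      }
    })
    if (!is.null(enr)) {
      if (!is.null(enr$degs)) emit(enr$degs, "enrichment_degs.tsv")
      if (!is.null(enr$hubs)) emit(enr$hubs, "enrichment_hubs.tsv")
    }

    screen <- stage("survival_analysis", {
      if (is.null(surv_table) && !is.na(config$survival_path))
        surv_table <- read_survival_table(config$survival_path)
      if (is.null(surv_table) || nrow(hubs) == 0) NULL
      else {
        genes <- intersect(hubs$gene, names(surv_table))
        if (!length(genes)) NULL
        else screen_genes(surv_table, genes,
                          cutoff_quantile = config$survival_cutoff)
      }
    })
    if (!is.null(screen)) emit(screen, "survival_screen.tsv")
    counts$survival_screened <- if (is.null(screen)) 0L else nrow(screen)

    manifest <- list(
      package_version = as.character(utils::packageVersion("hubscreen")),
      config = unclass(config)[setdiff(names(config), "out_dir")],
      counts = counts)
    emit(manifest, "manifest.json")

    list(degs = degs, partition = part, network = net, metrics = metrics,
         hubs = hubs, modules = modules, enrichment = enr,
         survival_screen = screen, manifest = manifest)
  }, error = on_failure)
}
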