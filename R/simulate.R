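# Seeded generators with planted ground truth. Each generator scopes its
# RNG use: the caller's .Random.seed is saved and restored, so adding a
# generator call never perturbs other randomness in the session.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulate a log2 expression matrix with planted differential genes
#'
#' Emulates a serial-xenograft design: `n_replicates` shared control
#' samples plus `n_replicates` treated samples per generation. Gene
#' baselines are uniform on (6, 10) log2 units; every value gets i.i.d.
#' Gaussian noise. A fraction `frac_up` of genes is shifted up by
#' `effect_logfc` in treated samples, `frac_down` shifted down; a fraction
#' `frac_discordant` of the planted genes has its shift sign flipped in the
#' last generation, producing cross-generation discordant ("both") calls.
#'
#' @param n_genes number of genes.
#' @param frac_up,frac_down fractions of genes planted up/down
#'   (`frac_up + frac_down <= 1`).
#' @param effect_logfc planted |log2 fold change| (> 1 so planted genes
#'   clear the conventional fold-change threshold).
#' @param noise_sd Gaussian noise standard deviation (log2 units); may be 0
#'   for the exact-recovery limit.
#' @param n_replicates replicates per group (>= 2).
#' @param generations integer vector of generation labels.
#' @param frac_discordant fraction of planted genes flipped in the last
#'   generation.
#' @param seed RNG seed.
#' @return list with `expr` (an [expr_matrix]) and `truth` (list with
#'   matrices `labels` ("up"/"down"/"null", genes x generations) and
#'   `logfc`).
#' @export
simulate_expression <- function(n_genes = 20000, frac_up = 0.025,
                                frac_down = 0.025, effect_logfc = 2,
                                noise_sd = 0.3, n_replicates = 3,
                                generations = c(1, 4, 9),
                                frac_discordant = 0.05, seed = 1) {
  stopifnot(frac_up >= 0, frac_down >= 0, frac_up + frac_down <= 1,
            effect_logfc > 1, noise_sd >= 0, frac_discordant >= 0,
            frac_discordant <= 1)
  if (n_replicates < 2)
    stop("n_replicates must be >= 2 (within-group variance undefined)")
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    n_up <- round(frac_up * n_genes)
    n_down <- round(frac_down * n_genes)
    planted <- sample(genes, n_up + n_down)
    up <- planted[seq_len(n_up)]
    down <- setdiff(planted, up)

    base_fc <- stats::setNames(numeric(n_genes), genes)
    base_fc[up] <- effect_logfc
    base_fc[down] <- -effect_logfc
    n_gen <- length(generations)
    logfc <- matrix(rep(base_fc, n_gen), ncol = n_gen,
                    dimnames = list(genes, paste0("gen", generations)))
    n_disc <- round(frac_discordant * length(planted))
    if (n_disc > 0 && n_gen > 1) {
      disc <- sample(planted, n_disc)
      logfc[disc, n_gen] <- -logfc[disc, n_gen]
    }
    labels <- matrix("null", n_genes, n_gen,
                     dimnames = dimnames(logfc))
    labels[logfc > 0] <- "up"
    labels[logfc < 0] <- "down"

    baseline <- stats::runif(n_genes, 6, 10)
    ctrl_ids <- sprintf("ctrl_%d", seq_len(n_replicates))
    vals <- matrix(baseline, n_genes, n_replicates) +
      matrix(stats::rnorm(n_genes * n_replicates, 0, noise_sd),
             n_genes, n_replicates)
    condition <- rep("control", n_replicates)
    generation <- rep(NA_integer_, n_replicates)
    sample_ids <- ctrl_ids
    for (j in seq_len(n_gen)) {
      trt <- matrix(baseline + logfc[, j], n_genes, n_replicates) +
        matrix(stats::rnorm(n_genes * n_replicates, 0, noise_sd),
               n_genes, n_replicates)
      vals <- cbind(vals, trt)
      condition <- c(condition, rep("treated", n_replicates))
      generation <- c(generation, rep(generations[j], n_replicates))
      sample_ids <- c(sample_ids,
                      sprintf("gen%d_%d", generations[j],
                              seq_len(n_replicates)))
    }
    dimnames(vals) <- list(genes, sample_ids)
    list(expr = expr_matrix(vals, condition, generation),
         truth = list(labels = labels, logfc = logfc,
                      generations = generations))
  })
}

#' Simulate an interaction network with planted modules and a planted hub
#'
#' A sparse background graph (Erdos-Renyi or preferential attachment) is
#' augmented with (i) planted cliques on fresh nodes, each attached to the
#' background by exactly one bridge edge, and (ii) a planted hub: one fresh
#' node wired to `hub_spokes` randomly chosen background nodes. Edge
#' confidences are uniform on `conf_range` (above the conventional 0.4
#' filter); an optional fraction of extra sub-threshold noise edges can be
#' added.
#'
#' @param n_background_nodes background graph order.
#' @param background_model `"erdos_renyi"` or `"preferential_attachment"`.
#' @param p edge probability (Erdos-Renyi).
#' @param pa_m edges per step (preferential attachment).
#' @param clique_sizes integer vector of planted clique sizes (each >= 3);
#'   may be empty.
#' @param hub_spokes spoke count of the planted hub (0 disables).
#' @param conf_range confidence range for retained edges.
#' @param noise_edge_frac fraction (of kept edge count) of extra random
#'   edges with confidence below 0.4.
#' @param node_names optional character vector renaming the nodes
#'   (length >= background + cliques + hub, assigned positionally:
#'   background first, then clique members, then the hub). Used to place
#'   the network on a caller-defined gene symbol space.
#' @param seed RNG seed.
#' @return list with `edges` (data.frame `node_a`, `node_b`, `confidence`)
#'   and `truth` (list with `modules` — list of planted clique node sets —
#'   and `hub` — planted hub id or `NA`).
#' @export
simulate_network <- function(n_background_nodes = 780,
                             background_model = c("erdos_renyi",
                                                  "preferential_attachment"),
                             p = 0.0165, pa_m = 3,
                             clique_sizes = c(8, 6), hub_spokes = 60,
                             conf_range = c(0.5, 0.999),
                             noise_edge_frac = 0, node_names = NULL,
                             seed = 1) {
  background_model <- match.arg(background_model)
  if (length(clique_sizes) && any(clique_sizes < 3))
    stop("clique sizes must be >= 3")
  if (hub_spokes > n_background_nodes)
    stop("hub spokes exceed the background node budget")
  n_total <- n_background_nodes + sum(clique_sizes) + (hub_spokes > 0)
  if (!is.null(node_names)) {
    if (length(node_names) < n_total || anyDuplicated(node_names))
      stop("node_names must supply >= ", n_total, " unique names")
  }
  with_seed(seed, {
    bg <- if (background_model == "erdos_renyi")
      igraph::sample_gnp(n_background_nodes, p)
    else igraph::sample_pa(n_background_nodes, m = pa_m, directed = FALSE)
    bg_names <- sprintf("N%04d", seq_len(n_background_nodes))
    el <- igraph::as_edgelist(bg, names = FALSE)
    edges <- data.frame(node_a = bg_names[el[, 1]],
                        node_b = bg_names[el[, 2]],
                        stringsAsFactors = FALSE)

    modules <- list()
    next_id <- n_background_nodes
    for (s in clique_sizes) {
      members <- sprintf("N%04d", next_id + seq_len(s))
      next_id <- next_id + s
      pairs <- utils::combn(members, 2)
      edges <- rbind(edges,
                     data.frame(node_a = pairs[1, ], node_b = pairs[2, ],
                                stringsAsFactors = FALSE))
      bridge_to <- sample(bg_names, 1)
      edges <- rbind(edges, data.frame(node_a = members[1],
                                       node_b = bridge_to,
                                       stringsAsFactors = FALSE))
      modules <- c(modules, list(members))
    }
    hub <- NA_character_
    if (hub_spokes > 0) {
      hub <- sprintf("N%04d", next_id + 1)
      spokes <- sample(bg_names, hub_spokes)
      edges <- rbind(edges, data.frame(node_a = hub, node_b = spokes,
                                       stringsAsFactors = FALSE))
    }
    edges$confidence <- stats::runif(nrow(edges), conf_range[1],
                                     conf_range[2])
    if (noise_edge_frac > 0) {
      n_noise <- round(noise_edge_frac * nrow(edges))
      all_nodes <- unique(c(edges$node_a, edges$node_b))
      na <- sample(all_nodes, n_noise, replace = TRUE)
      nb <- sample(all_nodes, n_noise, replace = TRUE)
      keep <- na != nb
      edges <- rbind(edges,
                     data.frame(node_a = na[keep], node_b = nb[keep],
                                confidence = stats::runif(sum(keep),
                                                          0.05, 0.39)))
    }
    if (!is.null(node_names)) {
      rename <- stats::setNames(node_names[seq_len(n_total)],
                                sprintf("N%04d", seq_len(n_total)))
      edges$node_a <- unname(rename[edges$node_a])
      edges$node_b <- unname(rename[edges$node_b])
      modules <- lapply(modules, function(m) unname(rename[m]))
      if (!is.na(hub)) hub <- unname(rename[hub])
    }
    edges <- normalize_edge_scores(
      data.frame(node_a = edges$node_a, node_b = edges$node_b,
                 score = edges$confidence), "unit")
    list(edges = edges,
         truth = list(modules = modules, hub = hub))
  })
}

#' Simulate a survival table with planted prognostic genes
#'
#' Each subject receives one standard-normal expression value per gene.
#' Event times are exponential with rate
#' `baseline_rate * prod(hazard_ratio ^ [expr > median])` over the
#' prognostic genes (for a single prognostic gene this is the classic
#' two-group proportional-hazards model); censoring times are independent
#' exponentials with rate `censor_rate` (0 disables censoring).
#'
#' @param n_subjects number of subjects.
#' @param gene_list character vector of gene symbols to tabulate.
#' @param prognostic_genes subset of `gene_list` with a real effect.
#' @param hazard_ratio hazard ratio of the high-expression group (> 0).
#' @param baseline_rate events per month in the low group (> 0).
#' @param censor_rate censoring rate (>= 0).
#' @param seed RNG seed.
#' @return list with `table` (survival data.frame) and `truth` (per-gene
#'   true hazard ratio and the high/low group labels used in generation).
#' @export
simulate_survival <- function(n_subjects = 200, gene_list = paste0("G", 1:5),
                              prognostic_genes = character(),
                              hazard_ratio = 2.5, baseline_rate = 0.02,
                              censor_rate = 0.01, seed = 1) {
  stopifnot(hazard_ratio > 0, baseline_rate > 0, censor_rate >= 0)
  if (!all(prognostic_genes %in% gene_list))
    stop("prognostic_genes must be a subset of gene_list")
  with_seed(seed, {
    for (attempt in 1:10) {
      expr <- matrix(stats::rnorm(n_subjects * length(gene_list)),
                     n_subjects, length(gene_list),
                     dimnames = list(NULL, gene_list))
      groups <- expr > rep(apply(expr, 2, stats::median),
                           each = n_subjects)
      rate <- rep(baseline_rate, n_subjects)
      for (g in prognostic_genes)
        rate <- rate * hazard_ratio^groups[, g]
      t_event <- stats::rexp(n_subjects, rate)
      t_cens <- if (censor_rate > 0)
        stats::rexp(n_subjects, censor_rate) else Inf
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)

      ok <- TRUE
      for (g in prognostic_genes) {
        if (!any(event[groups[, g]] == 1) || !any(event[!groups[, g]] == 1))
          ok <- FALSE
      }
      if (!any(event == 1)) ok <- FALSE
      if (ok) break
      if (attempt == 10)
        stop("could not generate >= 1 event per group in 10 attempts; ",
             "lower censor_rate")
      warning("a group had zero events; regenerating (attempt ",
              attempt, ")")
    }
    tab <- data.frame(subject_id = sprintf("S%04d", seq_len(n_subjects)),
                      time_months = time, event = event,
                      stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(expr))
    hr_true <- stats::setNames(rep(1, length(gene_list)), gene_list)
    hr_true[prognostic_genes] <- hazard_ratio
    list(table = tab,
         truth = list(hazard_ratio = hr_true,
                      groups = ifelse(groups, "high", "low")))
  })
}

#' Simulate a gene-set collection with planted over-representation
#'
#' Null sets are drawn uniformly from the universe. Each enriched set
#' contains exactly `overlap_count` members of `target_query`, with the
#' remainder drawn from outside the query.
#'
#' @param universe character vector of background symbols.
#' @param n_sets total number of sets.
#' @param set_size_range inclusive range of set sizes.
#' @param target_query gene list the enriched sets over-represent.
#' @param n_enriched number of enriched sets (first `n_enriched` ids).
#' @param overlap_count planted overlap of each enriched set with
#'   `target_query`.
#' @param seed RNG seed.
#' @return list with `collection` (a [gene_sets]) and `truth` (character
#'   vector of enriched set ids).
#' @export
simulate_annotation <- function(universe, n_sets = 50,
                                set_size_range = c(10, 40),
                                target_query = character(),
                                n_enriched = 0, overlap_count = 0,
                                seed = 1) {
  stopifnot(n_enriched <= n_sets, set_size_range[1] >= 1)
  if (max(set_size_range) > length(universe))
    stop("universe smaller than the largest requested set")
  if (n_enriched > 0) {
    if (overlap_count > min(set_size_range[1], length(target_query)))
      stop("overlap_count exceeds min(set size, |target_query|)")
    if (!all(target_query %in% universe))
      stop("target_query must lie inside the universe")
  }
  with_seed(seed, {
    ids <- sprintf("SET%03d", seq_len(n_sets))
    size_pool <- seq(set_size_range[1], set_size_range[2])
    sizes <- size_pool[sample.int(length(size_pool), n_sets,
                                  replace = TRUE)]
    off_query <- setdiff(universe, target_query)
    sets <- vector("list", n_sets)
    for (i in seq_len(n_sets)) {
      if (i <= n_enriched) {
        inside <- sample(target_query, overlap_count)
        outside <- sample(off_query, sizes[i] - overlap_count)
        sets[[i]] <- c(inside, outside)
      } else {
        sets[[i]] <- sample(universe, sizes[i])
      }
    }
    names(sets) <- ids
    desc <- stats::setNames(
      ifelse(seq_len(n_sets) <= n_enriched, "planted enriched set",
             "null set"), ids)
    list(collection = gene_sets(sets, desc, universe = universe),
         truth = list(enriched = ids[seq_len(n_enriched)]))
  })
}

#' Simulate a complete input bundle with planted truth
#'
#' Fans one seed out to the four generators (fixed offsets, so adding a
#' generator never perturbs the others) and optionally writes every input
#' file in the package's dialects plus a `truth.json`.
#'
#' @param seed master seed.
#' @param out_dir if non-NULL, write `expression.tsv`, `edges.tsv`,
#'   `sets.gmt`, `survival.tsv` and `truth.json` there.
#' @param n_genes,frac_up,frac_down,effect_logfc,noise_sd expression
#'   parameters (see [simulate_expression()]).
#' @param n_background_nodes,p,clique_sizes,hub_spokes network parameters
#'   (see [simulate_network()]).
#' @param n_subjects,hazard_ratio survival parameters (the planted
#'   prognostic gene is the first simulated hub spoke target, named after
#'   the planted hub).
#' @param n_sets,overlap_count annotation parameters.
#' @return list with elements `expr`, `edges`, `sets`, `survival`, `truth`.
#' @export
simulate_bundle <- function(seed = 1, out_dir = NULL,
                            n_genes = 2000, frac_up = 0.05, frac_down = 0.05,
                            effect_logfc = 2, noise_sd = 0.3,
                            n_background_nodes = 150, p = 0.02,
                            clique_sizes = c(7), hub_spokes = 40,
                            n_subjects = 200, hazard_ratio = 2.5,
                            n_sets = 40, overlap_count = 12) {
  sim_e <- simulate_expression(n_genes = n_genes, frac_up = frac_up,
                               frac_down = frac_down,
                               effect_logfc = effect_logfc,
                               noise_sd = noise_sd, seed = seed + 101L)
  # the interaction network lives on the consistently-planted DEG symbols,
  # mirroring a network built from the called DEG set
  labs <- sim_e$truth$labels
  consistent <- rownames(labs)[labs[, 1] != "null" &
                                 apply(labs, 1, function(r)
                                   length(unique(r)) == 1)]
  n_net <- n_background_nodes + sum(clique_sizes) + (hub_spokes > 0)
  if (length(consistent) < n_net)
    stop("not enough consistently planted DEGs (", length(consistent),
         ") to name ", n_net, " network nodes; raise frac_up/frac_down")
  sim_n <- simulate_network(n_background_nodes = n_background_nodes, p = p,
                            clique_sizes = clique_sizes,
                            hub_spokes = hub_spokes,
                            node_names = consistent, seed = seed + 202L)
  net_nodes <- sort(unique(c(sim_n$edges$node_a, sim_n$edges$node_b)))
  surv_genes <- c(sim_n$truth$hub,
                  setdiff(net_nodes, sim_n$truth$hub)[seq_len(4)])
  sim_s <- simulate_survival(n_subjects = n_subjects,
                             gene_list = surv_genes,
                             prognostic_genes = sim_n$truth$hub,
                             hazard_ratio = hazard_ratio,
                             seed = seed + 303L)
  # annotation over the expression universe, enriched for planted up-genes
  up_genes <- rownames(sim_e$truth$labels)[sim_e$truth$labels[, 1] == "up"]
  sim_a <- simulate_annotation(universe = rownames(sim_e$expr$values),
                               n_sets = n_sets,
                               set_size_range = c(max(15, overlap_count),
                                                  40),
                               target_query = up_genes, n_enriched = 2,
                               overlap_count = overlap_count,
                               seed = seed + 404L)
  truth <- list(expression = sim_e$truth, network = sim_n$truth,
                survival = sim_s$truth, annotation = sim_a$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_expression_table(sim_e$expr, file.path(out_dir, "expression.tsv"))
    write_edge_list(sim_n$edges, file.path(out_dir, "edges.tsv"))
    write_gmt(sim_a$collection, file.path(out_dir, "sets.gmt"))
    write_survival_table(sim_s$table, file.path(out_dir, "survival.tsv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(expr = sim_e$expr, edges = sim_n$edges, sets = sim_a$collection,
       survival = sim_s$table, truth = truth)
}
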