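#' Per-gene differential-expression statistics for one generation
#'
#' Compares treated samples of one xenograft generation against the shared
#' control samples. `logfc` is mean(treated) - mean(control) on the log2
#' scale. The default statistic is a two-sided Welch t-test (vectorized
#' row-wise, Welch-Satterthwaite degrees of freedom). The `"moderated"`
#' mode shrinks each gene's pooled variance toward the median pooled
#' variance (weight `shrink_weight`) before an equal-variance t-test — a
#' light-weight stand-in for moderated-variance pipelines; no
#' bit-compatibility with any of them is claimed.
#'
#' Genes with a missing value in either compared group are excluded from
#' the comparison (with a message). Genes where both groups have zero
#' variance get p = 1 when the means are equal and p = 0 otherwise (the
#' zero-noise limit).
#'
#' @param x gene-level [expr_matrix].
#' @param generation generation label to compare.
#' @param method `"welch"` (default) or `"moderated"`.
#' @param shrink_weight weight on the median pooled variance in
#'   `"moderated"` mode.
#' @return data.frame with columns `gene`, `logfc`, `t_stat`, `p_value`.
#' @export
test_differential <- function(x, generation,
                              method = c("welch", "moderated"),
                              shrink_weight = 0.5) {
  stopifnot(inherits(x, "expr_matrix"))
  method <- match.arg(method)
  ctrl <- x$samples$condition == "control"
  trt <- x$samples$condition == "treated" &
    !is.na(x$samples$generation) & x$samples$generation == generation
  if (sum(ctrl) < 2 || sum(trt) < 2)
    stop("need >= 2 control and >= 2 treated samples for generation ",
         generation)
  a <- x$values[, trt, drop = FALSE]   # treated
  b <- x$values[, ctrl, drop = FALSE]  # control
  complete <- stats::complete.cases(a) & stats::complete.cases(b)
  if (!all(complete)) {
    message(sum(!complete), " gene(s) with missing values excluded from ",
            "the generation-", generation, " comparison")
    a <- a[complete, , drop = FALSE]
    b <- b[complete, , drop = FALSE]
  }
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  logfc <- m1 - m2

  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    t_stat <- logfc / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    pos <- sp2[sp2 > 0]
    target <- if (length(pos)) stats::median(pos) else 0
    sp2 <- (1 - shrink_weight) * sp2 + shrink_weight * target
    t_stat <- logfc / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(logfc))
  }
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  degenerate <- !is.finite(t_stat)
  if (any(degenerate)) {
    # zero variance in both groups: equal means -> no evidence (p = 1),
    # different means -> the zero-noise limit (p = 0)
    p[degenerate] <- ifelse(abs(logfc[degenerate]) > 0, 0, 1)
    t_stat[degenerate] <- ifelse(abs(logfc[degenerate]) > 0,
                                 sign(logfc[degenerate]) * Inf, 0)
  }
  data.frame(gene = rownames(a), logfc = logfc, t_stat = t_stat,
             p_value = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially expressed genes by threshold
#'
#' Direction is `"up"` iff `logfc > logfc_threshold` and
#' `p < p_threshold`; `"down"` iff `logfc < -logfc_threshold` and
#' `p < p_threshold`; otherwise `"none"`. Both inequalities are strict, so
#' a gene sitting exactly on a threshold is not a DEG.
#'
#' @param stats data.frame from [test_differential()].
#' @param logfc_threshold fold-change cut (log2 units; default 1).
#' @param p_threshold p-value cut (default 0.05).
#' @param adjust `"none"` (default, raw p) or `"BH"`
#'   (Benjamini-Hochberg; the threshold is then applied to the adjusted p).
#' @return the input with a `direction` column, sorted by |logfc|
#'   descending with ties broken by gene symbol.
#' @export
call_degs <- function(stats, logfc_threshold = 1, p_threshold = 0.05,
                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  p <- stats$p_value
  if (adjust == "BH") {
    stats$adjusted_p <- stats::p.adjust(p, method = "BH")
    p <- stats$adjusted_p
  }
  stats$direction <- ifelse(
    stats$logfc > logfc_threshold & p < p_threshold, "up",
    ifelse(stats$logfc < -logfc_threshold & p < p_threshold, "down",
           "none"))
  stats[order(-abs(stats$logfc), stats$gene), , drop = FALSE]
}

#' Partition DEGs common to all generations
#'
#' A gene is common iff its direction is not `"none"` in every supplied
#' generation. Common genes split into `up` (up everywhere), `down` (down
#' everywhere) and `both` (a DEG everywhere but with discordant
#' directions). The three categories are disjoint and exhaust the common
#' set; the partition does not depend on the order of the inputs.
#'
#' @param deg_tables named list of per-generation data.frames from
#'   [call_degs()].
#' @return list with sorted character vectors `up`, `down`, `both`,
#'   `common`, and `per_generation_counts`.
#' @export
partition_common <- function(deg_tables) {
  if (length(deg_tables) < 2)
    stop("need >= 2 generations to partition")
  dirs <- lapply(deg_tables, function(d)
    stats::setNames(d$direction, d$gene))
  called <- lapply(dirs, function(d) names(d)[d != "none"])
  common <- Reduce(intersect, called)
  dir_mat <- vapply(dirs, function(d) d[common], character(length(common)))
  if (length(common) == 1) dir_mat <- matrix(dir_mat, nrow = 1)
  all_up <- apply(dir_mat, 1, function(r) all(r == "up"))
  all_down <- apply(dir_mat, 1, function(r) all(r == "down"))
  out <- list(up = sort(common[all_up]),
              down = sort(common[all_down]),
              both = sort(common[!all_up & !all_down]),
              common = sort(common),
              per_generation_counts = vapply(called, length, 0L))
  stopifnot(length(out$up) + length(out$down) + length(out$both) ==
              length(out$common))
  out
}

#' Classify a gene list by annotation class
#'
#' Intersects a query gene list with each class of a GMT-like class map
#' (growth factors, cytokines, proto-oncogenes, ...) and tallies up/down
#' directions from DEG records where available. Query genes without a
#' direction record count as members but not in the tallies.
#'
#' @param genes character vector of query symbols.
#' @param class_map a [gene_sets] object or a named list of character
#'   vectors.
#' @param deg optional data.frame from [call_degs()] supplying directions.
#' @return data.frame with columns `class`, `n_members`, `n_up`, `n_down`
#'   and a list-column `members`.
#' @export
classify_by_annotation <- function(genes, class_map, deg = NULL) {
  sets <- if (inherits(class_map, "gene_sets")) class_map$sets else class_map
  dirs <- if (!is.null(deg)) stats::setNames(deg$direction, deg$gene)
          else character()
  res <- lapply(names(sets), function(cl) {
    members <- sort(intersect(sets[[cl]], genes))
    d <- dirs[members]
    missing_dir <- members[is.na(d)]
    if (length(missing_dir) && !is.null(deg))
      message("class '", cl, "': ", length(missing_dir),
              " member(s) without a direction record")
    data.frame(class = cl, n_members = length(members),
               n_up = sum(d == "up", na.rm = TRUE),
               n_down = sum(d == "down", na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$members <- lapply(names(sets), function(cl)
    sort(intersect(sets[[cl]], genes)))
  out
}
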