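#' Construct an expression matrix with sample group labels
#'
#' The central expression container: a genes x samples matrix of log2
#' intensities together with a per-sample design (condition and xenograft
#' generation). Control samples are shared across generations and carry
#' `generation = NA`.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must
#'   carry row and column dimnames.
#' @param condition character vector, one of `"control"`/`"treated"` per
#'   sample (column).
#' @param generation integer vector per sample; `NA` for controls.
#' @param scale character scalar recorded as the value scale (default
#'   `"log2"`).
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix), `samples` (data.frame with `sample_id`, `condition`,
#'   `generation`) and `scale`.
#' @export
expr_matrix <- function(values, condition, generation, scale = "log2") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have row (gene) and column (sample) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  n <- ncol(values)
  if (length(condition) != n || length(generation) != n)
    stop("'condition' and 'generation' must have one entry per sample")
  condition <- as.character(condition)
  if (!all(condition %in% c("control", "treated")))
    stop("'condition' entries must be 'control' or 'treated'")
  structure(
    list(values = values,
         samples = data.frame(sample_id = colnames(values),
                              condition = condition,
                              generation = as.integer(generation),
                              stringsAsFactors = FALSE),
         scale = scale),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  tab <- table(x$samples$condition, x$samples$generation, useNA = "ifany")
  print(tab)
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression table from TSV
#'
#' The dialect is a plain TSV whose first column holds probe or gene ids and
#' whose remaining columns are samples, preceded by comment lines declaring
#' the value scale and the per-sample design:
#' ```
#' #scale=log2
#' #condition=control<TAB>control<TAB>treated ...
#' #generation=NA<TAB>NA<TAB>1 ...
#' id<TAB>s1<TAB>s2<TAB>s3 ...
#' ```
#'
#' @param path file to read.
#' @return An [expr_matrix].
#' @seealso [write_expression_table()]
#' @export
read_expression_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    m <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(m) != 1)
      stop("expression table must declare exactly one '#", key, "=' line")
    strsplit(sub(paste0("^#", key, "="), "", m), "\t", fixed = TRUE)[[1]]
  }
  scale <- get_hdr("scale")[1]
  condition <- get_hdr("condition")
  generation <- suppressWarnings(as.integer(get_hdr("generation")))

  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 2) stop("expression table has no data rows")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (length(condition) != length(sample_ids) ||
      length(generation) != length(sample_ids))
    stop("design header lines must have one field per sample column")

  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  nfield <- lengths(rows)
  if (any(nfield != length(header)))
    stop("row ", which(nfield != length(header))[1],
         " has ", nfield[nfield != length(header)][1],
         " fields, expected ", length(header))
  ids <- vapply(rows, `[[`, "", 1L)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(sample_ids),
                 dimnames = list(ids, sample_ids))
  for (i in seq_along(rows)) {
    cell <- rows[[i]][-1]
    num <- suppressWarnings(as.numeric(cell))
    bad <- is.na(num) & !(cell %in% c("NA", ""))
    if (any(bad))
      stop("non-numeric value '", cell[bad][1], "' at row '", ids[i],
           "', column '", sample_ids[bad][1], "'")
    vals[i, ] <- num
  }
  expr_matrix(vals, condition, generation, scale = scale)
}

#' Write an expression table to TSV
#'
#' @param x an [expr_matrix].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#scale=", x$scale),
    paste0("#condition=", paste(x$samples$condition, collapse = "\t")),
    paste0("#generation=", paste(x$samples$generation, collapse = "\t"))
  ), con)
  writeLines(paste(c("id", colnames(x$values)), collapse = "\t"), con)
  body <- apply(x$values, 1, function(v)
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(x$values), body, sep = "\t"), con)
  invisible(path)
}

#' Read a probe-to-gene annotation map
#'
#' Two-column TSV (`probe_id`, `gene_symbol`) with a header row. Probes with
#' an empty or `NA` symbol are kept in the map but flagged unmapped; they are
#' dropped by [collapse_probes()].
#'
#' @param path file to read.
#' @param uppercase fold gene symbols to upper case (default FALSE: symbols
#'   are opaque case-sensitive tokens, so that symbol-space mismatches
#'   surface as errors rather than silent folding).
#' @return data.frame with columns `probe_id`, `gene_symbol`, `mapped`.
#' @export
read_probe_annotation <- function(path, uppercase = FALSE) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (ncol(ann) < 2)
    stop("probe annotation needs two columns: probe_id, gene_symbol")
  names(ann)[1:2] <- c("probe_id", "gene_symbol")
  if (anyDuplicated(ann$probe_id))
    stop("duplicate probe ids in annotation")
  ann$mapped <- !is.na(ann$gene_symbol) & nzchar(trimws(ann$gene_symbol)) &
    ann$gene_symbol != "NA"
  if (uppercase) ann$gene_symbol <- toupper(ann$gene_symbol)
  ann[, c("probe_id", "gene_symbol", "mapped")]
}

#' Collapse a probe-level matrix to gene level
#'
#' Probes without a gene symbol are eliminated; where several probes map to
#' one gene, the gene's profile is the arithmetic mean of the probe rows,
#' per sample.
#'
#' @param x probe-level [expr_matrix].
#' @param ann annotation from [read_probe_annotation()] (or any data.frame
#'   with `probe_id`, `gene_symbol`, and optionally `mapped`).
#' @return gene-level [expr_matrix] with unique gene ids.
#' @export
collapse_probes <- function(x, ann) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(ann$mapped))
    ann$mapped <- !is.na(ann$gene_symbol) & nzchar(ann$gene_symbol)
  ann <- ann[ann$mapped, , drop = FALSE]
  sym <- ann$gene_symbol[match(rownames(x$values), ann$probe_id)]
  keep <- !is.na(sym)
  if (!any(keep))
    stop("no probe in the matrix maps to a gene symbol")
  vals <- x$values[keep, , drop = FALSE]
  sym <- sym[keep]
  collapsed <- rowsum(vals, group = sym) / as.vector(table(sym)[sort(unique(sym))])
  collapsed <- collapsed[order(rownames(collapsed)), , drop = FALSE]
  expr_matrix(collapsed, x$samples$condition, x$samples$generation,
              scale = x$scale)
}

#' Read a weighted interaction edge list
#'
#' STRING-export-style TSV with columns `node_a`, `node_b`,
#' `combined_score`. Scores are normalized to the unit interval:
#' `score_scale = "thousand"` divides by 1000, `"unit"` takes values as-is,
#' and `"auto"` treats the file as thousand-scaled if any score exceeds 1.
#' Endpoint order is canonicalized (undirected); exact duplicate pairs are
#' collapsed keeping the maximum confidence; self-loops are dropped with a
#' warning.
#'
#' @param path file to read.
#' @param score_scale one of `"auto"`, `"unit"`, `"thousand"`.
#' @param uppercase fold node symbols to upper case (default FALSE).
#' @return data.frame with columns `node_a`, `node_b`, `confidence`.
#' @export
read_edge_list <- function(path, score_scale = c("auto", "unit", "thousand"),
                           uppercase = FALSE) {
  score_scale <- match.arg(score_scale)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "numeric"))
  if (ncol(df) < 3)
    stop("edge list needs columns node_a, node_b, combined_score")
  names(df)[1:3] <- c("node_a", "node_b", "score")
  if (uppercase) {
    df$node_a <- toupper(df$node_a)
    df$node_b <- toupper(df$node_b)
  }
  normalize_edge_scores(df, score_scale)
}

normalize_edge_scores <- function(df, score_scale) {
  if (any(is.na(df$score))) stop("missing interaction score")
  if (any(df$score < 0)) stop("negative interaction score")
  scale_used <- score_scale
  if (score_scale == "auto")
    scale_used <- if (any(df$score > 1)) "thousand" else "unit"
  if (scale_used == "thousand") {
    if (any(df$score > 1000))
      stop("score exceeds 1000; not on the 0-1000 scale")
    df$score <- df$score / 1000
  } else if (any(df$score > 1)) {
    stop("score exceeds 1 under 'unit' scaling")
  }
  loop <- df$node_a == df$node_b
  if (any(loop)) {
    warning(sum(loop), " self-loop(s) dropped")
    df <- df[!loop, , drop = FALSE]
  }
  a <- pmin(df$node_a, df$node_b)
  b <- pmax(df$node_a, df$node_b)
  out <- data.frame(node_a = a, node_b = b, confidence = df$score,
                    stringsAsFactors = FALSE)
  # undirected dedup: keep max confidence per unordered pair
  key <- paste(out$node_a, out$node_b, sep = "\r")
  out <- out[order(key, -out$confidence), , drop = FALSE]
  out <- out[!duplicated(paste(out$node_a, out$node_b, sep = "\r")), ,
             drop = FALSE]
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an edge list to TSV
#'
#' @param edges data.frame with `node_a`, `node_b`, `confidence`.
#' @param path output file.
#' @param score_scale write confidences on the `"unit"` (default) or
#'   `"thousand"` scale.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path, score_scale = c("unit", "thousand")) {
  score_scale <- match.arg(score_scale)
  sc <- edges$confidence
  if (score_scale == "thousand") sc <- round(sc * 1000)
  df <- data.frame(node_a = edges$node_a, node_b = edges$node_b,
                   combined_score = sc)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `set_id`, `description`,
#' then member symbols. Duplicate members within a line are deduplicated.
#'
#' @param path file to read.
#' @param uppercase fold member symbols to upper case (default FALSE).
#' @return An object of class `gene_sets`: list with `sets` (named list of
#'   character vectors), `descriptions` (named character) and `universe`
#'   (union of all members; extend with [enrich()]'s `universe` argument).
#' @export
read_gmt <- function(path, uppercase = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short))
    stop("GMT line ", which(short)[1], " has fewer than 3 fields")
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate set ids in GMT")
  sets <- lapply(fields, function(f) {
    m <- f[-(1:2)]
    if (uppercase) m <- toupper(m)
    unique(m)
  })
  names(sets) <- ids
  desc <- vapply(fields, `[[`, "", 2L)
  names(desc) <- ids
  gene_sets(sets, desc)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of member symbols.
#' @param descriptions optional named character vector (defaults to the
#'   set ids).
#' @param universe optional explicit background; defaults to the union of
#'   all members.
#' @return A `gene_sets` object.
#' @export
gene_sets <- function(sets, descriptions = NULL, universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a named list")
  sets <- lapply(sets, function(s) {
    s <- unique(as.character(s))
    if (length(s) < 1 || any(!nzchar(s)))
      stop("every set needs >= 1 nonempty member symbol")
    s
  })
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  }
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)],
                 universe = universe),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d sets, universe of %d symbols\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' @param x a `gene_sets` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_sets"))
  lines <- vapply(names(x$sets), function(id)
    paste(c(id, x$descriptions[[id]], x$sets[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-subject survival table
#'
#' TSV with columns `subject_id`, `time_months`, `event` (0 censored /
#' 1 event) and one numeric column per screened gene.
#'
#' @param path file to read.
#' @return data.frame; gene columns follow the three mandatory columns.
#' @export
read_survival_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  need <- c("subject_id", "time_months", "event")
  if (!all(need %in% names(df)))
    stop("survival table needs columns: ", paste(need, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) stop("duplicate subject ids")
  if (any(df$time_months <= 0)) stop("survival times must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event flags must be 0 or 1")
  df
}

#' Write a survival table to TSV
#'
#' @param x survival data.frame as from [read_survival_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table to TSV or JSON
#'
#' Values are serialized at full double precision (15 significant digits)
#' so that a write/read round trip is an identity to at least 12
#' significant digits. Row order is taken as-is: every producing function
#' in the package documents and applies its own deterministic sort
#' (DEG tables by |logFC| descending then symbol; hubs by HCM descending
#' then symbol; modules and enrichment by score/p with id tie-breaks).
#'
#' @param x data.frame to write.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  x <- as.data.frame(x)
  if (format == "tsv") {
    y <- x
    num <- vapply(y, is.numeric, TRUE)
    y[num] <- lapply(y[num], function(v)
      format(v, digits = 15, trim = TRUE, scientific = TRUE))
    utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", digits = NA,
                         auto_unbox = FALSE, pretty = TRUE, na = "null")
  }
  invisible(path)
}
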