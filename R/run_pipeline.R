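#' Read and write a flat pipeline configuration file
#'
#' The configuration is a plain-text file of \code{key = value} lines
#' (\code{#} starts a comment). Recognised keys: the input paths
#' \code{expr_case}, \code{expr_control}, \code{edges}, the output
#' directory \code{out_dir}, every threshold accepted by [attracmod()]
#' (\code{score_threshold}, \code{edge_alpha}, \code{clique_min},
#' \code{clique_max}, \code{merge_threshold}, \code{jaccard_threshold},
#' \code{min_module_size}, \code{attract_alpha}) and the switches
#' \code{interconnect}, \code{tail}, \code{allow_many_to_many}. Values
#' round-trip unchanged through \code{write_pipeline_config()} /
#' \code{read_pipeline_config()}.
#'
#' @param path file path.
#' @return \code{read_pipeline_config} returns a named list with numeric,
#'   logical and character values coerced.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  out <- lapply(vals, function(v) {
    if (grepl("^(true|false)$", tolower(v))) return(tolower(v) == "true")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- keys
  out
}

#' @rdname read_pipeline_config
#' @param config named list of configuration values.
#' @export
write_pipeline_config <- function(config, path) {
  fmt <- vapply(config, function(v) {
    if (is.logical(v)) tolower(as.character(v))
    else if (is.numeric(v)) format(v, digits = 15)
    else as.character(v)
  }, "")
  writeLines(paste(names(config), fmt, sep = " = "), path)
  invisible(path)
}

#' Run the attractor-module pipeline from files
#'
#' File-level orchestration of [attracmod()]: reads the expression matrices
#' and edge list named in \code{config}, fits the pipeline, writes every
#' intermediate artifact into \code{out_dir} and returns the run report.
#' Outputs are deterministic: identical configuration and inputs give
#' byte-identical files.
#'
#' Artifacts written: \code{destination_case.tsv} /
#' \code{destination_control.tsv} (4 columns: gene_a, gene_b, weight,
#' p_value), \code{modules_case.jsonl} / \code{modules_control.jsonl} (one
#' JSON object per module: genes, wid, dcc, condition),
#' \code{modules_case.tsv} / \code{modules_control.tsv} summaries,
#' \code{pairs.tsv}, \code{attract_results.tsv} and
#' \code{run_report.json} (stage-wise counts, schema version 1.0).
#'
#' @param config path to a configuration file (see
#'   [read_pipeline_config()]) or an equivalent named list. Must name
#'   \code{expr_case}, \code{expr_control}, \code{edges} and
#'   \code{out_dir}; thresholds default as in [attracmod()].
#' @return Invisibly, the run report (named list of stage counts), with
#'   the full \code{attracmod} fit attached as attribute \code{"fit"}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  for (key in c("expr_case", "expr_control", "edges", "out_dir"))
    if (is.null(config[[key]])) stop("config is missing '", key, "'")

  expr_case <- read_expression(config$expr_case)
  expr_control <- read_expression(config$expr_control)
  edges <- read_edges(config$edges)

  arg <- function(key, default) {
    v <- config[[key]]
    if (is.null(v)) default else v
  }
  fit <- attracmod(expr_case, expr_control, edges,
                   score_threshold = arg("score_threshold", 0.8),
                   edge_alpha = arg("edge_alpha", 0.05),
                   clique_min = arg("clique_min", 4),
                   clique_max = arg("clique_max", 20),
                   merge_threshold = arg("merge_threshold", 0.5),
                   interconnect = arg("interconnect", "geometric"),
                   jaccard_threshold = arg("jaccard_threshold", 0.7),
                   min_module_size = arg("min_module_size", 5),
                   attract_alpha = arg("attract_alpha", 0.05),
                   tail = arg("tail", "two"),
                   allow_many_to_many = arg("allow_many_to_many", FALSE))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  for (cond in c("case", "control")) {
    net <- fit$networks[[cond]]$edges
    utils::write.table(
      data.frame(gene_a = net$gene_a, gene_b = net$gene_b,
                 weight = net$weight, p_value = net$p_value),
      p(sprintf("destination_%s.tsv", cond)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_modules_jsonl(fit$modules[[cond]],
                        p(sprintf("modules_%s.jsonl", cond)))
    utils::write.table(module_summary(fit$modules[[cond]]),
                       p(sprintf("modules_%s.tsv", cond)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(fit$pairs[, c("pair_id", "jaccard", "case_genes",
                                   "control_genes")],
                     p("pairs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fit$results, p("attract_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fit$report, p("run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(structure(fit$report, fit = fit))
}

write_modules_jsonl <- function(modules, path) {
  lines <- vapply(modules, function(m)
    as.character(jsonlite::toJSON(
      list(genes = I(m$genes), wid = m$wid, dcc = m$dcc,
           condition = m$condition),
      auto_unbox = TRUE, digits = NA)), "")
  writeLines(lines, path)
  invisible(path)
}
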