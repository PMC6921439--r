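#' Read a flat key-value pipeline configuration file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Keys mirror the arguments of [run_pipeline()]; `assoc` may be given as a
#' comma-separated list of paths.
#'
#' @param path Config file path.
#' @return Named list of raw (character) values.
#' @export
read_pipeline_config <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[lines != ""]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) {
    abort(paste0("malformed config line: ", lines[bad][[1]]),
          class = "dsim_config_error")
  }
  rlang::set_names(lapply(kv, `[[`, 2), vapply(kv, `[[`, character(1), 1))
}

#' Run the full disease-similarity pipeline
#'
#' Chains the stages over file inputs: parse the vocabulary, build one
#' Lin similarity network per association corpus, align the networks on
#' their union node set, run the restart random walk, fit the embedding,
#' score the benchmark pairs, and evaluate. All outputs plus a manifest
#' (inputs, parameters in effect, output hashes) are written to `outdir`.
#' Every parameter in effect is logged; re-running with the same inputs
#' and seed reproduces identical outputs.
#'
#' @param vocab Path to a MEDIC-style vocabulary file.
#' @param assoc Character vector of association file paths.
#' @param benchmark Path to a benchmark pair TSV (`id1  id2  label`).
#' @param outdir Output directory.
#' @param entity_col,disease_col Association column names.
#' @param threshold Similarity-network edge threshold (default 0).
#' @param a Restart probability, in (0, 1] (default 0.5).
#' @param d Embedding dimension (default 600; must be < the number of
#'   diseases in the union network).
#' @param method Embedding fitter, `"lbfgs"` (default) or `"svd"`.
#' @param seed Integer seed (default 0).
#' @param fraction Top-quantile fraction for the exported integrated
#'   network (default 0.003, the top 0.3% of pair scores).
#' @return Invisibly, a list with `report` (a `dsim_eval`), `ablation`
#'   tibble, `network_stats`, and `manifest` (tibble of artifacts).
#' @export
run_pipeline <- function(vocab, assoc, benchmark, outdir,
                         entity_col = "EntityID", disease_col = "DiseaseID",
                         threshold = 0, a = 0.5, d = 600,
                         method = c("lbfgs", "svd"), seed = 0L,
                         fraction = 0.003) {
  method <- match.arg(method)
  if (a <= 0 || a > 1) abort("restart probability a must be in (0, 1]",
                             class = "dsim_config_error")
  if (d < 1) abort("embedding dimension d must be >= 1", class = "dsim_config_error")
  if (threshold < 0 || threshold >= 1) {
    abort("threshold must be in [0, 1)", class = "dsim_config_error")
  }
  if (fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]", class = "dsim_config_error")
  }
  for (p in c(vocab, assoc, benchmark)) {
    if (!file.exists(p)) abort(paste0("input not found: ", p), class = "dsim_io_error")
  }
  inform(sprintf(
    "run_pipeline: a=%g d=%d method=%s threshold=%g seed=%d fraction=%g",
    a, d, method, threshold, seed, fraction))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
            class = "dsim_pipeline_error", parent = e)
    })
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  dag <- stage("ontology", parse_medic(vocab))
  if (d >= nrow(dag$terms)) {
    abort(paste0("d = ", d, " must be smaller than the vocabulary size ",
                 nrow(dag$terms)), class = "dsim_config_error")
  }

  nets <- stage("semsim", {
    lapply(assoc, function(p) {
      ft <- count_frequencies(
        read_associations(p, entity_col = entity_col, disease_col = disease_col),
        dag)
      build_similarity_network(ft, dag, threshold = threshold)
    })
  })
  net_paths <- file.path(outdir, sprintf("network_%d.tsv", seq_along(nets)))
  for (i in seq_along(nets)) write_network_tsv(nets[[i]], net_paths[[i]])

  universe <- sort(unique(unlist(lapply(nets, network_nodes))))
  if (d >= length(universe)) {
    abort(paste0("d = ", d, " must be smaller than the union node count ",
                 length(universe)), class = "dsim_config_error")
  }

  model <- stage("embed", embed_networks(nets, d = d, a = a, method = method,
                                         seed = seed))
  emb_path <- file.path(outdir, "embedding.tsv")
  write_embedding_tsv(model, emb_path)

  bench <- stage("benchmark", read_benchmark_tsv(benchmark))
  keep_pair <- function(p) p$id1 %in% model$node_ids & p$id2 %in% model$node_ids
  bench <- new_benchmark_set(bench$positives[keep_pair(bench$positives), ],
                             bench$negatives[keep_pair(bench$negatives), ])

  scores <- stage("score", {
    dplyr::bind_rows(score_pairs(model, bench$positives),
                     score_pairs(model, bench$negatives))
  })
  scores_path <- file.path(outdir, "scores.tsv")
  write_scores_tsv(scores, scores_path)

  report <- stage("eval", evaluate_embedding(model, bench))
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(as.list(glance(report)), report_path,
                       auto_unbox = TRUE, digits = NA)

  topq <- stage("network", top_quantile_network(model, fraction = fraction))
  gpsn_path <- file.path(outdir, "integrated_network.tsv")
  write_network_tsv(topq$network, gpsn_path)

  artifacts <- c(net_paths, emb_path, scores_path, report_path, gpsn_path)
  manifest <- tibble::tibble(
    artifact = basename(artifacts),
    path = artifacts,
    md5 = unname(tools::md5sum(artifacts))
  )
  params <- tibble::tibble(
    artifact = "parameters",
    path = NA_character_,
    md5 = sprintf("a=%g;d=%d;method=%s;threshold=%g;seed=%d;fraction=%g",
                  a, d, method, threshold, seed, fraction)
  )
  manifest_path <- file.path(outdir, "manifest.tsv")
  readr::write_tsv(dplyr::bind_rows(params, manifest), manifest_path,
                   progress = FALSE)

  invisible(list(report = report, model = model, networks = nets,
                 network_stats = topq$stats, manifest = manifest))
}
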