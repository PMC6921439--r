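#' Classification metrics for benchmark-vs-random disease pairs
#'
#' Treats benchmark pairs as positives and random pairs as negatives. AUC
#' uses the Mann-Whitney rank formulation (ties count 1/2); the remaining
#' metrics come from the confusion matrix at `threshold` (a pair is
#' predicted positive when its score is >= the threshold). With
#' `threshold = "auto"` the threshold maximizing Youden's J
#' (sensitivity + specificity - 1) is chosen; ties go to the smallest such
#' threshold. MCC is defined as 0 when any confusion-matrix marginal is 0.
#'
#' @param scores_pos,scores_neg Numeric score vectors (both nonempty).
#' @param threshold Numeric threshold or `"auto"` (default).
#' @return A `dsim_eval` object: list with `acc`, `auc`, `f1`, `mcc`,
#'   `pre`, `sen`, `spe`, `threshold`, `n_pos`, `n_neg` and the confusion
#'   counts `tp`, `fp`, `tn`, `fn`. Has [tidy()] / [glance()] /
#'   [autoplot()] methods.
#' @examples
#' m <- classification_metrics(c(0.9, 0.8, 0.4), c(0.7, 0.3), threshold = 0.75)
#' glance(m)
#' @export
classification_metrics <- function(scores_pos, scores_neg, threshold = "auto") {
  if (length(scores_pos) == 0 || length(scores_neg) == 0) {
    abort("both score classes must be nonempty", class = "dsim_validation_error")
  }
  np <- length(scores_pos); nn <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg)) # average ranks: ties count 1/2
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)

  if (identical(threshold, "auto")) {
    cand <- sort(unique(c(scores_pos, scores_neg)))
    j <- vapply(cand, function(th) {
      sum(scores_pos >= th) / np + sum(scores_neg < th) / nn - 1
    }, numeric(1))
    threshold <- cand[[which.max(j)]] # which.max takes the first (smallest)
  }
  tp <- sum(scores_pos >= threshold); fn <- np - tp
  fp <- sum(scores_neg >= threshold); tn <- nn - fp

  sen <- tp / np
  spe <- tn / nn
  pre <- if (tp + fp == 0) 0 else tp / (tp + fp)
  acc <- (tp + tn) / (np + nn)
  f1 <- if (pre + sen == 0) 0 else 2 * pre * sen / (pre + sen)
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / sqrt(mcc_den)

  structure(list(acc = acc, auc = auc, f1 = f1, mcc = mcc, pre = pre,
                 sen = sen, spe = spe, threshold = threshold,
                 n_pos = np, n_neg = nn, tp = tp, fp = fp, tn = tn, fn = fn,
                 scores_pos = scores_pos, scores_neg = scores_neg),
            class = "dsim_eval")
}

#' @export
print.dsim_eval <- function(x, ...) {
  cat("<dsim_eval> ", x$n_pos, " positives vs ", x$n_neg, " negatives\n",
      sprintf("  AUC %.3f  ACC %.3f  F1 %.3f  MCC %.3f  PRE %.3f  SEN %.3f  SPE %.3f",
              x$auc, x$acc, x$f1, x$mcc, x$pre, x$sen, x$spe),
      "\n  threshold ", format(x$threshold), "\n", sep = "")
  invisible(x)
}

#' Evaluate an embedding against a benchmark set
#'
#' Scores the positive and negative pairs and computes
#' [classification_metrics()].
#'
#' @param model A `dsim_embedding`.
#' @param benchmark A `benchmark_set` (see [generate_benchmark()] or
#'   [read_benchmark_tsv()]).
#' @param threshold Passed to [classification_metrics()].
#' @return A `dsim_eval`.
#' @export
evaluate_embedding <- function(model, benchmark, threshold = "auto") {
  sp <- score_pairs(model, benchmark$positives)$score
  sn <- score_pairs(model, benchmark$negatives)$score
  classification_metrics(sp, sn, threshold = threshold)
}

#' AUC across embedding dimensions
#'
#' Fits one embedding per dimension from the same diffusion states and
#' reports the benchmark AUC, mirroring the published dimension sweep
#' (d from 500 to 800, step 100, at corpus scale) used to check robustness
#' to the choice of d.
#'
#' @param S_list Diffusion states ([diffusion_states()]).
#' @param dims Integer vector of dimensions (all `< n`).
#' @param benchmark A `benchmark_set`.
#' @param seed Seed (used by the L-BFGS fitter).
#' @param method Embedding fitter, `"lbfgs"` (default) or `"svd"`.
#' @return Tibble `dim`, `auc`.
#' @export
dimension_sweep <- function(S_list, dims, benchmark, seed = 0L,
                            method = c("lbfgs", "svd")) {
  method <- match.arg(method)
  n <- nrow(as_diffusion_matrix(S_list[[1]]))
  if (any(dims >= n)) abort("all dims must be < n", class = "dsim_validation_error")
  ids <- rownames(as_diffusion_matrix(S_list[[1]])) %||% character(0)
  benchmark <- restrict_benchmark(benchmark, ids)
  auc <- vapply(dims, function(d) {
    model <- if (method == "svd") fit_embeddings_svd(S_list, d)
             else fit_embeddings_lbfgs(S_list, d, seed = seed)
    evaluate_embedding(model, benchmark)$auc
  }, numeric(1))
  tibble::tibble(dim = as.integer(dims), auc = auc)
}

# drop benchmark pairs naming diseases outside the embedding's node set
restrict_benchmark <- function(benchmark, ids) {
  keep <- function(p) p[p$id1 %in% ids & p$id2 %in% ids, , drop = FALSE]
  pos <- keep(benchmark$positives); neg <- keep(benchmark$negatives)
  dropped <- (nrow(benchmark$positives) - nrow(pos)) +
    (nrow(benchmark$negatives) - nrow(neg))
  if (dropped > 0) {
    inform(paste0("restrict_benchmark: dropped ", dropped,
                  " pair(s) outside the node universe"))
  }
  new_benchmark_set(pos, neg)
}

#' Single-source versus integrated embeddings
#'
#' Embeds each similarity network alone and all networks together, and
#' reports the benchmark AUC per configuration — the ablation contrasting
#' the gene-, process- and symptom-derived networks with their integration.
#'
#' @param nets List of (named) `dsim_network` objects.
#' @param benchmark A `benchmark_set`.
#' @param d Embedding dimension.
#' @param seed Seed (L-BFGS fitter).
#' @param a Restart probability.
#' @param method Embedding fitter, `"lbfgs"` (default) or `"svd"`.
#' @return Tibble `configuration`, `auc` with one row per network plus an
#'   `"integrated"` row (M + 1 rows).
#' @export
source_ablation <- function(nets, benchmark, d, seed = 0L, a = 0.5,
                            method = c("lbfgs", "svd")) {
  method <- match.arg(method)
  labels <- names(nets) %||% paste0("net", seq_along(nets))
  labels[labels == ""] <- paste0("net", which(labels == ""))
  universe <- sort(unique(unlist(lapply(nets, network_nodes))))
  benchmark <- restrict_benchmark(benchmark, universe)
  one_auc <- function(net_list) {
    S_list <- lapply(net_list, function(net) {
      rwr_diffusion(transition_matrix(net, node_ids = universe), a = a)
    })
    model <- if (method == "svd") fit_embeddings_svd(S_list, d)
             else fit_embeddings_lbfgs(S_list, d, seed = seed)
    evaluate_embedding(model, benchmark)$auc
  }
  single <- vapply(nets, function(net) one_auc(list(net)), numeric(1))
  integrated <- if (length(nets) > 1) one_auc(nets) else single[[1]]
  tibble::tibble(configuration = c(labels, "integrated"),
                 auc = c(unname(single), integrated))
}

#' Same-category versus different-category similarity contrast
#'
#' Compares the mean similarity of disease pairs whose two members share a
#' category (e.g. a MeSH top-level category) against pairs that do not,
#' with a permutation p-value obtained by shuffling the disease-to-category
#' assignment. The p-value uses the `(b + 1) / (n + 1)` correction, where
#' `b` counts permuted mean differences at least as large as the observed
#' one.
#'
#' @param scores Tibble `id1`, `id2`, `score` (e.g. from [score_pairs()]).
#' @param categories Named character vector: disease id -> category label.
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Seed for the permutations.
#' @return A list with `mean_same`, `mean_diff`, `observed` (their
#'   difference), `p_value`, `n_same`, `n_diff`.
#' @export
category_contrast <- function(scores, categories, n_permutations = 1000,
                              seed = 0L) {
  ids <- unique(c(scores$id1, scores$id2))
  miss <- setdiff(ids, names(categories))
  if (length(miss) > 0) {
    abort(paste0("no category for id(s): ", paste(head(miss, 5), collapse = ", ")),
          class = "dsim_lookup_error")
  }
  labs <- categories[ids]
  if (length(unique(labs)) < 2) {
    abort("need at least 2 categories represented", class = "dsim_validation_error")
  }
  i <- match(scores$id1, ids); j <- match(scores$id2, ids)
  s <- scores$score

  mean_diff_stat <- function(lab) {
    same <- lab[i] == lab[j]
    if (!any(same) || all(same)) return(NA_real_)
    mean(s[same]) - mean(s[!same])
  }
  same0 <- labs[i] == labs[j]
  if (all(same0)) abort("all pairs fall in the same category",
                        class = "dsim_validation_error")
  mean_same <- mean(s[same0])
  mean_diff <- mean(s[!same0])
  observed <- mean_same - mean_diff

  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    stat <- mean_diff_stat(sample(labs))
    if (!is.na(stat) && stat >= observed) hits <- hits + 1L
  }
  list(mean_same = mean_same, mean_diff = mean_diff, observed = observed,
       p_value = (hits + 1) / (n_permutations + 1),
       n_same = sum(same0), n_diff = sum(!same0))
}

#' Positives recovered among the top-k ranked pairs
#'
#' Sorts all scored pairs descending (stable lexicographic tie-break) and
#' counts how many benchmark positives appear among the top k, for each k —
#' the ranking curve showing how quickly a similarity measure surfaces the
#' known-related pairs.
#'
#' @param scores Tibble `id1`, `id2`, `score` covering the benchmark's
#'   positive and negative pairs.
#' @param benchmark A `benchmark_set`.
#' @param ks Integer vector of depths; values beyond the pair count are
#'   clamped with a warning.
#' @return Tibble `k`, `n_recovered` (monotone non-decreasing in k).
#' @export
topk_recovery_curve <- function(scores, benchmark, ks) {
  pos_keys <- pair_keys(benchmark$positives)
  all_keys <- pair_keys(scores)
  missing_pairs <- setdiff(c(pos_keys, pair_keys(benchmark$negatives)), all_keys)
  if (length(missing_pairs) > 0) {
    abort(paste0(length(missing_pairs), " benchmark pair(s) missing from scores"),
          class = "dsim_validation_error")
  }
  if (any(ks > nrow(scores))) {
    warn("k exceeding the number of scored pairs clamped")
    ks <- pmin(ks, nrow(scores))
  }
  ord <- order(-scores$score, scores$id1, scores$id2)
  is_pos <- all_keys[ord] %in% pos_keys
  cum <- cumsum(is_pos)
  tibble::tibble(k = as.integer(ks), n_recovered = as.integer(cum[ks]))
}

pair_keys <- function(pairs) {
  a <- as.character(pairs[[1]]); b <- as.character(pairs[[2]])
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Read / write a benchmark pair file
#'
#' TSV with columns `id1`, `id2`, `label` (1 = benchmark positive,
#' 0 = random negative).
#'
#' @param path File path.
#' @return A `benchmark_set`: list with `positives` and `negatives`
#'   tibbles (`id1`, `id2`).
#' @export
read_benchmark_tsv <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "cci", progress = FALSE,
                         comment = "#")
  names(tbl) <- c("id1", "id2", "label")
  new_benchmark_set(tbl[tbl$label == 1, 1:2], tbl[tbl$label == 0, 1:2])
}

#' @rdname read_benchmark_tsv
#' @param benchmark A `benchmark_set`.
#' @export
write_benchmark_tsv <- function(benchmark, path) {
  tbl <- dplyr::bind_rows(
    dplyr::mutate(benchmark$positives, label = 1L),
    dplyr::mutate(benchmark$negatives, label = 0L)
  )
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

new_benchmark_set <- function(positives, negatives) {
  positives <- tibble::as_tibble(positives); negatives <- tibble::as_tibble(negatives)
  names(positives)[1:2] <- c("id1", "id2"); names(negatives)[1:2] <- c("id1", "id2")
  overlap <- intersect(pair_keys(positives), pair_keys(negatives))
  if (length(overlap) > 0) {
    abort("benchmark positives and negatives overlap", class = "dsim_validation_error")
  }
  structure(list(positives = positives, negatives = negatives),
            class = "benchmark_set")
}

#' @export
print.benchmark_set <- function(x, ...) {
  cat("<benchmark_set> ", nrow(x$positives), " positive / ",
      nrow(x$negatives), " negative pairs\n", sep = "")
  invisible(x)
}
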