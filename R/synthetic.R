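#' Configuration for the synthetic disease-similarity test bed
#'
#' The generator emulates the three inputs of the pipeline: a MEDIC-style
#' vocabulary forming a rooted DAG whose top-level subtrees define disease
#' categories (stand-ins for MeSH categories), association corpora whose
#' entities preferentially annotate diseases of one home category (the
#' planted cluster signal), and benchmark positive/negative pair lists.
#'
#' Defaults are sized so a full pipeline run takes seconds: 200 diseases in
#' 10 categories, 3 sources with 500 entities and 10,000 records each,
#' within-cluster bias 0.8, DAG depth 3.
#'
#' @param n_diseases Total number of vocabulary terms including the root.
#' @param n_categories Number of planted clusters (top-level subtrees).
#' @param n_sources Number of association corpora.
#' @param entities_per_source Entities (genes/processes/symptoms) per corpus.
#' @param records_per_source Association records per corpus.
#' @param within_cluster_bias Probability that a record's disease lies in
#'   its entity's home category; must exceed `1 / n_categories` so the
#'   planted signal exists.
#' @param coverage Fraction of diseases each source covers, recycled across
#'   sources. Sources cover different random subsets of unequal breadth;
#'   the defaults 0.40 / 0.70 / 0.50 mirror the relative breadths of
#'   gene-, process- and symptom-derived corpora (which cover roughly 40%,
#'   70% and 50% of the union of diseases they jointly mention).
#' @param dag_depth Maximum depth of the DAG below the root.
#' @param seed Integer seed.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_diseases = 200, n_categories = 10, n_sources = 3,
                         entities_per_source = 500, records_per_source = 10000,
                         within_cluster_bias = 0.8,
                         coverage = c(0.40, 0.70, 0.50),
                         dag_depth = 3, seed = 0L) {
  cfg <- list(n_diseases = as.integer(n_diseases),
              n_categories = as.integer(n_categories),
              n_sources = as.integer(n_sources),
              entities_per_source = as.integer(entities_per_source),
              records_per_source = as.integer(records_per_source),
              within_cluster_bias = within_cluster_bias,
              coverage = rep_len(coverage, as.integer(n_sources)),
              dag_depth = as.integer(dag_depth),
              seed = as.integer(seed))
  if (cfg$n_categories > cfg$n_diseases - 1) {
    abort("n_categories must be <= n_diseases - 1", class = "dsim_config_error")
  }
  if (cfg$within_cluster_bias <= 1 / cfg$n_categories ||
      cfg$within_cluster_bias > 1) {
    abort("within_cluster_bias must be in (1/n_categories, 1]",
          class = "dsim_config_error")
  }
  if (cfg$dag_depth < 2 || cfg$dag_depth > ceiling(log2(cfg$n_diseases)) + 2) {
    abort("dag_depth infeasible for this vocabulary size",
          class = "dsim_config_error")
  }
  if (any(cfg$coverage <= 0) || any(cfg$coverage > 1)) {
    abort("coverage must be in (0, 1]", class = "dsim_config_error")
  }
  structure(cfg, class = "synth_config")
}

synth_id <- function(i) sprintf("MESH:D%06d", i)

#' Generate a synthetic disease vocabulary
#'
#' Builds a rooted DAG: one root, `n_categories` children of the root (the
#' category heads), and the remaining terms attached within a category to a
#' uniformly chosen shallower member (occasionally two, giving the
#' poly-hierarchy structure real disease vocabularies have). Every
#' non-root term is labeled with its category. About 10% of terms carry a
#' synthetic OMIM-style alternative id.
#'
#' @param cfg A `synth_config`.
#' @return A list with `dag` (a `disease_dag`), `labels` (named character
#'   vector id -> category, non-root terms only) and `root` (the root id).
#' @export
generate_vocabulary <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_diseases
  k <- cfg$n_categories
  ids <- synth_id(seq_len(n))
  root <- ids[[1]]
  cat_heads <- ids[1 + seq_len(k)]
  cat_of <- character(n)      # category per index ("" for root)
  level <- integer(n)
  parents <- vector("list", n)
  parents[[1]] <- character(0)
  for (c in seq_len(k)) {
    parents[[1 + c]] <- root
    cat_of[1 + c] <- paste0("C", sprintf("%02d", c))
    level[1 + c] <- 1L
  }
  rest <- setdiff(seq_len(n), seq_len(k + 1))
  assigned_cat <- rep(seq_len(k), length.out = length(rest)) # balanced clusters
  for (ii in seq_along(rest)) {
    i <- rest[[ii]]
    c <- assigned_cat[[ii]]
    cat_of[i] <- paste0("C", sprintf("%02d", c))
    pool <- which(cat_of == cat_of[i] & level < cfg$dag_depth &
                    seq_len(n) < i)
    p1 <- if (length(pool) == 1) pool else sample(pool, 1)
    ps <- ids[[p1]]
    # ~10% of terms get a second parent in the same category (poly-hierarchy)
    pool2 <- setdiff(pool[level[pool] == level[p1]], p1)
    if (length(pool2) > 0 && runif(1) < 0.1) {
      p2 <- if (length(pool2) == 1) pool2 else sample(pool2, 1)
      ps <- c(ps, ids[[p2]])
    }
    parents[[i]] <- ps
    level[i] <- max(level[match(ps, ids)]) + 1L
  }
  alt <- ifelse(runif(n) < 0.1, sprintf("OMIM:%06d", 100000 + seq_len(n)), "")
  alt[1] <- ""
  terms <- tibble::tibble(
    disease_id = ids,
    name = c("Synthetic root",
             paste("Synthetic category", seq_len(k)),
             paste("Synthetic disease", rest)),
    alt_ids = lapply(alt, function(a) if (a == "") character(0) else a),
    parent_ids = parents
  )
  dag <- new_disease_dag(terms)
  labels <- rlang::set_names(cat_of[-1], ids[-1])
  list(dag = dag, labels = labels, root = root)
}

#' Write a disease DAG in the MEDIC TSV dialect
#'
#' Emits `DiseaseID`, `DiseaseName`, `AltDiseaseIDs`, `ParentIDs` (multi
#' values joined with `"|"`) so [parse_medic()] round-trips the DAG.
#'
#' @param dag A `disease_dag`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(dag, path) {
  t <- dag$terms
  lines <- c("DiseaseID\tDiseaseName\tAltDiseaseIDs\tParentIDs",
             sprintf("%s\t%s\t%s\t%s", t$disease_id, t$name,
                     vapply(t$alt_ids, paste, character(1), collapse = "|"),
                     vapply(t$parent_ids, paste, character(1), collapse = "|")))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Generate association corpora with planted cluster structure
#'
#' Each source gets its own disjoint entity universe and covers a random
#' subset of the labeled diseases (every category keeps at least one
#' covered disease). Each entity is assigned a home category; each record
#' pairs a uniformly drawn entity with a disease drawn from its home
#' category with probability `within_cluster_bias`, otherwise uniformly
#' from the covered diseases of the other categories.
#'
#' @param cfg A `synth_config`.
#' @param vocab Result of [generate_vocabulary()].
#' @return List of association tibbles (`entity_id`, `disease_id`) with
#'   attributes `source_name` and `covered` (the disease subset).
#' @export
generate_associations <- function(cfg, vocab) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$records_per_source <= 0) {
    abort("records_per_source must be positive", class = "dsim_config_error")
  }
  labels <- vocab$labels
  set.seed(cfg$seed + 1L)
  lapply(seq_len(cfg$n_sources), function(s) {
    ids <- names(labels)
    covered <- sort(sample(ids, max(2, round(cfg$coverage[[s]] * length(ids)))))
    # keep every category represented
    for (c in unique(labels)) {
      in_cat <- ids[labels == c]
      if (!any(in_cat %in% covered)) covered <- sort(c(covered, sample(in_cat, 1)))
    }
    cov_lab <- labels[covered]
    entities <- sprintf("S%d_E%04d", s, seq_len(cfg$entities_per_source))
    home <- sample(unique(labels), cfg$entities_per_source, replace = TRUE)
    e_idx <- sample.int(cfg$entities_per_source, cfg$records_per_source,
                        replace = TRUE)
    within <- runif(cfg$records_per_source) < cfg$within_cluster_bias
    disease <- character(cfg$records_per_source)
    for (c in unique(labels)) {
      inside <- covered[cov_lab == c]
      outside <- covered[cov_lab != c]
      sel_in <- which(within & home[e_idx] == c)
      sel_out <- which(!within & home[e_idx] == c)
      if (length(sel_in) > 0) disease[sel_in] <- sample(inside, length(sel_in), replace = TRUE)
      if (length(sel_out) > 0) disease[sel_out] <- sample(outside, length(sel_out), replace = TRUE)
    }
    out <- tibble::tibble(entity_id = entities[e_idx], disease_id = disease)
    attr(out, "source_name") <- paste0("source_", s)
    attr(out, "covered") <- covered
    attr(out, "home_category") <- rlang::set_names(home, entities)
    out
  })
}

#' Write an association corpus as TSV
#'
#' Two columns `EntityID`, `DiseaseID` behind a CTD-style `#` comment
#' header; read back with
#' `read_associations(path, entity_col = "EntityID")`.
#'
#' @param assoc Association tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  lines <- c(paste0("# synthetic association corpus: ",
                    attr(assoc, "source_name") %||% "assoc"),
             "EntityID\tDiseaseID",
             sprintf("%s\t%s", assoc$entity_id, assoc$disease_id))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Generate a benchmark of positive and random negative pairs
#'
#' Positives are sampled from within-category disease pairs (the planted
#' "known related" pairs, analogous to a curated benchmark of highly
#' similar diseases); negatives from between-category pairs. The two sets
#' never overlap.
#'
#' @param labels Named character vector id -> category.
#' @param n_pos,n_neg Pair counts (defaults 40 and 500, the usual
#'   benchmark-vs-random sizes).
#' @param seed Integer seed.
#' @param ids Disease ids eligible for pairs (default: all labeled).
#' @return A `benchmark_set`.
#' @export
generate_benchmark <- function(labels, n_pos = 40, n_neg = 500, seed = 0L,
                               ids = names(labels)) {
  labels <- labels[ids]
  set.seed(seed)
  by_cat <- split(names(labels), labels)
  within <- dplyr::bind_rows(lapply(by_cat, function(v) {
    if (length(v) < 2) return(NULL)
    cmb <- utils::combn(sort(v), 2)
    tibble::tibble(id1 = cmb[1, ], id2 = cmb[2, ])
  }))
  if (nrow(within) < n_pos) {
    abort("not enough within-category pairs for the requested positives",
          class = "dsim_config_error")
  }
  pos <- within[sample.int(nrow(within), n_pos), ]

  # rejection-sample between-category pairs (they vastly outnumber n_neg)
  n_between <- (choose(length(labels), 2) - nrow(within))
  if (n_between < n_neg) {
    abort("not enough between-category pairs for the requested negatives",
          class = "dsim_config_error")
  }
  neg <- tibble::tibble(id1 = character(), id2 = character())
  guard <- 0L
  while (nrow(neg) < n_neg) {
    guard <- guard + 1L
    if (guard > 1000L) {
      abort("not enough between-category pairs for the requested negatives",
            class = "dsim_config_error")
    }
    a <- sample(names(labels), 2 * n_neg, replace = TRUE)
    b <- sample(names(labels), 2 * n_neg, replace = TRUE)
    ok <- a != b & labels[a] != labels[b]
    cand <- tibble::tibble(id1 = pmin(a[ok], b[ok]), id2 = pmax(a[ok], b[ok]))
    neg <- dplyr::distinct(dplyr::bind_rows(neg, cand))
    neg <- neg[!(pair_keys(neg) %in% pair_keys(pos)), ]
  }
  neg <- neg[seq_len(n_neg), ]
  new_benchmark_set(pos, neg)
}

#' Generate a complete synthetic study
#'
#' One call producing everything the pipeline consumes: vocabulary,
#' association corpora, benchmark, and the ground-truth category labels.
#'
#' @param cfg A `synth_config`.
#' @param n_pos,n_neg Benchmark sizes (defaults 40 / 500).
#' @return List with `dag`, `labels`, `associations`, `benchmark`, `cfg`.
#' @export
generate_study <- function(cfg = synth_config(), n_pos = 40, n_neg = 500) {
  vocab <- generate_vocabulary(cfg)
  assoc <- generate_associations(cfg, vocab)
  covered_union <- sort(unique(unlist(lapply(assoc, attr, "covered"))))
  bench <- generate_benchmark(vocab$labels, n_pos = n_pos, n_neg = n_neg,
                              seed = cfg$seed + 2L, ids = covered_union)
  list(dag = vocab$dag, labels = vocab$labels, associations = assoc,
       benchmark = bench, cfg = cfg)
}

#' Write a full synthetic fixture set to a directory
#'
#' Writes the vocabulary, one association TSV per source, the benchmark
#' TSV, and the ground-truth label map.
#'
#' @param study Result of [generate_study()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vocabulary = file.path(outdir, "vocabulary.tsv"))
  write_vocabulary(study$dag, paths[["vocabulary"]])
  for (s in seq_along(study$associations)) {
    p <- file.path(outdir, sprintf("associations_source_%d.tsv", s))
    write_associations(study$associations[[s]], p)
    paths[[paste0("associations_", s)]] <- p
  }
  paths[["benchmark"]] <- file.path(outdir, "benchmark.tsv")
  write_benchmark_tsv(study$benchmark, paths[["benchmark"]])
  paths[["labels"]] <- file.path(outdir, "labels.tsv")
  readr::write_tsv(tibble::tibble(disease_id = names(study$labels),
                                  category = unname(study$labels)),
                   paths[["labels"]], progress = FALSE)
  invisible(paths)
}
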