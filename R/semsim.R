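#' Read a disease-association table
#'
#' Reads a tab- or comma-separated association corpus (gene-disease,
#' GO-BP-disease, symptom-disease, ...) into the two columns the similarity
#' computation needs: an entity id and a `DiseaseID`. Column names are
#' configurable so the 9-field CTD gene-disease dialect works out of the box
#' (`entity_col = "GeneID"`, `disease_col = "DiseaseID"`). CTD-style `"#"`
#' comment headers are tolerated.
#'
#' @param path Path to the association file.
#' @param entity_col,disease_col Names of the entity and disease id columns.
#' @param source_name Label for the source (defaults to the file name).
#' @param dedupe If `TRUE`, identical (entity, disease) pairs are counted
#'   once; by default every record row contributes to the frequency counts.
#' @return A tibble with columns `entity_id`, `disease_id` and attributes
#'   `source_name`.
#' @export
read_associations <- function(path, entity_col = "GeneID",
                              disease_col = "DiseaseID",
                              source_name = NULL, dedupe = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("association file not found: ", path), class = "dsim_io_error")
  }
  tbl <- read_delim_commented_assoc(path, c(entity_col, disease_col))
  out <- tibble::tibble(
    entity_id = tbl[[entity_col]],
    disease_id = tbl[[disease_col]]
  )
  if (dedupe) out <- dplyr::distinct(out)
  attr(out, "source_name") <- source_name %||% basename(path)
  out
}

read_delim_commented_assoc <- function(path, required) {
  lines <- readr::read_lines(path)
  is_comment <- startsWith(lines, "#")
  body <- lines[!is_comment]
  comments <- lines[is_comment]
  header_line <- NULL
  has_all <- function(l) all(vapply(required, grepl, logical(1), x = l, fixed = TRUE))
  if (length(body) > 0 && has_all(body[[1]])) {
    header_line <- body[[1]]
    body <- body[-1]
  } else if (length(comments) > 0) {
    cand <- sub("^#+\\s*", "", comments)
    hit <- vapply(cand, has_all, logical(1))
    if (any(hit)) header_line <- cand[[max(which(hit))]]
  }
  if (is.null(header_line)) {
    abort(paste0("could not locate a header naming column(s): ",
                 paste(required, collapse = ", ")),
          class = "dsim_format_error")
  }
  delim <- if (lengths(regmatches(header_line, gregexpr("\t", header_line))) >=
               lengths(regmatches(header_line, gregexpr(",", header_line)))) "\t" else ","
  txt <- paste(c(header_line, body), collapse = "\n")
  tbl <- readr::read_delim(I(txt), delim = delim,
                           col_types = readr::cols(.default = "c"),
                           na = character(), progress = FALSE)
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("association file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "dsim_format_error")
  }
  tbl
}

#' Per-source term frequencies and occurrence probabilities
#'
#' For one association corpus, counts how often each disease term occurs
#' (`self`), propagates counts up the DAG (`freq`: a term's own occurrences
#' plus those of all its *distinct* strict descendants, so terms reachable by
#' several paths are counted once), and converts them to occurrence
#' probabilities `prob = freq / N`, where `N` is the total record count (the
#' frequency of the DAG's root, or of a virtual super-root when the
#' vocabulary has several roots). The information content of a term is
#' `-log(prob)`; rarer, more specific terms carry more information.
#'
#' Association records whose disease id does not resolve in the vocabulary
#' (directly or via an alternative id) are excluded and counted in the
#' `n_unresolved` attribute.
#'
#' @param assoc Association tibble with a `disease_id` column (see
#'   [read_associations()]), or any data frame with that column.
#' @param dag A `disease_dag`.
#' @return A tibble with columns `disease_id`, `self_n`, `freq`, `prob`, and
#'   attributes `n_total` (N), `n_unresolved`, `source_name`.
#' @export
count_frequencies <- function(assoc, dag) {
  if (!"disease_id" %in% names(assoc)) {
    abort("`assoc` must have a disease_id column", class = "dsim_format_error")
  }
  resolved <- resolve_ids(dag, assoc$disease_id)
  n_unresolved <- sum(is.na(resolved))
  resolved <- resolved[!is.na(resolved)]
  if (length(resolved) == 0) {
    abort("association set resolves to zero records; cannot derive probabilities",
          class = "dsim_validation_error")
  }
  ids <- dag_ids(dag)
  self_n <- tabulate(match(resolved, ids), nbins = length(ids))
  names(self_n) <- ids

  # f(t) = self(t) + sum of self over distinct strict descendants of t
  freq <- vapply(ids, function(t) {
    self_n[[t]] + sum(self_n[descendants(dag, t)])
  }, numeric(1))
  n_total <- length(resolved)

  out <- tibble::tibble(
    disease_id = ids,
    self_n = as.integer(self_n),
    freq = as.integer(freq),
    prob = freq / n_total
  )
  attr(out, "n_total") <- n_total
  attr(out, "n_unresolved") <- n_unresolved
  attr(out, "source_name") <- attr(assoc, "source_name") %||% "assoc"
  class(out) <- c("dsim_freq", class(out))
  out
}

#' Occurrence probability of a term
#'
#' @param ft Frequency table from [count_frequencies()].
#' @param t Disease id.
#' @return `prob(t) = f(t) / N`, in `[0, 1]`.
#' @export
term_probability <- function(ft, t) {
  i <- match(t, ft$disease_id)
  if (anyNA(i)) {
    abort(paste0("unknown disease id(s): ",
                 paste(t[is.na(i)], collapse = ", ")),
          class = "dsim_lookup_error")
  }
  ft$prob[i]
}

#' Lin information-content similarity of two disease terms
#'
#' `Score(t1, t2) = max over t in LCA(t1, t2) of
#' 2 * log prob(t) / (log prob(t1) + log prob(t2))`, the ratio of the shared
#' information content (at the most informative least common ancestor) to
#' the terms' own information content. Scores lie in `[0, 1]`.
#'
#' Degenerate cases: an empty LCA set (terms under disjoint roots) scores 0;
#' if either probability is 0 the score is 0; if both probabilities are 1
#' (no information) the score is 1 for `t1 == t2` and 0 otherwise.
#'
#' @param ft Frequency table from [count_frequencies()].
#' @param dag The `disease_dag` the table was computed on.
#' @param t1,t2 Disease ids.
#' @return Similarity in `[0, 1]`.
#' @export
lin_score <- function(ft, dag, t1, t2) {
  p1 <- term_probability(ft, t1)
  p2 <- term_probability(ft, t2)
  if (p1 == 0 || p2 == 0) return(0)
  denom <- log(p1) + log(p2)
  if (denom == 0) return(if (identical(t1, t2)) 1 else 0)
  lca <- least_common_ancestors(dag, t1, t2)
  if (length(lca) == 0) return(0)
  p_lca <- term_probability(ft, lca)
  score <- max(2 * log(p_lca) / denom)
  min(max(score, 0), 1)
}

#' Build a per-source disease similarity network
#'
#' Computes Lin similarity for every unordered pair of `node_ids` and keeps
#' pairs with score strictly above `threshold` as weighted edges. Weights
#' are symmetric and in `[0, 1]`; self-edges are excluded (a term's
#' similarity to itself is 1 by convention).
#'
#' Internally the max over least common ancestors is taken over all common
#' ancestors: occurrence probability is monotone non-decreasing from child
#' to parent, so the maximizing ancestor is always a minimal one and the two
#' formulations agree (a property the test-suite checks pair by pair).
#'
#' @param ft Frequency table from [count_frequencies()].
#' @param dag The `disease_dag`.
#' @param node_ids Diseases to include (default: all terms with `prob > 0`).
#' @param threshold Minimum similarity for an edge (strict; default 0).
#' @return A `dsim_network`: a tibble of edges `id1`, `id2`, `weight`
#'   (lexicographic `id1 < id2`, deterministic order) with attributes
#'   `node_ids`, `source_name`, `threshold`.
#' @export
build_similarity_network <- function(ft, dag, node_ids = NULL, threshold = 0) {
  if (is.null(node_ids)) node_ids <- ft$disease_id[ft$prob > 0]
  if (length(node_ids) < 2) {
    abort("need at least 2 nodes to build a similarity network",
          class = "dsim_validation_error")
  }
  assert_in_dag(dag, node_ids)
  A <- ancestor_matrix(dag)[node_ids, dag_ids(dag), drop = FALSE]
  logp <- log(rlang::set_names(ft$prob, ft$disease_id))[colnames(A)]
  n <- length(node_ids)
  logp_node <- logp[node_ids]

  edges <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    anc_i <- which(A[i, ])
    js <- (i + 1L):n
    # most negative log-prob among common ancestors == most informative LCA
    sub <- A[js, anc_i, drop = FALSE]
    lp <- matrix(logp[anc_i], nrow = length(js), ncol = length(anc_i), byrow = TRUE)
    lp[!sub] <- NA_real_
    best <- suppressWarnings(apply(lp, 1L, min, na.rm = TRUE)) # Inf when no common anc
    denom <- logp_node[[i]] + logp_node[js]
    score <- ifelse(is.finite(best) & is.finite(denom) & denom < 0,
                    2 * best / denom, 0)
    # both probs 1 (denom == 0) or either prob 0 (denom == -Inf): score 0 off-diagonal
    score[!is.finite(score)] <- 0
    score <- pmin(pmax(score, 0), 1)
    keep <- score > threshold
    if (any(keep)) {
      edges[[i]] <- tibble::tibble(id1 = node_ids[[i]],
                                   id2 = node_ids[js[keep]],
                                   weight = unname(score[keep]))
    }
  }
  out <- dplyr::bind_rows(edges)
  if (nrow(out) == 0) out <- tibble::tibble(id1 = character(), id2 = character(),
                                            weight = numeric())
  swap <- out$id1 > out$id2
  if (any(swap)) {
    tmp <- out$id1[swap]; out$id1[swap] <- out$id2[swap]; out$id2[swap] <- tmp
  }
  out <- dplyr::arrange(out, .data$id1, .data$id2)
  new_dsim_network(out, node_ids = node_ids,
                   source_name = attr(ft, "source_name") %||% "assoc",
                   threshold = threshold)
}

new_dsim_network <- function(edges, node_ids, source_name = "net", threshold = 0) {
  attr(edges, "node_ids") <- node_ids
  attr(edges, "source_name") <- source_name
  attr(edges, "threshold") <- threshold
  class(edges) <- unique(c("dsim_network", class(edges)))
  edges
}

#' Nodes of a similarity network
#' @param net A `dsim_network`.
#' @return Character vector of node ids.
#' @export
network_nodes <- function(net) attr(net, "node_ids")

#' Dense weight matrix of a similarity network
#'
#' @param net A `dsim_network`.
#' @param node_ids Node universe for the matrix (default: the network's own
#'   nodes). Nodes without edges get zero rows/columns.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
network_matrix <- function(net, node_ids = NULL) {
  node_ids <- node_ids %||% network_nodes(net)
  n <- length(node_ids)
  W <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
  keep <- net$id1 %in% node_ids & net$id2 %in% node_ids
  e <- net[keep, , drop = FALSE]
  if (nrow(e) > 0) {
    W[cbind(e$id1, e$id2)] <- e$weight
    W[cbind(e$id2, e$id1)] <- e$weight
  }
  W
}

#' Write / read a similarity network as a 3-column edge list
#'
#' Tab-separated `id1  id2  weight`, weights printed with 6 decimal places,
#' edges in deterministic lexicographic order. A `#nodes=` comment header
#' preserves isolated nodes across the round-trip.
#'
#' @param net A `dsim_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  hdr <- paste0("#nodes=", paste(network_nodes(net), collapse = "|"),
                " source=", attr(net, "source_name"))
  lines <- c(hdr, "id1\tid2\tweight",
             sprintf("%s\t%s\t%.6f", net$id1, net$id2, net$weight))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  lines <- readr::read_lines(path)
  nodes <- NULL; src <- basename(path)
  hdr <- lines[startsWith(lines, "#")]
  if (length(hdr) > 0 && grepl("^#nodes=", hdr[[1]])) {
    meta <- sub("^#nodes=", "", hdr[[1]])
    nodes <- strsplit(sub(" source=.*$", "", meta), "|", fixed = TRUE)[[1]]
    if (grepl(" source=", meta)) src <- sub("^.* source=", "", meta)
  }
  body <- lines[!startsWith(lines, "#")]
  tbl <- readr::read_tsv(I(paste(body, collapse = "\n")),
                         col_types = "ccd", progress = FALSE)
  names(tbl) <- c("id1", "id2", "weight")
  new_dsim_network(tbl, node_ids = nodes %||% sort(unique(c(tbl$id1, tbl$id2))),
                   source_name = src)
}
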