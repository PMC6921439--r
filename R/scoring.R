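#' Cosine similarity of two feature vectors
#'
#' `sum(x * y) / (||x|| * ||y||)`, clamped to `[-1, 1]`. A zero vector
#' yields score 0 with a warning (its direction is undefined).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) {
    abort("vectors must have the same dimension", class = "dsim_validation_error")
  }
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warn("cosine similarity of a zero vector is defined as 0")
    return(0)
  }
  min(max(sum(x * y) / (nx * ny), -1), 1)
}

#' Score disease pairs by embedding cosine similarity
#'
#' The similarity of two diseases is the cosine of their learned feature
#' vectors. Raw cosine lies in `[-1, 1]`; set `rescale = TRUE` to map it to
#' `[0, 1]` via `(c + 1) / 2`.
#'
#' @param model A `dsim_embedding`.
#' @param pairs Data frame (or tibble) whose first two columns are disease
#'   ids, or a 2-column character matrix.
#' @param rescale Rescale scores from `[-1, 1]` to `[0, 1]`? Default `FALSE`.
#' @return A tibble `id1`, `id2`, `score` (one row per input pair, same
#'   order), with attribute `rescaled`.
#' @export
score_pairs <- function(model, pairs, rescale = FALSE) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0) {
    out <- tibble::tibble(id1 = character(), id2 = character(), score = numeric())
    attr(out, "rescaled") <- rescale
    return(out)
  }
  id1 <- as.character(pairs[[1]]); id2 <- as.character(pairs[[2]])
  bad <- setdiff(unique(c(id1, id2)), model$node_ids)
  if (length(bad) > 0) {
    abort(paste0("id(s) absent from the embedding: ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "dsim_lookup_error")
  }
  X <- model$X
  norms <- sqrt(rowSums(X^2))
  i <- match(id1, model$node_ids); j <- match(id2, model$node_ids)
  dots <- rowSums(X[i, , drop = FALSE] * X[j, , drop = FALSE])
  denom <- norms[i] * norms[j]
  if (any(denom == 0)) warn("cosine similarity of a zero vector is defined as 0")
  score <- ifelse(denom == 0, 0, pmin(pmax(dots / denom, -1), 1))
  if (rescale) score <- (score + 1) / 2
  out <- tibble::tibble(id1 = id1, id2 = id2, score = unname(score))
  attr(out, "rescaled") <- rescale
  out
}

#' All-pairs similarity from an embedding
#'
#' @param model A `dsim_embedding`.
#' @param rescale As in [score_pairs()].
#' @return Tibble of all unordered non-self pairs `id1 < id2` with scores.
#' @export
score_all_pairs <- function(model, rescale = FALSE) {
  ids <- sort(model$node_ids)
  n <- length(ids)
  if (n < 2) abort("need at least 2 nodes", class = "dsim_validation_error")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  score_pairs(model, tibble::tibble(id1 = ids[idx[, 1]], id2 = ids[idx[, 2]]),
              rescale = rescale)
}

#' Top-quantile similarity network and its statistics
#'
#' Scores all unordered non-self disease pairs, keeps the top
#' `ceiling(fraction * n_pairs)` by score (ties at the cutoff are all
#' kept), and returns the induced network together with summary statistics:
#' node and edge counts, the maximum-degree node, and connected-component
#' sizes. With `fraction = 0.003` this reproduces the "top-ranking 0.3%"
#' network export.
#'
#' @param model A `dsim_embedding`.
#' @param fraction Fraction of pairs to keep, in `(0, 1]`.
#' @param rescale As in [score_pairs()].
#' @return A list with `network` (a `dsim_network` of the kept edges),
#'   `stats` (one-row tibble: `n_nodes`, `n_edges`, `max_degree`,
#'   `max_degree_node`, `n_components`, `largest_component`) and
#'   `component_sizes` (integer vector, decreasing).
#' @export
top_quantile_network <- function(model, fraction = 0.003, rescale = FALSE) {
  if (fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]", class = "dsim_validation_error")
  }
  scores <- score_all_pairs(model, rescale = rescale)
  k <- ceiling(fraction * nrow(scores))
  ord <- order(-scores$score, scores$id1, scores$id2)
  cutoff <- scores$score[ord[k]]
  keep <- scores$score >= cutoff
  edges <- scores[keep, , drop = FALSE]
  names(edges)[3] <- "weight"
  edges <- dplyr::arrange(edges, .data$id1, .data$id2)
  net <- new_dsim_network(edges, node_ids = sort(unique(c(edges$id1, edges$id2))),
                          source_name = "top_quantile")

  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = network_nodes(net)))
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  stats <- tibble::tibble(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    max_degree = max(deg),
    max_degree_node = names(deg)[which.max(deg)],
    n_components = comp$no,
    largest_component = max(comp$csize)
  )
  list(network = net, stats = stats,
       component_sizes = sort(as.integer(comp$csize), decreasing = TRUE))
}

#' Write ranked pair scores as TSV
#'
#' 3 columns `id1  id2  score`, sorted descending by score with a stable
#' lexicographic tie-break; a comment header records whether scores were
#' rescaled to `[0, 1]`.
#'
#' @param scores Tibble from [score_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  ord <- order(-scores$score, scores$id1, scores$id2)
  s <- scores[ord, , drop = FALSE]
  hdr <- paste0("#rescaled=", isTRUE(attr(scores, "rescaled")))
  lines <- c(hdr, "id1\tid2\tscore",
             sprintf("%s\t%s\t%.6f", s$id1, s$id2, s$score))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path) {
  lines <- readr::read_lines(path)
  body <- lines[!startsWith(lines, "#")]
  tbl <- readr::read_tsv(I(paste(body, collapse = "\n")),
                         col_types = "ccd", progress = FALSE)
  names(tbl) <- c("id1", "id2", "score")
  tbl
}
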