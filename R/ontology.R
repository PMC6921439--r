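#' Parse a MEDIC-style disease vocabulary into a disease DAG
#'
#' Reads a tab- or comma-separated disease vocabulary in the MEDIC dialect
#' (the merged MeSH + OMIM vocabulary distributed by CTD) and builds the
#' directed acyclic graph of disease terms used for semantic similarity.
#' Only four columns are used: `DiseaseID`, `DiseaseName`, `AltDiseaseIDs`
#' and `ParentIDs`; any extra columns are ignored. Multi-valued fields are
#' split on `"|"`. Comment lines starting with `"#"` are tolerated; if the
#' column names themselves live in a comment line (the CTD convention) that
#' line is used as the header.
#'
#' Parent references that do not resolve to a term in the vocabulary are
#' dropped with a warning; rows with an empty `DiseaseID` are skipped.
#' Terms with no (resolvable) parents become roots; multiple roots are
#' permitted, mirroring the multiple top-level trees of MeSH category C.
#'
#' @param path Path to the vocabulary file.
#' @return A `disease_dag` object: a list with
#'   \describe{
#'     \item{terms}{tibble with columns `disease_id`, `name`, `alt_ids`
#'       (list-column), `parent_ids` (list-column of resolved parents)}
#'     \item{graph}{an [igraph][igraph::graph_from_data_frame] directed graph
#'       with child-to-parent edges}
#'     \item{roots}{character vector of terms with no parents}
#'     \item{alt_index}{named character vector mapping alternative ids to
#'       primary ids}
#'     \item{n_dropped_edges, n_skipped_rows}{data-hygiene counters}
#'   }
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("DiseaseID\tDiseaseName\tAltDiseaseIDs\tParentIDs",
#'              "MESH:R\tRoot\t\t",
#'              "MESH:A\tDisease A\tOMIM:1\tMESH:R",
#'              "MESH:B\tDisease B\t\tMESH:R"), tf)
#' dag <- parse_medic(tf)
#' dag$roots
#' @export
parse_medic <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("vocabulary file not found: ", path), class = "dsim_io_error")
  }
  tbl <- read_delim_commented(path)
  required <- c("DiseaseID", "DiseaseName", "AltDiseaseIDs", "ParentIDs")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("vocabulary is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "dsim_format_error")
  }
  tbl <- tbl[required]
  names(tbl) <- c("disease_id", "name", "alt_ids", "parent_ids")
  tbl$disease_id <- trimws(tbl$disease_id)

  blank <- is.na(tbl$disease_id) | tbl$disease_id == ""
  n_skipped <- sum(blank)
  if (n_skipped > 0) {
    inform(paste0("parse_medic: skipped ", n_skipped, " row(s) with empty DiseaseID"))
    tbl <- tbl[!blank, , drop = FALSE]
  }
  if (anyDuplicated(tbl$disease_id)) {
    dup <- unique(tbl$disease_id[duplicated(tbl$disease_id)])
    abort(paste0("duplicate DiseaseID(s): ", paste(head(dup, 5), collapse = ", ")),
          class = "dsim_format_error")
  }

  terms <- tibble::tibble(
    disease_id = tbl$disease_id,
    name = ifelse(is.na(tbl$name), "", tbl$name),
    alt_ids = split_multi(tbl$alt_ids),
    parent_ids = split_multi(tbl$parent_ids)
  )
  new_disease_dag(terms)
}

# split "a|b|c" fields into character vectors, dropping empties
split_multi <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || v == "") return(character(0))
    out <- trimws(strsplit(v, "|", fixed = TRUE)[[1]])
    unique(out[out != ""])
  })
}

# Reader for CTD-style delimited text: "#" comment lines allowed, and the
# header may itself be the last comment line; tab vs comma auto-detected.
read_delim_commented <- function(path) {
  lines <- readr::read_lines(path)
  is_comment <- startsWith(lines, "#")
  body <- lines[!is_comment]
  comments <- lines[is_comment]
  header_line <- NULL
  if (length(body) > 0 && grepl("DiseaseID|disease_id", body[[1]])) {
    header_line <- body[[1]]
    body <- body[-1]
  } else if (length(comments) > 0) {
    cand <- sub("^#+\\s*", "", comments)
    hit <- grepl("DiseaseID", cand)
    if (any(hit)) header_line <- cand[[max(which(hit))]]
  }
  if (is.null(header_line)) {
    abort("could not locate a header row naming DiseaseID", class = "dsim_format_error")
  }
  delim <- if (lengths(regmatches(header_line, gregexpr("\t", header_line))) >=
               lengths(regmatches(header_line, gregexpr(",", header_line)))) "\t" else ","
  txt <- paste(c(header_line, body), collapse = "\n")
  readr::read_delim(I(txt), delim = delim, col_types = readr::cols(.default = "c"),
                    na = character(), progress = FALSE)
}

# Construct + validate the DAG from a terms tibble (internal; also used by
# the synthetic generator so round-trips share one validation path).
new_disease_dag <- function(terms) {
  ids <- terms$disease_id
  known <- rlang::set_names(seq_along(ids), ids)

  n_dropped <- 0L
  resolved_parents <- lapply(seq_along(ids), function(i) {
    p <- setdiff(terms$parent_ids[[i]], ids[[i]]) # self-parent dropped silently
    ok <- p %in% ids
    n_dropped <<- n_dropped + sum(!ok)
    unique(p[ok])
  })
  if (n_dropped > 0) {
    warn(paste0("parse_medic: dropped ", n_dropped,
                " parent reference(s) not present in the vocabulary"))
  }
  terms$parent_ids <- resolved_parents

  edges <- tibble::tibble(
    child = rep(ids, lengths(resolved_parents)),
    parent = unlist(resolved_parents, use.names = FALSE)
  )
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) {
    cyc <- find_one_cycle(g)
    abort(paste0("vocabulary graph contains a cycle: ",
                 paste(cyc, collapse = " -> ")),
          class = "dsim_validation_error")
  }
  roots <- ids[lengths(resolved_parents) == 0]
  if (length(roots) == 0) {
    abort("vocabulary has no root term", class = "dsim_validation_error")
  }

  alt <- unlist(lapply(seq_along(ids), function(i) {
    a <- setdiff(terms$alt_ids[[i]], ids)
    rlang::set_names(rep(ids[[i]], length(a)), a)
  }))
  alt <- alt[!duplicated(names(alt))]

  structure(
    list(terms = terms, graph = g, roots = roots,
         alt_index = alt %||% rlang::set_names(character(0), character(0)),
         n_dropped_edges = n_dropped, n_skipped_rows = 0L),
    class = "disease_dag"
  )
}

find_one_cycle <- function(g) {
  # report one feedback cycle for the error message
  for (v in igraph::V(g)$name) {
    reach <- igraph::subcomponent(g, v, mode = "out")$name
    for (u in setdiff(reach, v)) {
      if (v %in% igraph::subcomponent(g, u, mode = "out")$name) {
        p <- igraph::shortest_paths(g, v, u, mode = "out")$vpath[[1]]$name
        return(c(p, v))
      }
    }
  }
  character(0)
}

#' @export
print.disease_dag <- function(x, ...) {
  cat("<disease_dag> ", nrow(x$terms), " terms, ",
      igraph::ecount(x$graph), " child->parent edges, ",
      length(x$roots), " root(s)\n", sep = "")
  invisible(x)
}

#' @export
format.disease_dag <- function(x, ...) {
  paste0("<disease_dag: ", nrow(x$terms), " terms>")
}

dag_ids <- function(dag) dag$terms$disease_id

assert_in_dag <- function(dag, ids) {
  bad <- setdiff(ids, dag_ids(dag))
  if (length(bad) > 0) {
    abort(paste0("unknown disease id(s): ", paste(head(bad, 5), collapse = ", ")),
          class = "dsim_lookup_error")
  }
}

#' Resolve a disease identifier through the alternative-id index
#'
#' Association files may reference a disease by an alternative identifier
#' (e.g. an OMIM id merged into a MeSH term); those resolve to the primary
#' term. Unresolvable ids come back as `NA`.
#'
#' @param dag A `disease_dag`.
#' @param ids Character vector of disease ids.
#' @return Character vector of primary ids (`NA` where unresolvable).
#' @export
resolve_ids <- function(dag, ids) {
  out <- ifelse(ids %in% dag_ids(dag), ids, unname(dag$alt_index[ids]))
  as.character(out)
}

#' Map disease names to vocabulary identifiers
#'
#' Exact, case-insensitive match on `DiseaseName` (used, e.g., to map the
#' disease names of a symptom-disease corpus onto vocabulary ids).
#' Unmatched names are returned, never silently dropped.
#'
#' @param names Character vector of disease names.
#' @param dag A `disease_dag`.
#' @return A list with `mapped` (tibble `name`, `disease_id`) and
#'   `unmapped` (character vector).
#' @export
map_names_to_ids <- function(names, dag) {
  lut <- rlang::set_names(dag$terms$disease_id, tolower(dag$terms$name))
  lut <- lut[!duplicated(names(lut))]
  hit <- unname(lut[tolower(names)])
  list(
    mapped = tibble::tibble(name = names[!is.na(hit)],
                            disease_id = hit[!is.na(hit)]),
    unmapped = names[is.na(hit)]
  )
}

#' Ancestors of a term (inclusive)
#'
#' All terms reachable from `id` along child-to-parent edges, including
#' `id` itself.
#'
#' @param dag A `disease_dag`.
#' @param id A disease id present in the DAG.
#' @return Character vector of ancestor ids (unordered).
#' @export
ancestors <- function(dag, id) {
  assert_in_dag(dag, id)
  igraph::subcomponent(dag$graph, id, mode = "out")$name
}

# strict descendants (terms below t), used by the frequency counts
descendants <- function(dag, id) {
  setdiff(igraph::subcomponent(dag$graph, id, mode = "in")$name, id)
}

#' Least common ancestors of two terms
#'
#' The common ancestors of `t1` and `t2` that are minimal in the ancestor
#' partial order: no other common ancestor is a strict descendant of them.
#' A term is its own ancestor, so `least_common_ancestors(dag, t, t)`
#' is `t`. Terms under disjoint roots share no ancestor and yield an empty
#' set (their similarity is 0 downstream).
#'
#' @param dag A `disease_dag`.
#' @param t1,t2 Disease ids.
#' @return Character vector of least common ancestor ids (possibly empty).
#' @export
least_common_ancestors <- function(dag, t1, t2) {
  assert_in_dag(dag, c(t1, t2))
  common <- intersect(ancestors(dag, t1), ancestors(dag, t2))
  if (length(common) <= 1) return(common)
  # minimality: a is least iff no other common ancestor is a strict descendant of a
  keep <- vapply(common, function(a) {
    length(intersect(descendants(dag, a), common)) == 0
  }, logical(1))
  common[keep]
}

#' Ancestor indicator matrix
#'
#' Logical n-by-n matrix `A` with `A[i, k] = TRUE` iff term `k` is an
#' (inclusive) ancestor of term `i`. Used to vectorize all-pairs Lin
#' similarity.
#'
#' @param dag A `disease_dag`.
#' @return Logical matrix with dimnames set to the term ids.
#' @export
ancestor_matrix <- function(dag) {
  ids <- dag_ids(dag)
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    A[i, igraph::subcomponent(dag$graph, ids[[i]], mode = "out")$name] <- TRUE
  }
  A
}

#' Summarize and validate a vocabulary file
#'
#' Convenience wrapper used by the command-line `ontology validate`
#' subcommand: parses the vocabulary and returns node/edge/root counts.
#'
#' @param path Path to a MEDIC-style vocabulary file.
#' @return A one-row tibble with `n_terms`, `n_edges`, `n_roots`,
#'   `acyclic` (always `TRUE` when the call returns), `n_dropped_edges`.
#' @export
validate_vocabulary <- function(path) {
  dag <- parse_medic(path)
  tibble::tibble(
    n_terms = nrow(dag$terms),
    n_edges = igraph::ecount(dag$graph),
    n_roots = length(dag$roots),
    acyclic = TRUE,
    n_dropped_edges = dag$n_dropped_edges
  )
}
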