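# Fixture builders and independent oracles shared across the test files.

# Write a MEDIC-dialect vocabulary from (id, name, alt, parents) rows and
# parse it back, so every toy DAG goes through the real reader.
toy_dag <- function(rows, delim = "\t") {
  tf <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  header <- paste(c("DiseaseID", "DiseaseName", "AltDiseaseIDs", "ParentIDs"),
                  collapse = delim)
  lines <- c(header, vapply(rows, paste, character(1), collapse = delim))
  writeLines(lines, tf)
  parse_medic(tf)
}

row4 <- function(id, name = id, alt = "", parents = "") c(id, name, alt, parents)

# DAG R <- {A, B}: two siblings under one root.
sibling_dag <- function() {
  toy_dag(list(row4("R", "Root"),
               row4("A", "Disease A", parents = "R"),
               row4("B", "Disease B", parents = "R")))
}

# Diamond: C has parents P1 and P2, both children of R.
diamond_dag <- function() {
  toy_dag(list(row4("R"), row4("P1", parents = "R"), row4("P2", parents = "R"),
               row4("C", parents = "P1|P2")))
}

# Random DAG: node i picks 1-2 parents among earlier nodes (node 1 = root).
random_dag <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n))
  rows <- list(row4(ids[[1]]))
  for (i in 2:n) {
    np <- if (runif(1) < 0.2 && i > 2) 2 else 1
    ps <- sample(ids[seq_len(i - 1)], min(np, i - 1))
    rows[[i]] <- row4(ids[[i]], parents = paste(ps, collapse = "|"))
  }
  toy_dag(rows)
}

# records tibble from a named count vector, e.g. c(A = 2, B = 3)
records_from_counts <- function(counts) {
  tibble::tibble(
    entity_id = paste0("e", seq_len(sum(counts))),
    disease_id = rep(names(counts), counts)
  )
}

# --- independent oracles -----------------------------------------------------

# transitive ancestor closure by repeated parent expansion on the terms table
oracle_ancestors <- function(dag, id) {
  parent_of <- rlang::set_names(dag$terms$parent_ids, dag$terms$disease_id)
  out <- id
  repeat {
    nxt <- unique(c(out, unlist(parent_of[out])))
    if (length(nxt) == length(out)) return(sort(out))
    out <- nxt
  }
}

# least common ancestors: common ancestors minus those with a strict
# descendant in the common-ancestor set (descendant test via the oracle above)
oracle_lca <- function(dag, t1, t2) {
  common <- intersect(oracle_ancestors(dag, t1), oracle_ancestors(dag, t2))
  keep <- vapply(common, function(a) {
    others <- setdiff(common, a)
    # least iff no other common ancestor is a strict descendant of a
    !any(vapply(others, function(b) a %in% setdiff(oracle_ancestors(dag, b), b),
                logical(1)))
  }, logical(1))
  sort(common[keep])
}

# f(t) by direct recount: self plus self of every distinct strict descendant
oracle_freq <- function(dag, records) {
  ids <- dag$terms$disease_id
  self_n <- table(factor(records$disease_id, levels = ids))
  vapply(ids, function(t) {
    desc <- setdiff(ids[vapply(ids, function(u) t %in% oracle_ancestors(dag, u),
                               logical(1))], t)
    as.numeric(self_n[[t]] + sum(self_n[desc]))
  }, numeric(1))
}

# direct linear solve of the restart walk fixed point, one row per start node
oracle_rwr <- function(Tm, a) {
  n <- nrow(Tm)
  S <- a * diag(n) %*% solve(diag(n) - (1 - a) * Tm)
  dimnames(S) <- dimnames(Tm)
  S
}

# naive double-loop KL objective
oracle_objective <- function(S_list, X, W_list) {
  n <- nrow(S_list[[1]])
  total <- 0
  for (m in seq_along(S_list)) {
    S <- S_list[[m]]
    for (i in seq_len(n)) {
      z <- as.numeric(X[i, ] %*% t(W_list[[m]]))
      shat <- exp(z - max(z)) / sum(exp(z - max(z)))
      for (j in seq_len(n)) {
        if (S[i, j] > 0) total <- total + S[i, j] * log(S[i, j] / shat[j]) / n
      }
    }
  }
  total
}

# brute-force AUC: fraction of (pos, neg) pairs with pos > neg, ties 1/2
oracle_auc <- function(pos, neg) {
  wins <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(wins)
}

# three noisy similarity networks + benchmark from one planted clustering;
# used by the integration / dimension-stability / contrast tests
planted_study <- function(seed, n_diseases = 200, bias = 0.8) {
  cfg <- synth_config(n_diseases = n_diseases, seed = seed,
                      within_cluster_bias = bias)
  study <- generate_study(cfg)
  study$nets <- lapply(study$associations, function(a) {
    build_similarity_network(count_frequencies(a, study$dag), study$dag)
  })
  study
}
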