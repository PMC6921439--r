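# shared toy networks for the embedding tests
two_clique_nets <- function(noise_seeds = 1) {
  # 12 nodes, two disconnected 6-cliques
  ids <- sprintf("N%02d", 1:12)
  W <- matrix(0, 12, 12, dimnames = list(ids, ids))
  W[1:6, 1:6] <- 1; W[7:12, 7:12] <- 1
  diag(W) <- 0
  lapply(noise_seeds, function(s) {
    set.seed(s)
    Wm <- W * matrix(runif(144, 0.5, 1), 12, 12)
    Wm <- (Wm + t(Wm)) / 2
    e <- which(upper.tri(Wm) & Wm > 0, arr.ind = TRUE)
    new_dsim_network(tibble::tibble(id1 = ids[e[, 1]], id2 = ids[e[, 2]],
                                    weight = Wm[e]),
                     node_ids = ids, source_name = paste0("clique", s))
  })
}

test_that("transition matrix row-normalizes and self-loops isolated nodes", {
  ids <- c("a", "b")
  net <- new_dsim_network(tibble::tibble(id1 = "a", id2 = "b", weight = 0.5),
                          node_ids = ids)
  Tm <- transition_matrix(net)
  expect_equal(unname(Tm), matrix(c(0, 1, 1, 0), 2))

  net3 <- new_dsim_network(tibble::tibble(id1 = "a", id2 = "b", weight = 0.5),
                           node_ids = c("a", "b", "iso"))
  Tm3 <- transition_matrix(net3)
  expect_equal(Tm3["iso", ], c(a = 0, b = 0, iso = 1))

  set.seed(1)
  W <- matrix(runif(9), 3); W <- W + t(W); diag(W) <- 0
  dimnames(W) <- list(letters[1:3], letters[1:3])
  expect_equal(rowSums(transition_matrix(W)), c(a = 1, b = 1, c = 1),
               tolerance = 1e-12)
  W[1, 2] <- -1
  expect_error(transition_matrix(W), class = "dsim_validation_error")
})

test_that("RWR matches the closed-form linear solve and the analytic 2-node case", {
  Tm <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ds <- rwr_diffusion(Tm, a = 0.5)
  expect_equal(unname(ds$S[1, ]), c(2 / 3, 1 / 3), tolerance = 1e-7)
  expect_equal(unname(rowSums(ds$S)), c(1, 1), tolerance = 1e-8)

  # isolated node: diffusion state is the indicator at itself
  ds_iso <- rwr_diffusion(diag(1), a = 0.5)
  expect_equal(unname(ds_iso$S), matrix(1))

  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(5:50, 1)
    W <- matrix(runif(n * n), n); W <- W + t(W); diag(W) <- 0
    W[W < 1] <- 0 # sparsify, may isolate nodes
    dimnames(W) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
    Tm <- transition_matrix(W)
    ds <- rwr_diffusion(Tm, a = 0.5, tol = 1e-10)
    expect_lt(max(abs(ds$S - oracle_rwr(Tm, 0.5))), 1e-6)
    # fixed-point residual per row within tolerance
    resid <- max(rowSums(abs(ds$S - (0.5 * ds$S %*% Tm + 0.5 * diag(n)))))
    expect_lte(resid, 1e-10 + 1e-12)
  }
  expect_error(rwr_diffusion(Tm, a = 0), class = "dsim_validation_error")
  expect_error(rwr_diffusion(matrix(c(1, 1, 0, 1), 2), a = 0.5),
               class = "dsim_validation_error")
})

test_that("softmax model: uniform at zero features, hand case, normalization", {
  X <- matrix(0, 3, 2); W <- matrix(0, 3, 2)
  expect_equal(model_diffusion(X, W, 1), rep(1 / 3, 3))

  X1 <- matrix(1, 1, 1); W1 <- matrix(c(log(3), 0), 2, 1)
  expect_equal(model_diffusion(rbind(X1, 0), W1, 1), c(0.75, 0.25))

  set.seed(2)
  X <- matrix(rnorm(50), 10, 5); W <- matrix(rnorm(50), 10, 5)
  Shat <- dsim:::model_diffusion_all(X, W)
  expect_equal(unname(rowSums(Shat)), rep(1, 10), tolerance = 1e-12)
  expect_error(model_diffusion(X * NA, W, 1), class = "dsim_validation_error")
})

test_that("multi-network objective matches the naive double-loop oracle", {
  set.seed(3)
  n <- 10; d <- 3
  nets <- lapply(1:2, function(m) {
    W <- matrix(runif(n * n), n); W <- W + t(W); diag(W) <- 0
    dimnames(W) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
    rwr_diffusion(transition_matrix(W), a = 0.5)
  })
  X <- matrix(rnorm(n * d), n, d)
  Ws <- lapply(1:2, function(m) matrix(rnorm(n * d), n, d))
  obj <- multi_network_objective(nets, X, Ws)
  expect_equal(obj$value,
               oracle_objective(lapply(nets, function(x) x$S), X, Ws),
               tolerance = 1e-10)
  expect_gte(obj$value, 0)
  expect_length(obj$per_network_kl, 2)

  # exact model: KL is zero. softmax(log s) recovers s row-wise.
  S <- nets[[1]]$S
  Id <- diag(n)
  obj0 <- multi_network_objective(list(nets[[1]]), log(S), list(Id))
  expect_equal(obj0$value, 0, tolerance = 1e-10)

  # additivity: M identical copies give M times the single-network value
  obj3 <- multi_network_objective(rep(list(nets[[1]]), 3), X, rep(list(Ws[[1]]), 3))
  obj1 <- multi_network_objective(list(nets[[1]]), X, list(Ws[[1]]))
  expect_equal(obj3$value, 3 * obj1$value, tolerance = 1e-10)
})

test_that("L-BFGS fit: monotone trace, determinism, objective decreases", {
  nets <- two_clique_nets(1:2)
  S_list <- diffusion_states(nets)
  fit <- fit_embeddings_lbfgs(S_list, d = 4, seed = 42, max_iter = 200)
  expect_true(all(diff(fit$trace) <= 1e-10))
  expect_lt(fit$objective, fit$trace[[1]])
  fit2 <- fit_embeddings_lbfgs(S_list, d = 4, seed = 42, max_iter = 200)
  expect_equal(fit$X, fit2$X, tolerance = 1e-10)
  expect_error(fit_embeddings_lbfgs(S_list, d = 12),
               class = "dsim_validation_error")
})

test_that("both fitters separate the two planted cliques", {
  nets <- two_clique_nets(1)
  S_list <- diffusion_states(nets)
  sep <- function(X) {
    cs <- function(i, j) cosine_similarity(X[i, ], X[j, ])
    within <- c(utils::combn(1:6, 2, function(p) cs(p[1], p[2])),
                utils::combn(7:12, 2, function(p) cs(p[1], p[2])))
    between <- as.numeric(outer(1:6, 7:12, Vectorize(cs)))
    mean(within) - mean(between)
  }
  fit_svd <- fit_embeddings_svd(S_list, d = 4)
  fit_lb <- fit_embeddings_lbfgs(S_list, d = 4, seed = 1, max_iter = 300)
  expect_gt(sep(fit_svd$X), 0)
  expect_gt(sep(fit_lb$X), 0)
})

test_that("SVD fit reconstructs log(S + eps) at full rank and is equivariant", {
  nets <- two_clique_nets(1)
  S <- diffusion_states(nets)[[1]]
  n <- nrow(S$S)
  # row-centering drops the rank by one, so the d = n request warns and
  # returns the n - 1 informative components; reconstruction is still exact
  expect_warning(fit <- fit_embeddings_svd(list(S), d = n), "rank")
  L <- log(S$S + 1 / n)
  expect_lt(max(abs((fit$X %*% t(fit$W[[1]]) + fit$centers[[1]]) - L)), 1e-8)

  # permuting node order permutes the embedding rows
  d <- 4
  fit_d <- fit_embeddings_svd(list(S), d = d)
  set.seed(9)
  perm <- sample(n)
  Sp <- S$S[perm, perm]
  fit_p <- fit_embeddings_svd(list(structure(list(S = Sp, restart_prob = 0.5),
                                             class = "dsim_diffusion")), d = d)
  expect_equal(unname(fit_p$X), unname(fit_d$X[perm, ]), tolerance = 1e-6)

  expect_warning(fit_big <- fit_embeddings_svd(list(structure(
    list(S = matrix(0.25, 4, 4,
                    dimnames = list(letters[1:4], letters[1:4])),
         restart_prob = 0.5), class = "dsim_diffusion")), d = 4),
    "rank")
  expect_lt(fit_big$d, 4)
})

test_that("diffusion states align networks on the union node set", {
  ids_a <- c("x", "y"); ids_b <- c("y", "z")
  na <- new_dsim_network(tibble::tibble(id1 = "x", id2 = "y", weight = 1), ids_a)
  nb <- new_dsim_network(tibble::tibble(id1 = "y", id2 = "z", weight = 1), ids_b)
  S_list <- diffusion_states(list(na, nb), a = 0.5)
  expect_equal(rownames(S_list[[1]]$S), c("x", "y", "z"))
  # z is absent from the first network: near-indicator diffusion state
  expect_equal(unname(S_list[[1]]$S["z", ]), c(0, 0, 1))
})

test_that("embedding TSV round-trips features and header metadata", {
  nets <- two_clique_nets(1)
  fit <- fit_embeddings_svd(diffusion_states(nets), d = 3)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_embedding_tsv(fit, tf)
  expect_match(readLines(tf, n = 1), "^#dim=3 restart=0.5 method=svd$")
  back <- read_embedding_tsv(tf)
  expect_equal(back$node_ids, fit$node_ids)
  expect_equal(unname(back$X), unname(fit$X), tolerance = 1e-9)
  expect_equal(back$d, 3L)
})
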