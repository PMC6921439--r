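#' Row-stochastic transition matrix of a similarity network
#'
#' `T[i, j] = w(i, j) / sum_k w(i, k)`. Nodes with zero degree (isolated in
#' this source, e.g. diseases the source does not cover) get a self-loop
#' (`T[i, i] = 1`) so the random walk is well defined on the union node set.
#'
#' @param net A `dsim_network`, or a symmetric non-negative weight matrix.
#' @param node_ids Node universe (default: the network's nodes). Supplying
#'   the union of several networks' nodes aligns them for integration.
#' @return Row-stochastic matrix with dimnames.
#' @export
transition_matrix <- function(net, node_ids = NULL) {
  W <- if (is.matrix(net)) net else network_matrix(net, node_ids)
  if (any(W < 0)) {
    abort("negative edge weight in similarity network", class = "dsim_validation_error")
  }
  deg <- rowSums(W)
  iso <- deg == 0
  Tm <- W / ifelse(deg == 0, 1, deg)
  if (any(iso)) Tm[cbind(which(iso), which(iso))] <- 1
  Tm
}

#' Random walk with restart: diffusion states
#'
#' Iterates `s_i <- (1 - a) * s_i %*% T + a * e_i` for every start node `i`
#' simultaneously until the L1 change of every row is below `tol`. The fixed
#' point `s_i` — the stationary visiting-probability profile of a walker
#' that restarts at `i` with probability `a` — is node `i`'s "diffusion
#' state". Each row is a probability vector.
#'
#' @param Tm Row-stochastic transition matrix (see [transition_matrix()]).
#' @param a Restart probability in `(0, 1]` (default 0.5).
#' @param tol L1 convergence tolerance per row (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @return A `dsim_diffusion` object: list with `S` (n-by-n matrix, row i =
#'   diffusion state of node i), `node_ids`, `restart_prob`, `iterations`.
#' @export
rwr_diffusion <- function(Tm, a = 0.5, tol = 1e-8, max_iter = 1000) {
  stopifnot(is.matrix(Tm), nrow(Tm) == ncol(Tm))
  if (a <= 0 || a > 1) {
    abort("restart probability must be in (0, 1]", class = "dsim_validation_error")
  }
  rs <- rowSums(Tm)
  if (max(abs(rs - 1)) > 1e-8) {
    abort("transition matrix is not row-stochastic", class = "dsim_validation_error")
  }
  n <- nrow(Tm)
  S <- diag(n)
  E <- diag(n) * a
  for (it in seq_len(max_iter)) {
    S_new <- (1 - a) * (S %*% Tm) + E
    delta <- max(rowSums(abs(S_new - S)))
    S <- S_new
    if (delta <= tol) {
      dimnames(S) <- dimnames(Tm)
      return(structure(list(S = S, node_ids = rownames(Tm) %||% as.character(seq_len(n)),
                            restart_prob = a, iterations = it),
                       class = "dsim_diffusion"))
    }
  }
  abort(paste0("RWR did not converge in ", max_iter,
               " iterations (residual ", signif(delta, 3), ")"),
        class = "dsim_convergence_error")
}

#' @export
print.dsim_diffusion <- function(x, ...) {
  cat("<dsim_diffusion> ", nrow(x$S), " nodes, restart ", x$restart_prob,
      ", converged in ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' Diffusion states for several networks on their union node set
#'
#' Expands each network to the union of all node sets (absent nodes become
#' isolated self-loops whose diffusion state is the indicator vector at the
#' node), then runs [rwr_diffusion()] per network.
#'
#' @param nets List of `dsim_network` objects.
#' @param a,tol,max_iter Passed to [rwr_diffusion()].
#' @return List of `dsim_diffusion` objects sharing `node_ids`.
#' @export
diffusion_states <- function(nets, a = 0.5, tol = 1e-8, max_iter = 1000) {
  if (length(nets) == 0) abort("need at least one network", class = "dsim_validation_error")
  universe <- sort(unique(unlist(lapply(nets, network_nodes))))
  lapply(nets, function(net) {
    rwr_diffusion(transition_matrix(net, node_ids = universe),
                  a = a, tol = tol, max_iter = max_iter)
  })
}

#' Modeled diffusion state (softmax of feature inner products)
#'
#' The low-dimensional model assigns node `j` probability
#' `exp(x_i' w_j) / sum_j' exp(x_i' w_j')` in the diffusion state of node
#' `i`; computed with max-subtraction so large logits cannot overflow.
#'
#' @param X n-by-d node-feature matrix.
#' @param W n-by-d context-feature matrix.
#' @param i Node index (row of `X`).
#' @return Probability vector of length n (sums to 1).
#' @export
model_diffusion <- function(X, W, i) {
  if (!all(is.finite(X)) || !all(is.finite(W))) {
    abort("non-finite entries in X or W", class = "dsim_validation_error")
  }
  z <- as.numeric(W %*% X[i, ])
  z <- z - max(z)
  ez <- exp(z)
  ez / sum(ez)
}

# all rows at once: softmax over rows of X %*% t(W)
model_diffusion_all <- function(X, W) {
  exp(log_model_diffusion_all(X, W))
}

# log softmax, computed stably so downstream log-likelihoods stay finite
# even when some modeled probabilities underflow
log_model_diffusion_all <- function(X, W) {
  Z <- X %*% t(W)
  Z <- Z - apply(Z, 1L, max)
  Z - log(rowSums(exp(Z)))
}

#' Multi-network KL-divergence objective
#'
#' `C = (1/n) * sum_m sum_i KL(s_i^m || shat_i^m)` where `s_i^m` is the
#' observed diffusion state of node `i` in network `m` and `shat_i^m` the
#' softmax model with shared node features `X` and per-network context
#' features `W[[m]]`. The `0 * log(0/q) = 0` convention applies.
#'
#' @param S_list List of `dsim_diffusion` objects (or bare matrices) sharing
#'   node order.
#' @param X Shared n-by-d node-feature matrix.
#' @param W_list List of n-by-d context matrices, one per network.
#' @return A list with `value`, `per_network_kl` (the per-network summands,
#'   each already scaled by 1/n), and `n`.
#' @export
multi_network_objective <- function(S_list, X, W_list) {
  S_list <- lapply(S_list, as_diffusion_matrix)
  if (length(S_list) != length(W_list)) {
    abort("one context matrix per network is required", class = "dsim_validation_error")
  }
  ids <- lapply(S_list, rownames)
  if (length(unique(vapply(ids, paste, character(1), collapse = "\r"))) > 1) {
    abort("diffusion matrices have mismatched node orderings",
          class = "dsim_alignment_error")
  }
  n <- nrow(S_list[[1]])
  per <- mapply(function(S, W) {
    lShat <- log_model_diffusion_all(X, W)
    pos <- S > 0
    sum(S[pos] * (log(S[pos]) - lShat[pos])) / n
  }, S_list, W_list)
  list(value = sum(per), per_network_kl = as.numeric(per), n = n)
}

as_diffusion_matrix <- function(x) {
  if (inherits(x, "dsim_diffusion")) x$S else x
}

# objective + analytic gradient on the flattened parameter vector; used by
# the L-BFGS fitter. theta = c(vec(X), vec(W^1), ..., vec(W^M)).
kl_obj_grad <- function(theta, S_list, n, d, M) {
  X <- matrix(theta[seq_len(n * d)], n, d)
  Ws <- lapply(seq_len(M), function(m) {
    matrix(theta[n * d * m + seq_len(n * d)], n, d)
  })
  value <- 0
  gX <- matrix(0, n, d)
  gW <- vector("list", M)
  for (m in seq_len(M)) {
    S <- S_list[[m]]
    lShat <- log_model_diffusion_all(X, Ws[[m]])
    pos <- S > 0
    value <- value + sum(S[pos] * (log(S[pos]) - lShat[pos])) / n
    D <- (exp(lShat) - S) / n    # d(per-i KL)/d(z_ij), rows i
    gX <- gX + D %*% Ws[[m]]
    gW[[m]] <- t(D) %*% X
  }
  list(value = value, grad = c(gX, unlist(gW)))
}

#' Fit multi-network embeddings by L-BFGS
#'
#' Minimizes the multi-network KL objective over shared node features `X`
#' and per-network context features `W^m` with the quasi-Newton L-BFGS
#' method (analytic gradients), from a small seeded Gaussian initialization
#' (scale 1e-3). The optimizer runs in short segments so the objective can
#' be traced; the trace is non-increasing.
#'
#' @param S_list List of `dsim_diffusion` objects (shared node order).
#' @param d Embedding dimension (`d < n`).
#' @param seed Integer seed for the initialization.
#' @param max_iter Total L-BFGS iteration budget (default 500).
#' @param history L-BFGS memory (default 10).
#' @param pgtol Projected-gradient tolerance (default 1e-5).
#' @return A `dsim_embedding`: list with `node_ids`, `X` (n-by-d), `W`
#'   (list of n-by-d), `d`, `method = "lbfgs"`, `restart_prob`, `objective`
#'   (final value), `trace` (objective after each segment, starting with the
#'   initial value).
#' @export
fit_embeddings_lbfgs <- function(S_list, d, seed = 0L, max_iter = 500,
                                 history = 10, pgtol = 1e-5) {
  mats <- lapply(S_list, as_diffusion_matrix)
  n <- nrow(mats[[1]])
  if (d >= n) abort("embedding dimension d must be < number of nodes n",
                    class = "dsim_validation_error")
  M <- length(mats)
  a <- if (inherits(S_list[[1]], "dsim_diffusion")) S_list[[1]]$restart_prob else NA_real_
  set.seed(seed)
  theta <- rnorm(n * d * (M + 1)) * 1e-3

  fn <- function(th) kl_obj_grad(th, mats, n, d, M)$value
  gr <- function(th) kl_obj_grad(th, mats, n, d, M)$grad

  trace <- fn(theta)
  done <- 0L
  segment <- 50L
  repeat {
    it <- min(segment, max_iter - done)
    if (it <= 0) break
    res <- optim(theta, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = it, lmm = history, pgtol = pgtol))
    theta <- res$par
    trace <- c(trace, res$value)
    done <- done + it
    if (res$convergence == 0) break
    if (res$convergence != 1) {
      abort(paste0("L-BFGS failed: ", res$message, " (objective ",
                   signif(res$value, 6), ")"),
            class = "dsim_optim_error")
    }
  }
  X <- matrix(theta[seq_len(n * d)], n, d)
  Ws <- lapply(seq_len(M), function(m) matrix(theta[n * d * m + seq_len(n * d)], n, d))
  ids <- rownames(mats[[1]]) %||% as.character(seq_len(n))
  rownames(X) <- ids
  new_dsim_embedding(ids, X, Ws, d, "lbfgs", a, objective = trace[length(trace)],
                     trace = trace)
}

#' Fit multi-network embeddings by truncated SVD
#'
#' Deterministic alternative to the L-BFGS fit. The softmax model assigns
#' `log s_ij ~ x_i' w_j - c_i`, with the per-row constant `c_i` absorbed by
#' the softmax normalizer, so the least-squares surrogate fits the
#' row-centered log-diffusion matrices: each `log(S^m + eps)` (eps = 1/n
#' smoothing, since diffusion entries can be 0) has its row means removed
#' (the free `c_i^m`), the centered matrices are stacked side by side into
#' an n-by-(M n) matrix, and its rank-d truncated SVD `U_d D_d V_d'`
#' factors them with a shared row space: `X = U_d D_d^{1/2}` and
#' `W^m = V_d^{(m)} D_d^{1/2}`. At full rank `X %*% t(W^m) + c^m`
#' reconstructs `log(S^m + eps)` exactly. Singular-vector signs are fixed
#' by making the largest-magnitude entry of each left singular vector
#' positive, so the fit is fully deterministic.
#'
#' Without the centering the factorization is dominated by a rank-1
#' background component shared by all nodes (the `log eps` floor), which
#' carries no relational information but inflates every cosine.
#'
#' @param S_list List of `dsim_diffusion` objects (shared node order).
#' @param d Embedding dimension (`d < n`); if `d` exceeds the available
#'   rank, the available components are returned with a warning.
#' @return A `dsim_embedding` with `method = "svd"`; the per-network row
#'   centers are kept in `$centers`.
#' @export
fit_embeddings_svd <- function(S_list, d) {
  mats <- lapply(S_list, as_diffusion_matrix)
  n <- nrow(mats[[1]])
  if (d > n) abort("embedding dimension d cannot exceed the node count n",
                   class = "dsim_validation_error")
  a <- if (inherits(S_list[[1]], "dsim_diffusion")) S_list[[1]]$restart_prob else NA_real_
  eps <- 1 / n
  centers <- lapply(mats, function(S) rowMeans(log(S + eps)))
  L <- do.call(cbind, lapply(seq_along(mats), function(m) {
    log(mats[[m]] + eps) - centers[[m]]
  }))
  sv <- svd(L)
  avail <- sum(sv$d > max(dim(L)) * .Machine$double.eps * sv$d[1])
  if (d > avail) {
    warn(paste0("requested d = ", d, " exceeds available rank ", avail,
                "; returning ", avail, " components"))
    d <- avail
  }
  U <- sv$u[, seq_len(d), drop = FALSE]
  V <- sv$v[, seq_len(d), drop = FALSE]
  # sign convention: largest-magnitude entry of each component positive
  for (k in seq_len(d)) {
    s <- sign(U[which.max(abs(U[, k])), k])
    if (s < 0) { U[, k] <- -U[, k]; V[, k] <- -V[, k] }
  }
  sqd <- sqrt(sv$d[seq_len(d)])
  X <- U %*% diag(sqd, d)
  Wall <- V %*% diag(sqd, d)
  Ws <- lapply(seq_along(mats), function(m) {
    Wall[(m - 1L) * n + seq_len(n), , drop = FALSE]
  })
  ids <- rownames(mats[[1]]) %||% as.character(seq_len(n))
  rownames(X) <- ids
  out <- new_dsim_embedding(ids, X, Ws, d, "svd", a, objective = NA_real_,
                            trace = numeric())
  out$centers <- centers
  out
}

new_dsim_embedding <- function(node_ids, X, W, d, method, restart_prob,
                               objective = NA_real_, trace = numeric()) {
  structure(list(node_ids = node_ids, X = X, W = W, d = d, method = method,
                 restart_prob = restart_prob, objective = objective,
                 trace = trace),
            class = "dsim_embedding")
}

#' @export
print.dsim_embedding <- function(x, ...) {
  cat("<dsim_embedding> ", length(x$node_ids), " nodes, d = ", x$d,
      ", method = ", x$method,
      if (!is.na(x$objective)) paste0(", objective = ", signif(x$objective, 6)),
      "\n", sep = "")
  invisible(x)
}

#' Fit embeddings from similarity networks in one call
#'
#' Convenience wrapper: aligns the networks on their union node set, runs
#' the diffusion, and fits with the chosen method. The quasi-Newton KL fit
#' is the default — it recovers the benefit of integrating partially
#' overlapping sources markedly better than the least-squares SVD
#' surrogate, whose Frobenius objective over-weights the near-indicator
#' rows of diseases a source does not cover. The SVD fit remains available
#' as a fast deterministic alternative.
#'
#' @param nets List of `dsim_network` objects.
#' @param d Embedding dimension (default 600, capped below the node count).
#' @param a Restart probability (default 0.5).
#' @param method Embedding fitter, `"lbfgs"` (default) or `"svd"`.
#' @param seed Seed for the L-BFGS initialization.
#' @param ... Passed to the fitter.
#' @return A `dsim_embedding`.
#' @export
embed_networks <- function(nets, d = 600, a = 0.5, method = c("lbfgs", "svd"),
                           seed = 0L, ...) {
  method <- match.arg(method)
  S_list <- diffusion_states(nets, a = a)
  n <- nrow(S_list[[1]]$S)
  if (d >= n) abort(paste0("embedding dimension d = ", d,
                           " must be < number of nodes n = ", n),
                    class = "dsim_validation_error")
  if (method == "svd") fit_embeddings_svd(S_list, d)
  else fit_embeddings_lbfgs(S_list, d, seed = seed, ...)
}

#' Write / read an embedding as tab-separated text
#'
#' First column node id, then the d feature values; header comment line
#' `#dim=<d> restart=<a> method=<svd|lbfgs>`.
#'
#' @param model A `dsim_embedding`.
#' @param path Output path.
#' @return `path` invisibly; the reader returns a `dsim_embedding` (with
#'   empty context matrices, which are not serialized).
#' @export
write_embedding_tsv <- function(model, path) {
  hdr <- sprintf("#dim=%d restart=%s method=%s", model$d,
                 format(model$restart_prob), model$method)
  rows <- vapply(seq_along(model$node_ids), function(i) {
    paste(c(model$node_ids[[i]], sprintf("%.10g", model$X[i, ])), collapse = "\t")
  }, character(1))
  readr::write_lines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_embedding_tsv
#' @export
read_embedding_tsv <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- lines[[1]]
  stopifnot(startsWith(hdr, "#dim="))
  meta <- strsplit(sub("^#", "", hdr), " ")[[1]]
  kv <- do.call(rbind, strsplit(meta, "=", fixed = TRUE))
  opts <- rlang::set_names(kv[, 2], kv[, 1])
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  X <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  rownames(X) <- ids
  new_dsim_embedding(ids, X, W = list(), d = as.integer(opts[["dim"]]),
                     method = opts[["method"]],
                     restart_prob = as.numeric(opts[["restart"]]))
}
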