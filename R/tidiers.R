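#' Tidy an evaluation report
#'
#' One row per metric, broom-style.
#'
#' @param x A `dsim_eval`.
#' @param ... Unused.
#' @return Tibble with columns `metric`, `value`.
#' @export
tidy.dsim_eval <- function(x, ...) {
  tibble::tibble(
    metric = c("auc", "acc", "f1", "mcc", "pre", "sen", "spe"),
    value = c(x$auc, x$acc, x$f1, x$mcc, x$pre, x$sen, x$spe)
  )
}

#' Glance at an evaluation report
#'
#' @param x A `dsim_eval`.
#' @param ... Unused.
#' @return One-row tibble with all metrics, the threshold, and class sizes.
#' @export
glance.dsim_eval <- function(x, ...) {
  tibble::tibble(auc = x$auc, acc = x$acc, f1 = x$f1, mcc = x$mcc,
                 pre = x$pre, sen = x$sen, spe = x$spe,
                 threshold = x$threshold, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy an embedding
#'
#' @param x A `dsim_embedding`.
#' @param ... Unused.
#' @return Tibble with `disease_id` and one `dim_k` column per feature.
#' @export
tidy.dsim_embedding <- function(x, ...) {
  X <- x$X
  colnames(X) <- paste0("dim_", seq_len(ncol(X)))
  dplyr::bind_cols(tibble::tibble(disease_id = x$node_ids),
                   tibble::as_tibble(X))
}

#' Glance at an embedding
#'
#' @param x A `dsim_embedding`.
#' @param ... Unused.
#' @return One-row tibble: node count, dimension, method, restart
#'   probability, number of networks, final objective (NA for SVD fits).
#' @export
glance.dsim_embedding <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$node_ids), d = x$d, method = x$method,
                 restart_prob = x$restart_prob, n_networks = length(x$W),
                 objective = x$objective)
}
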