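#' Hypergeometric enrichment of DE genes near TE subfamilies
#'
#' The differential-expression enrichment baseline: for each TE subfamily
#' and each direction of change, tests whether differentially expressed
#' genes concentrate among the genes within cis-regulatory distance of the
#' subfamily's integrants (operationalized as a susceptibility of at least 1
#' in the hard-threshold matrix). With universe size `U` (genes retained in
#' the expression matrix, i.e., the matrix rows), `K` DE genes of the
#' direction, `n` genes near the subfamily and `k` of them DE, the p-value
#' is `P(X >= k)` for `X ~ Hypergeometric(U, K, n)`, computed exactly.
#' Up- and down-regulated results are gathered into a single table and
#' Benjamini-Hochberg adjusted together.
#'
#' @param de Tibble with columns `gene_id` and `direction`
#'   (`"up"` or `"down"`); gene ids must be rows of `N`, and no gene may be
#'   both up and down.
#' @param N A hard-mode `susceptibility_matrix` whose rows are the gene
#'   universe.
#' @return A tibble: `subfamily`, `direction`, `n_near`, `k_de`, `p_value`,
#'   `adj_p_value`.
#' @export
hypergeom_enrichment <- function(de, N) {
  stopifnot(inherits(N, "susceptibility_matrix"))
  universe <- rownames(N$values)
  if (!all(de$gene_id %in% universe)) {
    bad <- setdiff(de$gene_id, universe)[1]
    te_abort(sprintf("DE gene '%s' is not in the universe (matrix rows)", bad),
             "te_validation_error")
  }
  if (!all(de$direction %in% c("up", "down"))) {
    te_abort("direction must be 'up' or 'down'", "te_validation_error")
  }
  up <- unique(de$gene_id[de$direction == "up"])
  down <- unique(de$gene_id[de$direction == "down"])
  if (length(intersect(up, down)) > 0) {
    te_abort("a gene cannot be both up- and down-regulated", "te_validation_error")
  }
  U <- length(universe)
  near <- N$values >= 1
  res <- purrr::map_dfr(c(up = "up", down = "down"), function(dir) {
    de_genes <- if (dir == "up") up else down
    K <- length(de_genes)
    is_de <- universe %in% de_genes
    purrr::map_dfr(colnames(near), function(sf) {
      n <- sum(near[, sf])
      k <- sum(near[, sf] & is_de)
      p <- if (K == 0) 1 else
        stats::phyper(k - 1, K, U - K, n, lower.tail = FALSE)
      tibble::tibble(subfamily = sf, direction = dir, n_near = n, k_de = k,
                     p_value = p)
    })
  })
  res$adj_p_value <- bh_adjust(res$p_value)
  res
}

#' Area under the ROC curve for subfamily classification
#'
#' Mann-Whitney AUC of a score (typically `1 - adjusted p-value`) for
#' separating truly cis-regulatory subfamilies from the rest:
#' `P(score_pos > score_neg) + 0.5 P(tie)` over all positive/negative
#' pairs, computed from ranks.
#'
#' @param truth Tibble with columns `subfamily`, `score` (in `[0, 1]`) and
#'   `positive` (logical ground-truth label).
#' @return AUC in `[0, 1]`.
#' @export
classification_auc <- function(truth) {
  pos <- truth$positive
  if (!any(pos) || all(pos)) {
    te_abort("classification_auc needs both positive and negative labels",
             "te_validation_error")
  }
  r <- rank(truth$score)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
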