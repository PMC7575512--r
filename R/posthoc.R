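# Post hoc pairwise rate comparisons and compact-letter summaries.

#' Post hoc pairwise evolutionary-rate comparisons
#'
#' For every unordered pair of traits, runs a two-trait [compare_rates()] on
#' the same species set (df = 1 each) and summarises which traits evolve at
#' statistically indistinguishable rates with a compact letter display:
#' traits that are not significantly different at level `alpha` share a
#' letter. Raw p-values are reported by default (no multiple-testing
#' correction); set `adjust` to any [stats::p.adjust()] method to correct
#' both the reported p-values and the lettering.
#'
#' @inheritParams fit_common
#' @param alpha Significance level for the letter grouping (default 0.05).
#' @param adjust Multiple-testing correction method; default `"none"`.
#' @return A `rate_posthoc` object: `table` (one row per pair with rates,
#'   ratio, LRT, df, p-value), `p_matrix`, `letters`, `rates`, `alpha`.
#' @export
posthoc_pairwise <- function(X, C, alpha = 0.05, adjust = "none",
                             common_model = c("joint", "fixed_correlations")) {
  common_model <- match.arg(common_model)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop_input("alpha must be in (0, 1)")
  p <- ncol(X)
  if (p < 2) stop_input("post hoc comparisons need at least 2 traits")
  traits <- colnames(X)
  full <- fit_observed(X, C)
  prs <- combn(p, 2)
  rows <- lapply(seq_len(ncol(prs)), function(k) {
    i <- prs[1, k]; j <- prs[2, k]
    cmp <- compare_rates(X[, c(i, j), drop = FALSE], C, common_model)
    data.frame(trait_i = traits[i], trait_j = traits[j],
               sigma2_i = cmp$observed$rates[[1]],
               sigma2_j = cmp$observed$rates[[2]],
               ratio = cmp$observed$rates[[1]] / cmp$observed$rates[[2]],
               LRT = cmp$LRT, df = cmp$df, p_value = cmp$p_value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- p.adjust(tab$p_value, method = adjust)

  pm <- matrix(NA_real_, p, p, dimnames = list(traits, traits))
  for (k in seq_len(nrow(tab))) {
    i <- tab$trait_i[k]; j <- tab$trait_j[k]
    pm[i, j] <- pm[j, i] <- tab$p_adjusted[k]
  }
  out <- list(table = tab, p_matrix = pm,
              letters = grouping_letters(pm, alpha = alpha),
              rates = full$rates, alpha = alpha, adjust = adjust,
              n = nrow(X), p = p)
  class(out) <- "rate_posthoc"
  out
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Builds the non-significance graph (edge when `p > alpha`) and covers it
#' with cliques found greedily in trait input order; each clique gets the
#' next letter and each trait's label is the concatenation of the letters of
#' the cliques containing it. Two traits share a letter if and only if they
#' belong to a common clique, i.e. sharing a letter implies the pair (and
#' every pair within the clique) is not significantly different.
#'
#' @param p_matrix Symmetric matrix of pairwise p-values with trait dimnames
#'   (diagonal ignored).
#' @param alpha Significance level.
#' @return Named character vector of letter labels.
#' @export
grouping_letters <- function(p_matrix, alpha = 0.05) {
  if (!is.matrix(p_matrix) || nrow(p_matrix) != ncol(p_matrix))
    stop_input("p_matrix must be a square matrix")
  k <- nrow(p_matrix)
  adj <- p_matrix > alpha
  adj[is.na(adj)] <- FALSE
  diag(adj) <- TRUE
  cliques <- list()
  covered <- matrix(FALSE, k, k)
  if (k >= 2) {
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      if (!adj[i, j] || covered[i, j]) next
      cl <- c(i, j)
      for (v in seq_len(k))
        if (!(v %in% cl) && all(adj[v, cl])) cl <- c(cl, v)
      cl <- sort(cl)
      covered[cl, cl] <- TRUE
      cliques[[length(cliques) + 1L]] <- cl
    }
  }
  for (i in seq_len(k))
    if (!any(vapply(cliques, function(cl) i %in% cl, logical(1))))
      cliques[[length(cliques) + 1L]] <- i
  lab <- rep("", k)
  for (ci in seq_along(cliques))
    lab[cliques[[ci]]] <- paste0(lab[cliques[[ci]]], letters[ci])
  setNames(lab, rownames(p_matrix))
}

#' @export
print.rate_posthoc <- function(x, digits = 2, ...) {
  cat(sprintf("Post hoc pairwise rate comparisons (n = %d, p = %d, alpha = %g%s)\n",
              x$n, x$p, x$alpha,
              if (x$adjust != "none") paste0(", ", x$adjust, "-adjusted") else ""))
  tab <- x$table
  tab$p_value <- format_p(tab$p_value)
  tab$p_adjusted <- NULL
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  cat("\nrate groupings (traits sharing a letter do not differ):\n")
  print(data.frame(sigma2 = round(x$rates, digits), group = x$letters))
  invisible(x)
}
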