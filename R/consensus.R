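# Rank aggregation of context-free scores, cross-method concordance,
# tissue-maximum profiling, and top-quantile consensus prioritization.
#
# Convention: rank 1 = most functional in every method, after applying each
# column's direction flag. Ties receive average ranks; missing scores yield
# missing ranks.

#' Rank variants per method
#'
#' @param scores a [score_matrix()] (each column needs >= 2 non-missing
#'   values).
#' @return a `ranking_table`: list(ranks matrix, variant_ids, method_ids).
#' @export
rank_scores <- function(scores) {
  vals <- scores$values
  ranks <- matrix(NA_real_, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    ok <- !is.na(x)
    if (sum(ok) == 0) stop("all scores missing in column '", colnames(vals)[j],
                           "'", call. = FALSE)
    if (sum(ok) < 2) stop("column '", colnames(vals)[j],
                          "' has fewer than 2 non-missing scores", call. = FALSE)
    oriented <- if (scores$direction[j] == "higher") -x[ok] else x[ok]
    ranks[ok, j] <- rank(oriented, ties.method = "average")
  }
  structure(list(ranks = ranks, variant_ids = rownames(vals),
                 method_ids = colnames(vals)), class = "ranking_table")
}

#' @export
print.ranking_table <- function(x, ...) {
  cat("ranking_table:", length(x$variant_ids), "variants x",
      length(x$method_ids), "methods\n")
  invisible(x)
}

#' Average ranking across methods
#'
#' Per variant, the mean of its available method ranks; variants with fewer
#' than `min_methods` available ranks are flagged (`included = FALSE`) and
#' excluded from downstream ordering.
#'
#' @param table a [rank_scores()] result.
#' @param min_methods minimum number of available method ranks (default: all
#'   methods, the strict complete-table policy).
#' @return data frame: variant_id, average_ranking, n_methods_used, included.
#' @export
average_ranking <- function(table, min_methods = length(table$method_ids)) {
  if (min_methods < 1) stop("min_methods must be >= 1", call. = FALSE)
  n_used <- rowSums(!is.na(table$ranks))
  avg <- ifelse(n_used > 0, rowMeans(table$ranks, na.rm = TRUE), NA_real_)
  data.frame(variant_id = table$variant_ids,
             average_ranking = avg,
             n_methods_used = as.integer(n_used),
             included = n_used >= min_methods,
             stringsAsFactors = FALSE)
}

#' Permutation p-values for the average ranking
#'
#' Null model: each method's rank column is permuted independently (within
#' its non-missing entries). For variant i,
#' `p_i = (1 + #permutations with permuted average <= observed) / (n_perm + 1)`
#' (one-sided, more-functional-than-chance), followed by Benjamini-Hochberg
#' adjustment across variants.
#'
#' @param table a [rank_scores()] result.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @param min_methods passed to [average_ranking()].
#' @return data frame: variant_id, average_ranking, n_methods_used,
#'   included, p_value, adjusted_p.
#' @export
permutation_pvalue <- function(table, n_perm = 999L, seed = 1L,
                               min_methods = length(table$method_ids)) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  res <- average_ranking(table, min_methods)
  ranks <- table$ranks
  obs <- res$average_ranking
  n_used <- res$n_methods_used
  hits <- numeric(nrow(ranks))
  ok_cols <- lapply(seq_len(ncol(ranks)), function(j) which(!is.na(ranks[, j])))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- ranks
      for (j in seq_len(ncol(ranks))) {
        idx <- ok_cols[[j]]
        perm[idx, j] <- ranks[idx[sample.int(length(idx))], j]
      }
      avg_p <- rowSums(perm, na.rm = TRUE) / pmax(n_used, 1)
      hits <- hits + (avg_p <= obs + 1e-12)
    }
  })
  res$p_value <- (1 + hits) / (n_perm + 1)
  res$p_value[n_used == 0] <- NA_real_
  res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Spearman rank correlation of two score vectors
#'
#' Pairwise-complete; Pearson correlation of tie-averaged ranks.
#'
#' @param x,y numeric vectors of equal length (>= 3 shared non-missing
#'   pairs).
#' @return correlation in \[-1, 1\].
#' @export
spearman_scores <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need >= 3 paired non-missing values", call. = FALSE)
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stop("Spearman correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(rank(xs, ties.method = "average"),
             rank(ys, ties.method = "average"))
}

#' Pearson correlation matrix of method rank columns
#'
#' Entry (j, k) is the Pearson correlation of the two methods' rank columns
#' over their shared (both non-missing) variants; for complete columns this
#' equals the Spearman correlation of the raw scores. Pairs with fewer than
#' 3 shared variants get NA with a warning.
#'
#' @param table a [rank_scores()] result.
#' @return symmetric m x m correlation matrix with unit diagonal.
#' @export
pearson_rank_correlation <- function(table) {
  ranks <- table$ranks
  m <- ncol(ranks)
  out <- matrix(NA_real_, m, m, dimnames = list(table$method_ids,
                                                table$method_ids))
  for (j in seq_len(m)) {
    out[j, j] <- 1
    for (k in seq_len(m)) {
      if (k <= j) next
      ok <- !is.na(ranks[, j]) & !is.na(ranks[, k])
      if (sum(ok) < 3) {
        warning("methods '", table$method_ids[j], "' and '",
                table$method_ids[k], "' share fewer than 3 variants; ",
                "correlation undefined", call. = FALSE)
        next
      }
      r <- stats::cor(ranks[ok, j], ranks[ok, k])
      out[j, k] <- r
      out[k, j] <- r
    }
  }
  out
}

#' Profile which tissues attain each variant's maximum score
#'
#' The argmax set contains every tissue whose score is within `tie_tol` of
#' the row maximum. A variant is `unique_to_group` if the argmax set lies
#' entirely inside the supplied tissue group, `shared_with_group` if it
#' intersects both the group and its complement, and `outside_group`
#' otherwise.
#'
#' @param tissue_scores a [score_matrix()] (variants x tissues).
#' @param group non-empty character vector of tissue column ids.
#' @param tie_tol tie tolerance (default 1e-9: exact ties only, configurable
#'   because upstream scores may be rounded).
#' @return data frame: variant_id, max_score, argmax_tissues
#'   (comma-collapsed), classification.
#' @export
tissue_max_profile <- function(tissue_scores, group, tie_tol = 1e-9) {
  if (length(group) == 0) stop("tissue group is empty", call. = FALSE)
  vals <- tissue_scores$values
  miss <- setdiff(group, colnames(vals))
  if (length(miss) > 0) {
    stop("group tissue(s) absent from score matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (tie_tol < 0) stop("tie_tol must be >= 0", call. = FALSE)
  out <- lapply(seq_len(nrow(vals)), function(i) {
    x <- vals[i, ]
    if (all(is.na(x))) {
      stop("variant ", rownames(vals)[i], " has no tissue scores", call. = FALSE)
    }
    mx <- max(x, na.rm = TRUE)
    arg <- colnames(vals)[!is.na(x) & x >= mx - tie_tol]
    in_g <- arg %in% group
    cls <- if (all(in_g)) "unique_to_group"
           else if (any(in_g)) "shared_with_group"
           else "outside_group"
    data.frame(variant_id = rownames(vals)[i], max_score = mx,
               argmax_tissues = paste(arg, collapse = ","),
               classification = cls, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Top-quantile consensus prioritization
#'
#' A variant passes when (a) its target-tissue score stands in the top
#' `ceiling(q * n)` of all variants and (b) it stands in the top
#' `ceiling(q * n)` of at least `ceiling(min_method_fraction * m)`
#' context-free method columns. "Top k" is count-based on tie-averaged ranks
#' (rank <= k), so small n behaves deterministically.
#'
#' @param tissue_scores a [score_matrix()] containing `target_tissue`.
#' @param target_tissue tissue column id.
#' @param table a [rank_scores()] result over the context-free methods (same
#'   variants).
#' @param q top quantile, strictly in (0, 1) (default 0.05).
#' @param min_method_fraction minimum fraction of methods, in (0, 1\]
#'   (default 0.5).
#' @return data frame (passers first, ordered by average ranking):
#'   variant_id, tissue_rank, n_methods_top, pass_tissue, pass_methods,
#'   pass, average_ranking.
#' @export
consensus_prioritize <- function(tissue_scores, target_tissue, table,
                                 q = 0.05, min_method_fraction = 0.5) {
  if (q <= 0 || q >= 1) stop("q must lie strictly in (0, 1)", call. = FALSE)
  if (min_method_fraction <= 0 || min_method_fraction > 1) {
    stop("min_method_fraction must lie in (0, 1]", call. = FALSE)
  }
  vals <- tissue_scores$values
  if (!target_tissue %in% colnames(vals)) {
    stop("target tissue '", target_tissue, "' absent from tissue scores",
         call. = FALSE)
  }
  ids <- table$variant_ids
  if (!all(ids %in% rownames(vals))) {
    stop("tissue scores are missing ",
         sum(!ids %in% rownames(vals)), " ranked variant(s)", call. = FALSE)
  }
  tscore <- vals[ids, target_tissue]
  if (tissue_scores$direction[target_tissue] == "lower") tscore <- -tscore
  if (any(is.na(tscore))) {
    stop("missing target-tissue score for ", sum(is.na(tscore)),
         " variant(s)", call. = FALSE)
  }
  n <- length(ids)
  m <- length(table$method_ids)
  k <- ceiling(q * n)
  needed <- ceiling(min_method_fraction * m)
  t_rank <- rank(-tscore, ties.method = "average")
  pass_tissue <- t_rank <= k
  n_top <- rowSums(table$ranks <= k, na.rm = TRUE)
  pass_methods <- n_top >= needed
  avg <- average_ranking(table, min_methods = 1L)$average_ranking
  out <- data.frame(variant_id = ids,
                    tissue_rank = t_rank,
                    n_methods_top = as.integer(n_top),
                    pass_tissue = pass_tissue,
                    pass_methods = pass_methods,
                    pass = pass_tissue & pass_methods,
                    average_ranking = avg,
                    stringsAsFactors = FALSE)
  ord <- order(!out$pass, out$average_ranking, out$variant_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
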