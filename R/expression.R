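# Expression thresholding, expression bins, knockdown cross-tabulation and
# the 2x2 homology co-binding test.

#' Build an expression table from per-replicate FPKM values
#'
#' @param gene_id character vector.
#' @param fpkm numeric matrix (genes x replicates) of FPKM values.
#' @return data.frame with `gene_id`, `fpkm_1..r`, `mean_fpkm`.
#' @export
expression_table <- function(gene_id, fpkm) {
  fpkm <- as.matrix(fpkm)
  stopifnot(length(gene_id) == nrow(fpkm), all(fpkm >= 0))
  df <- data.frame(gene_id = gene_id, fpkm)
  names(df)[-1] <- paste0("fpkm_", seq_len(ncol(fpkm)))
  df$mean_fpkm <- rowMeans(fpkm)
  df
}

#' Call active genes by mean FPKM
#'
#' Active genes are transcripts whose mean FPKM over replicates is at least
#' `threshold` (default 4).
#'
#' @param expr data.frame with `gene_id` and `mean_fpkm` (see
#'   [expression_table()]).
#' @param threshold FPKM cutoff (inclusive).
#' @return character vector of active gene ids.
#' @export
call_active_genes <- function(expr, threshold = 4) {
  stopifnot(threshold >= 0)
  expr$gene_id[expr$mean_fpkm >= threshold]
}

#' Quantile expression bins (high / intermediate / low)
#'
#' Genes with positive mean FPKM are split into `n_bins` equal-count bins of
#' increasing expression; ties are resolved by stable input order and
#' zero-expression genes are excluded. With the default 3 bins the labels
#' are `low`, `intermediate`, `high`.
#'
#' @param expr data.frame with `gene_id` and `mean_fpkm`.
#' @param n_bins number of bins (default 3).
#' @return named character vector gene_id -> bin label; bin boundaries in
#'   attribute `boundaries`.
#' @export
expression_bins <- function(expr, n_bins = 3) {
  stopifnot(n_bins >= 2)
  nz <- expr[expr$mean_fpkm > 0, , drop = FALSE]
  n <- nrow(nz)
  if (n < n_bins) stop("fewer nonzero-expression genes than bins")
  ord <- order(nz$mean_fpkm)              # stable: ties keep input order
  bin_idx <- ceiling(seq_len(n) * n_bins / n)
  labels <- if (n_bins == 3) c("low", "intermediate", "high")
            else paste0("bin_", seq_len(n_bins))
  out <- setNames(rep(NA_character_, n), nz$gene_id)
  out[ord] <- labels[bin_idx]
  cuts <- vapply(seq_len(n_bins - 1), function(b)
    nz$mean_fpkm[ord][max(which(bin_idx == b))], 0)
  attr(out, "boundaries") <- cuts
  out
}

#' Cross-tabulate knockdown differential expression by target class
#'
#' For every (target class, group) cell: the number of classified genes, the
#' number significantly up- and downregulated (adjusted p-value at most
#' `alpha`; direction by the sign of the log2 fold change), and the
#' corresponding fractions of the cell's gene count. Genes present in the DE
#' table but absent from the classification are excluded and counted in the
#' `n_unclassified` attribute.
#'
#' @param de data.frame with `gene_id`, `log2_fold_change`, `padj`.
#' @param classes data.frame from [classify_targets()] for one factor
#'   (columns `gene_id`, `status`), or any data.frame mapping gene_id to a
#'   class via the column named in `class_col`.
#' @param groups optional named vector gene_id -> group (e.g. expression bin
#'   from [expression_bins()], or chromosome); default: a single group.
#' @param alpha adjusted p-value cutoff (default 0.01).
#' @param class_col name of the class column in `classes`.
#' @return data.frame: class, group, n_total, n_up, n_down, frac_up,
#'   frac_down.
#' @export
de_crosstab <- function(de, classes, groups = NULL, alpha = 0.01,
                        class_col = "status") {
  stopifnot(all(c("gene_id", "log2_fold_change", "padj") %in% names(de)),
            all(c("gene_id", class_col) %in% names(classes)),
            alpha >= 0, alpha <= 1,
            all(de$padj >= 0 & de$padj <= 1))
  cls <- setNames(as.character(classes[[class_col]]), classes$gene_id)
  known <- de$gene_id %in% names(cls)
  n_unclassified <- sum(!known)
  de <- de[known, , drop = FALSE]
  gclass <- cls[de$gene_id]
  ggroup <- if (is.null(groups)) rep("all", nrow(de))
            else as.character(groups[de$gene_id])
  sig <- de$padj <= alpha
  up <- sig & de$log2_fold_change > 0
  down <- sig & de$log2_fold_change < 0
  key <- interaction(gclass, ggroup, drop = TRUE, sep = "\r")
  agg <- function(x) as.numeric(tapply(x, key, sum))
  n_tot <- as.numeric(table(key))
  parts <- strsplit(levels(key), "\r", fixed = TRUE)
  out <- data.frame(class = vapply(parts, `[[`, "", 1),
                    group = vapply(parts, `[[`, "", 2),
                    n_total = n_tot, n_up = agg(up), n_down = agg(down))
  out$frac_up <- out$n_up / out$n_total
  out$frac_down <- out$n_down / out$n_total
  attr(out, "n_unclassified") <- n_unclassified
  out
}

#' Welch two-sample t test between expression groups
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom,
#' two-sided.
#'
#' @param group_a,group_b numeric vectors (at least 2 values each).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
compare_group_expression <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values")
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(statistic = 0, p_value = 1, df = NA_real_))
    }
    stop("both groups have zero variance")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Pearson chi-square test of co-binding independence
#'
#' Tests independence of binary binding calls across homologous gene pairs
#' (e.g. NSL binding in fly vs mouse) on the 2x2 contingency table.
#'
#' @param fly_bound,mouse_bound logical vectors of equal length, or pass a
#'   2x2 `table` as `fly_bound` with `mouse_bound` missing.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with `statistic`, `p_value`, `df`, `table`.
#' @export
homology_cooccurrence_test <- function(fly_bound, mouse_bound = NULL,
                                       correct = FALSE) {
  tab <- if (is.null(mouse_bound)) {
    as.table(as.matrix(fly_bound))
  } else {
    stopifnot(length(fly_bound) == length(mouse_bound))
    table(factor(fly_bound, levels = c(FALSE, TRUE)),
          factor(mouse_bound, levels = c(FALSE, TRUE)))
  }
  if (!all(dim(tab) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all margins of the 2x2 table must be positive")
  }
  ct <- stats::chisq.test(tab, correct = correct)
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter), table = tab)
}
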