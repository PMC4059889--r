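# Rank-transform Ward clustering of region signal matrices and per-cluster
# summaries.

.matrix_values <- function(x) {
  if (inherits(x, "region_signal_matrix")) x$values
  else if (is.matrix(x)) x
  else stop("expected a matrix or region_signal_matrix")
}

#' Column-wise rank transform of a signal matrix
#'
#' Each column (sample x bin feature) is independently replaced by the ranks
#' of its values across regions (ties receive the average rank), then divided
#' by the row count so columns are on a common 0-1 scale. This removes
#' per-sample dynamic-range differences before clustering, so that the
#' clusters reflect co-binding patterns rather than signal amplitude.
#'
#' @param matrix a numeric matrix or `region_signal_matrix`.
#' @return the same type, values replaced by scaled ranks.
#' @export
rank_transform <- function(matrix) {
  v <- .matrix_values(matrix)
  if (anyNA(v)) stop("matrix must not contain missing values")
  r <- apply(v, 2, rank, ties.method = "average") / nrow(v)
  if (is.null(dim(r))) r <- base::matrix(r, nrow = nrow(v))
  dimnames(r) <- dimnames(v)
  if (inherits(matrix, "region_signal_matrix")) {
    matrix$values <- r
    matrix
  } else r
}

# canonical labels: clusters renumbered by first occurrence in row order
.canonical_labels <- function(labels) match(labels, unique(labels))

#' Ward hierarchical clustering cut at k clusters
#'
#' Euclidean distances between rows are clustered agglomeratively with
#' Ward's minimum-variance criterion (`hclust` method `ward.D2`, the variant
#' that is variance-correct on unsquared Euclidean distances: the height of
#' each merge equals `sqrt(2 * delta SSE)`). Labels come from cutting the
#' dendrogram at `k` and are canonicalized so that cluster numbers follow
#' first occurrence in row order, making the output deterministic.
#'
#' @param matrix numeric matrix or `region_signal_matrix` (rows = regions).
#' @param k number of clusters, `2 <= k <= nrow`.
#' @return a `cluster_assignment`: list with `k`, `labels` (integers in
#'   `1..k`), and `linkage` (the `hclust` object).
#' @export
ward_cluster <- function(matrix, k) {
  v <- .matrix_values(matrix)
  n <- nrow(v)
  if (k < 2 || k > n) stop("k out of range [2, n_regions]")
  h <- stats::hclust(stats::dist(v, method = "euclidean"),
                     method = "ward.D2")
  labels <- .canonical_labels(stats::cutree(h, k = k))
  structure(list(k = as.integer(k), labels = labels, linkage = h),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment: k =", x$k, "sizes:",
      paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Cut one Ward dendrogram at a range of cluster counts
#'
#' The linkage is computed once and cut at each `k`; because all cuts come
#' from the same tree, the partition at `k + 1` always refines the partition
#' at `k`.
#'
#' @param matrix numeric matrix or `region_signal_matrix`.
#' @param k_range integer vector of cluster counts (default `2:10`).
#' @return named list `k -> cluster_assignment` (sharing one linkage).
#' @export
prune_scan <- function(matrix, k_range = 2:10) {
  v <- .matrix_values(matrix)
  n <- nrow(v)
  k_range <- as.integer(k_range)
  if (any(k_range < 2 | k_range > n)) stop("k_range out of [2, n_regions]")
  h <- stats::hclust(stats::dist(v, method = "euclidean"),
                     method = "ward.D2")
  out <- lapply(k_range, function(k) {
    structure(list(k = k,
                   labels = .canonical_labels(stats::cutree(h, k = k)),
                   linkage = h),
              class = "cluster_assignment")
  })
  names(out) <- as.character(k_range)
  out
}

#' Per-cluster summary statistics
#'
#' For each cluster: region count, median width, and the fractions of
#' regions falling in each genomic compartment (1 kb upstream of a TSS,
#' gene body, intergenic; mutually exclusive, see [assign_compartment()]).
#' When per-sample peak lists are supplied, additionally the fraction of
#' each sample's peaks residing inside the cluster's regions.
#'
#' @param assignment a `cluster_assignment`.
#' @param regions the clustered `GRanges` (row order of the matrix).
#' @param annotation an [annotation_bundle] (for compartments); may be NULL.
#' @param samples optional named list of peak `GRanges`.
#' @return list with `clusters` (data.frame: cluster, n_regions,
#'   median_width_bp, frac_upstream_1kb, frac_gene_body, frac_intergenic)
#'   and `sample_fractions` (cluster x sample matrix or NULL).
#' @export
cluster_summary <- function(assignment, regions, annotation = NULL,
                            samples = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            length(regions) == length(assignment$labels))
  k <- assignment$k
  labels <- assignment$labels
  widths <- GenomicRanges::width(regions)
  comp <- if (!is.null(annotation)) {
    assign_compartment(regions, annotation$genes)
  } else NULL
  rows <- lapply(seq_len(k), function(cl) {
    sel <- labels == cl
    fr <- if (!is.null(comp)) {
      tab <- table(factor(comp[sel],
                          levels = c("upstream_1kb", "gene_body", "intergenic")))
      as.numeric(tab) / max(1L, sum(sel))
    } else rep(NA_real_, 3)
    data.frame(cluster = cl, n_regions = sum(sel),
               median_width_bp = if (any(sel)) stats::median(widths[sel]) else NA_real_,
               frac_upstream_1kb = fr[1], frac_gene_body = fr[2],
               frac_intergenic = fr[3])
  })
  clusters <- do.call(rbind, rows)
  sample_fractions <- NULL
  if (!is.null(samples)) {
    sample_fractions <- vapply(samples, function(p) {
      tot <- length(p)
      vapply(seq_len(k), function(cl) {
        if (!tot) return(NA_real_)
        sum(IRanges::overlapsAny(p, regions[labels == cl],
                                       ignore.strand = TRUE)) / tot
      }, 0)
    }, numeric(k))
    if (k == 1L) sample_fractions <- matrix(sample_fractions, nrow = 1)
    rownames(sample_fractions) <- seq_len(k)
  }
  list(clusters = clusters, sample_fractions = sample_fractions)
}
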