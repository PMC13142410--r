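#' Minimum-fragment cell retention filter
#'
#' A cell is retained when it has strictly more than `min_frags` fragments in
#' at least one of the three modalities (two mono-occupancy, one combined
#' co-occupancy).
#'
#' @param counts Numeric matrix or data.frame of per-cell fragment counts,
#'   one column per modality, rownames (or a `cell` column) identifying cells.
#' @param min_frags Retention threshold (default 250; strict `>`).
#' @return Character vector of retained cell identifiers.
#' @export
min_fragment_filter <- function(counts, min_frags = 250L) {
  cells <- rownames(counts)
  if (is.data.frame(counts) && "cell" %in% names(counts)) {
    cells <- counts$cell
    counts <- counts[setdiff(names(counts), "cell")]
  }
  m <- as.matrix(counts)
  if (is.null(cells)) cells <- as.character(seq_len(nrow(m)))
  cells[apply(m, 1L, max) > min_frags]
}

#' Remove clusters enriched for putative doublets
#'
#' Cells with doublet scores above `score_threshold` are putative doublets;
#' a cluster is removed when its putative-doublet fraction exceeds
#' `fraction_threshold` (strict `>`).
#'
#' @param doublet_score Named numeric vector of per-cell doublet scores.
#' @param clusters Named character vector of per-cell cluster labels (same
#'   cells).
#' @param score_threshold Score above which a cell counts as a putative
#'   doublet.
#' @param fraction_threshold Cluster-level removal threshold.
#' @return List with `removed_clusters`, `retained_cells`, and `fractions`
#'   (per-cluster putative-doublet fraction).
#' @export
cluster_doublet_filter <- function(doublet_score, clusters, score_threshold,
                                   fraction_threshold) {
  stopifnot(length(doublet_score) == length(clusters))
  putative <- doublet_score > score_threshold
  fractions <- tapply(putative, clusters, mean)
  removed <- names(fractions)[fractions > fraction_threshold]
  keep <- !(clusters %in% removed)
  cells <- names(clusters)
  if (is.null(cells)) cells <- as.character(seq_along(clusters))
  list(removed_clusters = removed, retained_cells = cells[keep],
       fractions = fractions)
}

#' Remove genotype-doublet-enriched embedding neighborhoods
#'
#' Partitions cells into `n_groups` groups by seeded k-means in the batch-
#' corrected embedding, computes each group's fraction of genotype-labelled
#' doublets, and removes all cells of groups whose fraction exceeds
#' `max_doublet_fraction` (strict `>`). The removed cell set is meant to be
#' applied to every modality's cell list.
#'
#' @param embedding Numeric cell x dimension matrix (rownames = cells).
#' @param genotype_status Character vector aligned with the rows; cells with
#'   value `"doublet"` are genotype doublets.
#' @param n_groups Number of k-means groups (default 100; lowered to the
#'   number of cells when fewer).
#' @param max_doublet_fraction Group removal threshold (default 0.15).
#' @param seed Integer seed for k-means.
#' @param nstart Number of k-means restarts (default 10).
#' @return List with `retained_cells`, `removed_cells`, `group` (per-cell
#'   group id), `group_doublet_fraction`, `removed_groups`.
#' @export
genotype_doublet_filter <- function(embedding, genotype_status,
                                    n_groups = 100L,
                                    max_doublet_fraction = 0.15,
                                    seed = 1L, nstart = 10L) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) == 0L || is.null(dim(embedding)))
    stop("embedding matrix required")
  stopifnot(length(genotype_status) == nrow(embedding))
  cells <- rownames(embedding)
  if (is.null(cells)) cells <- as.character(seq_len(nrow(embedding)))
  k <- min(as.integer(n_groups), nrow(embedding))
  set.seed(seed)
  km <- stats::kmeans(embedding, centers = k, nstart = nstart,
                      iter.max = 100L, algorithm = "Lloyd")
  grp <- km$cluster
  frac <- tapply(genotype_status == "doublet", grp, mean)
  removed_groups <- as.integer(names(frac)[frac > max_doublet_fraction])
  removed <- grp %in% removed_groups
  list(retained_cells = cells[!removed], removed_cells = cells[removed],
       group = stats::setNames(grp, cells),
       group_doublet_fraction = frac,
       removed_groups = removed_groups)
}

#' Pair-closeness embedding fidelity score
#'
#' For matched same-cell profile pairs, `s_pair()` measures how unusually
#' close the two members sit in the embedding: for each member, the fraction
#' of up to `sample_size` sampled other cells that are closer to it than its
#' true partner (Euclidean distance over the designated reduced dimensions),
#' averaged over the two members. 0 means the partner is each member's
#' nearest neighbour; 0.5 is the expectation for unrelated points.
#'
#' @param embedding Numeric cell x dimension matrix (rownames = cells);
#'   typically the first 15 batch-corrected dimensions.
#' @param pairs Two-column data.frame (or matrix) of matched cell
#'   identifiers or row indices.
#' @param sample_size Cells sampled per member (default 5000); when fewer
#'   other cells exist, all are used.
#' @param dims Columns of `embedding` to use (default all).
#' @param seed Integer seed for the sampling.
#' @return Data.frame with the pair columns, per-member scores `s_i`, `s_j`,
#'   and `s_pair = (s_i + s_j) / 2`.
#' @export
s_pair <- function(embedding, pairs, sample_size = 5000L, dims = NULL,
                   seed = 1L) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) < 3L) stop("need at least 3 cells")
  if (!is.null(dims)) embedding <- embedding[, dims, drop = FALSE]
  idx <- function(v) {
    if (is.numeric(v)) as.integer(v) else match(v, rownames(embedding))
  }
  i <- idx(pairs[[1]]); j <- idx(pairs[[2]])
  if (any(is.na(i)) || any(is.na(j)))
    stop("pair members absent from embedding")
  set.seed(seed)
  member_score <- function(c_idx, p_idx) {
    others <- setdiff(seq_len(nrow(embedding)), c(c_idx, p_idx))
    if (length(others) > sample_size)
      others <- sample(others, sample_size)
    dp <- sqrt(sum((embedding[c_idx, ] - embedding[p_idx, ])^2))
    diff <- embedding[others, , drop = FALSE] -
      matrix(embedding[c_idx, ], length(others), ncol(embedding), byrow = TRUE)
    dk <- sqrt(rowSums(diff^2))
    mean(dk < dp)
  }
  s_i <- mapply(member_score, i, j)
  s_j <- mapply(member_score, j, i)
  data.frame(i = pairs[[1]], j = pairs[[2]], s_i = s_i, s_j = s_j,
             s_pair = (s_i + s_j) / 2)
}

#' Cross-modality cluster overlap matrix
#'
#' Contingency matrix of per-cell cluster labels from two modalities; entry
#' (a, b) counts cells labelled `a` in modality A and `b` in modality B.
#'
#' @param labels_a,labels_b Named vectors of cluster labels; cells are
#'   matched by name (or by position when unnamed).
#' @return List with `counts` (matrix) and `row_normalized`.
#' @export
cluster_overlap_matrix <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    common <- intersect(names(labels_a), names(labels_b))
    labels_a <- labels_a[common]; labels_b <- labels_b[common]
  } else stopifnot(length(labels_a) == length(labels_b))
  counts <- as.matrix(table(labels_a, labels_b))
  rn <- counts / pmax(rowSums(counts), 1L)
  list(counts = counts, row_normalized = rn)
}

#' Marker-set annotation score against a reference expression matrix
#'
#' Reference expression rows (genes) are z-scaled across cell types
#' (zero-variance rows set to 0); each (cluster, cell type) entry is the mean
#' scaled expression of that cluster's marker genes present in the reference.
#'
#' @param marker_sets Named list: cluster -> character vector of marker genes.
#' @param ref_expr Numeric gene x cell-type matrix of normalized expression.
#' @return List with `scores` (cluster x cell-type matrix) and
#'   `missing_genes` (per cluster, markers absent from the reference).
#' @export
annotation_score <- function(marker_sets, ref_expr) {
  ref_expr <- as.matrix(ref_expr)
  mu <- rowMeans(ref_expr)
  sd <- apply(ref_expr, 1L, stats::sd)
  z <- (ref_expr - mu) / ifelse(sd == 0, 1, sd)
  z[sd == 0, ] <- 0
  scores <- t(vapply(marker_sets, function(genes) {
    present <- intersect(genes, rownames(z))
    if (length(present) == 0L) return(rep(NA_real_, ncol(z)))
    colMeans(z[present, , drop = FALSE])
  }, numeric(ncol(z))))
  dimnames(scores) <- list(names(marker_sets), colnames(ref_expr))
  missing <- lapply(marker_sets, function(g) setdiff(g, rownames(ref_expr)))
  list(scores = scores, missing_genes = missing)
}
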