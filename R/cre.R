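# cis-regulatory element classification: gene domains, summit merging,
# fixed-width windows, CPM quantification, clustering and the associated
# enrichment / co-occurrence / per-domain statistics.
# Coordinates are BED 0-based half-open throughout; GRanges conversions add 1.

df_to_gr <- function(df, start = "start", end = "end") {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df[[start]] + 1L, df[[end]]))
}

#' Gene regulatory domains from a gene annotation
#'
#' Each gene's domain runs from the end of its nearest upstream
#' non-overlapping gene to the start of its nearest downstream
#' non-overlapping gene (chromosome-by-chromosome scan); genes at chromosome
#' edges are bounded by the minimum / maximum annotated coordinate on that
#' chromosome. When transcript-level records are supplied they are first
#' filtered to protein-coding entries (if a `type` column is present) and
#' collapsed per gene to the most upstream start and most downstream end.
#' Invalid intervals are dropped and counted.
#'
#' @param annotation Data.frame with columns `chrom,start,end,gene` (0-based
#'   half-open; optional `type` column filtered to `"protein_coding"`), or a
#'   GTF/GFF3 path (read via rtracklayer, transcript records with
#'   `transcript_type`/`transcript_biotype` protein_coding).
#' @return Data.frame `chrom, domain_start, domain_end, gene, gene_start,
#'   gene_end`, sorted; attribute `n_dropped` counts invalid intervals.
#' @export
gene_domains <- function(annotation) {
  if (is.character(annotation)) annotation <- read_gene_annotation(annotation)
  need <- c("chrom", "start", "end", "gene")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) stop("missing annotation columns: ",
                         paste(miss, collapse = ", "))
  if ("type" %in% names(annotation))
    annotation <- annotation[annotation$type == "protein_coding", ,
                             drop = FALSE]
  if (nrow(annotation) == 0L) stop("no usable annotation records")
  # collapse transcripts: union span per gene
  genes <- do.call(rbind, lapply(split(annotation, annotation$gene), function(g) {
    if (length(unique(g$chrom)) > 1L) return(NULL)
    data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
               gene = g$gene[1], stringsAsFactors = FALSE)
  }))
  n_multi <- length(unique(annotation$gene)) - nrow(genes)
  out <- do.call(rbind, lapply(split(genes, genes$chrom), function(g) {
    chrom_min <- min(g$start); chrom_max <- max(g$end)
    ends_sorted <- sort(g$end)
    starts_sorted <- sort(g$start)
    up <- vapply(g$start, function(s) {
      k <- findInterval(s, ends_sorted)
      if (k >= 1L) ends_sorted[k] else chrom_min
    }, numeric(1))
    down <- vapply(g$end, function(e) {
      k <- findInterval(e - 0.5, starts_sorted)   # first start >= e
      if (k < length(starts_sorted)) starts_sorted[k + 1L] else chrom_max
    }, numeric(1))
    data.frame(chrom = g$chrom, domain_start = pmin(up, g$start),
               domain_end = pmax(down, g$end), gene = g$gene,
               gene_start = g$start, gene_end = g$end,
               stringsAsFactors = FALSE)
  }))
  bad <- out$domain_start >= out$domain_end
  out <- out[!bad, , drop = FALSE]
  out <- out[order(out$chrom, out$domain_start, out$domain_end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(bad) + n_multi
  out
}

#' @rdname gene_domains
#' @param path GTF/GFF3 file path.
#' @export
read_gene_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF/GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("transcript", "mRNA")
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]
  type_col <- intersect(c("transcript_type", "transcript_biotype",
                          "gene_type", "gene_biotype"), names(md))
  gene_col <- intersect(c("gene_name", "gene_id"), names(md))[1]
  if (is.na(gene_col)) stop("annotation lacks gene_name/gene_id attributes")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   gene = as.character(md[[gene_col]]),
                   stringsAsFactors = FALSE)
  if (length(type_col)) df$type <- as.character(md[[type_col[1]]])
  df
}

#' Greedy collapse of nearby peak summits
#'
#' A single sorted sweep per chromosome: a summit within `collapse_bp` of the
#' current retained summit is merged into it, the higher-scoring of the two
#' (position and score) being retained — later comparisons are anchored to
#' the retained summit, not to chained raw positions. Score ties keep the
#' earlier summit.
#'
#' @param summits Data.frame `chrom, pos, score` (additional columns kept
#'   from the retained summit's row).
#' @param collapse_bp Collapse radius in bp (default 100).
#' @return Data.frame of retained summits, sorted by (chrom, pos).
#' @export
merge_summits <- function(summits, collapse_bp = 100L) {
  if (nrow(summits) == 0L) return(summits)
  out <- lapply(split(summits, summits$chrom), function(s) {
    s <- s[order(s$pos), , drop = FALSE]
    keep <- integer(0)
    cur <- 1L
    for (i in seq_len(nrow(s))[-1]) {
      if (s$pos[i] - s$pos[cur] <= collapse_bp) {
        if (s$score[i] > s$score[cur]) cur <- i
      } else {
        keep <- c(keep, cur)
        cur <- i
      }
    }
    s[c(keep, cur), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fixed-width windows centered on summits
#'
#' `[pos - width/2, pos + width/2)`, clipped to `[0, chromosome length)` so
#' edge windows may be narrower than `width`.
#'
#' @param summits Data.frame `chrom, pos, score`.
#' @param width Window width in bp (default 200).
#' @param chrom_sizes Optional named vector / two-column data.frame of
#'   chromosome lengths for clipping.
#' @return Data.frame `chrom, start, end, id, score`.
#' @export
summit_windows <- function(summits, width = 200L, chrom_sizes = NULL) {
  half <- as.integer(width) %/% 2L
  start <- pmax(summits$pos - half, 0L)
  end <- summits$pos + (width - half)
  if (!is.null(chrom_sizes)) {
    sizes <- normalize_chrom_sizes(chrom_sizes)
    end <- pmin(end, sizes[summits$chrom])
  }
  data.frame(chrom = summits$chrom, start = as.integer(start),
             end = as.integer(end),
             id = paste0(summits$chrom, ":", summits$pos),
             score = summits$score, stringsAsFactors = FALSE)
}

#' Merge per-lineage summit windows into one standardized feature set
#'
#' Windows from all lineages are concatenated and overlapping intervals
#' merged. Merged intervals wider than `width` (different lineages placed
#' their summits at different positions) are reassigned to a single
#' representative summit: the highest-scoring original summit overlapping the
#' interval, re-centered into a fixed `width` window. The output is
#' non-redundant and sorted.
#'
#' @param window_list List of window data.frames (from [summit_windows()]).
#' @param all_summits Data.frame of all original summits (`chrom,pos,score`).
#' @param width Standard window width (default 200).
#' @param chrom_sizes Optional chromosome sizes for clipping.
#' @return Window data.frame `chrom, start, end, id, score`.
#' @export
cross_lineage_merge <- function(window_list, all_summits, width = 200L,
                                chrom_sizes = NULL) {
  all_win <- do.call(rbind, lapply(window_list, function(w)
    w[c("chrom", "start", "end", "id", "score")]))
  merged <- GenomicRanges::reduce(df_to_gr(all_win))
  mdf <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                    start = GenomicRanges::start(merged) - 1L,
                    end = GenomicRanges::end(merged),
                    stringsAsFactors = FALSE)
  wide <- (mdf$end - mdf$start) > width
  keep <- mdf[!wide, , drop = FALSE]
  # narrow intervals are single windows: recover their id/score
  if (nrow(keep)) {
    m <- match(paste(keep$chrom, keep$start, keep$end),
               paste(all_win$chrom, all_win$start, all_win$end))
    keep$id <- all_win$id[m]
    keep$score <- all_win$score[m]
  }
  out <- keep
  if (any(wide)) {
    wdf <- mdf[wide, , drop = FALSE]
    sgr <- GenomicRanges::GRanges(all_summits$chrom,
                                  IRanges::IRanges(all_summits$pos + 1L,
                                                   all_summits$pos + 1L))
    hits <- GenomicRanges::findOverlaps(df_to_gr(wdf), sgr)
    rep_summits <- do.call(rbind, lapply(seq_len(nrow(wdf)), function(i) {
      s <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
      if (length(s) == 0L) {   # defensive: no original summit overlaps
        center <- (wdf$start[i] + wdf$end[i]) %/% 2L
        return(data.frame(chrom = wdf$chrom[i], pos = center, score = NA_real_))
      }
      best <- s[which.max(all_summits$score[s])]
      data.frame(chrom = all_summits$chrom[best], pos = all_summits$pos[best],
                 score = all_summits$score[best])
    }))
    out <- rbind(out, summit_windows(rep_summits, width, chrom_sizes))
  }
  out <- out[!duplicated(paste(out$chrom, out$start, out$end)), , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quantify fragments over the standardized element windows
#'
#' Counts fragments overlapping each window by at least 1 bp (half-open
#' arithmetic) for every (cluster, mark) fragment set and scales to counts
#' per million of that set's total fragments.
#'
#' @param windows Window data.frame (`chrom,start,end,id`).
#' @param frag_sets Named list of fragment data.frames, one per
#'   (cluster, mark) combination; names become the matrix columns (use e.g.
#'   `"HSC.H3K4me2"`).
#' @return List of class `element_matrix`: `windows`, `counts`, `cpm`
#'   (window x column matrices), `totals` (fragments per set).
#' @export
quantify_elements <- function(windows, frag_sets) {
  wgr <- df_to_gr(windows)
  counts <- vapply(frag_sets, function(fr)
    GenomicRanges::countOverlaps(wgr, fragments_to_granges(fr)),
    numeric(nrow(windows)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = nrow(windows))
  totals <- vapply(frag_sets, nrow, integer(1))
  cpm <- sweep(counts, 2L, pmax(totals, 1L), "/") * 1e6
  dimnames(counts) <- dimnames(cpm) <- list(windows$id, names(frag_sets))
  structure(list(windows = windows, counts = counts, cpm = cpm,
                 totals = totals), class = "element_matrix")
}

#' @export
print.element_matrix <- function(x, ...) {
  cat("element_matrix:", nrow(x$cpm), "windows x", ncol(x$cpm),
      "(cluster, mark) columns\n")
  invisible(x)
}

#' Remove cumulative-signal outlier elements
#'
#' Cumulative signal is the row sum of the CPM matrix across all columns;
#' rows strictly below the `low_q` percentile or strictly above the `high_q`
#' percentile are removed (linear-interpolation percentiles, so a fully tied
#' matrix is retained in full).
#'
#' @param em An `element_matrix` from [quantify_elements()] (or a bare
#'   numeric matrix).
#' @param low_q,high_q Percentile bounds (defaults 0.05 and 0.95).
#' @return Filtered object of the same type; attribute `n_removed`.
#' @export
outlier_filter <- function(em, low_q = 0.05, high_q = 0.95) {
  mat <- if (inherits(em, "element_matrix")) em$cpm else em
  s <- rowSums(mat)
  q <- stats::quantile(s, c(low_q, high_q), type = 7, names = FALSE)
  keep <- !(s < q[1] | s > q[2])
  if (inherits(em, "element_matrix")) {
    out <- em
    out$windows <- em$windows[keep, , drop = FALSE]
    out$counts <- em$counts[keep, , drop = FALSE]
    out$cpm <- em$cpm[keep, , drop = FALSE]
    attr(out, "n_removed") <- sum(!keep)
    return(out)
  }
  structure(mat[keep, , drop = FALSE], n_removed = sum(!keep))
}

standardize_columns <- function(mat) {
  mu <- colMeans(mat)
  sd <- apply(mat, 2L, stats::sd)
  z <- sweep(sweep(mat, 2L, mu), 2L, ifelse(sd == 0, 1, sd), "/")
  z[, sd == 0] <- 0
  z
}

block_norm_rescale <- function(mat, marks) {
  norms <- vapply(unique(marks), function(m)
    sqrt(sum(mat[, marks == m, drop = FALSE]^2)), numeric(1))
  target <- stats::median(norms)
  for (m in unique(marks)) {
    nm <- norms[[m]]
    if (nm > 0) mat[, marks == m] <- mat[, marks == m] * (target / nm)
  }
  attr(mat, "block_norms") <- norms
  mat
}

knn_graph <- function(x, k) {
  n <- nrow(x)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(x))
  edges <- matrix(0L, 0L, 2L); wts <- numeric(0)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1L)]
    edges <- rbind(edges, cbind(i, nb))
    wts <- c(wts, 1 / pmax(d[i, nb], 1e-12))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- wts
  igraph::simplify(g, edge.attr.comb = list(weight = "max"))
}

canonical_labels <- function(membership) {
  sizes <- sort(table(membership), decreasing = TRUE)
  new <- stats::setNames(seq_along(sizes), names(sizes))
  as.integer(new[as.character(membership)])
}

#' Cluster regulatory elements by their chromatin-signal profiles
#'
#' The CPM matrix is column-standardized (zero-variance columns set to 0) and
#' each histone-mark column block rescaled to the median block Frobenius norm
#' so no mark dominates. PCA is followed by a k-nearest-neighbour graph with
#' inverse-Euclidean edge weights (distances floored at 1e-12) and seeded
#' Leiden community detection; labels are canonicalized by descending class
#' size. A 2-D UMAP of the PCA space (40 neighbours, min-dist 0.25,
#' Euclidean) is attached for reporting when the uwot package is available.
#'
#' @param em `element_matrix` (filtered) or bare CPM matrix.
#' @param marks Character vector assigning each column to a histone mark; by
#'   default parsed from column names of the form `"cluster.mark"`.
#' @param n_pcs Principal components for graph construction (default 16;
#'   lowered with a warning when the matrix is smaller).
#' @param k Neighbours in the kNN graph (default 30).
#' @param resolution Leiden resolution parameter (default 4).
#' @param seed Integer seed.
#' @param umap Compute the reporting UMAP (default TRUE).
#' @return List: `labels` (integer per element), `pca` (score matrix),
#'   `embedding` (UMAP or NULL), `block_norms`.
#' @export
cluster_elements <- function(em, marks = NULL, n_pcs = 16L, k = 30L,
                             resolution = 4, seed = 1L, umap = TRUE) {
  mat <- if (inherits(em, "element_matrix")) em$cpm else as.matrix(em)
  if (is.null(marks))
    marks <- sub("^[^.]*\\.", "", colnames(mat))
  stopifnot(length(marks) == ncol(mat))
  z <- standardize_columns(mat)
  z <- block_norm_rescale(z, marks)
  max_pcs <- min(ncol(z), nrow(z) - 1L)
  if (n_pcs > max_pcs) {
    warning("n_pcs lowered from ", n_pcs, " to ", max_pcs)
    n_pcs <- max_pcs
  }
  pca <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  scores <- pca$x[, seq_len(n_pcs), drop = FALSE]
  g <- knn_graph(scores, k)
  set.seed(seed)
  part <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution,
                                 weights = igraph::E(g)$weight,
                                 n_iterations = 5L)
  labels <- canonical_labels(igraph::membership(part))
  emb <- NULL
  if (umap && requireNamespace("uwot", quietly = TRUE)) {
    set.seed(seed)
    emb <- uwot::umap(scores, n_neighbors = min(40L, nrow(scores) - 1L),
                      min_dist = 0.25, metric = "euclidean")
  }
  list(labels = labels, pca = scores, embedding = emb,
       block_norms = attr(z, "block_norms"))
}

#' Refine selected element classes by a second clustering round
#'
#' Reruns [cluster_elements()] on the subset of elements whose label is in
#' `select`, at a lower resolution, and overwrites their labels with refined
#' sublabels (`"<old>.<sub>"`); non-selected elements keep their labels.
#'
#' @param em `element_matrix` or CPM matrix (full set).
#' @param labels Current labels (from [cluster_elements()]).
#' @param select Labels to refine; empty selection returns `labels`
#'   unchanged.
#' @param n_pcs,k,resolution,seed As in [cluster_elements()] (defaults 15,
#'   30, 0.5).
#' @return Character label vector over all elements.
#' @export
recluster_elements <- function(em, labels, select, n_pcs = 15L, k = 30L,
                               resolution = 0.5, seed = 1L) {
  out <- as.character(labels)
  sel <- labels %in% select
  if (!any(sel)) return(out)
  mat <- if (inherits(em, "element_matrix")) em$cpm else as.matrix(em)
  sub <- cluster_elements(mat[sel, , drop = FALSE], n_pcs = n_pcs, k = k,
                          resolution = resolution, seed = seed, umap = FALSE)
  out[sel] <- paste0(labels[sel], ".", sub$labels)
  out
}

#' Promoter fraction per element class
#'
#' Transcription start sites are expanded by `flank` bp on each side
#' (clipped to chromosome bounds); an element is promoter-overlapping when it
#' intersects any expanded TSS window by >= 1 bp. Returns the fraction of
#' promoter-overlapping elements per class.
#'
#' @param windows Window data.frame.
#' @param labels Element class labels (aligned with `windows` rows).
#' @param tss Data.frame `chrom, pos` of TSS coordinates (0-based).
#' @param flank Expansion in bp (default 2000).
#' @param chrom_sizes Optional chromosome sizes for clipping.
#' @return List: `fraction` (named per class), `overall`, `is_promoter`
#'   (logical per window).
#' @export
promoter_fraction <- function(windows, labels, tss, flank = 2000L,
                              chrom_sizes = NULL) {
  prom <- data.frame(chrom = tss$chrom, start = pmax(tss$pos - flank, 0L),
                     end = tss$pos + flank)
  if (!is.null(chrom_sizes)) {
    sizes <- normalize_chrom_sizes(chrom_sizes)
    prom$end <- pmin(prom$end, sizes[prom$chrom])
  }
  shared <- intersect(unique(windows$chrom), unique(prom$chrom))
  is_prom <- rep(FALSE, nrow(windows))
  if (length(shared)) {
    hits <- GenomicRanges::countOverlaps(df_to_gr(windows), df_to_gr(prom))
    is_prom <- hits > 0L
  }
  list(fraction = tapply(is_prom, labels, mean),
       overall = mean(is_prom), is_promoter = is_prom)
}

#' Element-class enrichment over gene-domain groups
#'
#' Observed counts O[e, g] are elements of class e overlapping any domain of
#' group g; expected counts are `N_e * f_g` with `f_g` the genome-wide
#' fraction of elements overlapping group g. Enrichment is
#' `log2((O + 0.5) / (E + 0.5))`, converted to row-wise softmax weights so
#' each element class's domain-group contributions sum to one. Domain groups
#' must be mutually exclusive in their genes; a violation is an error listing
#' the offending genes.
#'
#' @param windows Window data.frame.
#' @param labels Element class labels.
#' @param domain_groups Named list of gene-domain data.frames
#'   (`chrom, domain_start, domain_end, gene`).
#' @return List: `observed`, `expected`, `log2_enrichment`, `weights`.
#' @export
domain_enrichment <- function(windows, labels, domain_groups) {
  genes <- lapply(domain_groups, function(d) unique(d$gene))
  all_genes <- unlist(genes)
  dup <- unique(all_genes[duplicated(all_genes)])
  if (length(dup))
    stop("gene-domain groups are not disjoint; shared genes: ",
         paste(utils::head(dup, 10L), collapse = ", "))
  wgr <- df_to_gr(windows)
  overlaps <- vapply(domain_groups, function(d)
    GenomicRanges::countOverlaps(wgr, df_to_gr(d, "domain_start",
                                               "domain_end")) > 0L,
    logical(nrow(windows)))
  if (is.null(dim(overlaps))) overlaps <- matrix(overlaps, nrow = nrow(windows))
  classes <- sort(unique(as.character(labels)))
  O <- t(vapply(classes, function(e)
    colSums(overlaps[labels == e, , drop = FALSE]),
    numeric(length(domain_groups))))
  dimnames(O) <- list(classes, names(domain_groups))
  f_g <- colSums(overlaps) / nrow(windows)
  N_e <- as.numeric(table(factor(labels, classes)))
  E <- outer(N_e, f_g)
  dimnames(E) <- dimnames(O)
  enr <- log2((O + 0.5) / (E + 0.5))
  weights <- exp(enr) / rowSums(exp(enr))
  list(observed = O, expected = E, log2_enrichment = enr, weights = weights)
}

#' Presence/absence of element classes within gene domains
#'
#' @param windows Window data.frame.
#' @param labels Element class labels.
#' @param domains Gene-domain data.frame.
#' @return Logical gene x element-class matrix: TRUE when at least one
#'   element of the class overlaps the gene's domain.
#' @export
element_presence <- function(windows, labels, domains) {
  hits <- GenomicRanges::findOverlaps(
    df_to_gr(domains, "domain_start", "domain_end"), df_to_gr(windows))
  classes <- sort(unique(as.character(labels)))
  out <- matrix(FALSE, nrow(domains), length(classes),
                dimnames = list(domains$gene, classes))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    cls <- as.character(labels)[S4Vectors::subjectHits(hits)]
    out[cbind(q, match(cls, classes))] <- TRUE
  }
  out
}

#' Pairwise element-class co-occurrence across gene domains
#'
#' For each pair of element classes a 2x2 contingency table over genes
#' (both / only first / only second / neither) is tested with a two-sided
#' Fisher exact test; enrichment is the Haldane-stabilized log2 odds ratio
#' (0.5 added to every cell). P values are Benjamini-Hochberg adjusted
#' across all pairs; network edges are the significant positive
#' associations, optionally thinned to a top-weight backbone.
#'
#' @param presence Logical gene x element-class matrix (from
#'   [element_presence()]).
#' @param fdr FDR cutoff for edges (default 0.05).
#' @param min_degree Drop edge-list nodes below this degree (default 1).
#' @param top_n Keep at most this many edges by |log2 OR| (default 50).
#' @return List: `pairs` (data.frame class_a, class_b, both, only_a, only_b,
#'   neither, log2_or, p, fdr), `edges` (significant positive backbone).
#' @export
cooccurrence <- function(presence, fdr = 0.05, min_degree = 1L, top_n = 50L) {
  classes <- colnames(presence)
  if (length(classes) < 2L) stop("need at least two element classes")
  cmb <- utils::combn(classes, 2L)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    a <- presence[, cmb[1, k]]; b <- presence[, cmb[2, k]]
    both <- sum(a & b); only_a <- sum(a & !b)
    only_b <- sum(!a & b); neither <- sum(!a & !b)
    tab <- matrix(c(both, only_a, only_b, neither), 2L, byrow = TRUE)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    data.frame(class_a = cmb[1, k], class_b = cmb[2, k], both = both,
               only_a = only_a, only_b = only_b, neither = neither,
               log2_or = log2(((both + 0.5) * (neither + 0.5)) /
                                ((only_a + 0.5) * (only_b + 0.5))),
               p = p, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  pairs$fdr <- stats::p.adjust(pairs$p, method = "BH")
  edges <- pairs[pairs$fdr < fdr & pairs$log2_or > 0, , drop = FALSE]
  if (nrow(edges) > top_n)
    edges <- edges[order(-abs(edges$log2_or))[seq_len(top_n)], , drop = FALSE]
  deg <- table(c(edges$class_a, edges$class_b))
  keep_nodes <- names(deg)[deg >= min_degree]
  edges <- edges[edges$class_a %in% keep_nodes &
                   edges$class_b %in% keep_nodes, , drop = FALSE]
  rownames(edges) <- NULL
  list(pairs = pairs, edges = edges)
}

#' Per-gene element counts, peak signal maxima and group comparisons
#'
#' Summarizes, for every gene domain, the number of enhancer-class and
#' promoter-class elements it contains; assigns each peak its global maximum
#' CPM across cell-type clusters for the designated mark (H3K4me1 for
#' enhancers, H3K4me3 for promoters); and compares the count and signal
#' distributions between stated gene groups with two-sided Mann-Whitney
#' (Wilcoxon rank-sum) tests, Benjamini-Hochberg adjusted across all
#' comparisons.
#'
#' @param windows Window data.frame.
#' @param labels Element class labels.
#' @param domains Gene-domain data.frame.
#' @param gene_groups Named list: group -> character vector of genes.
#' @param enhancer_classes,promoter_classes Labels counting as enhancer /
#'   promoter elements.
#' @param em Optional `element_matrix` for the signal summaries.
#' @param enhancer_mark,promoter_mark Mark names used for the per-peak
#'   maximum signal (matched against the `"cluster.mark"` column names).
#' @param comparisons List of 2-vectors of group names to test (default:
#'   all pairs).
#' @return List: `per_gene` (gene, enhancer/promoter counts), `per_peak`
#'   (peak id, class, max enhancer/promoter-mark signal), `tests`
#'   (comparison, measure, U statistic, p, fdr).
#' @export
domain_element_stats <- function(windows, labels, domains, gene_groups,
                                 enhancer_classes, promoter_classes,
                                 em = NULL, enhancer_mark = "H3K4me1",
                                 promoter_mark = "H3K4me3",
                                 comparisons = NULL) {
  pres_counts <- function(classes) {
    sel <- labels %in% classes
    hits <- GenomicRanges::countOverlaps(
      df_to_gr(domains, "domain_start", "domain_end"),
      df_to_gr(windows[sel, , drop = FALSE]))
    stats::setNames(hits, domains$gene)
  }
  per_gene <- data.frame(gene = domains$gene,
                         enhancer_count = unname(pres_counts(enhancer_classes)),
                         promoter_count = unname(pres_counts(promoter_classes)),
                         stringsAsFactors = FALSE)
  per_peak <- NULL
  if (!is.null(em)) {
    mark_of <- sub("^[^.]*\\.", "", colnames(em$cpm))
    max_sig <- function(mark) {
      cols <- mark_of == mark
      if (!any(cols)) return(rep(NA_real_, nrow(em$cpm)))
      apply(em$cpm[, cols, drop = FALSE], 1L, max)
    }
    per_peak <- data.frame(id = em$windows$id, class = as.character(labels),
                           enhancer_signal = max_sig(enhancer_mark),
                           promoter_signal = max_sig(promoter_mark),
                           stringsAsFactors = FALSE)
  }
  if (is.null(comparisons) && length(gene_groups) >= 2L) {
    cmb <- utils::combn(names(gene_groups), 2L)
    comparisons <- lapply(seq_len(ncol(cmb)), function(k) cmb[, k])
  }
  tests <- NULL
  if (length(comparisons)) {
    rows <- list()
    for (cmp in comparisons) {
      ga <- gene_groups[[cmp[1]]]; gb <- gene_groups[[cmp[2]]]
      for (measure in c("enhancer_count", "promoter_count")) {
        va <- per_gene[[measure]][per_gene$gene %in% ga]
        vb <- per_gene[[measure]][per_gene$gene %in% gb]
        if (length(va) == 0L || length(vb) == 0L) next
        wt <- suppressWarnings(
          stats::wilcox.test(va, vb, alternative = "two.sided"))
        rows[[length(rows) + 1L]] <-
          data.frame(group_a = cmp[1], group_b = cmp[2], measure = measure,
                     U = unname(wt$statistic), p = wt$p.value,
                     stringsAsFactors = FALSE)
      }
    }
    tests <- do.call(rbind, rows)
    if (!is.null(tests)) tests$fdr <- stats::p.adjust(tests$p, method = "BH")
  }
  list(per_gene = per_gene, per_peak = per_peak, tests = tests)
}
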