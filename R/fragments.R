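#' Convert BEDPE read-pair records to fragments
#'
#' A fragment spans from the leftmost mate start to the rightmost mate end,
#' in 0-based half-open coordinates. Cross-chromosome pairs (discordant pairs
#' that slipped through upstream filtering) are skipped and counted, as are
#' fragments longer than the insert-size cap.
#'
#' @param bedpe A data.frame with columns `chrom1,start1,end1,chrom2,start2,
#'   end2,cell` (extra columns ignored), or a path to a BEDPE file whose
#'   seventh column is the cell barcode.
#' @param max_insert Insert-size cap in bp (default 1000, the aligner's
#'   maximum fragment length).
#' @return A fragment data.frame (`chrom,start,end,cell`), sorted by
#'   (chrom, start, end, cell), with attributes `n_cross_chrom` and
#'   `n_too_long`.
#' @export
bedpe_to_fragments <- function(bedpe, max_insert = 1000L) {
  if (is.character(bedpe)) {
    bedpe <- utils::read.table(bedpe, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)
    if (ncol(bedpe) < 7L)
      stop("BEDPE needs >= 7 columns (chrom1,start1,end1,chrom2,start2,end2,cell); line 1 has ",
           ncol(bedpe))
    names(bedpe)[1:7] <- c("chrom1", "start1", "end1", "chrom2", "start2",
                           "end2", "cell")
  }
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "cell")
  miss <- setdiff(need, names(bedpe))
  if (length(miss)) stop("missing BEDPE columns: ", paste(miss, collapse = ", "))
  bad <- !is.finite(bedpe$start1) | !is.finite(bedpe$end1) |
    !is.finite(bedpe$start2) | !is.finite(bedpe$end2)
  if (any(bad)) stop("malformed BEDPE record at line ", which(bad)[1])
  cross <- bedpe$chrom1 != bedpe$chrom2
  keep <- bedpe[!cross, , drop = FALSE]
  frags <- data.frame(chrom = keep$chrom1,
                      start = pmin(keep$start1, keep$start2),
                      end = pmax(keep$end1, keep$end2),
                      cell = keep$cell, stringsAsFactors = FALSE)
  if (any(frags$start >= frags$end))
    stop("invalid fragment (start >= end) at input line ",
         which(!cross)[frags$start >= frags$end][1])
  too_long <- (frags$end - frags$start) > max_insert
  frags <- frags[!too_long, , drop = FALSE]
  frags <- frags[order(frags$chrom, frags$start, frags$end, frags$cell), ,
                 drop = FALSE]
  rownames(frags) <- NULL
  attr(frags, "n_cross_chrom") <- sum(cross)
  attr(frags, "n_too_long") <- sum(too_long)
  frags
}

#' Deduplicate fragments
#'
#' In single-cell mode one fragment is kept per unique
#' `(chrom, start, end, cell)` — biological duplicates from the same cell are
#' vanishingly unlikely, so identical coordinates within a cell are PCR
#' duplicates. Identical coordinates in different cells are kept. Bulk mode
#' retains duplicates and returns the input unchanged.
#'
#' @param frags Fragment data.frame (`chrom,start,end,cell`).
#' @param mode `"single_cell"` or `"bulk"`.
#' @return Deduplicated fragment data.frame.
#' @export
deduplicate <- function(frags, mode = c("single_cell", "bulk")) {
  mode <- match.arg(mode)
  if (mode == "bulk") return(frags)
  key <- paste(frags$chrom, frags$start, frags$end, frags$cell, sep = "\r")
  out <- frags[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coverage-based track scaling factor
#'
#' `1e10 / total coverage`, where total coverage is the summed fragment
#' length over all intervals. [anchor_scale_factor()] computes the same
#' quantity on an anchor mark (e.g. H3K27ac) so one shared factor can be
#' applied to every track of a paired sample, making co-occupancy depths
#' quantitatively comparable across samples.
#'
#' @param frags Fragment data.frame.
#' @return A scale factor (positive numeric) with attribute `basis`.
#' @export
coverage_scale_factor <- function(frags) {
  if (nrow(frags) == 0L) stop("cannot scale an empty fragment set")
  total <- sum(as.numeric(frags$end - frags$start))
  structure(1e10 / total, basis = "coverage")
}

#' @rdname coverage_scale_factor
#' @param anchor Fragment data.frame of the anchor mark.
#' @export
anchor_scale_factor <- function(anchor) {
  f <- coverage_scale_factor(anchor)
  attr(f, "basis") <- "anchor_coverage"
  f
}

fragments_to_granges <- function(frags) {
  GenomicRanges::GRanges(frags$chrom,
                         IRanges::IRanges(frags$start + 1L, frags$end))
}

#' Scaled per-base coverage track
#'
#' Fragment pileup times the scaling factor, emitted as maximal
#' constant-value intervals (BedGraph semantics, 0-based half-open), clipped
#' to chromosome sizes. Zero-coverage runs are omitted.
#'
#' @param frags Fragment data.frame.
#' @param factor Scaling factor (e.g. from [coverage_scale_factor()]).
#' @param chrom_sizes Named vector of chromosome lengths, or a data.frame
#'   with columns `chrom`, `size`.
#' @param digits Fixed decimal precision of emitted values (default 5).
#' @return BedGraph data.frame (`chrom,start,end,value`).
#' @export
make_bedgraph <- function(frags, factor = 1, chrom_sizes, digits = 5L) {
  sizes <- normalize_chrom_sizes(chrom_sizes)
  if (nrow(frags) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0)))
  unknown <- setdiff(unique(frags$chrom), names(sizes))
  if (length(unknown))
    stop("fragments on chromosomes absent from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  over <- frags$end > sizes[frags$chrom]
  if (any(over)) {
    warning(sum(over), " fragment(s) extend beyond chromosome end; clipped")
    frags$end <- pmin(frags$end, sizes[frags$chrom])
    frags <- frags[frags$start < frags$end, , drop = FALSE]
  }
  gr <- fragments_to_granges(frags)
  cov <- GenomicRanges::coverage(gr)
  out <- lapply(names(cov), function(chr) {
    r <- cov[[chr]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, ends[-length(ends)])
    vals <- S4Vectors::runValue(r)
    keep <- vals > 0L
    if (!any(keep)) return(NULL)
    data.frame(chrom = chr, start = starts[keep],
               end = pmin(ends[keep], sizes[chr]),
               value = round(as.numeric(vals[keep]) * as.numeric(factor),
                             digits))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

normalize_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    sizes <- chrom_sizes[[2]]
    names(sizes) <- chrom_sizes[[1]]
  } else sizes <- chrom_sizes
  if (is.null(names(sizes))) stop("chrom_sizes must be named")
  sizes
}

#' Read/write helpers for fragment BED and chrom.sizes files
#'
#' Fragments travel as BED: `chrom start end cell` (0-based half-open,
#' column 4 the cell barcode). `read_chrom_sizes()` reads the UCSC two-column
#' format.
#'
#' @param path File path (gzip transparent on read).
#' @return `read_fragments()`: fragment data.frame. `read_chrom_sizes()`:
#'   named vector of lengths.
#' @export
read_fragments <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4L) names(x)[4] <- "cell" else x$cell <- NA_character_
  x[c("chrom", "start", "end", "cell")]
}

#' @rdname read_fragments
#' @param frags Fragment data.frame.
#' @export
write_fragments <- function(frags, path) {
  utils::write.table(frags[c("chrom", "start", "end", "cell")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname read_fragments
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  stats::setNames(x[[2]], x[[1]])
}

#' @rdname read_fragments
#' @param bedgraph BedGraph data.frame from [make_bedgraph()].
#' @param digits Fixed decimal precision for values.
#' @export
write_bedgraph <- function(bedgraph, path, digits = 5L) {
  lines <- sprintf(paste0("%s\t%d\t%d\t%.", digits, "f"), bedgraph$chrom,
                   bedgraph$start, bedgraph$end, bedgraph$value)
  writeLines(lines, path)
  invisible(path)
}

#' Group fragments into per-cluster pseudobulks
#'
#' Fragments are grouped by their cell's cluster; each cluster gets the
#' cell-number scaling factor `10000 / n_cells(cluster)` used for
#' cell-number-normalized coverage tracks. Cells absent from the cluster map
#' are excluded and counted.
#'
#' @param frags Fragment data.frame.
#' @param clusters Named character vector or two-column data.frame mapping
#'   cell barcode to cluster label.
#' @return List with `fragments` (named list of per-cluster fragment
#'   data.frames), `scale_factors` (named numeric, `1e4 / n_cells`),
#'   `n_cells`, and `n_unmapped_fragments`.
#' @export
pseudobulk <- function(frags, clusters) {
  if (is.data.frame(clusters))
    clusters <- stats::setNames(as.character(clusters[[2]]),
                                as.character(clusters[[1]]))
  cl <- clusters[frags$cell]
  unmapped <- is.na(cl)
  split_frags <- split(frags[!unmapped, , drop = FALSE], cl[!unmapped])
  n_cells <- table(clusters)
  sf <- 1e4 / as.numeric(n_cells)
  names(sf) <- names(n_cells)
  list(fragments = split_frags,
       scale_factors = sf,
       n_cells = stats::setNames(as.integer(n_cells), names(n_cells)),
       n_unmapped_fragments = sum(unmapped))
}

#' Average per-cell gene scores into a pseudobulk matrix
#'
#' Arithmetic mean of each gene's score over the cells of each cluster.
#'
#' @param scores Numeric gene x cell matrix (rownames genes, colnames cells).
#' @param clusters Named vector or two-column data.frame mapping cell to
#'   cluster.
#' @return Gene x cluster matrix of means.
#' @export
pseudobulk_genescores <- function(scores, clusters) {
  if (is.data.frame(clusters))
    clusters <- stats::setNames(as.character(clusters[[2]]),
                                as.character(clusters[[1]]))
  cl <- clusters[colnames(scores)]
  if (any(is.na(cl)))
    stop("cells without a cluster label: ",
         paste(utils::head(colnames(scores)[is.na(cl)]), collapse = ", "))
  groups <- sort(unique(cl))
  out <- vapply(groups, function(g)
    rowMeans(scores[, cl == g, drop = FALSE]), numeric(nrow(scores)))
  dimnames(out) <- list(rownames(scores), groups)
  out
}
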