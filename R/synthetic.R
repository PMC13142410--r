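#' Configuration for the synthetic-data generators
#'
#' Bundles the study conditions every generator draws from. All generators
#' are pure functions of (config, seed): rerunning with the same
#' configuration reproduces the outputs byte for byte, and each generator
#' returns the ground truth needed to score downstream modules.
#'
#' The score-mixture defaults place the low and high components 4 standard
#' deviations apart on the `log10(score + 0.1)` scale — the separation regime
#' in which mixture thresholding is expected to work — and the state
#' fractions give all four chromatin states substantial mass.
#'
#' @param seed Integer seed.
#' @param n_cells Number of cells.
#' @param n_genes Number of genes.
#' @param n_clusters Number of cell-type clusters.
#' @param n_fragments_per_cell Mean fragments per cell (Poisson).
#' @param barcode_error_rate Per-barcode corruption probability; a corrupted
#'   barcode receives exactly one random substitution.
#' @param state_fractions Named probabilities over
#'   `active`, `repressed`, `bivalent`, `unmarked`; must sum to 1.
#' @param score_mixture List `mu_low`, `mu_high`, `sigma` on the
#'   `log10(score + 0.1)` scale (applied to every mark), or a named list of
#'   such triples per mark.
#' @param n_summits Number of planted regulatory elements.
#' @param n_lineages Number of lineages / pseudobulk clusters for the summit
#'   generator.
#' @param doublet_fraction Fraction of cells placed in the planted
#'   doublet-enriched neighborhood of the embedding generator.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_cells = 200L, n_genes = 500L,
                       n_clusters = 6L, n_fragments_per_cell = 1000,
                       barcode_error_rate = 0,
                       state_fractions = c(active = 0.30, repressed = 0.25,
                                           bivalent = 0.25, unmarked = 0.20),
                       score_mixture = list(mu_low = -0.2, mu_high = 1.4,
                                            sigma = 0.4),
                       n_summits = 300L, n_lineages = 3L,
                       doublet_fraction = 0.05) {
  stopifnot(barcode_error_rate >= 0, barcode_error_rate <= 1,
            doublet_fraction >= 0, doublet_fraction <= 1)
  if (abs(sum(state_fractions) - 1) > 1e-8)
    stop("state_fractions must sum to 1")
  mix <- if (!is.null(score_mixture$mu_low)) list(default = score_mixture)
         else score_mixture
  for (m in mix)
    if (!(m$mu_low < m$mu_high)) stop("score_mixture needs mu_low < mu_high")
  structure(list(seed = as.integer(seed), n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 n_clusters = as.integer(n_clusters),
                 n_fragments_per_cell = n_fragments_per_cell,
                 barcode_error_rate = barcode_error_rate,
                 state_fractions = state_fractions,
                 score_mixture = score_mixture,
                 n_summits = as.integer(n_summits),
                 n_lineages = as.integer(n_lineages),
                 doublet_fraction = doublet_fraction),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_cells, "cells,", x$n_genes,
      "genes,", x$n_clusters, "clusters,", x$n_summits, "summits,",
      x$n_lineages, "lineages\n")
  invisible(x)
}

mixture_for_mark <- function(config, mark) {
  mix <- config$score_mixture
  if (!is.null(mix$mu_low)) return(mix)
  if (!is.null(mix[[mark]])) return(mix[[mark]])
  mix[[1]]
}

substitute_base <- function(seq, pos) {
  base <- substr(seq, pos, pos)
  repl <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
  substr(seq, pos, pos) <- repl
  seq
}

random_seq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Simulate combinatorially indexed reads with known assignments
#'
#' Cells occupy wells of the dual 8x12 plate scheme and unique nanowell index
#' combinations. Each read pair draws a cell and a stream; the stream
#' determines which plate's s5/s7 barcodes are emitted (same-plate
#' combinations are mono-occupancy, mixed combinations co-occupancy). Each of
#' the four barcodes is independently corrupted with probability
#' `barcode_error_rate` by a single random substitution. Genomic read
#' sequences are random A/C/G/T — everything downstream of demultiplexing is
#' exercised on fragments, not alignments.
#'
#' @param config A [sim_config()].
#' @param scheme A [barcode_scheme()].
#' @param n_reads Total read pairs to simulate.
#' @param stream_props Probabilities over
#'   `c(target1, target2, co1, co2)`.
#' @param read_len Genomic read length (default 50).
#' @param out_dir Optional directory; when given, writes `R1/R2/I1/I2`
#'   FASTQ files and the truth table TSV.
#' @return List with `reads` (list of data.frames r1, r2, i1, i2 with
#'   columns id/seq/qual) and `truth` (per read: true barcode indices,
#'   stream, cell barcode, number of corrupted barcodes).
#' @export
simulate_reads <- function(config, scheme, n_reads = 10000L,
                           stream_props = c(target1 = 0.35, target2 = 0.35,
                                            co1 = 0.15, co2 = 0.15),
                           read_len = 50L, out_dir = NULL) {
  set.seed(config$seed)
  n_reads <- as.integer(n_reads)
  empty <- function() data.frame(id = character(0), seq = character(0),
                                 qual = character(0))
  if (config$n_cells == 0L || n_reads == 0L) {
    return(list(reads = list(r1 = empty(), r2 = empty(), i1 = empty(),
                             i2 = empty()),
                truth = data.frame()))
  }
  n_wells_p5 <- length(scheme$p5_wells); n_wells_p7 <- length(scheme$p7_wells)
  combos <- expand.grid(row = 1:8, col = 1:12,
                        p5 = seq_len(n_wells_p5), p7 = seq_len(n_wells_p7))
  cells <- combos[sample(nrow(combos), config$n_cells), , drop = FALSE]

  ci <- sample(config$n_cells, n_reads, replace = TRUE)
  stream <- sample(names(stream_props), n_reads, replace = TRUE,
                   prob = stream_props)
  row <- cells$row[ci]; col <- cells$col[ci]
  s5 <- ifelse(stream %in% c("target1", "co1"), row, row + 8L)
  s7 <- ifelse(stream %in% c("target1", "co2"), col, col + 12L)
  p5 <- cells$p5[ci]; p7 <- cells$p7[ci]

  s5_seq <- scheme$s5[s5]; s7_seq <- scheme$s7[s7]
  p5_seq <- scheme$p5_wells[p5]; p7_seq <- scheme$p7_wells[p7]
  corrupt <- function(seqs) {
    hit <- stats::runif(n_reads) < config$barcode_error_rate
    if (any(hit)) {
      pos <- sample.int(nchar(seqs[1]), sum(hit), replace = TRUE)
      seqs[hit] <- mapply(substitute_base, seqs[hit], pos)
    }
    list(seqs = seqs, hit = hit)
  }
  c_s5 <- corrupt(s5_seq); c_s7 <- corrupt(s7_seq)
  c_p5 <- corrupt(p5_seq); c_p7 <- corrupt(p7_seq)
  n_corrupt <- c_s5$hit + c_s7$hit + c_p5$hit + c_p7$hit

  ids <- sprintf("read%07d", seq_len(n_reads))
  q <- function(len) strrep("I", len)
  i1_seq <- paste0(c_s7$seqs, c_p7$seqs)
  i2_seq <- paste0(c_s5$seqs, c_p5$seqs)
  reads <- list(
    r1 = data.frame(id = ids, seq = random_seq(n_reads, read_len),
                    qual = q(read_len), stringsAsFactors = FALSE),
    r2 = data.frame(id = ids, seq = random_seq(n_reads, read_len),
                    qual = q(read_len), stringsAsFactors = FALSE),
    i1 = data.frame(id = ids, seq = i1_seq, qual = q(nchar(i1_seq[1])),
                    stringsAsFactors = FALSE),
    i2 = data.frame(id = ids, seq = i2_seq, qual = q(nchar(i2_seq[1])),
                    stringsAsFactors = FALSE))
  truth <- data.frame(read = ids, s5 = s5, s7 = s7, p5 = p5, p7 = p7,
                      stream = stream,
                      well = well_id(s5, s7),
                      cell_barcode = cell_barcode(well_id(s5, s7), p5, p7),
                      n_corrupt = as.integer(n_corrupt),
                      stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(reads))
      write_fastq(reads[[nm]], file.path(out_dir, paste0(toupper(nm), ".fastq")))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(reads = reads, truth = truth)
}

#' Simulate pseudobulk gene-score matrices with planted chromatin states
#'
#' For each gene x cluster a true state is drawn from the configured state
#' fractions. Mark scores are drawn from the high or low mixture component
#' according to the state rule: H3K27me3 high for repressed and bivalent
#' genes, each H3K4 mark high for active and bivalent genes, and the
#' co-occupancy signal high only for bivalent genes. Values are drawn as
#' normals on the `log10(score + 0.1)` scale and back-transformed to raw
#' scores (floored at 0).
#'
#' @param config A [sim_config()].
#' @param k4_marks Names of the H3K4 marks (default me1/me2/me3).
#' @return List: `k27` (gene x cluster matrix), `k4` (named list of three
#'   matrices), `co` (named list of three co-occupancy matrices), `truth`
#'   (data.frame gene, cluster, state).
#' @export
simulate_genescores <- function(config,
                                k4_marks = c("H3K4me1", "H3K4me2", "H3K4me3")) {
  set.seed(config$seed)
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  clusters <- sprintf("C%d", seq_len(config$n_clusters))
  n <- config$n_genes * config$n_clusters
  state <- sample(names(config$state_fractions), n, replace = TRUE,
                  prob = config$state_fractions)
  # scores live on the log10(score + 0.1) scale; a valid nonnegative score
  # requires x >= -1, so the components are normals truncated at -1
  draw <- function(high, mark) {
    mix <- mixture_for_mark(config, mark)
    mu <- ifelse(high, mix$mu_high, mix$mu_low)
    lo <- stats::pnorm(-1, mu, mix$sigma)
    x <- stats::qnorm(stats::runif(n, lo, 1), mu, mix$sigma)
    matrix(10^x - 0.1, config$n_genes, config$n_clusters,
           dimnames = list(genes, clusters))
  }
  k27 <- draw(state %in% c("repressed", "bivalent"), "H3K27me3")
  k4 <- lapply(stats::setNames(k4_marks, k4_marks), function(m)
    draw(state %in% c("active", "bivalent"), m))
  co <- lapply(stats::setNames(paste0("co_", k4_marks), k4_marks), function(m)
    draw(state == "bivalent", m))
  truth <- data.frame(gene = rep(genes, times = config$n_clusters),
                      cluster = rep(clusters, each = config$n_genes),
                      state = state, stringsAsFactors = FALSE)
  list(k27 = k27, k4 = k4, co = co, truth = truth)
}

#' Simulate a low-dimensional embedding with matched pairs and a planted
#' doublet neighborhood
#'
#' Cells form Gaussian blobs around well-separated cluster centroids; every
#' cell has a matched partner (the same cell profiled twice) displaced by
#' isotropic noise of scale `displacement`. A `doublet_fraction` of extra
#' cells is planted at the midpoint of the first two centroids — mirroring
#' how barcode-collision doublets project between their parents — and
#' genotype-doublet labels are assigned at `planted_doublet_rate` inside the
#' planted neighborhood and `background_doublet_rate` elsewhere.
#'
#' @param config A [sim_config()].
#' @param n_clusters Number of background blobs (default 4).
#' @param dim Embedding dimensionality (default 15).
#' @param displacement Partner displacement scale (0 = coincident partners).
#' @param background_doublet_rate,planted_doublet_rate Genotype-doublet
#'   label rates.
#' @param centroid_scale Centroid coordinate scale; blobs have unit
#'   within-cluster standard deviation.
#' @return List: `coords` (matrix, rownames = profile ids; cells then
#'   partners), `pairs` (data.frame i, j), `cluster`, `genotype_status`
#'   (`"singlet"`/`"doublet"`), `is_planted` (logical, TRUE in the planted
#'   doublet neighborhood), all aligned with `coords` rows.
#' @export
simulate_embedding <- function(config, n_clusters = 4L, dim = 15L,
                               displacement = 0.5,
                               background_doublet_rate = 0.02,
                               planted_doublet_rate = 0.30,
                               centroid_scale = 10) {
  stopifnot(dim >= 2L)
  set.seed(config$seed)
  n_bg <- config$n_cells
  n_pl <- round(config$doublet_fraction * config$n_cells)
  centroids <- matrix(stats::rnorm(n_clusters * dim, sd = centroid_scale),
                      n_clusters, dim)
  cl_bg <- sample(n_clusters, n_bg, replace = TRUE)
  base <- centroids[cl_bg, , drop = FALSE] +
    matrix(stats::rnorm(n_bg * dim), n_bg, dim)
  cluster <- paste0("C", cl_bg)
  is_planted <- rep(FALSE, n_bg)
  if (n_pl > 0L) {
    mid <- (centroids[1, ] + centroids[2, ]) / 2
    blob <- matrix(mid, n_pl, dim, byrow = TRUE) +
      matrix(stats::rnorm(n_pl * dim), n_pl, dim)
    base <- rbind(base, blob)
    cluster <- c(cluster, rep("DBL", n_pl))
    is_planted <- c(is_planted, rep(TRUE, n_pl))
  }
  n <- nrow(base)
  rate <- ifelse(is_planted, planted_doublet_rate, background_doublet_rate)
  genotype <- ifelse(stats::runif(n) < rate, "doublet", "singlet")
  partners <- base + matrix(stats::rnorm(n * dim, sd = displacement), n, dim)
  coords <- rbind(base, partners)
  ids <- c(sprintf("cell%05d", seq_len(n)), sprintf("cell%05d_rep", seq_len(n)))
  rownames(coords) <- ids
  list(coords = coords,
       pairs = data.frame(i = ids[seq_len(n)], j = ids[n + seq_len(n)],
                          stringsAsFactors = FALSE),
       cluster = rep(cluster, 2L),
       genotype_status = rep(genotype, 2L),
       is_planted = rep(is_planted, 2L))
}

#' Simulate summit and fragment sets with planted element classes
#'
#' Plants `n_summits` regulatory elements on one synthetic chromosome, in
#' three classes: promoters (H3K4me3-high in every lineage, at planted TSSs),
#' enhancers (H3K4me1-high, strongest in a lineage-specific home lineage,
#' distal to every TSS), and Polycomb-repressed elements (H3K27me3-high).
#' Per lineage a summit list (jittered element centers with scores) is
#' emitted, and per (lineage, mark) a fragment set concentrated around the
#' elements with class- and lineage-dependent rates plus uniform background.
#'
#' @param config A [sim_config()].
#' @param chrom Chromosome name.
#' @param chrom_len Chromosome length in bp (default 10 Mb).
#' @param marks Histone marks to emit fragments for.
#' @param frag_rate Mean fragments per element at a "high" (element, mark,
#'   lineage) combination (Poisson; low combinations get `frag_rate / 20`,
#'   non-home enhancer lineages `frag_rate / 4`).
#' @param n_background Uniform background fragments per (lineage, mark).
#' @param jitter Summit position jitter in bp (default 30).
#' @return List: `summits` (per-lineage data.frames `chrom,pos,score`),
#'   `fragments` (named list `"<lineage>.<mark>"` of fragment data.frames),
#'   `truth` (element id, chrom, pos, class, home lineage), `tss`
#'   (data.frame `chrom,pos`), `chrom_sizes`.
#' @export
simulate_summits <- function(config, chrom = "chr1", chrom_len = 1e7,
                             marks = c("H3K4me3", "H3K4me1", "H3K27me3"),
                             frag_rate = 40, n_background = 1000L,
                             jitter = 30L) {
  set.seed(config$seed)
  n_el <- config$n_summits
  lineages <- paste0("L", seq_len(config$n_lineages))
  spacing <- floor(chrom_len / (n_el + 1L))
  pos <- spacing * seq_len(n_el) +
    sample(-500L:500L, n_el, replace = TRUE)
  class <- sample(rep(c("promoter", "enhancer", "repressed"),
                      length.out = n_el))
  home <- sample(lineages, n_el, replace = TRUE)
  truth <- data.frame(id = sprintf("el%04d", seq_len(n_el)), chrom = chrom,
                      pos = pos, class = class, home = home,
                      stringsAsFactors = FALSE)
  tss <- data.frame(chrom = chrom, pos = pos[class == "promoter"])

  high_mark <- c(promoter = "H3K4me3", enhancer = "H3K4me1",
                 repressed = "H3K27me3")
  summits <- lapply(stats::setNames(lineages, lineages), function(L) {
    data.frame(chrom = chrom,
               pos = pos + sample(seq(-jitter, jitter), n_el, replace = TRUE),
               score = stats::runif(n_el, 2, 10),
               stringsAsFactors = FALSE)
  })
  frag_sets <- list()
  for (L in lineages) for (mk in marks) {
    rate <- ifelse(high_mark[class] == mk,
                   ifelse(class == "enhancer" & home != L,
                          frag_rate / 4, frag_rate),
                   frag_rate / 20)
    n_fr <- stats::rpois(n_el, rate)
    centers <- rep(pos, n_fr) +
      sample(seq(-75L, 75L), sum(n_fr), replace = TRUE)
    bg <- sample.int(chrom_len - 200L, n_background)
    starts <- pmax(c(centers - 75L, bg), 0L)
    fr <- data.frame(chrom = chrom, start = starts,
                     end = pmin(starts + 150L, chrom_len),
                     cell = "bulk", stringsAsFactors = FALSE)
    fr <- fr[order(fr$start), , drop = FALSE]
    rownames(fr) <- NULL
    frag_sets[[paste0(L, ".", mk)]] <- fr
  }
  list(summits = summits, fragments = frag_sets, truth = truth, tss = tss,
       chrom_sizes = stats::setNames(chrom_len, chrom))
}
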