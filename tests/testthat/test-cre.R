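test_that("gene domains extend to nearest non-overlapping neighbours and chromosome edges", {
  ann <- data.frame(chrom = "chr1", start = c(100, 500, 900),
                    end = c(200, 600, 1000), gene = c("A", "B", "C"))
  dom <- gene_domains(ann)
  expect_identical(dom$domain_start[dom$gene == "B"], 200)
  expect_identical(dom$domain_end[dom$gene == "B"], 900)
  # chromosome-edge genes bounded by min/max annotated coordinate
  expect_identical(dom$domain_start[dom$gene == "A"], 100)
  expect_identical(dom$domain_end[dom$gene == "C"], 1000)
  # overlapping neighbour is skipped in favour of the nearest non-overlapping
  ann2 <- data.frame(chrom = "chr1", start = c(100, 250, 900),
                     end = c(300, 600, 1000), gene = c("A", "B", "C"))
  dom2 <- gene_domains(ann2)
  expect_identical(dom2$domain_start[dom2$gene == "C"], 600)
  # brute-force oracle on random layouts
  set.seed(17)
  for (rep in 1:5) {
    n <- 12
    s <- sort(sample(0:5000, n))
    g <- data.frame(chrom = "chrZ", start = s,
                    end = s + sample(50:400, n, TRUE),
                    gene = paste0("g", 1:n))
    dom3 <- gene_domains(g)
    for (i in seq_len(n)) {
      ups <- g$end[g$end <= g$start[i]]
      dns <- g$start[g$start >= g$end[i]]
      expect_equal(dom3$domain_start[dom3$gene == g$gene[i]],
                   if (length(ups)) max(ups) else min(g$start))
      expect_equal(dom3$domain_end[dom3$gene == g$gene[i]],
                   if (length(dns)) min(dns) else max(g$end))
    }
  }
  # transcript collapse: union span per gene, non-protein-coding dropped
  tr <- data.frame(chrom = "chr1", start = c(10, 30, 500, 700),
                   end = c(100, 150, 600, 800),
                   gene = c("A", "A", "B", "X"),
                   type = c("protein_coding", "protein_coding",
                            "protein_coding", "lncRNA"))
  dom4 <- gene_domains(tr)
  expect_identical(nrow(dom4), 2L)
  expect_identical(dom4$gene_start[dom4$gene == "A"], 10)
  expect_identical(dom4$gene_end[dom4$gene == "A"], 150)
})

test_that("greedy summit merge anchors to the retained summit and matches the oracle", {
  s <- data.frame(chrom = "chr1", pos = c(100, 180, 270), score = c(5, 9, 3))
  m <- merge_summits(s)
  expect_identical(nrow(m), 1L)
  expect_identical(m$pos, 180)
  # beyond the window: both retained; single summit unchanged
  s2 <- data.frame(chrom = "chr1", pos = c(100, 251), score = c(5, 9))
  expect_identical(nrow(merge_summits(s2)), 2L)
  expect_identical(merge_summits(s[1, ]), s[1, ])
  # property: pairwise gaps of the output exceed the collapse radius, and
  # the result equals the exhaustive stepwise oracle (random <=6-summit sets)
  set.seed(18)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    pos <- sample(0:1200, n)
    score <- round(runif(n, 1, 10), 3)
    got <- merge_summits(data.frame(chrom = "c", pos = pos, score = score))
    want <- greedy_oracle(pos, score)
    expect_equal(got$pos, want$pos)
    expect_equal(got$score, want$score)
    if (nrow(got) > 1) expect_true(all(diff(got$pos) > 100))
  }
})

test_that("summit windows are 200 bp, centered, and clipped at chromosome edges", {
  s <- data.frame(chrom = "chr1", pos = c(500, 50, 9990), score = 1:3)
  w <- summit_windows(s, 200, c(chr1 = 10000))
  expect_identical(w$start, c(400L, 0L, 9890L))
  expect_identical(w$end, c(600L, 150L, 10000L))
  expect_true(all(w$end - w$start <= 200))
})

test_that("cross-lineage merge re-centers wide intervals on the top-scoring original summit", {
  sA <- data.frame(chrom = "chr1", pos = 1000, score = 5)
  sB <- data.frame(chrom = "chr1", pos = 1100, score = 9)
  all_s <- rbind(sA, sB)
  wins <- list(summit_windows(sA), summit_windows(sB))
  std <- cross_lineage_merge(wins, all_s)
  expect_identical(nrow(std), 1L)
  expect_identical(std$start, 1000L)        # centered on the score-9 summit
  expect_identical(std$end, 1200L)
  # identical windows collapse to one; disjoint windows pass through
  sC <- data.frame(chrom = "chr1", pos = c(1000, 5000), score = c(5, 2))
  std2 <- cross_lineage_merge(list(summit_windows(sC), summit_windows(sC)),
                              sC)
  expect_identical(nrow(std2), 2L)
  expect_identical(std2$start, c(900L, 4900L))
})

test_that("window quantification equals the brute-force intersection oracle, in counts and CPM", {
  set.seed(19)
  wins <- data.frame(chrom = "chr1", start = seq(0, 9000, by = 1000),
                     end = seq(0, 9000, by = 1000) + 200)
  wins$id <- paste0("w", seq_len(nrow(wins)))
  wins$score <- 1
  frs <- lapply(1:3, function(i) {
    st <- sample(0:9500, 400, TRUE)
    data.frame(chrom = "chr1", start = st,
               end = st + sample(50:300, 400, TRUE), cell = "b")
  })
  names(frs) <- paste0("CL", 1:3, ".mark")
  em <- quantify_elements(wins, frs)
  for (k in 1:3) {
    want <- count_overlap_oracle(wins$start, wins$end,
                                 frs[[k]]$start, frs[[k]]$end)
    expect_equal(unname(em$counts[, k]), want)
    expect_equal(unname(em$cpm[, k]), want * 1e6 / 400)
  }
  expect_equal(unname(colSums(em$cpm)),
               1e6 * unname(colSums(em$counts)) / 400)
  # half-open: an abutting fragment does not count
  w1 <- data.frame(chrom = "c", start = 100, end = 300, id = "w", score = 1)
  ab <- list(x = data.frame(chrom = "c", start = c(300, 0, 299),
                            end = c(400, 100, 350), cell = "b"))
  expect_identical(as.integer(quantify_elements(w1, ab)$counts[1, 1]), 1L)
})

test_that("outlier filter drops the strict percentile tails and keeps ties intact", {
  m <- matrix(1:100, 100, 1)
  kept <- outlier_filter(m)
  expect_identical(nrow(kept), 90L)
  q <- quantile(rowSums(m), c(.05, .95), type = 7)
  expect_true(all(rowSums(kept) >= q[1] & rowSums(kept) <= q[2]))
  tied <- matrix(3, 50, 2)
  expect_identical(nrow(outlier_filter(tied)), 50L)
  set.seed(20)
  r <- matrix(rexp(600), 200, 3)
  kept2 <- outlier_filter(r)
  s <- rowSums(r)
  qq <- quantile(s, c(.05, .95), type = 7)
  expect_identical(nrow(kept2), sum(!(s < qq[1] | s > qq[2])))
})

test_that("element clustering: block norms equalized, duplicates co-labelled, planted classes recovered", {
  # two mark blocks with norms 10 and 20 are both rescaled to their median 15
  ns <- getFromNamespace("block_norm_rescale", "cooctag")
  m <- cbind(a = c(10, 0, 0), b = c(0, 20, 0))
  out <- ns(m, marks = c("m1", "m2"))
  expect_equal(sqrt(sum(out[, 1]^2)), 15)
  expect_equal(sqrt(sum(out[, 2]^2)), 15)
  # planted recovery on the synthetic summit fixture
  cfg <- sim_config(seed = 23, n_summits = 240, n_lineages = 3)
  ss <- simulate_summits(cfg)
  wins <- lapply(ss$summits, function(s)
    summit_windows(merge_summits(s), chrom_sizes = ss$chrom_sizes))
  std <- cross_lineage_merge(wins, do.call(rbind, ss$summits),
                             chrom_sizes = ss$chrom_sizes)
  em <- outlier_filter(quantify_elements(std, ss$fragments))
  expect_warning(cl <- cluster_elements(em, resolution = 0.5, seed = 1),
                 "n_pcs")
  truth <- match_truth_class(em$windows, ss$truth)
  expect_gte(ari_oracle(cl$labels, truth), 0.8)
  # duplicated rows land in the same class
  dup <- rbind(em$cpm, em$cpm[7, , drop = FALSE])
  cl2 <- suppressWarnings(cluster_elements(dup, resolution = 0.5, seed = 1))
  expect_identical(cl2$labels[7], cl2$labels[nrow(dup)])
  # recluster: non-selected rows unchanged, empty selection is identity
  ref <- recluster_elements(em, cl$labels, select = integer(0))
  expect_identical(ref, as.character(cl$labels))
  ref2 <- suppressWarnings(
    recluster_elements(em, cl$labels, select = 1L, seed = 1))
  expect_identical(ref2[cl$labels != 1L],
                   as.character(cl$labels)[cl$labels != 1L])
  expect_true(all(startsWith(ref2[cl$labels == 1L], "1.")))
})

test_that("promoter fraction is the TSS±2kb overlap rate per class", {
  wins <- data.frame(chrom = "chr1",
                     start = c(900, 5000, 9000), end = c(1100, 5200, 9200),
                     id = paste0("w", 1:3), score = 1)
  tss <- data.frame(chrom = "chr1", pos = 1000)
  pf <- promoter_fraction(wins, c("P", "E", "E"), tss)
  expect_equal(unname(pf$fraction["P"]), 1)
  expect_equal(unname(pf$fraction["E"]), 0)
  # window starting exactly at the flank edge does not overlap (half-open)
  w2 <- data.frame(chrom = "chr1", start = 3000, end = 3100, id = "w",
                   score = 1)
  expect_equal(promoter_fraction(w2, "x", tss)$overall, 0)
  w3 <- data.frame(chrom = "chr1", start = 2999, end = 3100, id = "w",
                   score = 1)
  expect_equal(promoter_fraction(w3, "x", tss)$overall, 1)
  # disjoint chromosome set -> 0
  w4 <- data.frame(chrom = "chr9", start = 0, end = 100, id = "w", score = 1)
  expect_equal(promoter_fraction(w4, "x", tss)$overall, 0)
})

test_that("domain enrichment arithmetic: log2((O+.5)/(E+.5)), softmax rows, disjointness check", {
  wins <- data.frame(chrom = "chr1",
                     start = c(100, 300, 2100, 2300, 4100, 4300),
                     end = c(100, 300, 2100, 2300, 4100, 4300) + 200,
                     id = paste0("w", 1:6), score = 1)
  labels <- c("A", "A", "B", "B", "B", "A")
  dg <- list(g1 = data.frame(chrom = "chr1", domain_start = 0,
                             domain_end = 1000, gene = "x"),
             g2 = data.frame(chrom = "chr1", domain_start = 2000,
                             domain_end = 3000, gene = "y"))
  de <- domain_enrichment(wins, labels, dg)
  # direct arithmetic oracle: w1,w2 (A) hit g1; w3,w4 (B) hit g2
  O <- rbind(A = c(2, 0), B = c(0, 2))
  f <- c(2, 2) / 6
  E <- outer(c(3, 3), f)
  expect_equal(unname(de$observed), unname(O))
  expect_equal(unname(de$log2_enrichment),
               unname(log2((O + 0.5) / (E + 0.5))))
  expect_equal(unname(rowSums(de$weights)), c(1, 1), tolerance = 1e-12)
  # O = E everywhere -> enrichment 0, weights uniform
  deq <- list(observed = matrix(4, 2, 2), expected = matrix(4, 2, 2))
  enr0 <- log2((deq$observed + 0.5) / (deq$expected + 0.5))
  expect_true(all(enr0 == 0))
  # shared gene across groups is an error
  dg_bad <- dg
  dg_bad$g2$gene <- "x"
  expect_error(domain_enrichment(wins, labels, dg_bad), "disjoint")
})

test_that("co-occurrence: Haldane log2 OR worked example, Fisher equals enumeration, antisymmetry", {
  # direct arithmetic: both=10, onlyA=5, onlyB=5, neither=80
  lor <- log2((10.5 * 80.5) / (5.5 * 5.5))
  expect_equal(lor, 4.80437, tolerance = 1e-5)
  pres <- matrix(FALSE, 100, 2, dimnames = list(NULL, c("A", "B")))
  pres[1:15, "A"] <- TRUE; pres[c(1:10, 16:20), "B"] <- TRUE
  co <- cooccurrence(pres)
  expect_equal(co$pairs$log2_or, lor, tolerance = 1e-6)
  expect_equal(co$pairs$p, fisher_enum(10, 5, 5, 80), tolerance = 1e-9)
  # independence: OR ~ 1 (log2 ~ 0), p = 1
  ind <- matrix(FALSE, 40, 2, dimnames = list(NULL, c("A", "B")))
  ind[1:20, "A"] <- TRUE; ind[seq(1, 40, 2), "B"] <- TRUE
  coi <- cooccurrence(ind)
  expect_lt(abs(coi$pairs$log2_or), 0.1)
  expect_gt(coi$pairs$p, 0.99)
  # exhaustive small-n check against hypergeometric enumeration
  set.seed(24)
  for (i in 1:20) {
    m <- matrix(runif(24) < 0.5, 12, 2, dimnames = list(NULL, c("A", "B")))
    cc <- cooccurrence(m)$pairs
    expect_equal(cc$p, fisher_enum(cc$both, cc$only_a, cc$only_b,
                                   cc$neither), tolerance = 1e-9)
    # antisymmetry of the log2 OR under swapping the only-A/only-B cells
    swapped <- log2(((cc$both + .5) * (cc$neither + .5)) /
                      ((cc$only_b + .5) * (cc$only_a + .5)))
    expect_equal(cc$log2_or, swapped)
  }
})

test_that("element presence within gene domains drives per-gene counts and rank-sum tests", {
  wins <- data.frame(chrom = "chr1",
                     start = c(100, 150, 2100, 4100),
                     end = c(300, 350, 2300, 4300),
                     id = paste0("w", 1:4), score = 1)
  labels <- c("enh", "enh", "prom", "enh")
  dom <- data.frame(chrom = "chr1", domain_start = c(0, 2000, 4000),
                    domain_end = c(1000, 3000, 5000),
                    gene = c("g1", "g2", "g3"))
  pres <- element_presence(wins, labels, dom)
  expect_identical(unname(pres["g1", ]), c(TRUE, FALSE))
  expect_identical(unname(pres["g2", ]), c(FALSE, TRUE))
  st <- domain_element_stats(wins, labels, dom,
                             gene_groups = list(u2a = c("g1"),
                                                b2a = c("g2", "g3")),
                             enhancer_classes = "enh",
                             promoter_classes = "prom")
  expect_identical(st$per_gene$enhancer_count, c(2L, 0L, 1L))
  expect_identical(st$per_gene$promoter_count, c(0L, 1L, 0L))
  expect_identical(nrow(st$tests), 2L)
})

test_that("rank-sum p-values match exact enumeration and BH follows the step-up rule", {
  # identical groups: U = n1 n2 / 2, p ~ 1 (normal approximation with ties)
  a <- rep(c(1, 2, 3), 4); b <- rep(c(1, 2, 3), 4)
  wt <- suppressWarnings(wilcox.test(a, b))
  expect_equal(unname(wt$statistic), length(a) * length(b) / 2)
  expect_gt(wt$p.value, 0.9)
  # extreme separation: exact two-sided p = 0.1 by enumeration
  p_enum <- ranksum_enum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(p_enum, 0.1)
  expect_equal(wilcox.test(c(1, 2, 3), c(10, 11, 12))$p.value, p_enum)
  # BH: worked example and random agreement with the step-up oracle
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
  set.seed(25)
  p <- runif(20)
  expect_equal(p.adjust(p, "BH"), bh_oracle(p))
})
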