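# Independent brute-force oracles used to check the package implementations.
# Each is written against the definition, not the implementation path.

# argmin |w1*phi1 - w2*phi2| on a fine grid between the means
grid_intersection <- function(mu, sigma, w, step = 1e-4) {
  xs <- seq(mu[1], mu[2], by = step)
  d <- abs(w[1] * dnorm(xs, mu[1], sigma[1]) -
             w[2] * dnorm(xs, mu[2], sigma[2]))
  xs[which.min(d)]
}

# local quadratic regression with tricube weights over the span-fraction
# nearest neighbours (the textbook definition)
loess_oracle <- function(x, y, span = 0.75, newx = x) {
  n <- length(x)
  q <- floor(n * span)
  sapply(newx, function(x0) {
    d <- abs(x - x0)
    dq <- sort(d)[q]
    w <- if (dq == 0) as.numeric(d == 0) else
      ifelse(d <= dq, (1 - (d / dq)^3)^3, 0)
    fit <- stats::lm(y ~ x + I(x^2), weights = w, subset = w > 0)
    unname(stats::predict(fit, data.frame(x = x0)))
  })
}

# stepwise restatement of the greedy summit sweep, written recursively and
# operating on unsorted input
greedy_oracle <- function(pos, score, collapse_bp = 100) {
  o <- order(pos)
  pos <- pos[o]; score <- score[o]
  step <- function(kept_pos, kept_score, rest_pos, rest_score) {
    if (length(rest_pos) == 0)
      return(data.frame(pos = kept_pos, score = kept_score))
    p <- rest_pos[1]; s <- rest_score[1]
    last <- length(kept_pos)
    if (p - kept_pos[last] <= collapse_bp) {
      if (s > kept_score[last]) {
        kept_pos[last] <- p; kept_score[last] <- s
      }
    } else {
      kept_pos <- c(kept_pos, p); kept_score <- c(kept_score, s)
    }
    step(kept_pos, kept_score, rest_pos[-1], rest_score[-1])
  }
  step(pos[1], score[1], pos[-1], score[-1])
}

# per-base pileup on an integer grid
pileup_oracle <- function(starts, ends, factor = 1, chrom_len) {
  depth <- numeric(chrom_len)
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1):min(ends[i], chrom_len)
    depth[idx] <- depth[idx] + 1
  }
  depth * factor
}

# O(n*m) interval intersection counts, half-open coordinates
count_overlap_oracle <- function(win_start, win_end, fr_start, fr_end) {
  vapply(seq_along(win_start), function(i)
    sum(fr_start < win_end[i] & fr_end > win_start[i]), numeric(1))
}

# two-sided Fisher p by full hypergeometric enumeration over tables with the
# observed margins
fisher_enum <- function(both, only_a, only_b, neither) {
  m <- both + only_a          # margin: A present
  k <- both + only_b          # margin: B present
  n <- both + only_a + only_b + neither
  xs <- max(0, m + k - n):min(m, k)
  probs <- dhyper(xs, k, n - k, m)
  p_obs <- dhyper(both, k, n - k, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumeration of all group assignments
ranksum_enum <- function(a, b) {
  v <- c(a, b); n1 <- length(a)
  combos <- utils::combn(length(v), n1)
  r <- rank(v)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  center <- n1 * length(b) / 2
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}

# BH step-up by the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# match element windows back to the planted truth (elements are far apart,
# so any overlap is unambiguous)
match_truth_class <- function(windows, truth) {
  wg <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$start + 1, windows$end))
  tg <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$pos + 1, truth$pos + 1))
  ov <- GenomicRanges::findOverlaps(wg, tg)
  cls <- rep(NA_character_, nrow(windows))
  cls[S4Vectors::queryHits(ov)] <- truth$class[S4Vectors::subjectHits(ov)]
  cls
}

# adjusted Rand index (independent of any clustering library)
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# write the four simulated FASTQ files and return their paths
write_sim_fastq <- function(sim, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  paths <- list()
  writer <- get("write_fastq", envir = asNamespace("cooctag"))
  for (nm in names(sim$reads)) {
    paths[[nm]] <- file.path(dir, paste0(toupper(nm), ".fastq"))
    writer(sim$reads[[nm]], paths[[nm]])
  }
  paths
}
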