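#' Fit a two-component Gaussian mixture to pseudobulk gene scores
#'
#' Pseudobulk gene-score distributions for a chromatin mark are bimodal on the
#' log scale: a low-signal (background) and a high-signal (marked) component.
#' The fit is an expectation-maximization run on `log10(score + 0.1)`, with
#' components canonically ordered by mean, and the classification threshold
#' placed at the intersection of the two weighted component densities — the
#' point of equal likelihood between the low- and high-signal components.
#'
#' Initialization splits the data at the median (below/above), so the fit is
#' deterministic and invariant to input order. If the density intersection has
#' no root between the means, or the mixture degenerates (a single Gaussian
#' fits at least as well by BIC, or the component separation falls below
#' `sep_floor` standard deviations), the threshold falls back to the midpoint
#' of the means and the fit is flagged so callers can treat it specially.
#'
#' @param scores Positive gene scores (raw scale) — or already-transformed
#'   values when `log_transform = FALSE`. At least 20 values with nonzero
#'   variance.
#' @param log_transform Apply `log10(x + 0.1)` first (default `TRUE`).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter Maximum EM iterations (default 500).
#' @param sep_floor Minimum `|mu2 - mu1| / max(sigma)` treated as a real
#'   mixture (default 0.5); below it the fit is flagged as degenerate.
#' @return Object of class `mix2`: list with `mu`, `sigma`, `w` (each length
#'   2, low component first), `threshold` (on the transformed scale),
#'   `converged`, `degenerate`, `threshold_fallback`, `loglik`, `n_iter`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, 0, 1), rnorm(300, 4, 1))
#' fit <- fit_mixture(x, log_transform = FALSE)
#' fit$threshold
#' @export
fit_mixture <- function(scores, log_transform = TRUE, tol = 1e-8,
                        max_iter = 500L, sep_floor = 0.5) {
  x <- as.numeric(scores)
  x <- x[is.finite(x)]
  if (log_transform) x <- log10(x + 0.1)
  if (length(x) < 20L) stop("need >= 20 finite values to fit a mixture")
  if (stats::sd(x) == 0) stop("no mixture structure: all values identical")

  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (length(hi) == 0L) { hi <- max(x); lo <- x[-which.max(x)] }
  mu <- c(mean(lo), mean(hi))
  sigma <- pmax(c(stats::sd(lo), stats::sd(hi)), stats::sd(x) / 100, 1e-6)
  sigma[is.na(sigma)] <- stats::sd(x)
  w <- c(length(lo), length(hi)) / length(x)

  loglik <- -Inf; converged <- FALSE; iter <- 0L
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sigma[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - loglik) < tol) { converged <- TRUE; loglik <- ll; break }
    loglik <- ll
    n2 <- sum(r2); n1 <- length(x) - n2
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum((1 - r2) * x) / n1, sum(r2 * x) / n2)
    sigma <- sqrt(c(sum((1 - r2) * (x - mu[1])^2) / n1,
                    sum(r2 * (x - mu[2])^2) / n2))
    # variance floor: a duplicated-value spike must not collapse a component
    sigma <- pmax(sigma, stats::sd(x) / 50)
    w <- c(n1, n2) / length(x)
  }
  if (mu[1] > mu[2]) { # canonical order: low-signal component first
    mu <- rev(mu); sigma <- rev(sigma); w <- rev(w)
  }
  # degenerate when a single Gaussian explains the data at least as well
  # (BIC), or the components are closer than the separation floor
  n <- length(x)
  sd1 <- sqrt(mean((x - mean(x))^2))
  bic1 <- -2 * sum(stats::dnorm(x, mean(x), sd1, log = TRUE)) + 2 * log(n)
  bic2 <- -2 * loglik + 5 * log(n)
  degenerate <- (bic1 <= bic2) ||
    (mu[2] - mu[1]) < sep_floor * max(sigma)
  fit <- structure(list(mu = mu, sigma = sigma, w = w, threshold = NA_real_,
                        converged = converged, degenerate = degenerate,
                        threshold_fallback = FALSE, loglik = loglik,
                        n_iter = iter, n = length(x),
                        log_transform = log_transform),
                   class = "mix2")
  thr <- tryCatch(intersection_threshold(fit), error = function(e) NA_real_)
  if (degenerate || is.na(thr)) {
    fit$threshold <- mean(mu)
    fit$threshold_fallback <- TRUE
  } else fit$threshold <- thr
  fit
}

#' @export
print.mix2 <- function(x, ...) {
  cat("Two-component Gaussian mixture (log10(score + 0.1) scale)\n")
  cat(sprintf("  low : mu = %.4f  sigma = %.4f  w = %.3f\n",
              x$mu[1], x$sigma[1], x$w[1]))
  cat(sprintf("  high: mu = %.4f  sigma = %.4f  w = %.3f\n",
              x$mu[2], x$sigma[2], x$w[2]))
  cat(sprintf("  threshold = %.4f%s   (n = %d, %s in %d iterations)\n",
              x$threshold,
              if (x$threshold_fallback) " [midpoint fallback]" else "",
              x$n, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  if (x$degenerate) cat("  warning: components barely separated (degenerate)\n")
  invisible(x)
}

#' @export
coef.mix2 <- function(object, ...) {
  c(mu1 = object$mu[1], mu2 = object$mu[2], sigma1 = object$sigma[1],
    sigma2 = object$sigma[2], w1 = object$w[1], w2 = object$w[2],
    threshold = object$threshold)
}

#' @export
predict.mix2 <- function(object, newdata, ...) {
  x <- if (object$log_transform) log10(newdata + 0.1) else newdata
  ifelse(x > object$threshold, "high", "low")
}

#' @export
plot.mix2 <- function(x, ...) {
  xs <- seq(x$mu[1] - 4 * x$sigma[1], x$mu[2] + 4 * x$sigma[2], length.out = 400)
  d1 <- x$w[1] * stats::dnorm(xs, x$mu[1], x$sigma[1])
  d2 <- x$w[2] * stats::dnorm(xs, x$mu[2], x$sigma[2])
  graphics::plot(xs, d1 + d2, type = "l", xlab = "log10(score + 0.1)",
                 ylab = "density", ...)
  graphics::lines(xs, d1, lty = 2); graphics::lines(xs, d2, lty = 3)
  graphics::abline(v = x$threshold, col = 2)
  invisible(x)
}

#' Intersection of two weighted Gaussian densities
#'
#' Solves `w1 * phi(x; mu1, sigma1) = w2 * phi(x; mu2, sigma2)` and returns
#' the root lying strictly between the two means. With equal variances this
#' reduces to the closed form
#' `x = (mu1 + mu2)/2 + sigma^2 * log(w1/w2) / (mu2 - mu1)`.
#'
#' @param fit A `mix2` object, or a list with `mu`, `sigma`, `w` (low
#'   component first, `mu[1] < mu[2]`).
#' @return The threshold (numeric scalar).
#' @export
intersection_threshold <- function(fit) {
  mu <- fit$mu; s <- fit$sigma; w <- fit$w
  if (!(mu[1] < mu[2])) stop("components must be ordered mu1 < mu2")
  if (abs(s[1] - s[2]) < 1e-12) {
    x <- mean(mu) + s[1]^2 * log(w[1] / w[2]) / (mu[2] - mu[1])
    if (x <= mu[1] || x >= mu[2])
      stop("density intersection falls outside (mu1, mu2)")
    return(x)
  }
  # log w1 - log s1 - (x-mu1)^2/(2 s1^2) = log w2 - log s2 - (x-mu2)^2/(2 s2^2)
  a <- 1 / (2 * s[2]^2) - 1 / (2 * s[1]^2)
  b <- mu[1] / s[1]^2 - mu[2] / s[2]^2
  cc <- mu[2]^2 / (2 * s[2]^2) - mu[1]^2 / (2 * s[1]^2) +
    log(w[1] / w[2]) + log(s[2] / s[1])
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("no real density intersection")
  roots <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
  inside <- roots[roots > mu[1] & roots < mu[2]]
  if (length(inside) == 0L)
    stop("no density intersection inside (mu1, mu2)")
  inside[1]
}

#' Classify gene chromatin states from thresholded mark signals
#'
#' Per gene (all signals and thresholds on the `log10(score + 0.1)` scale,
#' "above" strict): bivalent if the H3K4 signal, the H3K27me3 signal and the
#' co-occupancy signal all exceed their thresholds; active if H3K4 above and
#' H3K27me3 below; repressed if H3K27me3 above and H3K4 below; unmarked if
#' both below; otherwise (both marks above but co-occupancy not) "other".
#'
#' @param k4,k27,co Numeric vectors of transformed signals for one H3K4 mark,
#'   H3K27me3, and their co-occupancy stream.
#' @param thresholds Named numeric: `k4`, `k27`, `co` (from
#'   [fit_mixture()]`$threshold` of the respective mark).
#' @return Character vector over
#'   `c("active","repressed","bivalent","unmarked","other")`.
#' @export
classify_states <- function(k4, k27, co, thresholds) {
  stopifnot(all(c("k4", "k27", "co") %in% names(thresholds)))
  k4_up <- k4 > thresholds[["k4"]]
  k27_up <- k27 > thresholds[["k27"]]
  co_up <- co > thresholds[["co"]]
  out <- rep("other", length(k4))
  out[k4_up & k27_up & co_up] <- "bivalent"
  out[k4_up & !k27_up] <- "active"
  out[!k4_up & k27_up] <- "repressed"
  out[!k4_up & !k27_up] <- "unmarked"
  out
}

#' Consensus state across the three H3K4 marker pairs
#'
#' The modal per-pair state if it occurs at least twice among the three pairs
#' (H3K27me3 paired with H3K4me1/me2/me3), else `"none"`. "other" votes like
#' any label.
#'
#' @param pair1,pair2,pair3 Character state vectors of equal length.
#' @return Character vector (consensus state or `"none"`).
#' @export
consensus_state <- function(pair1, pair2, pair3) {
  mapply(function(a, b, c) {
    tab <- sort(table(c(a, b, c)), decreasing = TRUE)
    if (tab[1] >= 2L) names(tab)[1] else "none"
  }, pair1, pair2, pair3, USE.NAMES = FALSE)
}

#' Fate map of chromatin-state transitions from a root population
#'
#' Counts, per downstream lineage, how many genes move from each root state
#' to each downstream state; the fraction of genes per root state that reach
#' `"active"` in at least one lineage; and how lineage-specific those
#' activations are (active in exactly 1, 2, ..., all lineages).
#'
#' @param root_states Named character vector: gene -> state in the root
#'   cluster (e.g. HSC/MPP).
#' @param lineage_states Named list of named character vectors: per lineage,
#'   gene -> state in that lineage's committed cluster. Genes are matched by
#'   name; genes missing from a lineage are ignored for that lineage.
#' @param states State universe used to order table dimensions.
#' @return List with `transitions` (named list of root x downstream count
#'   matrices per lineage), `frac_active` (per root state, fraction of genes
#'   active in >= 1 lineage), and `specificity` (root state x number-of-
#'   lineages-active count matrix).
#' @export
transition_table <- function(root_states, lineage_states,
                             states = c("active", "repressed", "bivalent",
                                        "unmarked", "other")) {
  genes <- names(root_states)
  transitions <- lapply(lineage_states, function(ls) {
    common <- intersect(genes, names(ls))
    table(root = factor(root_states[common], states),
          downstream = factor(ls[common], states))
  })
  n_lin <- length(lineage_states)
  active_in <- sapply(lineage_states, function(ls) {
    v <- ls[genes] == "active"
    v[is.na(v)] <- FALSE
    v
  })
  if (is.null(dim(active_in))) active_in <- matrix(active_in, nrow = 1)
  n_active <- rowSums(active_in)
  root_f <- factor(root_states, states)
  frac_active <- tapply(n_active >= 1L, root_f, mean)
  specificity <- table(root = root_f,
                       n_lineages_active = factor(n_active, 0:n_lin))
  list(transitions = transitions,
       frac_active = frac_active,
       specificity = specificity)
}

#' Run the full state-calling step on pseudobulk score matrices
#'
#' Fits one mixture per mark (genes pooled across clusters — thresholds are
#' shared across clusters; set `per_cluster = TRUE` to fit per cluster) and
#' classifies every gene x cluster for the three marker pairs plus the
#' consensus.
#'
#' @param k27 Gene x cluster pseudobulk score matrix for H3K27me3.
#' @param k4 Named list of three gene x cluster matrices
#'   (`H3K4me1`, `H3K4me2`, `H3K4me3` or similar).
#' @param co Named list of three gene x cluster co-occupancy matrices, in the
#'   same order as `k4`.
#' @param per_cluster Fit thresholds per cluster instead of pooled.
#' @return List with `calls` (long data.frame: gene, cluster, one state
#'   column per pair, consensus) and `fits` (list of `mix2` objects per mark).
#' @export
call_states <- function(k27, k4, co, per_cluster = FALSE) {
  stopifnot(length(k4) == 3L, length(co) == 3L)
  tf <- function(m) log10(m + 0.1)
  marks <- c(list(k27 = k27), k4, co)
  if (per_cluster) {
    fits <- lapply(marks, function(m)
      apply(m, 2, function(col) fit_mixture(col), simplify = FALSE))
    thr <- lapply(fits, function(fl) vapply(fl, `[[`, 0, "threshold"))
  } else {
    fits <- lapply(marks, function(m) fit_mixture(as.vector(m)))
    thr <- lapply(fits, function(f)
      stats::setNames(rep(f$threshold, ncol(k27)), colnames(k27)))
  }
  genes <- rownames(k27); clusters <- colnames(k27)
  calls <- expand.grid(gene = genes, cluster = clusters,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pair_names <- paste0("state_", names(k4))
  for (p in 1:3) {
    st <- matrix(NA_character_, length(genes), length(clusters))
    for (j in seq_along(clusters)) {
      th <- c(k4 = unname(thr[[1 + p]][j]), k27 = unname(thr[["k27"]][j]),
              co = unname(thr[[4 + p]][j]))
      st[, j] <- classify_states(tf(k4[[p]][, j]), tf(k27[, j]),
                                 tf(co[[p]][, j]), th)
    }
    calls[[pair_names[p]]] <- as.vector(st)
  }
  calls$consensus <- consensus_state(calls[[pair_names[1]]],
                                     calls[[pair_names[2]]],
                                     calls[[pair_names[3]]])
  list(calls = calls, fits = fits)
}
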