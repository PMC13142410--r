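#' Rank-scaled pseudotime
#'
#' Cells are ranked along the trajectory and the ranks scaled to `[0, 100]`:
#' `tau = 100 * (rank - 1) / (n - 1)`, ties sharing the mean rank. A single
#' cell gets `tau = 0` by convention.
#'
#' @param x Numeric vector ordering the cells (raw pseudotime or ranks).
#' @return Numeric vector of tau values in `[0, 100]`.
#' @export
scale_pseudotime <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(0)
  r <- rank(x, ties.method = "average")
  100 * (r - 1) / (n - 1)
}

#' Gene-module score per cell
#'
#' Gene scores are standardized per gene (z-score across cells, zero-variance
#' genes set to 0); the per-cell module score is the median z over the
#' module's gene list. Duplicated genes in the list contribute duplicated
#' values to the median.
#'
#' @param scores Numeric gene x cell matrix (rownames = genes).
#' @param gene_list Character vector of module genes; genes absent from the
#'   matrix are dropped.
#' @return Named numeric vector of per-cell module scores.
#' @export
module_score <- function(scores, gene_list) {
  present <- gene_list[gene_list %in% rownames(scores)]
  if (length(present) == 0L) stop("no module genes found in score matrix")
  m <- scores[present, , drop = FALSE]
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  z <- (m - mu) / ifelse(sd == 0, 1, sd)
  z[sd == 0, ] <- 0
  apply(z, 2L, stats::median)
}

#' Locally weighted smoothing of a pseudotime profile
#'
#' Degree-2 loess (tricube weights) of the values over pseudotime, evaluated
#' at the observed tau; non-positive fitted values are set to 0.
#'
#' @param tau Pseudotime values.
#' @param values Gene scores or expression at those cells.
#' @param span Loess span (default 0.75, the smoother's default).
#' @return Numeric fitted values at the input tau (clamped at 0), in input
#'   order.
#' @export
smooth_profile <- function(tau, values, span = 0.75) {
  if (length(tau) < 10L) stop("need >= 10 points to smooth")
  stopifnot(length(tau) == length(values))
  fit <- stats::loess(values ~ tau, span = span, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  pred <- stats::predict(fit, data.frame(tau = tau))
  pred[pred <= 0] <- 0
  as.numeric(pred)
}

#' Half-maximum activation time along a lineage
#'
#' The smoothed (and zero-clamped) profile is min-max rescaled to `[0, 1]`;
#' the activation time is the earliest observed pseudotime whose rescaled
#' value strictly exceeds 0.5. Flat profiles (zero range after smoothing)
#' have no defined activation time and return `NA`. Because of the min-max
#' rescaling the result is invariant to positive affine transforms of the
#' raw values.
#'
#' @inheritParams smooth_profile
#' @return Named list: `t_half` (numeric or `NA`), `smoothed` (rescaled
#'   profile in tau order), `tau` (sorted tau).
#' @export
activation_time <- function(tau, values, span = 0.75) {
  ord <- order(tau)
  tau_s <- tau[ord]
  sm <- smooth_profile(tau_s, values[ord], span = span)
  rng <- range(sm)
  if (diff(rng) <= 1e-10 * max(1, abs(rng[2])))   # flat up to roundoff
    return(list(t_half = NA_real_, smoothed = rep(NA_real_, length(sm)),
                tau = tau_s))
  scaled <- (sm - rng[1]) / diff(rng)
  hit <- which(scaled > 0.5)
  list(t_half = if (length(hit)) tau_s[hit[1]] else NA_real_,
       smoothed = scaled, tau = tau_s)
}

#' Activation times for a gene panel along one lineage
#'
#' @param scores Gene x cell matrix of (imputed) gene scores.
#' @param tau Pseudotime per cell (columns of `scores`).
#' @param genes Genes to time (default all rows).
#' @param span Loess span.
#' @return Data.frame `gene`, `t_half` (NA when undefined).
#' @export
activation_times <- function(scores, tau, genes = rownames(scores),
                             span = 0.75) {
  t_half <- vapply(genes, function(g)
    activation_time(tau, scores[g, ], span = span)$t_half, numeric(1))
  data.frame(gene = genes, t_half = unname(t_half))
}
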