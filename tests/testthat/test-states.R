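test_that("EM recovers the parameters of a well-separated mixture and is order-invariant", {
  set.seed(2)
  x <- c(rnorm(2500, 0, 1), rnorm(2500, 4, 1))
  fit <- fit_mixture(x, log_transform = FALSE)
  expect_true(fit$converged)
  expect_lt(abs(fit$mu[1] - 0), 0.1)
  expect_lt(abs(fit$mu[2] - 4), 0.1)
  expect_lt(abs(fit$w[1] - 0.5), 0.05)
  expect_lt(abs(fit$w[2] - 0.5), 0.05)
  fit2 <- fit_mixture(sample(x), log_transform = FALSE)
  expect_equal(coef(fit), coef(fit2))
  # cross-check against an independent EM (mclust) on the same data
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$mu), sort(unname(mc$parameters$mean)),
               tolerance = 0.05)
})

test_that("degenerate inputs are flagged or rejected", {
  expect_error(fit_mixture(rep(2, 100), log_transform = FALSE), "no mixture")
  expect_error(fit_mixture(rnorm(10), log_transform = FALSE), ">= 20")
  # single-component data is flagged degenerate; a finite fallback
  # threshold is still returned so per-mark pipelines never abort
  set.seed(4)
  one <- fit_mixture(rnorm(500, 1, 0.5), log_transform = FALSE)
  expect_true(one$degenerate)
  expect_true(one$threshold_fallback)
  expect_true(is.finite(one$threshold))
  # and clearly bimodal data is not flagged
  two <- fit_mixture(c(rnorm(300, 0, 0.5), rnorm(300, 4, 0.5)),
                     log_transform = FALSE)
  expect_false(two$degenerate)
})

test_that("density-intersection threshold: symmetry, closed form, grid oracle, component relabeling", {
  sym <- list(mu = c(0, 2), sigma = c(1, 1), w = c(0.5, 0.5))
  expect_equal(intersection_threshold(sym), 1.0)
  skew <- list(mu = c(0, 2), sigma = c(1, 1), w = c(0.8, 0.2))
  expect_equal(intersection_threshold(skew), 1 + log(4) / 2,
               tolerance = 1e-4)
  set.seed(7)
  for (i in 1:20) {
    mu <- sort(runif(2, -3, 3) + c(0, 2))
    sigma <- runif(2, 0.3, 1.5)
    w1 <- runif(1, 0.2, 0.8)
    fit <- list(mu = mu, sigma = sigma, w = c(w1, 1 - w1))
    thr <- tryCatch(intersection_threshold(fit), error = function(e) NA)
    if (is.na(thr)) next
    expect_lt(abs(thr - grid_intersection(mu, sigma, fit$w)), 1e-3)
    expect_gt(thr, mu[1]); expect_lt(thr, mu[2])
  }
  expect_error(intersection_threshold(list(mu = c(2, 0), sigma = c(1, 1),
                                           w = c(.5, .5))), "ordered")
})

test_that("the five-way state rule is a partition and matches the quoted combinations", {
  thr <- c(k4 = 0, k27 = 0, co = 0)
  expect_identical(classify_states(1, 1, 1, thr), "bivalent")
  expect_identical(classify_states(1, -1, 1, thr), "active")
  expect_identical(classify_states(-1, 1, -1, thr), "repressed")
  expect_identical(classify_states(-1, -1, 1, thr), "unmarked")
  expect_identical(classify_states(1, 1, -1, thr), "other")
  # ties at the threshold fall below (strict >)
  expect_identical(classify_states(0, 0, 0, thr), "unmarked")
  # partition over a random grid
  set.seed(5)
  k4 <- rnorm(500); k27 <- rnorm(500); co <- rnorm(500)
  st <- classify_states(k4, k27, co, thr)
  expect_identical(length(st), 500L)
  expect_true(all(st %in% c("active", "repressed", "bivalent", "unmarked",
                            "other")))
  # monotonicity: raising the H3K27me3 threshold never creates
  # repressed/bivalent calls from unmarked/active ones
  st_hi <- classify_states(k4, k27, co, c(k4 = 0, k27 = 0.5, co = 0))
  was_low <- st %in% c("unmarked", "active")
  expect_false(any(st_hi[was_low] %in% c("repressed", "bivalent")))
})

test_that("consensus requires two concordant marker pairs; 'other' votes like any label", {
  expect_identical(consensus_state("bivalent", "bivalent", "active"),
                   "bivalent")
  expect_identical(consensus_state("active", "repressed", "unmarked"), "none")
  expect_identical(consensus_state("active", "active", "active"), "active")
  expect_identical(consensus_state("other", "other", "bivalent"), "other")
})

test_that("planted chromatin states are recovered at 4-sigma component separation", {
  cfg <- sim_config(seed = 13, n_genes = 1200, n_clusters = 4)
  mix <- cfg$score_mixture
  expect_gte(mix$mu_high - mix$mu_low + 1e-12, 4 * mix$sigma)
  gs <- simulate_genescores(cfg)
  # degenerate fractions: all bivalent -> all three signals drawn from the
  # high component (sample means sit at mu_high, far above the low mean)
  cfg_b <- sim_config(seed = 13, n_genes = 100, n_clusters = 2,
                      state_fractions = c(active = 0, repressed = 0,
                                          bivalent = 1, unmarked = 0))
  gsb <- simulate_genescores(cfg_b)
  expect_gt(mean(log10(gsb$k27 + 0.1)), mix$mu_high - 3 * mix$sigma /
              sqrt(length(gsb$k27)) - 0.1)
  expect_gt(mean(log10(gsb$co[[2]] + 0.1)), mix$mu_high - 0.1)
  expect_gt(mean(log10(gsb$k4[[1]] + 0.1)), mix$mu_high - 0.1)
  # reproducibility
  expect_identical(simulate_genescores(cfg), gs)
  # recovery
  cs <- call_states(gs$k27, gs$k4, gs$co)
  expect_gte(mean(cs$calls$consensus == gs$truth$state), 0.95)
  # state labels partition genes in every pair column
  tab <- table(cs$calls$state_H3K4me1)
  expect_identical(sum(tab), nrow(cs$calls))
})

test_that("fate maps count transitions, >=1-lineage activation and lineage specificity exactly", {
  root <- c(g1 = "bivalent", g2 = "bivalent", g3 = "repressed",
            g4 = "active", g5 = "unmarked")
  lin <- list(
    B = c(g1 = "active", g2 = "bivalent", g3 = "repressed", g4 = "active",
          g5 = "unmarked"),
    M = c(g1 = "active", g2 = "active", g3 = "repressed", g4 = "active",
          g5 = "unmarked"),
    E = c(g1 = "repressed", g2 = "active", g3 = "active", g4 = "active",
          g5 = "unmarked"))
  tt <- transition_table(root, lin)
  expect_identical(as.integer(tt$transitions$B["bivalent", "active"]), 1L)
  expect_identical(as.integer(tt$transitions$E["repressed", "active"]), 1L)
  expect_equal(unname(tt$frac_active["bivalent"]), 1)     # g1,g2 both reach active
  expect_equal(unname(tt$frac_active["unmarked"]), 0)
  expect_identical(as.integer(tt$specificity["bivalent", "2"]), 2L)
  expect_identical(as.integer(tt$specificity["active", "3"]), 1L)
  # all-static table is diagonal
  tt2 <- transition_table(root, list(L = root))
  m <- tt2$transitions$L
  expect_identical(sum(diag(m)), length(root))
  expect_identical(sum(m), length(root))
  # random small table equals brute-force enumeration
  set.seed(8)
  states <- c("active", "repressed", "bivalent", "unmarked", "other")
  r <- setNames(sample(states, 30, TRUE), paste0("g", 1:30))
  ls <- lapply(1:3, function(i) setNames(sample(states, 30, TRUE), names(r)))
  names(ls) <- c("A", "B", "C")
  tt3 <- transition_table(r, ls)
  for (lin_name in names(ls)) for (s1 in states) for (s2 in states)
    expect_identical(as.integer(tt3$transitions[[lin_name]][s1, s2]),
                     sum(r == s1 & ls[[lin_name]][names(r)] == s2))
  n_act <- rowSums(sapply(ls, function(v) v[names(r)] == "active"))
  for (s1 in states)
    expect_equal(unname(tt3$frac_active[s1]), mean(n_act[r == s1] >= 1))
})
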