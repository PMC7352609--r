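test_that("perturbation propagation matches hand-solved linear systems", {
  ab <- chain_pathway(c("A", "B"))
  res <- accumulate(ab, c(A = 2, B = 0))
  expect_equal(unname(res$pf), c(2, 2))
  expect_equal(unname(res$acc), c(0, 2))
  expect_equal(res$tA, 2)
  expect_equal(accumulate(chain_pathway(c("A", "B", "C")),
                          c(A = 1, B = 0, C = 0))$tA, 2)
  inhib <- pathway_topology("i", data.frame(source = "A", target = "B",
                                            sign = -1), c("A", "B"))
  res2 <- accumulate(inhib, c(A = 1, B = 0))
  expect_equal(unname(res2$acc["B"]), -1)
  expect_equal(res2$tA, -1)
})

test_that("propagation is linear and equals fixed-point iteration", {
  set.seed(17)
  for (i in 1:10) {
    pw <- generate_pathways(1, sample(3:6, 1), seed = i)[[1]]
    de <- stats::setNames(rnorm(length(pw$genes)), pw$genes)
    res <- accumulate(pw, de)
    expect_equal(accumulate(pw, 3 * de)$pf, 3 * res$pf)
    # fixed-point oracle: PF <- dE + M PF iterated to convergence
    m <- sweep(pw$beta, 2, pmax(pw$n_downstream, 1), "/")
    pf <- de
    for (k in 1:200) pf <- de + as.numeric(m %*% pf)
    expect_equal(res$pf, stats::setNames(pf, pw$genes), tolerance = 1e-10)
  }
})

test_that("a unit-gain cycle raises a named singularity error", {
  cyc <- pathway_topology("loop", data.frame(source = c("A", "B"),
                                             target = c("B", "A"),
                                             sign = 1), c("A", "B"))
  expect_error(accumulate(cyc, c(A = 1, B = 0)), "loop")
})

test_that("over-representation p equals exact combinatorics", {
  expect_equal(p_nde(20, 5, 4, 3), 155 / 4845)
  expect_equal(p_nde(20, 5, 4, 0), 1)
  expect_equal(p_nde(10, 10, 10, 10), 1)
  expect_error(p_nde(10, 5, 4, 6), "inconsistent")
  # exhaustive subset enumeration for a small universe
  n_univ <- 9; k_path <- 4; n_de <- 3
  subsets <- utils::combn(n_univ, n_de)
  for (obs in 0:3) {
    exact <- mean(apply(subsets, 2, function(s) sum(s <= k_path) >= obs))
    expect_equal(p_nde(n_univ, k_path, n_de, obs), exact)
  }
})

test_that("bootstrap perturbation p behaves at its extremes", {
  # no edges: every placement gives tA = 0, so nothing is ever more extreme
  flat <- pathway_topology("flat", data.frame(source = character(),
                                              target = character(),
                                              sign = numeric()),
                           sprintf("g%d", 1:6))
  deg <- data.frame(gene = "g1", mean_lfc = 2)
  expect_equal(p_pert(flat, deg, n_boot = 200, seed = 1), 1)
  # DE gene planted on the hub of a star: only 1 of 26 placements matches
  star <- pathway_topology("star",
                           data.frame(source = "hub",
                                      target = sprintf("t%02d", 1:25),
                                      sign = 1),
                           c("hub", sprintf("t%02d", 1:25)))
  p <- p_pert(star, data.frame(gene = "hub", mean_lfc = 2),
              n_boot = 2000, seed = 3)
  expect_lte(p, 0.05)
  expect_identical(p, p_pert(star, data.frame(gene = "hub", mean_lfc = 2),
                             n_boot = 2000, seed = 3))
  # empty DEG list
  expect_equal(p_pert(star, data.frame(gene = character(),
                                       mean_lfc = numeric()),
                      n_boot = 200, seed = 1), 1)
})

test_that("bootstrap p converges between 2000 and 10000 resamples", {
  chain <- chain_pathway(sprintf("g%02d", 1:10))
  deg <- data.frame(gene = c("g01", "g02"), mean_lfc = c(1.5, 1.2))
  p2 <- p_pert(chain, deg, n_boot = 2000, seed = 5)
  p10 <- p_pert(chain, deg, n_boot = 10000, seed = 6)
  expect_equal(p2, p10, tolerance = 0.012)
})

test_that("full perturbation analysis flags a planted cascade", {
  pws <- c(list(chain_pathway(sprintf("a%02d", 1:20), name = "planted")),
           generate_pathways(5, 20, seed = 2))
  deg <- data.frame(gene = sprintf("a%02d", 1:5), mean_lfc = 1.5)
  res <- run_spia(deg, pws, n_boot = 500, seed = 7)
  expect_true(res$significant[res$pathway == "planted"])
  expect_equal(res$status[res$pathway == "planted"], "activated")
  # empty DEG list: everything at pG = 1
  res0 <- run_spia(data.frame(gene = character(), mean_lfc = numeric()),
                   pws, n_boot = 500, seed = 7)
  expect_true(all(res0$pG == 1))
  # Fisher combination of (0.05, 1) against the chi-square oracle
  expect_equal(combine_fisher(c(0.05, 1)),
               pchisq(-2 * log(0.05), 4, lower.tail = FALSE))
})

test_that("normality test matches reference implementation values", {
  x <- c(0.5, 1.2, -0.3, 2.4, 0.8, -1.1, 0.2, 1.9, -0.6, 0.4, 1.1, -0.2)
  res <- dagostino_pearson(x)
  expect_equal(res$statistic, 0.2660841236001857, tolerance = 1e-9)
  expect_equal(res$p_value, 0.875428269245502, tolerance = 1e-9)
  y <- c(0.1, 0.2, 0.3, 0.5, 0.9, 1.8, 4.0, 9.5, 20.0, 45.0)
  res2 <- dagostino_pearson(y)
  expect_equal(res2$statistic, 16.111540710190493, tolerance = 1e-9)
  expect_equal(res2$p_value, 0.00031726589344119256, tolerance = 1e-9)
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
})

test_that("paired comparison picks its test by normality", {
  set.seed(23)
  expect_equal(paired_difference_test(rnorm(20, 1))$method, "paired_t")
  skewed <- rexp(20)^3
  expect_equal(paired_difference_test(skewed)$method, "signed_rank")
  expect_equal(paired_difference_test(rep(0, 5))$p_value, 1)
})

test_that("fine-tuning comparison behaves on planted and degenerate inputs", {
  mk <- function(tA, sig = TRUE) {
    structure(data.frame(pathway = sprintf("p%02d", seq_along(tA)), tA = tA,
                         significant = sig, stringsAsFactors = FALSE),
              class = c("spia_result", "data.frame"))
  }
  early <- mk(c(5, -6, 7, -8, 9, -10, 11, -12))
  late <- mk(c(8, -9, 10, -11, 12, -13, 14, -15))
  res <- fine_tuning_comparison(early, late)
  expect_true(res$supported)
  expect_equal(res$mean_delta, 3)
  # identical runs: zero change, p = 1
  same <- fine_tuning_comparison(early, early)
  expect_equal(same$p_value, 1)
  expect_false(same$supported)
  # sign flip with equal magnitude: magnitudes compared, zero change
  flip <- fine_tuning_comparison(early, mk(-c(5, -6, 7, -8, 9, -10, 11, -12)))
  expect_equal(flip$mean_delta, 0)
  # too few shared significant pathways
  few <- fine_tuning_comparison(mk(5, sig = FALSE), mk(6, sig = FALSE))
  expect_equal(few$method, "none")
  expect_false(few$supported)
})

test_that("backward-functional analysis damps an opposed cascade", {
  pw <- chain_pathway(c("u1", "u2", "rev", "d1"), name = "toy")
  deg3 <- data.frame(gene = c("u1", "u2"), mean_lfc = c(2, 2))
  reverted <- data.frame(gene = "rev", mean_lfc = -2)
  res <- backward_functional_test(deg3, reverted, list(pw), n_boot = 200,
                                  seed = 1)
  expect_lt(res$deltas$delta[res$deltas$pathway == "toy"], 0)
  # reverted gene off-pathway changes nothing
  off <- backward_functional_test(deg3, data.frame(gene = "zz", mean_lfc = -2),
                                  list(pw), n_boot = 200, seed = 1)
  expect_equal(off$deltas$delta, 0)
  expect_false(isTRUE(off$supported))
  # zero fold-change contributes nothing
  nil <- backward_functional_test(deg3, data.frame(gene = "rev", mean_lfc = 0),
                                  list(pw), n_boot = 200, seed = 1)
  expect_equal(nil$deltas$delta, 0)
  expect_error(backward_functional_test(deg3, reverted[0, ], list(pw)),
               "empty")
  expect_error(backward_functional_test(deg3,
                                        data.frame(gene = "u1", mean_lfc = 1),
                                        list(pw)), "absent")
})

test_that("fold-change mapping onto pathways is zero-filled", {
  pw <- chain_pathway(c("A", "B", "C"))
  de <- delta_e(data.frame(gene = "B", mean_lfc = 2), pw)
  expect_equal(unname(de), c(0, 2, 0))
  expect_equal(unname(delta_e(data.frame(gene = character(),
                                         mean_lfc = numeric()), pw)),
               rep(0, 3))
  expect_error(delta_e(data.frame(gene = c("B", "B"), mean_lfc = c(1, 2)), pw),
               "duplicate")
})
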