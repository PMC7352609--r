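test_that("weighted voting reproduces the hand-worked example", {
  set.seed(61)
  # one gene, class means 0 and 2, both sds ~1, test point at 2
  g <- c(scale(rnorm(20)) * 1, scale(rnorm(20)) * 1 + 2)
  train <- matrix(g, 1, 40, dimnames = list("g", paste0("s", 1:40)))
  labels <- rep(c("c1", "c2"), each = 20)
  res <- weighted_voting_classify(train, labels, c(g = 2))
  expect_equal(unname(res$margin), -1)  # w = -1, vote = -(2 - 1)
  expect_equal(unname(res$class), "c2")
  # decision midpoint: zero margin, deterministic class-1 tie-break
  mid <- weighted_voting_classify(train, labels, c(g = 1))
  expect_equal(unname(mid$margin), 0)
  expect_equal(unname(mid$class), "c1")
  # swapping class labels flips every vote
  swapped <- weighted_voting_classify(train, factor(labels,
                                                    levels = c("c2", "c1")),
                                      c(g = 2))
  expect_equal(unname(swapped$margin), 1)
})

test_that("leave-one-out weighted voting separates planted classes", {
  co <- small_cohort()
  st <- co$studies[[1]]
  keep <- st$samples$stage %in% c("dcis", "idc")
  expr <- st$expr[, keep]
  labels <- factor(st$samples$stage[keep])
  informative <- co$genes$symbol[co$genes$planted_class == "disparate"][1:10]
  pred <- vapply(seq_len(ncol(expr)), function(j) {
    weighted_voting_classify(expr[informative, -j, drop = FALSE], labels[-j],
                             expr[informative, j])$class
  }, character(1))
  expect_gte(mean(pred == as.character(labels)), 0.95)
})

test_that("kNN classifies with lower-class tie-break", {
  train <- matrix(c(0, 0, 0, 5, 5, 5), 1, 6,
                  dimnames = list("g", paste0("s", 1:6)))
  labels <- rep(c("c1", "c2"), each = 3)
  expect_equal(unname(knn_classify(train, labels, c(g = 0.1))$class), "c1")
  expect_equal(unname(knn_classify(train, labels, c(g = 4.9))$class), "c2")
  # k = 2 split vote goes to the first class level
  expect_equal(unname(knn_classify(train, labels, c(g = 2.5), k = 2)$class),
               "c1")
})

test_that("AUC equals Mann-Whitney pair counting", {
  expect_equal(roc_auc(c(3, 4, 5, 0, 1, 2), rep(c("pos", "neg"), each = 3),
                       positive = "pos"), 1)
  expect_equal(roc_auc(rep(1, 6), rep(c("pos", "neg"), each = 3),
                       positive = "pos"), 0.5)
  expect_error(roc_auc(1:3, rep("pos", 3)), "both classes")
  set.seed(71)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    scores <- sample(seq_len(8), n, TRUE)  # many ties
    labels <- sample(c("pos", "neg"), n, TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels, positive = "pos"),
                 pair_count_auc(scores, labels, "pos"))
  }
})

test_that("concordance index equals pair enumeration and survival's", {
  rec <- data.frame(time_months = c(1, 2, 3), event = 1,
                    risk_score = c(3, 1, 2))
  expect_equal(concordance_index(rec), 2 / 3)
  perfect <- data.frame(time_months = 1:10, event = 1, risk_score = 10:1)
  expect_equal(concordance_index(perfect), 1)
  # risk equal to negative time with no censoring is perfectly concordant
  t <- runif(15, 1, 50)
  expect_equal(concordance_index(time = t, event = rep(1, 15), risk = -t), 1)
  expect_error(concordance_index(data.frame(time_months = 1:3, event = 0,
                                            risk_score = 1:3)),
               "no comparable")
  set.seed(81)
  for (i in 1:10) {
    n <- 30
    time <- rexp(n, 0.1)
    event <- rbinom(n, 1, 0.7)
    risk <- rnorm(n)
    if (sum(event) == 0) next
    ci <- concordance_index(time = time, event = event, risk = risk)
    expect_equal(ci, pair_count_ci(time, event, risk))
    sv <- survival::concordance(survival::Surv(time, event) ~ risk,
                                reverse = TRUE)
    expect_equal(ci, unname(sv$concordance), tolerance = 1e-9)
  }
})

test_that("iterative selection finds planted genes then stops on noise", {
  set.seed(91)
  n <- 60
  expr <- matrix(rnorm(40 * n), 40, n,
                 dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:n)))
  labels <- rep(c("dcis", "idc"), each = n / 2)
  expr[c("g01", "g02"), labels == "idc"] <-
    expr[c("g01", "g02"), labels == "idc"] + 2.5
  rounds <- iterative_feature_selection(expr, labels, max_rounds = 9,
                                        seed = 3)
  expect_gt(rounds$auc[1], 0.9)
  expect_true(all(c("g01", "g02") %in% attr(rounds, "genes")[[1]]))
  # all-noise data stall immediately near chance
  noise <- matrix(rnorm(30 * n), 30, n,
                  dimnames = list(sprintf("n%02d", 1:30), paste0("s", 1:n)))
  r0 <- iterative_feature_selection(noise, labels, max_rounds = 9, seed = 3)
  expect_lte(max(r0$auc[-1], 0), 0.75)
  expect_lt(nrow(r0), 9)
  r1 <- iterative_feature_selection(expr, labels, max_rounds = 1, seed = 3)
  expect_equal(nrow(r1), 1)
})

test_that("signature size drives concordance for planted additive risk", {
  co <- small_cohort()
  surv <- co$survival
  beta <- abs(surv$weights)
  ranked <- rownames(surv$expr)[order(-beta)]
  sets <- lapply(seq(10, 100, 10), function(k) ranked[seq_len(k)])
  res <- signature_size_correlation(sets, surv$expr, surv$records, seed = 5)
  r <- function(m) res$cor$r[res$cor$measure == m]
  expect_gt(r("ranked_ci"), 0)
  expect_gt(r("random_ci"), 0)
  expect_error(signature_size_correlation(sets[rep(1, 4)], surv$expr,
                                          surv$records), "constant")
  expect_error(signature_size_correlation(sets[1:2], surv$expr,
                                          surv$records), "at least 3")
})

test_that("null survival weights give no size-concordance trend", {
  set.seed(15)
  expr <- matrix(rnorm(80 * 150), 80, 150,
                 dimnames = list(sprintf("sv%02d", 1:80), NULL))
  records <- data.frame(time_months = rexp(150, 0.02),
                        event = rbinom(150, 1, 0.7))
  sets <- lapply(seq(10, 60, 10), function(k) rownames(expr)[seq_len(k)])
  # fixed external weights: risk is independent of survival by construction
  w <- stats::setNames(rnorm(nrow(expr)), rownames(expr))
  res <- signature_size_correlation(sets, expr, records, seed = 6,
                                    weights = w)
  expect_gt(res$cor$p[res$cor$measure == "ranked_ci"], 0.01)
  expect_lt(abs(res$cor$r[res$cor$measure == "ranked_ci"]), 0.8)
})

test_that("median-split hazard ratio recovers a planted risk effect", {
  set.seed(19)
  risk <- rnorm(300)
  time <- rexp(300, 0.02 * exp(risk))
  rec <- data.frame(time_months = pmin(time, 100),
                    event = as.integer(time <= 100), risk_score = risk)
  hr <- hazard_ratio(rec)
  expect_gt(hr$hr, 1.5)
  expect_lt(hr$p_value, 0.01)
})
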