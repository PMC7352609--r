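#' Weighted-voting two-class classifier
#'
#' Signal-to-noise weighted voting: each informative gene `g` gets weight
#' `w_g = (mu1_g - mu2_g) / (sigma1_g + sigma2_g)` and casts the vote
#' `v_g = w_g * (x_g - (mu1_g + mu2_g) / 2)` for a test profile `x`. The
#' summed vote decides the class: positive (or zero, the deterministic
#' tie-break) for the first class level, negative for the second. Genes with
#' `sigma1 + sigma2 = 0` are dropped.
#'
#' @param train genes x samples training matrix.
#' @param labels class labels for the training samples (2 classes; the first
#'   factor level is "class 1").
#' @param test numeric test profile (named by gene) or genes x samples matrix.
#' @return list with `class`, `margin` (summed vote) per test sample.
#' @export
weighted_voting_classify <- function(train, labels, test) {
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2)
  s <- wv_scores(train, labels, as_test_matrix(test, rownames(train)))
  list(class = ifelse(s >= 0, levels(labels)[1], levels(labels)[2]),
       margin = s)
}

as_test_matrix <- function(test, genes) {
  if (is.null(dim(test))) test <- matrix(test, ncol = 1,
                                         dimnames = list(names(test) %||% genes,
                                                         "test"))
  test[genes, , drop = FALSE]
}

wv_scores <- function(train, labels, test) {
  i1 <- labels == levels(labels)[1]
  m1 <- rowMeans(train[, i1, drop = FALSE])
  m2 <- rowMeans(train[, !i1, drop = FALSE])
  s1 <- apply(train[, i1, drop = FALSE], 1, stats::sd)
  s2 <- apply(train[, !i1, drop = FALSE], 1, stats::sd)
  keep <- (s1 + s2) > 0
  w <- (m1 - m2)[keep] / (s1 + s2)[keep]
  b <- ((m1 + m2) / 2)[keep]
  colSums(w * (test[keep, , drop = FALSE] - b))
}

#' k-nearest-neighbor two-class classifier
#'
#' Euclidean k-NN (default k = 3) on per-gene z-scored expression (training
#' mean/sd). Majority vote; ties go to the lower (first) class level. The
#' score is the fraction of neighbors from the first class.
#'
#' @inheritParams weighted_voting_classify
#' @param k neighborhood size.
#' @return list with `class` and `score` per test sample.
#' @export
knn_classify <- function(train, labels, test, k = 3) {
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2)
  test <- as_test_matrix(test, rownames(train))
  mu <- rowMeans(train); sg <- apply(train, 1, stats::sd)
  sg[sg == 0] <- 1
  ztr <- (train - mu) / sg
  zte <- (test - mu) / sg
  score <- vapply(seq_len(ncol(zte)), function(j) {
    d <- sqrt(colSums((ztr - zte[, j])^2))
    nb <- order(d)[seq_len(min(k, length(d)))]
    mean(labels[nb] == levels(labels)[1])
  }, numeric(1))
  list(class = ifelse(score >= 0.5, levels(labels)[1], levels(labels)[2]),
       score = score)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with half credit for ties: the probability
#' that a positive sample scores above a negative one.
#'
#' @param scores numeric classifier scores.
#' @param labels class labels; `positive` names the positive class (default:
#'   first factor level).
#' @param positive positive class label.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- factor(labels)
  if (is.null(positive)) positive <- levels(labels)[1]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# cross-validated AUC of a gene subset under a classifier
cv_auc <- function(expr, labels, genes, classifier, folds) {
  labels <- factor(labels)
  scores <- numeric(length(labels))
  for (f in unique(folds)) {
    tr <- folds != f
    sub <- expr[genes, , drop = FALSE]
    scores[!tr] <- if (classifier == "weighted_voting") {
      wv_scores(sub[, tr, drop = FALSE], labels[tr], sub[, !tr, drop = FALSE])
    } else {
      knn_classify(sub[, tr, drop = FALSE], labels[tr],
                   sub[, !tr, drop = FALSE])$score
    }
  }
  roc_auc(scores, labels)
}

#' Iterative discriminative-feature selection
#'
#' Repeats, for up to `max_rounds` rounds: greedily grow a gene feature that
#' maximizes cross-validated AUC (candidate genes ranked by absolute
#' signal-to-noise; a gene is kept when it improves the CV AUC; at most
#' `max_genes` genes per feature), record the round, then remove the selected
#' genes from the pool and rerun. Iteration stops early when the pool is
#' exhausted or the round AUC is at most 0.5 or unchanged from the previous
#' round.
#'
#' @param expr genes x samples matrix.
#' @param labels two-class labels.
#' @param classifier `"weighted_voting"` or `"knn"`.
#' @param max_rounds maximum feature rounds.
#' @param max_genes cap on genes per feature.
#' @param n_candidates how many top-ranked pool genes are tried per round.
#' @param n_folds cross-validation folds.
#' @param seed integer seed (fold assignment).
#' @return data frame of class `feature_rounds` (`round`, `n_genes`, `auc`)
#'   with the per-round gene vectors in `attr(, "genes")`.
#' @export
iterative_feature_selection <- function(expr, labels,
                                        classifier = c("weighted_voting", "knn"),
                                        max_rounds = 9, max_genes = 60,
                                        n_candidates = 30, n_folds = 5,
                                        seed = 1L) {
  classifier <- match.arg(classifier)
  labels <- factor(labels)
  set.seed(split_seed(seed, 13L))
  folds <- stats::ave(seq_along(labels), labels,
                      FUN = function(i) sample(rep(seq_len(n_folds),
                                                   length.out = length(i))))
  pool <- rownames(expr)
  rounds <- list(); gene_sets <- list()
  prev_auc <- NA_real_
  for (r in seq_len(max_rounds)) {
    if (length(pool) == 0) break
    i1 <- labels == levels(labels)[1]
    m1 <- rowMeans(expr[pool, i1, drop = FALSE])
    m2 <- rowMeans(expr[pool, !i1, drop = FALSE])
    s1 <- apply(expr[pool, i1, drop = FALSE], 1, stats::sd)
    s2 <- apply(expr[pool, !i1, drop = FALSE], 1, stats::sd)
    snr <- abs(m1 - m2) / pmax(s1 + s2, .Machine$double.eps)
    cand <- pool[order(-snr)][seq_len(min(n_candidates, length(pool)))]
    sel <- cand[1]
    best <- cv_auc(expr, labels, sel, classifier, folds)
    for (g in cand[-1]) {
      if (length(sel) >= max_genes) break
      a <- cv_auc(expr, labels, c(sel, g), classifier, folds)
      if (a > best) { best <- a; sel <- c(sel, g) }
    }
    rounds[[r]] <- data.frame(round = r, n_genes = length(sel), auc = best)
    gene_sets[[r]] <- sel
    pool <- setdiff(pool, sel)
    if (best <= 0.5 || (!is.na(prev_auc) && abs(best - prev_auc) < 1e-8)) break
    prev_auc <- best
  }
  out <- do.call(rbind, rounds)
  structure(out, genes = gene_sets, classifier = classifier,
            class = c("feature_rounds", "data.frame"))
}

#' Harrell concordance index of a risk score
#'
#' Fraction of comparable subject pairs (the earlier time is an observed
#' event) in which the higher risk score belongs to the shorter survival;
#' risk ties earn half credit.
#'
#' @param records data frame with `time_months`, `event` (1 = event,
#'   0 = censored) and `risk_score`; or supply the three vectors.
#' @param time,event,risk alternative vector interface.
#' @return concordance index in `[0, 1]`.
#' @export
concordance_index <- function(records = NULL, time = NULL, event = NULL,
                              risk = NULL) {
  if (!is.null(records)) {
    time <- records$time_months; event <- records$event
    risk <- records$risk_score
  }
  comparable <- outer(time, time, "<") & (event == 1)
  conc <- outer(risk, risk, ">")
  tied <- outer(risk, risk, "==")
  n <- sum(comparable)
  if (n == 0) stop("no comparable pairs")
  (sum(conc & comparable) + 0.5 * sum(tied & comparable)) / n
}

#' Hazard ratio of the median-split risk groups
#'
#' Splits subjects at the median risk score and fits a two-group Cox
#' proportional-hazards model; returns the high-vs-low hazard ratio.
#'
#' @inheritParams concordance_index
#' @return list with `hr`, `p_value`.
#' @export
hazard_ratio <- function(records = NULL, time = NULL, event = NULL,
                         risk = NULL) {
  if (!is.null(records)) {
    time <- records$time_months; event <- records$event
    risk <- records$risk_score
  }
  grp <- factor(risk > stats::median(risk), levels = c(FALSE, TRUE),
                labels = c("low", "high"))
  if (nlevels(droplevels(grp)) < 2) stop("constant risk score")
  fit <- survival::coxph(survival::Surv(time, event) ~ grp)
  s <- summary(fit)
  list(hr = unname(exp(stats::coef(fit))), p_value = s$coefficients[1, 5])
}

#' Correlation of signature size with survival performance
#'
#' For a list of nested (or otherwise ordered) gene sets, computes per set a
#' risk score (per-gene univariate Cox coefficients times expression, summed
#' over the set), the concordance index and the median-split hazard ratio,
#' and the Pearson correlation of set size with CI and with HR. A seeded
#' random-gene-set control (same sizes, genes drawn uniformly) is evaluated
#' identically.
#'
#' @param gene_sets list of character vectors (rows of `expr`).
#' @param expr genes x subjects expression matrix.
#' @param records survival records (`time_months`, `event`).
#' @param seed integer seed for the random control.
#' @param weights optional named per-gene risk weights; by default they are
#'   the univariate Cox coefficients fitted on `records` (note this
#'   in-sample weighting inflates the concordance of larger sets — supply
#'   externally derived weights for an unbiased null).
#' @return list with `ranked` and `random` per-set data frames
#'   (`n_genes`, `ci`, `hr`) and `cor` — a data frame of Pearson `r` and `p`
#'   for size-vs-CI and size-vs-HR in both arms.
#' @export
signature_size_correlation <- function(gene_sets, expr, records, seed = 1L,
                                       weights = NULL) {
  if (length(gene_sets) < 3) stop("need at least 3 gene sets")
  sizes <- lengths(gene_sets)
  if (length(unique(sizes)) == 1) stop("constant signature sizes")
  beta <- weights %||% marginal_cox_coefficients(expr, records)
  eval_sets <- function(sets) {
    do.call(rbind, lapply(sets, function(g) {
      risk <- as.numeric(crossprod(expr[g, , drop = FALSE], beta[g]))
      data.frame(n_genes = length(g),
                 ci = concordance_index(time = records$time_months,
                                        event = records$event, risk = risk),
                 hr = hazard_ratio(time = records$time_months,
                                   event = records$event, risk = risk)$hr)
    }))
  }
  ranked <- eval_sets(gene_sets)
  set.seed(split_seed(seed, 14L))
  random_sets <- lapply(sizes, function(k) sample(rownames(expr), k))
  random <- eval_sets(random_sets)
  cors <- do.call(rbind, lapply(list(ranked_ci = ranked$ci, ranked_hr = ranked$hr,
                                     random_ci = random$ci,
                                     random_hr = random$hr),
                                function(v) {
    ct <- stats::cor.test(sizes, v)
    data.frame(r = unname(ct$estimate), p = ct$p.value)
  }))
  cors$measure <- rownames(cors)
  rownames(cors) <- NULL
  list(ranked = ranked, random = random, cor = cors)
}

# univariate Cox coefficient per gene (the supervised signature weights)
marginal_cox_coefficients <- function(expr, records) {
  srv <- survival::Surv(records$time_months, records$event)
  vapply(rownames(expr), function(g) {
    unname(stats::coef(survival::coxph(srv ~ expr[g, ])))
  }, numeric(1))
}
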