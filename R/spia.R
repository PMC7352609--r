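#' Construct a signed pathway topology
#'
#' Stores a pathway as an ordered gene list plus a square influence matrix
#' `beta` with `beta[target, source]` in `{-1, 0, +1}` (sign of the
#' regulation of `target` by `source`), and the per-gene count of downstream
#' targets.
#'
#' @param name pathway name.
#' @param edges data frame with `source`, `target`, `sign` columns.
#' @param genes optional ordered gene vector; defaults to the genes seen in
#'   `edges`.
#' @return object of class `pathway_topology`.
#' @export
pathway_topology <- function(name, edges, genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(c(edges$source, edges$target)))
  stopifnot(all(edges$sign %in% c(-1, 1)),
            all(c(edges$source, edges$target) %in% genes))
  beta <- matrix(0, length(genes), length(genes),
                 dimnames = list(genes, genes))
  for (i in seq_len(nrow(edges))) {
    beta[edges$target[i], edges$source[i]] <- edges$sign[i]
  }
  structure(list(name = name, genes = genes, beta = beta,
                 n_downstream = colSums(beta != 0)),
            class = "pathway_topology")
}

#' Per-gene signed fold-change vector for a pathway
#'
#' Maps a DEG list onto the genes of a pathway: differentially expressed
#' genes contribute their mean log2 fold-change, all other pathway genes are
#' assigned 0.
#'
#' @param deg_list data frame with `gene` and `mean_lfc` (e.g. a `deg_list`).
#' @param pathway a `pathway_topology`.
#' @return named numeric vector over `pathway$genes`.
#' @export
delta_e <- function(deg_list, pathway) {
  if (anyDuplicated(deg_list$gene)) {
    stop("duplicate gene symbols in DEG list")
  }
  de <- stats::setNames(rep(0, length(pathway$genes)), pathway$genes)
  hit <- intersect(pathway$genes, deg_list$gene)
  de[hit] <- deg_list$mean_lfc[match(hit, deg_list$gene)]
  de
}

#' Propagate perturbation through a signed topology
#'
#' Solves the linear propagation model `PF = dE + M %*% PF` with
#' `M[t, s] = beta[t, s] / n_downstream(s)`: each gene passes its
#' perturbation factor on to its targets, split over its downstream edges and
#' signed by the regulation. The accumulation is `Acc = PF - dE` and the net
#' total accumulation `tA = sum(Acc)` summarizes activation (`tA > 0`) or
#' inhibition (`tA < 0`) of the pathway.
#'
#' @param pathway a `pathway_topology`.
#' @param delta_e signed fold-change vector over `pathway$genes`.
#' @return list with `pf`, `acc`, `tA`.
#' @export
accumulate <- function(pathway, delta_e) {
  nds <- pmax(pathway$n_downstream, 1)
  m <- sweep(pathway$beta, 2, nds, "/")
  a <- diag(length(pathway$genes)) - m
  pf <- tryCatch(solve(a, delta_e),
                 error = function(e) stop("singular propagation system in pathway '",
                                          pathway$name,
                                          "' (cycle with unit gain)", call. = FALSE))
  acc <- pf - delta_e
  list(pf = pf, acc = acc, tA = sum(acc))
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of observing at least `n_de_on_pathway` DE genes on
#' a pathway of `n_pathway` genes, when `n_de_total` of the `n_universe`
#' genes are DE.
#'
#' @param n_universe,n_pathway,n_de_total,n_de_on_pathway consistent counts.
#' @return `P(X >= n_de_on_pathway)`.
#' @export
p_nde <- function(n_universe, n_pathway, n_de_total, n_de_on_pathway) {
  if (n_de_on_pathway > min(n_pathway, n_de_total) ||
      n_pathway > n_universe || n_de_total > n_universe) {
    stop("inconsistent hypergeometric counts")
  }
  stats::phyper(n_de_on_pathway - 1, n_pathway, n_universe - n_pathway,
                n_de_total, lower.tail = FALSE)
}

#' Bootstrap p-value for the net accumulation
#'
#' Re-places the observed DE fold-changes onto random pathway gene positions
#' (same number of DE genes, values permuted), recomputes `tA` each time, and
#' reports the smoothed exceedance fraction
#' `(#{|tA_boot| >= |tA_obs|} + 1) / (n_boot + 1)`.
#'
#' @param pathway a `pathway_topology`.
#' @param deg_list DEG data frame (`gene`, `mean_lfc`).
#' @param n_boot bootstrap resamples (>= 200).
#' @param seed integer seed.
#' @return `pPERT` in `(0, 1]`.
#' @export
p_pert <- function(pathway, deg_list, n_boot = 2000, seed = 1L) {
  stopifnot(n_boot >= 200)
  de <- delta_e(deg_list, pathway)
  lfc <- de[de != 0]
  nde <- length(lfc)
  if (nde == 0) return(1)
  t_obs <- accumulate(pathway, de)$tA
  set.seed(split_seed(seed, 11L))
  ng <- length(pathway$genes)
  hits <- 0L
  for (b in seq_len(n_boot)) {
    pos <- sample.int(ng, nde)
    deb <- numeric(ng)
    deb[pos] <- lfc[sample.int(nde)]
    names(deb) <- pathway$genes
    if (abs(accumulate(pathway, deb)$tA) >= abs(t_obs)) hits <- hits + 1L
  }
  (hits + 1) / (n_boot + 1)
}

#' Signed-topology pathway perturbation analysis
#'
#' For every pathway: counts the DE genes on it (`NDE`), computes the
#' over-representation p-value `pNDE` (hypergeometric over the universe of
#' all genes on any supplied pathway), the net accumulation `tA` and its
#' bootstrap p-value `pPERT`, combines `pNDE` and `pPERT` by Fisher's method
#' into `pG`, and flags pathways with BH-adjusted `pG` below `alpha`. Status
#' is `activated` when `tA > 0`, else `inhibited`.
#'
#' @param deg_list DEG data frame (`gene`, `mean_lfc`).
#' @param pathways list of `pathway_topology` objects.
#' @param alpha significance level on adjusted `pG`.
#' @param n_boot bootstrap resamples for `pPERT`.
#' @param seed integer seed.
#' @return a `spia_result` data frame sorted by `pG`: `pathway`, `NDE`,
#'   `pNDE`, `tA`, `pPERT`, `pG`, `pG_adj`, `status`, `significant`.
#' @export
run_spia <- function(deg_list, pathways, alpha = 0.05, n_boot = 2000,
                     seed = 1L) {
  if (length(pathways) == 0) stop("pathways must be nonempty")
  universe <- unique(unlist(lapply(pathways, `[[`, "genes")))
  de_total <- length(intersect(deg_list$gene, universe))
  rows <- lapply(seq_along(pathways), function(i) {
    pw <- pathways[[i]]
    de <- delta_e(deg_list, pw)
    nde <- sum(de != 0)
    pnde <- p_nde(length(universe), length(pw$genes), de_total, nde)
    ta <- accumulate(pw, de)$tA
    ppert <- p_pert(pw, deg_list, n_boot = n_boot,
                    seed = split_seed(seed, 200L + i))
    data.frame(pathway = pw$name, NDE = nde, pNDE = pnde, tA = ta,
               pPERT = ppert, pG = combine_fisher(c(pnde, ppert)),
               status = if (ta > 0) "activated" else "inhibited",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pG_adj <- stats::p.adjust(out$pG, method = "BH")
  out$significant <- out$pG_adj < alpha
  out <- out[order(out$pG), ]
  rownames(out) <- NULL
  structure(out, alpha = alpha, class = c("spia_result", "data.frame"))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino) and kurtosis
#' (Anscombe-Glynn) into `K2 = Z1^2 + Z2^2`, referred to chi-square with 2
#' degrees of freedom. Requires `n >= 8`.
#'
#' @param x numeric vector.
#' @return list with `statistic` (K2) and `p_value`.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test needs n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  # skewness component
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  dlt <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- dlt * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis component
  g2 <- m4 / m2^2
  eg2 <- 3 * (n - 1) / (n + 1)
  vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (g2 - eg2) / sqrt(vg2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Paired comparison with normality-gated test choice
#'
#' Applies a paired Student t-test when the differences pass the
#' D'Agostino-Pearson normality test (p > 0.05), otherwise the exact
#' signed-rank test; below n = 8 (where the normality test is undefined) the
#' signed-rank test is always used.
#'
#' @param diffs paired differences.
#' @return list with `p_value`, `mean_diff`, `method`.
#' @export
paired_difference_test <- function(diffs) {
  diffs <- diffs[!is.na(diffs)]
  n <- length(diffs)
  if (n < 2) return(list(p_value = NA_real_, mean_diff = mean(diffs),
                         method = "none"))
  if (stats::sd(diffs) == 0) {
    return(list(p_value = if (mean(diffs) == 0) 1 else .Machine$double.xmin,
                mean_diff = mean(diffs), method = "degenerate"))
  }
  normal <- n >= 8 && dagostino_pearson(diffs)$p_value > 0.05
  if (normal) {
    list(p_value = stats::t.test(diffs)$p.value, mean_diff = mean(diffs),
         method = "paired_t")
  } else {
    list(p_value = suppressWarnings(wilcoxon_signed_rank(diffs)$p_value),
         mean_diff = mean(diffs), method = "signed_rank")
  }
}

#' Fine-tuning comparison of two perturbation runs
#'
#' Compares the perturbation magnitude `|tA|` of an early-stage gene set
#' against a late-stage (expanded) gene set over the pathways significant in
#' both runs. Fine-tuning — late alterations amplifying the pathways already
#' perturbed early — is supported when the mean `|tA|` change is positive
#' with `p < alpha` in the normality-gated paired test.
#'
#' @param results_early,results_late `spia_result` objects over the same
#'   pathway set.
#' @param alpha significance level.
#' @return list with `deltas` (per shared significant pathway), `p_value`,
#'   `mean_delta`, `method`, `supported`, `flag`.
#' @export
fine_tuning_comparison <- function(results_early, results_late, alpha = 0.05) {
  shared <- intersect(results_early$pathway[results_early$significant],
                      results_late$pathway[results_late$significant])
  if (length(shared) < 2) {
    return(list(deltas = data.frame(pathway = shared, delta = numeric(length(shared))),
                p_value = NA_real_, mean_delta = NA_real_, method = "none",
                supported = FALSE, flag = "fewer than 2 shared significant pathways"))
  }
  e <- abs(results_early$tA[match(shared, results_early$pathway)])
  l <- abs(results_late$tA[match(shared, results_late$pathway)])
  delta <- l - e
  tst <- paired_difference_test(delta)
  list(deltas = data.frame(pathway = shared, delta = delta,
                           stringsAsFactors = FALSE),
       p_value = tst$p_value, mean_delta = tst$mean_diff,
       method = tst$method,
       supported = !is.na(tst$p_value) && tst$mean_diff > 0 &&
         tst$p_value < alpha,
       flag = NA_character_)
}

#' Backward-functional test of reverted genes
#'
#' Adds genes whose in situ expression change was later erased (the
#' "reverted" genes, re-entered with their original in situ fold-changes) to
#' the invasive DEG list and re-runs the perturbation analysis. On pathways
#' containing at least one reverted gene, backward function is supported when
#' the perturbation magnitude `|tA|` significantly decreases.
#'
#' @param deg3 invasive-stage DEG data frame (`gene`, `mean_lfc`).
#' @param reverted data frame (`gene`, `mean_lfc`) of reverted genes with
#'   their in situ fold-changes; must be disjoint from `deg3`.
#' @param pathways list of `pathway_topology` objects.
#' @param alpha significance level.
#' @param n_boot,seed passed to [run_spia()].
#' @return list with `deltas` (all pathways, `delta = |tA_aug| - |tA_base|`,
#'   `has_reverted` flag), `p_value`, `mean_delta`, `method`, `supported`.
#' @export
backward_functional_test <- function(deg3, reverted, pathways, alpha = 0.05,
                                     n_boot = 2000, seed = 1L) {
  if (nrow(reverted) == 0) stop("reverted gene set is empty")
  if (length(intersect(deg3$gene, reverted$gene))) {
    stop("reverted genes must be absent from the invasive DEG list")
  }
  aug <- rbind(deg3[, c("gene", "mean_lfc")], reverted[, c("gene", "mean_lfc")])
  base <- run_spia(deg3, pathways, alpha = alpha, n_boot = n_boot, seed = seed)
  full <- run_spia(aug, pathways, alpha = alpha, n_boot = n_boot, seed = seed)
  has_rev <- vapply(pathways, function(pw) any(reverted$gene %in% pw$genes),
                    logical(1))
  nm <- vapply(pathways, `[[`, character(1), "name")
  delta <- abs(full$tA[match(nm, full$pathway)]) -
    abs(base$tA[match(nm, base$pathway)])
  deltas <- data.frame(pathway = nm, delta = delta, has_reverted = has_rev,
                       stringsAsFactors = FALSE)
  dsub <- delta[has_rev]
  if (length(dsub) < 1) {
    return(list(deltas = deltas, p_value = NA_real_, mean_delta = NA_real_,
                method = "none", supported = FALSE))
  }
  tst <- paired_difference_test(dsub)
  list(deltas = deltas, p_value = tst$p_value, mean_delta = tst$mean_diff,
       method = tst$method,
       supported = !is.na(tst$p_value) && tst$mean_diff < 0 &&
         tst$p_value < alpha)
}
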