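#' Wilcoxon matched-pair signed-rank test
#'
#' Exact, tie-aware implementation of the paired signed-rank test used by the
#' directional evolution analyses. Zero differences are dropped (standard
#' convention). For `n <= exact_limit` the null distribution of the positive
#' rank sum is computed by a shifted-convolution dynamic program over the
#' midranks — exactly equivalent to enumerating all `2^n` sign assignments,
#' and valid in the presence of tied absolute differences. Above the limit a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param differences numeric vector of paired differences.
#' @param exact_limit largest n for which the exact distribution is used.
#' @return list with `statistic` (positive rank sum `V`), `p_value`
#'   (two-sided), `n` (non-zero pairs) and `method`.
#' @export
wilcoxon_signed_rank <- function(differences, exact_limit = 25) {
  d <- differences[!is.na(differences)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences zero; p = 1")
    return(list(statistic = 0, p_value = 1, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of 2*V over all sign assignments (midranks doubled to ints)
    w2 <- round(2 * r)
    counts <- numeric(sum(w2) + 1)  # counts[k+1] = #assignments with 2V == k
    counts[1] <- 1
    for (wi in w2) {
      shifted <- c(rep(0, wi), counts[seq_len(length(counts) - wi)])
      counts <- counts + shifted
    }
    total <- 2^n
    v2 <- round(2 * v)
    p_ge <- sum(counts[(v2 + 1):length(counts)]) / total
    p_le <- sum(counts[seq_len(v2 + 1)]) / total
    p <- min(1, 2 * min(p_ge, p_le))
    return(list(statistic = v, p_value = p, n = n, method = "exact"))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = v, p_value = p, n = n, method = "normal")
}

evolution_test_result <- function(model, diffs, predicted_sign, alpha, flag = NA) {
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 2) {
    return(structure(list(model = model, n_pairs = length(diffs),
                          statistic = NA_real_, p_value = 1,
                          median_diff = if (length(diffs)) stats::median(diffs)
                                        else NA_real_,
                          direction_supported = FALSE,
                          flag = "insufficient_pairs", alpha = alpha),
                     class = "evolution_test"))
  }
  wt <- suppressWarnings(wilcoxon_signed_rank(diffs))
  md <- stats::median(diffs)
  structure(list(model = model, n_pairs = wt$n, statistic = wt$statistic,
                 p_value = wt$p_value, median_diff = md,
                 direction_supported = wt$p_value < alpha &&
                   sign(md) == predicted_sign,
                 flag = flag, alpha = alpha),
            class = "evolution_test")
}

#' @export
print.evolution_test <- function(x, ...) {
  cat(sprintf("%s test: n = %d pairs, V = %s, p = %.4g, median diff = %.3g\n",
              x$model, x$n_pairs, format(x$statistic), x$p_value,
              x$median_diff))
  cat(if (isTRUE(x$direction_supported)) "direction supported\n"
      else "direction not supported\n")
  if (!is.na(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

# densities for one (region, class) pair in the direction concordant /
# discordant with the region's CNA direction
density_lookup <- function(tab, rid, cl, dir) {
  v <- tab$density[tab$region_id == rid & tab$gene_class == cl &
                     tab$direction == dir]
  if (length(v)) v[1] else NA_real_
}

usable_regions <- function(tab, klasses) {
  u <- unique(tab[tab$region_id != "outside",
                  c("region_id", "klass", "cna_direction")])
  u <- u[u$cna_direction %in% c("gain", "loss") & u$klass %in% klasses, ,
         drop = FALSE]
  u
}

conc_dir <- function(cna_direction) ifelse(cna_direction == "gain", "up", "down")
disc_dir <- function(cna_direction) ifelse(cna_direction == "gain", "down", "up")

#' Stage-concordance test between SGA direction and CNA direction
#'
#' Tests, per tumor stage, whether the density of expression changes matching
#' the copy-number direction (upregulated genes in gains, downregulated in
#' losses) exceeds the density of opposing changes across prototype regions.
#' For the in situ stage the common gene class is paired with prototypes
#' aberrant in DCIS; for the invasive stage the disparate class is paired
#' with prototypes aberrant in IDC. Complex-direction prototypes are
#' excluded. The paired differences (concordant - discordant density) are
#' tested with the exact signed-rank test; support requires a positive median
#' and `p < alpha`.
#'
#' @param density_table a `density_table`.
#' @param prototype_map the matching `prototype_map` (interface completeness;
#'   the class/direction annotation carried by the table is used).
#' @param stage `"dcis"` or `"idc"`.
#' @param alpha significance level.
#' @return an `evolution_test` result.
#' @export
stage_concordance_test <- function(density_table, prototype_map = NULL,
                                   stage = c("dcis", "idc"), alpha = 0.05) {
  stage <- match.arg(stage)
  cl <- if (stage == "dcis") "common" else "disparate"
  klasses <- if (stage == "dcis") {
    c("dcis_specific", "progressive", "regressive", "constant")
  } else {
    c("idc_specific", "progressive", "regressive", "constant")
  }
  u <- usable_regions(density_table, klasses)
  diffs <- vapply(seq_len(nrow(u)), function(i) {
    density_lookup(density_table, u$region_id[i], cl, conc_dir(u$cna_direction[i])) -
      density_lookup(density_table, u$region_id[i], cl, disc_dir(u$cna_direction[i]))
  }, numeric(1))
  evolution_test_result(paste0("stage_concordance_", stage), diffs, +1, alpha)
}

#' Forward evolution test
#'
#' Under a forward model, invasion-acquired (disparate) alterations reinforce
#' the direction of the in situ (common) alterations inside the late copy
#' number changes: in IDC-specific and progressive prototypes the concordant
#' disparate density should exceed the concordant common density. Tested with
#' the paired signed-rank test on per-prototype differences
#' (disparate - common concordant density).
#'
#' @inheritParams stage_concordance_test
#' @return an `evolution_test` result.
#' @export
forward_evolution_test <- function(density_table, prototype_map = NULL,
                                   alpha = 0.05) {
  u <- usable_regions(density_table, c("idc_specific", "progressive"))
  diffs <- vapply(seq_len(nrow(u)), function(i) {
    cd <- conc_dir(u$cna_direction[i])
    density_lookup(density_table, u$region_id[i], "disparate", cd) -
      density_lookup(density_table, u$region_id[i], "common", cd)
  }, numeric(1))
  evolution_test_result("forward", diffs, +1, alpha)
}

#' Backward evolution test
#'
#' Under a backward model, late copy-number changes are selected to erase
#' inherited alterations that oppose them: inside IDC-specific and
#' progressive prototypes, the density of common genes whose direction is
#' discordant with the CNA (downregulated genes in gains, upregulated in
#' losses) should fall below a reference density for the same gene class and
#' direction. The default reference is the genome-wide density outside all
#' prototype regions; `reference = "constant"` instead uses the mean
#' discordant density over constant prototypes.
#'
#' @inheritParams stage_concordance_test
#' @param reference `"outside"` or `"constant"`.
#' @return an `evolution_test` result.
#' @export
backward_evolution_test <- function(density_table, prototype_map = NULL,
                                    reference = c("outside", "constant"),
                                    alpha = 0.05) {
  reference <- match.arg(reference)
  u <- usable_regions(density_table, c("idc_specific", "progressive"))
  ref_density <- function(dir) {
    if (reference == "outside") {
      density_lookup(density_table, "outside", "common", dir)
    } else {
      uc <- usable_regions(density_table, "constant")
      uc <- uc[disc_dir(uc$cna_direction) == dir, , drop = FALSE]
      if (nrow(uc) == 0) return(NA_real_)
      mean(vapply(uc$region_id, density_lookup, numeric(1),
                  tab = density_table, cl = "common", dir = dir))
    }
  }
  diffs <- vapply(seq_len(nrow(u)), function(i) {
    dd <- disc_dir(u$cna_direction[i])
    density_lookup(density_table, u$region_id[i], "common", dd) - ref_density(dd)
  }, numeric(1))
  evolution_test_result("backward", diffs, -1, alpha)
}
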