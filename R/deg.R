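#' Per-study differential expression for one stage contrast
#'
#' Welch two-sample t-test on log2 intensities for every gene, comparing the
#' two stages of a contrast within a single study, with Benjamini-Hochberg
#' adjustment across all genes of the study. Genes whose pooled standard
#' error is zero (e.g. identical values in both groups) get `p = 1`.
#'
#' @param expr genes x samples matrix of log2 intensities.
#' @param samples sample sheet with columns `sample` and `stage`.
#' @param contrast length-2 character vector `c(case, control)`; the log2
#'   fold-change is `mean(case) - mean(control)`.
#' @return data frame with one row per gene: `gene`, `lfc`, `p`, `p_adj`.
#' @export
fit_study_deg <- function(expr, samples, contrast) {
  stopifnot(length(contrast) == 2)
  g1 <- samples$sample[samples$stage == contrast[1]]
  g2 <- samples$sample[samples$stage == contrast[2]]
  if (length(g1) < 2 || length(g2) < 2) {
    stop("contrast group absent or has fewer than 2 samples: ",
         paste(contrast, collapse = " vs "))
  }
  x1 <- expr[, g1, drop = FALSE]
  x2 <- expr[, g2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m1 - m2
  t <- lfc / sqrt(se2)
  # Welch-Satterthwaite degrees of freedom
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[se2 == 0] <- 1
  lfc[se2 == 0 & abs(lfc) < .Machine$double.eps] <- 0
  data.frame(gene = rownames(expr), lfc = lfc, p = p,
             p_adj = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Combine independent p-values by Fisher's method
#'
#' The statistic is `X = -2 * sum(log(p))`, referred to the upper tail of a
#' chi-square distribution with `2k` degrees of freedom. Zeros are clamped to
#' the smallest positive double before taking logs. With a single p-value the
#' combination is the identity.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return the combined p-value.
#' @export
combine_fisher <- function(p) {
  if (length(p) == 0) stop("empty p-value list")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  x <- -2 * sum(log(clamp_p(p)))
  stats::pchisq(x, df = 2 * length(p), lower.tail = FALSE)
}

#' Multi-study DEG meta-analysis for one contrast
#'
#' Runs [fit_study_deg()] in every study of a cohort, Fisher-combines the
#' per-study p-values across studies, averages log2 fold-changes, and keeps
#' genes with combined p below `alpha`. Genes with discordant per-study
#' fold-change signs are flagged (`discordant_flag`) but retained; the emitted
#' direction is the sign of the unweighted mean fold-change.
#'
#' By default raw per-study p-values enter the combination, which keeps the
#' null false-positive rate at the nominal level; `combine_on = "adjusted"`
#' instead combines the per-study BH-adjusted values (see the methods
#' vignette for the trade-off).
#'
#' @param cohort a `cohort` from [generate_cohort()], or any list of studies
#'   each holding `expr` and `samples`.
#' @param contrast one of `"DEG1"` (DCIS vs normal), `"DEG2"` (IDC vs normal),
#'   `"DEG3"` (IDC vs DCIS), `"DEG4"` (Met vs IDC), or an explicit
#'   `c(case, control)` stage pair.
#' @param alpha combined-p significance cutoff.
#' @param combine_on `"raw"` or `"adjusted"` per-study p-values.
#' @return object of class `deg_list`: data frame (`gene`, `mean_lfc`,
#'   `combined_p`, `direction`, `n_studies`, `discordant_flag`) with
#'   attributes `contrast` and `alpha`.
#' @export
run_deg_analysis <- function(cohort, contrast, alpha = 0.05,
                             combine_on = c("raw", "adjusted")) {
  combine_on <- match.arg(combine_on)
  pair <- deg_contrast_pair(contrast)
  studies <- if (inherits(cohort, "cohort")) cohort$studies else cohort
  fits <- lapply(studies, function(st) {
    if (!all(pair %in% st$samples$stage)) return(NULL)
    fit_study_deg(st$expr, st$samples, pair)
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0) stop("no study contains both stages of ", contrast[1])
  genes <- fits[[1]]$gene
  pcol <- if (combine_on == "raw") "p" else "p_adj"
  pmat <- vapply(fits, function(f) f[[pcol]][match(genes, f$gene)],
                 numeric(length(genes)))
  lmat <- vapply(fits, function(f) f$lfc[match(genes, f$gene)],
                 numeric(length(genes)))
  pmat <- matrix(pmat, nrow = length(genes))
  lmat <- matrix(lmat, nrow = length(genes))
  combined <- apply(pmat, 1, combine_fisher)
  mean_lfc <- rowMeans(lmat)
  discord <- apply(lmat, 1, function(v) {
    v <- v[v != 0]
    length(v) > 0 && length(unique(sign(v))) > 1
  })
  keep <- combined < alpha & mean_lfc != 0
  out <- data.frame(gene = genes[keep], mean_lfc = mean_lfc[keep],
                    combined_p = combined[keep],
                    direction = ifelse(mean_lfc[keep] > 0, "up", "down"),
                    n_studies = length(fits),
                    discordant_flag = discord[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$combined_p), ]
  rownames(out) <- NULL
  structure(out, contrast = if (length(contrast) == 1) contrast else
              paste(pair, collapse = "_vs_"),
            alpha = alpha, class = c("deg_list", "data.frame"))
}

deg_contrast_pair <- function(contrast) {
  if (length(contrast) == 2) return(contrast)
  switch(contrast,
         DEG1 = c("dcis", "normal"),
         DEG2 = c("idc", "normal"),
         DEG3 = c("idc", "dcis"),
         DEG4 = c("met", "idc"),
         stop("unknown contrast: ", contrast))
}

#' Partition an invasive-stage DEG list into common and disparate genes
#'
#' Common genes are those already altered in the in situ stage: members of all
#' three of DEG1 (DCIS vs normal), DEG2 (IDC vs normal) and DEG3 (IDC vs
#' DCIS). Disparate genes are the remaining DEG3 genes, acquired specifically
#' at invasion. The two sets are disjoint and cover DEG3. The overlap of the
#' disparate set with DEG2 is reported separately (`disparate_in_deg2`)
#' because published counts are compatible with either reading.
#'
#' @param deg1,deg2,deg3 `deg_list` objects (or data frames with a `gene`
#'   column) for the three contrasts.
#' @return list with `common`, `disparate` (character vectors) and
#'   `disparate_in_deg2` (count).
#' @export
partition_common_disparate <- function(deg1, deg2, deg3) {
  g1 <- deg1$gene; g2 <- deg2$gene; g3 <- deg3$gene
  common <- intersect(intersect(g1, g2), g3)
  disparate <- setdiff(g3, common)
  stopifnot(length(intersect(common, disparate)) == 0,
            setequal(union(common, disparate), g3))
  list(common = common, disparate = disparate,
       disparate_in_deg2 = length(intersect(disparate, g2)))
}

#' Write / read a DEG list as TSV
#'
#' @param deg a `deg_list`.
#' @param path file path.
#' @return the path (write) or a `deg_list` (read).
#' @export
write_deg_list <- function(deg, path) {
  write_tsv(as.data.frame(deg), path)
}

#' @rdname write_deg_list
#' @param alpha cutoff recorded on the read list.
#' @export
read_deg_list <- function(path, alpha = 0.05) {
  df <- read_tsv(path)
  structure(df, alpha = alpha, class = c("deg_list", "data.frame"))
}
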