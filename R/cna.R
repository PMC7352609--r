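#' Call aberrant regions from a population CNA frequency profile
#'
#' Keeps the intervals of a per-stage gain/loss frequency profile whose gain
#' or loss fraction strictly exceeds `threshold` (default 10%, the population
#' prevalence above which a region counts as copy-number altered). Adjacent
#' intervals with the same direction are merged, carrying length-weighted
#' fractions. An interval whose gain and loss fractions both exceed the
#' threshold in the same stage is labeled `"complex"`.
#'
#' @param profile data frame (`chrom`, `start`, `end`, `stage`,
#'   `gain_fraction`, `loss_fraction`), intervals 0-based half-open and
#'   non-overlapping within a stage.
#' @param threshold strict lower bound on the altered sample fraction.
#' @return data frame of calls (`chrom`, `start`, `end`, `stage`, `direction`,
#'   `gain_fraction`, `loss_fraction`).
#' @export
call_aberrant_regions <- function(profile, threshold = 0.10) {
  check_no_overlap(profile)
  out <- list()
  for (st in unique(profile$stage)) {
    p <- profile[profile$stage == st, , drop = FALSE]
    g <- p$gain_fraction > threshold
    l <- p$loss_fraction > threshold
    keep <- g | l
    if (!any(keep)) next
    p <- p[keep, , drop = FALSE]
    p$direction <- ifelse(g[keep] & l[keep], "complex",
                          ifelse(g[keep], "gain", "loss"))
    p <- p[order(p$chrom, p$start), , drop = FALSE]
    out[[st]] <- merge_adjacent(p, by = c("chrom", "stage", "direction"))
  }
  res <- do.call(rbind, out) %||% profile[0, ]
  rownames(res) <- NULL
  res
}

check_no_overlap <- function(profile) {
  for (st in unique(profile$stage %||% "all")) {
    p <- if ("stage" %in% names(profile)) {
      profile[profile$stage == st, , drop = FALSE]
    } else profile
    for (chr in unique(p$chrom)) {
      q <- p[p$chrom == chr, , drop = FALSE]
      q <- q[order(q$start), , drop = FALSE]
      if (nrow(q) > 1 && any(q$start[-1] < q$end[-nrow(q)])) {
        stop("overlapping input intervals on ", chr)
      }
    }
  }
  invisible(profile)
}

# merge touching intervals that agree on the grouping columns,
# length-weighting the fraction columns
merge_adjacent <- function(df, by) {
  if (nrow(df) < 2) return(df)
  key <- do.call(paste, df[by])
  runs <- list()
  i <- 1L
  while (i <= nrow(df)) {
    j <- i
    while (j < nrow(df) && key[j + 1] == key[i] &&
           df$chrom[j + 1] == df$chrom[i] && df$start[j + 1] == df$end[j]) {
      j <- j + 1L
    }
    seg <- df[i:j, , drop = FALSE]
    w <- seg$end - seg$start
    row <- seg[1, , drop = FALSE]
    row$end <- seg$end[j - i + 1]
    for (col in intersect(c("gain_fraction", "loss_fraction",
                            "dcis_fraction", "idc_fraction"), names(df))) {
      row[[col]] <- sum(seg[[col]] * w) / sum(w)
    }
    runs[[length(runs) + 1L]] <- row
    i <- j + 1L
  }
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  out
}

#' Classify called CNA regions into stage-transition prototypes
#'
#' Overlays the in situ (DCIS) and invasive (IDC) aberrant-region calls on a
#' common elementary grid and assigns every aberrant stretch, independently
#' for the gain and the loss direction, one of the transition classes:
#' \describe{
#'   \item{dcis_specific}{aberrant in DCIS only.}
#'   \item{idc_specific}{aberrant in IDC only.}
#'   \item{progressive}{aberrant in both, IDC fraction exceeding the DCIS
#'     fraction by more than `constancy_tolerance`.}
#'   \item{regressive}{aberrant in both, DCIS fraction exceeding IDC by more
#'     than the tolerance (a frequency decrease on invasion).}
#'   \item{constant}{aberrant in both with `|difference| <= tolerance`.}
#' }
#' Regions called `"complex"` (gain and loss both above threshold in one
#' stage) keep direction `"complex"`; they are classed `shared_complex` when
#' aberrant in both stages, otherwise by the stage they appear in. Adjacent
#' grid cells with identical direction and class are merged back, so the
#' classification is invariant to interval subdivision.
#'
#' @param dcis_calls,idc_calls outputs of [call_aberrant_regions()] for the
#'   two stages (each filtered to one stage).
#' @param constancy_tolerance width of the "constant" frequency band.
#' @return a `prototype_map`: data frame (`region_id`, `chrom`, `start`,
#'   `end`, `direction`, `klass`, `dcis_fraction`, `idc_fraction`) sorted by
#'   position, with attribute `constancy_tolerance`.
#' @export
classify_prototypes <- function(dcis_calls, idc_calls,
                                constancy_tolerance = 0.02) {
  chroms <- union(dcis_calls$chrom, idc_calls$chrom)
  rows <- list()
  for (chr in chroms) {
    d <- dcis_calls[dcis_calls$chrom == chr, , drop = FALSE]
    i <- idc_calls[idc_calls$chrom == chr, , drop = FALSE]
    bp <- sort(unique(c(d$start, d$end, i$start, i$end)))
    if (length(bp) < 2) next
    for (k in seq_len(length(bp) - 1)) {
      s <- bp[k]; e <- bp[k + 1]
      dr <- d[d$start <= s & d$end >= e, , drop = FALSE]
      ir <- i[i$start <= s & i$end >= e, , drop = FALSE]
      if (nrow(dr) == 0 && nrow(ir) == 0) next
      rows[[length(rows) + 1L]] <-
        classify_cell(chr, s, e,
                      if (nrow(dr)) dr[1, ] else NULL,
                      if (nrow(ir)) ir[1, ] else NULL,
                      constancy_tolerance)
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               direction = character(), klass = character(),
               dcis_fraction = numeric(), idc_fraction = numeric())
  if (nrow(out)) {
    out <- out[order(out$chrom, out$start, out$direction), , drop = FALSE]
    merged <- list()
    for (dir in unique(out$direction)) {
      sub <- out[out$direction == dir, , drop = FALSE]
      merged[[dir]] <- merge_adjacent(sub, by = c("chrom", "direction", "klass"))
    }
    out <- do.call(rbind, merged)
    out <- out[order(out$chrom, out$start, out$direction), , drop = FALSE]
  }
  out$region_id <- sprintf("R%03d", seq_len(nrow(out)))
  out <- out[, c("region_id", "chrom", "start", "end", "direction", "klass",
                 "dcis_fraction", "idc_fraction")]
  rownames(out) <- NULL
  structure(out, constancy_tolerance = constancy_tolerance,
            class = c("prototype_map", "data.frame"))
}

classify_cell <- function(chr, s, e, drow, irow, tol) {
  res <- list()
  cplx_d <- !is.null(drow) && drow$direction == "complex"
  cplx_i <- !is.null(irow) && irow$direction == "complex"
  if (cplx_d || cplx_i) {
    klass <- if (!is.null(drow) && !is.null(irow)) "shared_complex"
             else if (!is.null(drow)) "dcis_specific" else "idc_specific"
    return(data.frame(chrom = chr, start = s, end = e, direction = "complex",
                      klass = klass,
                      dcis_fraction = if (is.null(drow)) 0 else
                        max(drow$gain_fraction, drow$loss_fraction),
                      idc_fraction = if (is.null(irow)) 0 else
                        max(irow$gain_fraction, irow$loss_fraction),
                      stringsAsFactors = FALSE))
  }
  for (dir in c("gain", "loss")) {
    in_d <- !is.null(drow) && drow$direction == dir
    in_i <- !is.null(irow) && irow$direction == dir
    if (!in_d && !in_i) next
    fd <- if (in_d) drow[[paste0(dir, "_fraction")]] else 0
    fi <- if (in_i) irow[[paste0(dir, "_fraction")]] else 0
    klass <- if (in_d && !in_i) "dcis_specific"
             else if (!in_d && in_i) "idc_specific"
             else if (fi - fd > tol) "progressive"
             else if (fd - fi > tol) "regressive"
             else "constant"
    res[[dir]] <- data.frame(chrom = chr, start = s, end = e, direction = dir,
                             klass = klass, dcis_fraction = fd,
                             idc_fraction = fi, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Build a prototype map straight from a two-stage frequency profile
#'
#' Convenience wrapper: calls aberrant regions in the DCIS and IDC layers of
#' a frequency profile and classifies them into transition prototypes.
#'
#' @inheritParams call_aberrant_regions
#' @inheritParams classify_prototypes
#' @return a `prototype_map` (see [classify_prototypes()]).
#' @export
build_prototype_map <- function(profile, threshold = 0.10,
                                constancy_tolerance = 0.02) {
  calls <- call_aberrant_regions(profile, threshold)
  classify_prototypes(calls[calls$stage == "dcis", , drop = FALSE],
                      calls[calls$stage == "idc", , drop = FALSE],
                      constancy_tolerance)
}
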