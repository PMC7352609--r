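#' Assign genes to CNA prototype regions
#'
#' A gene is "within" a prototype region if its interval overlaps the region
#' by at least one base pair; a gene straddling several regions goes to the
#' one with the largest overlap (first by position on ties). Genes on
#' chromosomes absent from the map are outside. Overlap is computed with
#' GenomicRanges.
#'
#' @param genes data frame with `chrom`, `start`, `end`, `symbol`.
#' @param prototype_map a `prototype_map` (rows may repeat a genomic region
#'   for the gain and loss direction; assignment is by `region_id`).
#' @return named character vector mapping `symbol` to a `region_id` or
#'   `"outside"`.
#' @export
assign_genes_to_regions <- function(genes, prototype_map) {
  out <- stats::setNames(rep("outside", nrow(genes)), genes$symbol)
  regions <- prototype_map[!duplicated(prototype_map$region_id), , drop = FALSE]
  if (nrow(regions) == 0 || nrow(genes) == 0) return(out)
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start + 1, genes$end))
  gr_reg <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1, regions$end))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_reg)
  if (length(hits) == 0) return(out)
  ov <- IRanges::width(IRanges::pintersect(gr_genes[S4Vectors_from(hits)],
                                           gr_reg[S4Vectors_to(hits)]))
  df <- data.frame(gene = S4Vectors_from(hits), region = S4Vectors_to(hits),
                   ov = ov)
  df <- df[order(df$gene, -df$ov, df$region), , drop = FALSE]
  df <- df[!duplicated(df$gene), , drop = FALSE]
  out[df$gene] <- regions$region_id[df$region]
  out
}

# small shims so the igraph-style generics of S4Vectors stay in one place
S4Vectors_from <- function(h) S4Vectors::queryHits(h)
S4Vectors_to <- function(h) S4Vectors::subjectHits(h)

#' Compute the SGA density table
#'
#' Counts, for every prototype region, gene class (common / disparate) and
#' expression direction (up / down), the genes falling inside the region, and
#' converts counts to densities per megabase pair
#' (`density = count / (region length / 1e6)`). Rows with zero counts are
#' kept. One extra row block (`region_id = "outside"`) holds the densities of
#' genes outside every prototype region, over the genomic length not covered
#' by the map; it serves as the backward-test reference.
#'
#' Genes missing from the annotation are excluded with a warning.
#'
#' @param deg_sets named list; each element (`common`, `disparate`) is a data
#'   frame with columns `gene` and `direction` (`"up"`/`"down"`).
#' @param prototype_map a `prototype_map`.
#' @param annotation gene annotation (`chrom`, `start`, `end`, `symbol`).
#' @param genome_length_bp total genome length; defaults to the summed
#'   per-chromosome maxima over annotation and map.
#' @return a `density_table` data frame: `region_id`, `klass`,
#'   `cna_direction`, `gene_class`, `direction`, `count`, `length_mbp`,
#'   `density`.
#' @export
compute_density_table <- function(deg_sets, prototype_map, annotation,
                                  genome_length_bp = NULL) {
  if (is.null(genome_length_bp)) {
    ends <- c(tapply(annotation$end, annotation$chrom, max),
              if (nrow(prototype_map)) tapply(prototype_map$end,
                                              prototype_map$chrom, max))
    genome_length_bp <- sum(tapply(ends, names(ends), max))
  }
  regions <- prototype_map[!duplicated(prototype_map$region_id), , drop = FALSE]
  region_len <- stats::setNames(regions$end - regions$start, regions$region_id)
  if (any(region_len <= 0)) stop("zero-length prototype region")
  outside_len <- genome_length_bp - sum(region_len)
  rows <- list()
  for (cl in names(deg_sets)) {
    set <- deg_sets[[cl]]
    known <- set$gene %in% annotation$symbol
    if (any(!known)) {
      warning(sum(!known), " genes without coordinates excluded from class ", cl)
      set <- set[known, , drop = FALSE]
    }
    ann <- annotation[match(set$gene, annotation$symbol), , drop = FALSE]
    ann$symbol <- set$gene
    assign <- assign_genes_to_regions(ann, prototype_map)
    for (rid in c(regions$region_id, "outside")) {
      len <- if (rid == "outside") outside_len else region_len[[rid]]
      ridx <- which(regions$region_id == rid)
      for (dd in c("up", "down")) {
        cnt <- sum(assign[set$gene] == rid & set$direction == dd)
        rows[[length(rows) + 1L]] <- data.frame(
          region_id = rid,
          klass = if (rid == "outside") "outside" else
            paste(unique(prototype_map$klass[prototype_map$region_id == rid]),
                  collapse = "+"),
          cna_direction = if (rid == "outside") NA_character_ else
            region_primary_direction(prototype_map, rid),
          gene_class = cl, direction = dd, count = cnt,
          length_mbp = len / 1e6, density = cnt / (len / 1e6),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("density_table", "data.frame"))
}

# a region that carries both a gain and a loss record is direction-ambiguous
# and treated like complex by the directional tests
region_primary_direction <- function(map, rid) {
  d <- unique(map$direction[map$region_id == rid])
  if (length(d) == 1) d else "complex"
}

#' Split gene classes by CNA membership (CWC / COC / DWC / DOC)
#'
#' Partitions the common and disparate gene sets into the four groups used
#' for network construction: common within CNA regions (CWC), common outside
#' (COC), disparate within (DWC) and disparate outside (DOC).
#'
#' @param common,disparate character vectors of gene symbols.
#' @param prototype_map a `prototype_map`.
#' @param annotation gene annotation.
#' @return list with elements `cwc`, `coc`, `dwc`, `doc`.
#' @export
sga_partition <- function(common, disparate, prototype_map, annotation) {
  genes <- annotation[annotation$symbol %in% c(common, disparate), , drop = FALSE]
  assign <- assign_genes_to_regions(genes, prototype_map)
  within <- names(assign)[assign != "outside"]
  out <- list(cwc = intersect(common, within),
              coc = setdiff(common, within),
              dwc = intersect(disparate, within),
              doc = setdiff(disparate, within))
  stopifnot(length(out$cwc) + length(out$coc) == length(common),
            length(out$dwc) + length(out$doc) == length(disparate))
  out
}

#' Find SGA-enriched chromosomal stretches
#'
#' Scans gene midpoints per chromosome for maximal runs in which consecutive
#' genes are at most `max_gap_bp` apart (default 5 Mb) and which contain at
#' least `min_genes` genes. The emitted interval spans the first to the last
#' midpoint of the run; no run can be extended by a neighboring gene without
#' breaking the gap rule.
#'
#' @param genes data frame with `chrom`, `start`, `end` (and optionally
#'   `symbol`); positions are taken at interval midpoints.
#' @param max_gap_bp maximum allowed midpoint gap within a run.
#' @param min_genes minimum genes per emitted region.
#' @return data frame `chrom`, `start`, `end`, `n_genes`.
#' @export
find_sga_enriched_regions <- function(genes, max_gap_bp = 5e6, min_genes = 2) {
  rows <- list()
  for (chr in unique(genes$chrom)) {
    mid <- sort((genes$start[genes$chrom == chr] +
                   genes$end[genes$chrom == chr]) / 2)
    if (length(mid) == 0) next
    run_start <- 1L
    for (i in seq_along(mid)) {
      closes <- i == length(mid) || mid[i + 1] - mid[i] > max_gap_bp
      if (closes) {
        if (i - run_start + 1L >= min_genes) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chr, start = mid[run_start], end = mid[i],
            n_genes = i - run_start + 1L, stringsAsFactors = FALSE)
        }
        run_start <- i + 1L
      }
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_genes = integer())
  rownames(out) <- NULL
  out
}
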