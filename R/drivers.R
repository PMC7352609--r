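#' Filter mutation frequencies by stage-specific cutoffs
#'
#' Keeps, per stage, the genes whose mutation frequency reaches the stage's
#' cutoff (inclusive `>=`). The default cutoffs are 5% for the in situ stage,
#' 2.5% for the invasive stage (lower because the invasive population is more
#' heterogeneous) and 5% for metastasis.
#'
#' @param table data frame with `gene`, `stage`, `frequency`.
#' @param cutoffs named numeric vector of per-stage cutoffs in `(0, 1)`.
#' @return named list of per-stage gene vectors.
#' @export
filter_frequent_mutations <- function(table,
                                      cutoffs = c(dcis = 0.05, idc = 0.025,
                                                  met = 0.05)) {
  stopifnot(all(cutoffs > 0 & cutoffs < 1))
  unknown <- setdiff(unique(table$stage), names(cutoffs))
  if (length(unknown)) stop("unknown stage label: ", paste(unknown, collapse = ", "))
  lapply(stats::setNames(nm = names(cutoffs)), function(st) {
    sub <- table[table$stage == st, , drop = FALSE]
    sort(unique(sub$gene[sub$frequency >= cutoffs[[st]]]))
  })
}

#' Network-based driver-gene detection for one stage
#'
#' Adds the stage's frequently mutated genes to its DEG symbols, induces the
#' protein-interaction subnetwork on that gene list (edges kept when both
#' endpoints are on the list), takes the hub nodes with degree at or above
#' `degree_cutoff`, finds the pathways over-represented in the hub set
#' (hypergeometric, BH-adjusted p < `alpha`, universe = all genes on any
#' supplied pathway), and returns as drivers the hubs that sit on at least
#' one pathway that is both over-represented and significantly perturbed in
#' the stage's perturbation results.
#'
#' @param stage_deg character vector of the stage's DEG symbols.
#' @param stage_mutations character vector of frequently mutated genes.
#' @param ppin edge-list data frame (or igraph graph) of the interaction
#'   network.
#' @param spia_results `spia_result` for the stage (used for its
#'   `significant` pathways).
#' @param pathways list of `pathway_topology` objects.
#' @param degree_cutoff minimum hub degree.
#' @param alpha BH-adjusted enrichment cutoff.
#' @return list with `drivers`, `hubs`, `enriched_pathways`,
#'   `selected_pathways`, `degree` (of the induced network).
#' @export
detect_drivers <- function(stage_deg, stage_mutations, ppin, spia_results,
                           pathways, degree_cutoff = 20, alpha = 0.05) {
  gene_list <- union(stage_deg, stage_mutations)
  g <- if (igraph::is_igraph(ppin)) ppin else build_network(ppin)
  keep <- intersect(igraph::V(g)$name, gene_list)
  sub <- igraph::induced_subgraph(g, keep)
  if (igraph::vcount(sub) == 0) stop("empty induced network")
  deg <- igraph::degree(sub)
  hubs <- names(deg)[deg >= degree_cutoff]
  if (length(hubs) == 0) {
    return(list(drivers = character(), hubs = character(),
                enriched_pathways = character(),
                selected_pathways = character(), degree = deg))
  }
  universe <- unique(unlist(lapply(pathways, `[[`, "genes")))
  n_hub <- length(intersect(hubs, universe))
  enr_p <- vapply(pathways, function(pw) {
    p_nde(length(universe), length(pw$genes), n_hub,
          length(intersect(hubs, pw$genes)))
  }, numeric(1))
  nm <- vapply(pathways, `[[`, character(1), "name")
  enriched <- nm[stats::p.adjust(enr_p, "BH") < alpha]
  perturbed <- spia_results$pathway[spia_results$significant]
  selected <- intersect(enriched, perturbed)
  on_selected <- unique(unlist(lapply(pathways[nm %in% selected],
                                      `[[`, "genes")))
  list(drivers = sort(intersect(hubs, on_selected)), hubs = sort(hubs),
       enriched_pathways = enriched, selected_pathways = selected,
       degree = deg)
}

#' Compare driver-gene sets across stages
#'
#' Reports shared and unique counts for every pair of stages and a 2x2
#' association test (membership in set A x membership in set B over the union
#' of all drivers), using the chi-square test when all expected cells are at
#' least 5 and Fisher's exact test otherwise.
#'
#' @param sets named list of character vectors (one per stage).
#' @return data frame with one row per stage pair: `stage_a`, `stage_b`,
#'   `shared`, `unique_a`, `unique_b`, `p_value`, `method`.
#' @export
compare_driver_sets <- function(sets) {
  stopifnot(length(sets) >= 2)
  universe <- unique(unlist(sets))
  pairs <- utils::combn(names(sets), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- sets[[pairs[1, k]]]; b <- sets[[pairs[2, k]]]
    tab <- table(factor(universe %in% a, levels = c(TRUE, FALSE)),
                 factor(universe %in% b, levels = c(TRUE, FALSE)))
    res <- if (any(tab == 0) ||
               !all(outer(rowSums(tab), colSums(tab)) / sum(tab) >= 5)) {
      list(p = stats::fisher.test(tab)$p.value, m = "fisher_exact")
    } else {
      list(p = stats::chisq.test(tab, correct = FALSE)$p.value,
           m = "chi-square")
    }
    data.frame(stage_a = pairs[1, k], stage_b = pairs[2, k],
               shared = length(intersect(a, b)),
               unique_a = length(setdiff(a, b)),
               unique_b = length(setdiff(b, a)),
               p_value = res$p, method = res$m, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the binary mutation character matrix
#'
#' Encodes per-stage mutated gene sets as a taxa x genes 0/1 matrix for
#' parsimony analysis (1 = gene mutated in the stage). An all-zero outgroup
#' taxon (default `"normal"`) is prepended for rooting unless disabled.
#'
#' @param stage_gene_sets named list of mutated-gene vectors per stage.
#' @param genes optional explicit gene (character) universe; defaults to the
#'   union of all sets.
#' @param add_outgroup prepend the all-zero outgroup taxon.
#' @param outgroup_name its name.
#' @return integer 0/1 matrix, taxa in rows.
#' @export
binary_character_matrix <- function(stage_gene_sets, genes = NULL,
                                    add_outgroup = TRUE,
                                    outgroup_name = "normal") {
  if (is.null(genes)) genes <- sort(unique(unlist(stage_gene_sets)))
  m <- do.call(rbind, lapply(stage_gene_sets,
                             function(s) as.integer(genes %in% s)))
  dimnames(m) <- list(names(stage_gene_sets), genes)
  if (add_outgroup) {
    m <- rbind(matrix(0L, 1, ncol(m), dimnames = list(outgroup_name, genes)), m)
  }
  storage.mode(m) <- "integer"
  if (anyDuplicated(rownames(m))) stop("taxa names must be unique")
  m
}

#' Fitch parsimony length of a tree for a binary character matrix
#'
#' Sums, over characters, the minimum number of 0/1 state changes required on
#' the tree (small parsimony, Fitch's bottom-up pass; multifurcations are
#' folded pairwise). The score does not depend on the rooting.
#'
#' @param tree an `ape::phylo` tree whose tip labels equal the matrix taxa.
#' @param matrix taxa x characters 0/1 matrix.
#' @return total parsimony length (integer).
#' @export
fitch_score <- function(tree, matrix) {
  if (!setequal(tree$tip.label, rownames(matrix))) {
    stop("tree leaves and matrix taxa differ")
  }
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tipstate <- matrix[tree$tip.label, , drop = FALSE]
  total <- 0L
  for (ch in seq_len(ncol(matrix))) {
    sets <- integer(nnode)
    sets[seq_len(ntip)] <- ifelse(tipstate[, ch] == 0L, 1L, 2L)  # bit sets
    changes <- 0L
    for (k in seq_along(tree$edge[, 1])) {
      parent <- tree$edge[k, 1]; child <- tree$edge[k, 2]
      if (sets[parent] == 0L) {
        sets[parent] <- sets[child]
      } else {
        inter <- bitwAnd(sets[parent], sets[child])
        if (inter == 0L) {
          sets[parent] <- bitwOr(sets[parent], sets[child])
          changes <- changes + 1L
        } else {
          sets[parent] <- inter
        }
      }
    }
    total <- total + changes
  }
  total
}

#' Exhaustive maximum-parsimony tree search
#'
#' Scores every unrooted binary topology over the matrix taxa (enumerated
#' with `phangorn::allTrees`; at most 8 taxa) with [fitch_score()] and
#' returns all minimum-length trees, ordered deterministically by their
#' newick string.
#'
#' @param matrix taxa x characters 0/1 matrix.
#' @return list with `trees` (`multiPhylo`), `length` (minimal score) and
#'   `scores` (all enumerated scores).
#' @export
best_parsimony_tree <- function(matrix) {
  taxa <- rownames(matrix)
  n <- length(taxa)
  if (n > 8) stop("exhaustive search limited to 8 taxa")
  if (n < 3) stop("need at least 3 taxa")
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  # index with [[ so compressed multiPhylo tip labels are restored
  scores <- vapply(seq_along(trees),
                   function(i) fitch_score(trees[[i]], matrix), numeric(1))
  best <- which(scores == min(scores))
  nwk <- vapply(best, function(i) ape::write.tree(trees[[i]]), character(1))
  best <- best[order(nwk)]
  out <- lapply(best, function(i) trees[[i]])
  class(out) <- "multiPhylo"
  list(trees = out, length = min(scores), scores = scores)
}
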