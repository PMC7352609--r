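#' Default end-to-end pipeline configuration
#'
#' Builds the simulated study conditions used by [run_all()]: a three-study
#' cohort (20 samples per group, plus 10 metastatic samples per study) with
#' planted common/disparate/carried-over genes, a genome-wide prototype plan
#' covering every transition class, a mutation plan exceeding the stage
#' cutoffs for a small driver-ready gene set, and all analysis thresholds at
#' their published defaults (DEG alpha 0.05, CNA threshold 0.10, 5 Mb SGA
#' gap, homogeneity 0.75 at degree >= 4, mutation cutoffs 5%/2.5%/5%, driver
#' degree 20).
#'
#' @param seed master integer seed.
#' @param out_dir optional output directory for stage TSV/JSON artifacts.
#' @return a named list, the `config` argument of [run_all()].
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = NULL) {
  plan <- default_prototype_plan()
  hub_genes <- sprintf("G%04d", 1:6)
  mut <- rbind(
    data.frame(gene = hub_genes, stage = "dcis", frequency = 0.08),
    data.frame(gene = hub_genes, stage = "idc", frequency = 0.06),
    data.frame(gene = hub_genes, stage = "met", frequency = 0.08),
    data.frame(gene = sprintf("G%04d", 101:110), stage = "dcis", frequency = 0.06),
    data.frame(gene = sprintf("G%04d", 101:125), stage = "idc", frequency = 0.03),
    data.frame(gene = sprintf("G%04d", c(101:105, 131:140)), stage = "met",
               frequency = 0.07))
  list(seed = as.integer(seed), out_dir = out_dir,
       spec = cohort_spec(n_genes = 600, n_chromosomes = 5,
                          chromosome_length_bp = 1e8,
                          studies = rep(list(c(normal = 20, dcis = 20,
                                               idc = 20, met = 10)), 3),
                          effect_size_lfc = 1.5, noise_sd = 1,
                          n_common = 60, n_disparate = 60, n_dcis_only = 10,
                          prototype_plan = plan, mutation_plan = mut,
                          seed = seed),
       alpha = 0.05, cna_threshold = 0.10, constancy_tolerance = 0.02,
       max_gap_bp = 5e6, homogeneity_fraction = 0.75, min_degree = 4,
       mutation_cutoffs = c(dcis = 0.05, idc = 0.025, met = 0.05),
       driver_degree = 20, n_boot = 500,
       n_pathways = 12, genes_per_pathway = 20)
}

#' Genome-wide default prototype plan
#'
#' Twenty-four 10 Mb intervals spread over four chromosomes covering every
#' transition class in both copy-number directions.
#'
#' @return data frame usable as `prototype_plan` in [cohort_spec()].
#' @export
default_prototype_plan <- function() {
  classes <- list(
    c("gain", 0.00, 0.20), c("loss", 0.00, 0.20),   # idc_specific
    c("gain", 0.12, 0.25), c("loss", 0.12, 0.25),   # progressive
    c("gain", 0.15, 0.15), c("loss", 0.15, 0.15),   # constant
    c("gain", 0.15, 0.02), c("loss", 0.15, 0.02),   # dcis_specific
    c("gain", 0.25, 0.12), c("loss", 0.25, 0.12),   # regressive
    c("gain", 0.18, 0.30), c("loss", 0.18, 0.30))   # progressive
  rows <- list()
  k <- 0
  for (chr in paste0("chr", 1:4)) {
    for (i in 1:6) {
      k <- k + 1
      cl <- classes[[((k - 1) %% length(classes)) + 1]]
      rows[[k]] <- data.frame(chrom = chr, start = (2 * i - 2) * 1e7,
                              end = (2 * i - 1) * 1e7, direction = cl[1],
                              dcis_freq = as.numeric(cl[2]),
                              idc_freq = as.numeric(cl[3]),
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

validate_pipeline_config <- function(config) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  chk(inherits(config$spec, "cohort_spec"), "spec must be a cohort_spec")
  chk(config$alpha > 0 && config$alpha < 1, "alpha outside (0,1)")
  chk(config$cna_threshold >= 0 && config$cna_threshold < 1,
      "cna_threshold outside [0,1)")
  chk(config$constancy_tolerance >= 0, "negative constancy_tolerance")
  chk(config$max_gap_bp > 0, "max_gap_bp must be positive")
  chk(config$homogeneity_fraction >= 0 && config$homogeneity_fraction <= 1,
      "homogeneity_fraction outside [0,1]")
  chk(config$min_degree >= 1, "min_degree must be >= 1")
  chk(all(config$mutation_cutoffs > 0 & config$mutation_cutoffs < 1),
      "mutation cutoffs outside (0,1)")
  chk(config$driver_degree >= 1, "driver_degree must be >= 1")
  chk(config$n_boot >= 200, "n_boot must be >= 200")
  invisible(config)
}

#' Run the full evolution-analysis pipeline
#'
#' Orchestrates every stage on a simulated cohort: cohort generation, DEG
#' meta-analysis for the four contrasts, common/disparate partition, CNA
#' prototype map, SGA density integration and enriched regions, the three
#' directional evolution tests, pathway perturbation with fine-tuning and the
#' backward-functional analysis, hub-homogeneity comparison, per-stage driver
#' detection and driver-set comparison, binary-character parsimony phylogeny,
#' and iterative feature selection with survival concordance. Reruns with an
#' identical config (same seed) are byte-identical.
#'
#' @param config a config list from [default_pipeline_config()] (or a path to
#'   a YAML file holding the scalar fields, merged over the defaults).
#' @return nested result list (class `pipeline_result`) with a `summary`
#'   element holding the headline verdicts; if `config$out_dir` is set, stage
#'   tables and `summary.json` are written there.
#' @export
run_all <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- load_pipeline_config(config)
  validate_pipeline_config(config)
  seed <- config$seed
  cohort <- generate_cohort(config$spec)

  deg <- lapply(stats::setNames(nm = c("DEG1", "DEG2", "DEG3", "DEG4")),
                function(k) run_deg_analysis(cohort, k, alpha = config$alpha))
  part <- partition_common_disparate(deg$DEG1, deg$DEG2, deg$DEG3)

  proto <- build_prototype_map(cohort$cna, threshold = config$cna_threshold,
                               constancy_tolerance = config$constancy_tolerance)
  deg_sets <- list(
    common = deg$DEG3[deg$DEG3$gene %in% part$common, c("gene", "direction")],
    disparate = deg$DEG3[deg$DEG3$gene %in% part$disparate,
                         c("gene", "direction")])
  dens <- compute_density_table(deg_sets, proto, cohort$genes)
  partition4 <- sga_partition(part$common, part$disparate, proto, cohort$genes)
  within_genes <- cohort$genes[cohort$genes$symbol %in%
                                 c(partition4$cwc, partition4$dwc), ]
  enriched <- find_sga_enriched_regions(within_genes,
                                        max_gap_bp = config$max_gap_bp)

  evo <- list(
    stage_concordance_dcis = stage_concordance_test(dens, proto, "dcis",
                                                    config$alpha),
    stage_concordance_idc = stage_concordance_test(dens, proto, "idc",
                                                   config$alpha),
    forward = forward_evolution_test(dens, proto, config$alpha),
    backward = backward_evolution_test(dens, proto, alpha = config$alpha))

  pathways <- cohort_pathways(cohort, n_pathways = config$n_pathways,
                              genes_per_pathway = config$genes_per_pathway,
                              seed = split_seed(seed, 21L))
  spia_common <- run_spia(deg$DEG3[deg$DEG3$gene %in% part$common, ],
                          pathways, alpha = config$alpha,
                          n_boot = config$n_boot, seed = split_seed(seed, 22L))
  spia_all <- run_spia(deg$DEG3, pathways, alpha = config$alpha,
                       n_boot = config$n_boot, seed = split_seed(seed, 23L))
  finetune <- fine_tuning_comparison(spia_common, spia_all, config$alpha)

  reverted_pool <- cohort$genes$symbol[cohort$genes$planted_class == "dcis_only"]
  reverted <- deg$DEG1[deg$DEG1$gene %in%
                         setdiff(reverted_pool, deg$DEG3$gene), ]
  backward_fun <- if (nrow(reverted) > 0) {
    backward_functional_test(deg$DEG3, reverted[, c("gene", "mean_lfc")],
                             pathways, alpha = config$alpha,
                             n_boot = config$n_boot,
                             seed = split_seed(seed, 24L))
  } else NULL

  net_common <- generate_ppin(300, 20, 6, hub_homogeneity_fraction = 0.9,
                              background_edge_prob = 0.002,
                              seed = split_seed(seed, 25L))
  net_all <- generate_ppin(300, 20, 6, hub_homogeneity_fraction = 0.5,
                           background_edge_prob = 0.002,
                           seed = split_seed(seed, 26L))
  hom_common <- classify_hub_homogeneity(
    build_network(net_common$edges, net_common$directions),
    min_degree = config$min_degree, fraction = config$homogeneity_fraction)
  hom_all <- classify_hub_homogeneity(
    build_network(net_all$edges, net_all$directions),
    min_degree = config$min_degree, fraction = config$homogeneity_fraction)
  homogeneity <- compare_homogeneity(hom_common$counts, hom_all$counts)

  mut_sets <- filter_frequent_mutations(cohort$mutations,
                                        config$mutation_cutoffs)
  ppin_genes <- cohort_ppin(cohort, n_hubs = 6,
                            hub_degree = config$driver_degree + 5,
                            seed = split_seed(seed, 27L))
  stage_degs <- list(dcis = deg$DEG1$gene,
                     idc = union(deg$DEG2$gene, deg$DEG3$gene),
                     met = union(deg$DEG2$gene, deg$DEG4$gene))
  stage_spia <- list(dcis = run_spia(deg$DEG1, pathways, alpha = config$alpha,
                                     n_boot = config$n_boot,
                                     seed = split_seed(seed, 28L)),
                     idc = spia_all,
                     met = run_spia(deg$DEG2, pathways, alpha = config$alpha,
                                    n_boot = config$n_boot,
                                    seed = split_seed(seed, 29L)))
  drivers <- lapply(stats::setNames(nm = names(mut_sets)), function(st) {
    tryCatch(detect_drivers(stage_degs[[st]], mut_sets[[st]], ppin_genes,
                            stage_spia[[st]], pathways,
                            degree_cutoff = config$driver_degree,
                            alpha = config$alpha)$drivers,
             error = function(e) character())
  })
  driver_cmp <- tryCatch(compare_driver_sets(drivers), error = function(e) NULL)

  charmat <- binary_character_matrix(mut_sets)
  phylo <- best_parsimony_tree(charmat)

  st1 <- cohort$studies[[1]]
  keep <- st1$samples$stage %in% c("dcis", "idc")
  fr <- iterative_feature_selection(st1$expr[, keep],
                                    st1$samples$stage[keep],
                                    classifier = "weighted_voting",
                                    seed = split_seed(seed, 30L))
  surv <- cohort$survival
  beta <- marginal_cox_coefficients(surv$expr, surv$records)
  ranked_genes <- names(sort(-abs(beta)))
  sets <- lapply(seq(10, 100, 10), function(k) ranked_genes[seq_len(k)])
  sizecor <- signature_size_correlation(sets, surv$expr, surv$records,
                                        seed = split_seed(seed, 31L))

  summary <- list(
    n_deg = vapply(deg, nrow, integer(1)),
    n_common = length(part$common), n_disparate = length(part$disparate),
    n_prototypes = nrow(proto),
    stage_concordance_dcis_supported = evo$stage_concordance_dcis$direction_supported,
    stage_concordance_idc_supported = evo$stage_concordance_idc$direction_supported,
    forward_supported = evo$forward$direction_supported,
    backward_supported = evo$backward$direction_supported,
    fine_tuning_supported = finetune$supported,
    backward_functional_supported = if (is.null(backward_fun)) NA
                                    else backward_fun$supported,
    homogeneity_p = homogeneity$p_value,
    n_drivers = lengths(drivers),
    parsimony_length = phylo$length,
    tree_newick = ape::write.tree(phylo$trees[[1]]),
    round1_auc = fr$auc[1],
    size_ci_correlation = sizecor$cor$r[sizecor$cor$measure == "ranked_ci"])

  res <- structure(list(cohort = cohort, deg = deg, partition = part,
                        prototype_map = proto, density_table = dens,
                        sga_partition = partition4,
                        enriched_regions = enriched, evolution = evo,
                        spia = list(common = spia_common, all = spia_all),
                        fine_tuning = finetune,
                        backward_functional = backward_fun,
                        homogeneity = list(common = hom_common, all = hom_all,
                                           comparison = homogeneity),
                        mutation_sets = mut_sets, drivers = drivers,
                        driver_comparison = driver_cmp, phylogeny = phylo,
                        feature_rounds = fr, size_correlation = sizecor,
                        summary = summary, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

# pathways over cohort gene symbols, planted directionally: each pathway is
# an all-activation cascade populated with common and disparate genes of one
# expression direction (so late alterations reinforce the early
# perturbation) plus carried-over genes of the opposite direction (so the
# backward-functional analysis has genes that damp the cascade)
cohort_pathways <- function(cohort, n_pathways = 12, genes_per_pathway = 20,
                            seed = 1L) {
  set.seed(split_seed(seed, 32L))
  ann <- cohort$genes
  hubish <- sprintf("G%04d", 1:6)
  pool <- function(cl, d) {
    setdiff(ann$symbol[ann$planted_class == cl & ann$planted_direction == d],
            hubish)
  }
  nulls <- setdiff(ann$symbol[ann$planted_class == "null"], hubish)
  pick <- function(p, k) sample(p, min(k, length(p)))
  lapply(seq_len(n_pathways), function(i) {
    d <- if (i %% 2 == 1) 1L else -1L
    planted <- c(sample(pick(pool("common", d), 6)),
                 sample(pick(pool("disparate", d), 4)),
                 sample(pick(pool("dcis_only", -d), 2)))
    planted <- planted[!duplicated(planted)]
    hub_part <- if (i %% 3 == 1) setdiff(hubish, planted) else character()
    filler <- sample(setdiff(nulls, c(planted, hub_part)))
    # planted (differentially expressed) genes sit upstream of the cascade —
    # the early-stage common genes topmost — so their perturbation propagates
    # through the whole pathway; hub genes ride along downstream
    ord <- c(planted, hub_part,
             filler[seq_len(max(0, genes_per_pathway - length(planted) -
                                  length(hub_part)))])
    edges <- data.frame(source = ord[-length(ord)], target = ord[-1], sign = 1,
                        stringsAsFactors = FALSE)
    pathway_topology(sprintf("pathway%02d", i), edges, ord)
  })
}

# interaction network over cohort genes: the first genes act as hubs wired
# to planted common genes (which populate every stage's DEG list), so hub
# degree survives induction on stage gene lists
cohort_ppin <- function(cohort, n_hubs = 6, hub_degree = 25, seed = 1L) {
  set.seed(split_seed(seed, 34L))
  ann <- cohort$genes
  hubs <- sprintf("G%04d", seq_len(n_hubs))
  commons <- setdiff(ann$symbol[ann$planted_class == "common"], hubs)
  edges <- do.call(rbind, lapply(hubs, function(h) {
    data.frame(node_a = h,
               node_b = sample(commons, min(hub_degree, length(commons))),
               stringsAsFactors = FALSE)
  }))
  others <- setdiff(ann$symbol, hubs)
  bg <- data.frame(node_a = sample(others, 200, replace = TRUE),
                   node_b = sample(others, 200, replace = TRUE),
                   stringsAsFactors = FALSE)
  rbind(edges, bg[bg$node_a != bg$node_b, ])
}

load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  config <- default_pipeline_config(seed = raw$seed %||% 1L,
                                    out_dir = raw$out_dir)
  scalar <- intersect(names(raw), c("alpha", "cna_threshold",
                                    "constancy_tolerance", "max_gap_bp",
                                    "homogeneity_fraction", "min_degree",
                                    "driver_degree", "n_boot", "n_pathways",
                                    "genes_per_pathway"))
  config[scalar] <- raw[scalar]
  if (!is.null(raw$mutation_cutoffs)) {
    config$mutation_cutoffs <- unlist(raw$mutation_cutoffs)
  }
  config
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in names(res$deg)) {
    write_deg_list(res$deg[[k]], file.path(dir, paste0(tolower(k), ".tsv")))
  }
  write_tsv(as.data.frame(res$prototype_map), file.path(dir, "prototypes.tsv"))
  write_tsv(as.data.frame(res$density_table), file.path(dir, "densities.tsv"))
  write_tsv(res$enriched_regions, file.path(dir, "enriched_regions.tsv"))
  write_tsv(as.data.frame(res$spia$all), file.path(dir, "spia_all.tsv"))
  writeLines(res$summary$tree_newick, file.path(dir, "stages.nwk"))
  jsonlite::write_json(res$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("tumor evolution pipeline result\n")
  cat(sprintf("  DEG lists: %s\n",
              paste(names(s$n_deg), s$n_deg, sep = "=", collapse = ", ")))
  cat(sprintf("  common/disparate: %d / %d; prototypes: %d\n",
              s$n_common, s$n_disparate, s$n_prototypes))
  cat(sprintf("  concordance (DCIS/IDC): %s / %s; forward: %s; backward: %s\n",
              s$stage_concordance_dcis_supported,
              s$stage_concordance_idc_supported,
              s$forward_supported, s$backward_supported))
  cat(sprintf("  fine-tuning: %s; backward-functional: %s\n",
              s$fine_tuning_supported, s$backward_functional_supported))
  cat(sprintf("  parsimony tree (%d steps): %s\n", s$parsimony_length,
              s$tree_newick))
  invisible(x)
}
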