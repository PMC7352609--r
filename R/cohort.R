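#' Specify a synthetic multi-stage tumor cohort
#'
#' Builds and validates the parameter object consumed by [generate_cohort()].
#' The generator emulates the population-level inputs of a staged breast-tumor
#' evolution analysis: several independent two-group expression studies
#' (normal / in situ / invasive / metastatic samples on a log2 microarray-like
#' scale), per-stage genome-wide copy-number gain/loss frequency profiles,
#' per-stage mutation frequency tables, and survival records driven by a known
#' risk score. Signal is *planted*: each gene carries a class that fixes in
#' which contrasts it is differentially expressed.
#'
#' Planted classes and their stage effects (direction `d` is +1/-1, magnitude
#' `effect_size_lfc`):
#' \describe{
#'   \item{common}{shifted `d*lfc` in DCIS and `2*d*lfc` in IDC/Met — significant,
#'     with one direction, in the DCIS-vs-normal, IDC-vs-normal and IDC-vs-DCIS
#'     contrasts (the "common" genes that originate in the in situ stage and
#'     strengthen on invasion).}
#'   \item{disparate}{shifted `d*lfc` in IDC/Met only — significant only in the
#'     IDC contrasts (acquired at invasion).}
#'   \item{dcis_only}{shifted `d*lfc` in DCIS and `0.95*d*lfc` in IDC/Met —
#'     genes whose change is acquired in situ and then barely moves, so they
#'     appear in the DCIS contrasts but never in the IDC-vs-DCIS list; the
#'     backward-functional analysis re-enters them with their in situ
#'     fold-change.}
#'   \item{null}{no shift anywhere.}
#' }
#'
#' @param n_genes total number of genes.
#' @param n_chromosomes number of chromosomes the genes are spread over.
#' @param chromosome_length_bp length of every chromosome (bp).
#' @param studies list of per-study group sizes, each a named vector with
#'   elements `normal`, `dcis`, `idc` and optionally `met`.
#' @param effect_size_lfc planted log2 fold-change magnitude (>= 0; 0 gives a
#'   pure null cohort).
#' @param noise_sd residual standard deviation of log2 intensities.
#' @param n_common,n_disparate,n_dcis_only numbers of planted genes per class.
#' @param prototype_plan data frame (`chrom`, `start`, `end`, `direction`,
#'   `dcis_freq`, `idc_freq`) of planted copy-number frequency intervals;
#'   `direction` is `"gain"` or `"loss"`. Intervals are 0-based half-open and
#'   must not overlap within a chromosome.
#' @param mutation_plan data frame (`gene`, `stage`, `frequency`) of planted
#'   mutation frequencies; unlisted pairs are zero.
#' @param placement_weights named weights steering where planted genes land
#'   relative to the prototype plan (`common_conc`, `common_disc`,
#'   `disparate_conc`, `disparate_disc`). A "conc" weight applies to gene
#'   slots inside a planned interval whose copy-number direction matches the
#'   gene's expression direction (gain/up, loss/down) — early (DCIS-aberrant)
#'   intervals for common genes, late (IDC-acquired or progressing) intervals
#'   for disparate genes; a "disc" weight applies to slots inside any planned
#'   interval of the opposite direction; all other slots have weight 1.
#'   The defaults plant stage concordance, a forward-style excess of
#'   disparate over common density in late CNAs, and a backward-style
#'   depletion of discordant common genes inside late CNAs. Set all weights
#'   to 1 for uniform placement.
#' @param n_survival_subjects,n_survival_genes size of the survival component.
#' @param survival_effect_sd standard deviation of the small per-gene effects
#'   that sum to the survival risk score.
#' @param seed master integer seed; fixes all randomness.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_genes = 1000,
                        n_chromosomes = 5,
                        chromosome_length_bp = 1e8,
                        studies = list(c(normal = 20, dcis = 20, idc = 20),
                                       c(normal = 20, dcis = 20, idc = 20),
                                       c(normal = 20, dcis = 20, idc = 20)),
                        effect_size_lfc = 1.5,
                        noise_sd = 1,
                        n_common = 60,
                        n_disparate = 60,
                        n_dcis_only = 10,
                        prototype_plan = NULL,
                        mutation_plan = NULL,
                        placement_weights = c(common_conc = 8,
                                              common_disc = 0.05,
                                              disparate_conc = 16,
                                              disparate_disc = 0.25),
                        n_survival_subjects = 200,
                        n_survival_genes = 200,
                        survival_effect_sd = 0.08,
                        seed = 1L) {
  stopifnot(n_genes >= 1, n_chromosomes >= 1, chromosome_length_bp > 0,
            effect_size_lfc >= 0, noise_sd > 0,
            n_common + n_disparate + n_dcis_only <= n_genes)
  for (s in studies) {
    if (!all(c("normal", "dcis", "idc") %in% names(s))) {
      stop("each study needs 'normal', 'dcis' and 'idc' group sizes")
    }
  }
  if (!is.null(prototype_plan)) {
    validate_prototype_plan(prototype_plan)
  }
  if (!is.null(mutation_plan)) {
    if (any(mutation_plan$frequency < 0 | mutation_plan$frequency > 1)) {
      stop("mutation frequencies must lie in [0, 1]")
    }
  }
  stopifnot(all(placement_weights > 0),
            all(c("common_conc", "common_disc", "disparate_conc",
                  "disparate_disc") %in% names(placement_weights)))
  structure(list(n_genes = n_genes, n_chromosomes = n_chromosomes,
                 chromosome_length_bp = chromosome_length_bp, studies = studies,
                 effect_size_lfc = effect_size_lfc, noise_sd = noise_sd,
                 n_common = n_common, n_disparate = n_disparate,
                 n_dcis_only = n_dcis_only,
                 prototype_plan = prototype_plan, mutation_plan = mutation_plan,
                 placement_weights = placement_weights,
                 n_survival_subjects = n_survival_subjects,
                 n_survival_genes = n_survival_genes,
                 survival_effect_sd = survival_effect_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

validate_prototype_plan <- function(plan) {
  req <- c("chrom", "start", "end", "direction", "dcis_freq", "idc_freq")
  if (!all(req %in% names(plan))) {
    stop("prototype_plan needs columns: ", paste(req, collapse = ", "))
  }
  if (any(plan$start >= plan$end)) stop("prototype intervals need start < end")
  fr <- c(plan$dcis_freq, plan$idc_freq)
  if (any(fr < 0 | fr > 1)) stop("prototype frequencies must lie in [0, 1]")
  for (chr in unique(plan$chrom)) {
    p <- plan[plan$chrom == chr, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    if (nrow(p) > 1 && any(p$start[-1] < p$end[-nrow(p)])) {
      stop("overlapping prototype intervals on ", chr)
    }
  }
  invisible(plan)
}

#' Generate a synthetic cohort bundle
#'
#' Draws every pipeline input from a [cohort_spec()]: BED-style gene
#' annotation, one expression matrix + sample sheet per study, per-stage CNA
#' gain/loss frequency profiles (the population-frequency representation:
#' fractions are emitted directly from the plan, never re-estimated from
#' per-sample segments), a mutation frequency table, and survival records with
#' exponential event times whose hazard is proportional to `exp(risk score)`
#' and uniform censoring.
#'
#' Identical seeds give byte-identical bundles.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `cohort` with elements `genes`, `studies`
#'   (each `list(expr, samples)`), `cna`, `mutations`, `survival`, `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  genes <- make_gene_annotation(spec)
  studies <- make_expression_studies(spec, genes)
  cna <- make_cna_profile(spec)
  mutations <- make_mutation_table(spec)
  surv <- make_survival_component(spec)
  structure(list(genes = genes, studies = studies, cna = cna,
                 mutations = mutations, survival = surv, spec = spec),
            class = "cohort")
}

make_gene_annotation <- function(spec) {
  set.seed(split_seed(spec$seed, 1L))
  n <- spec$n_genes
  chrom_idx <- rep(seq_len(spec$n_chromosomes), length.out = n)
  # evenly spaced, non-overlapping loci per chromosome
  start <- integer(n); end <- integer(n)
  for (c in seq_len(spec$n_chromosomes)) {
    idx <- which(chrom_idx == c)
    m <- length(idx)
    spacing <- floor(spec$chromosome_length_bp / max(1, m))
    glen <- max(1L, min(50000L, floor(spacing / 2)))
    start[idx] <- as.integer((seq_len(m) - 1L) * spacing)
    end[idx] <- start[idx] + glen
  }
  chrom <- paste0("chr", chrom_idx)
  # slot context relative to the prototype plan: copy-number direction, and
  # whether the interval is DCIS-aberrant (early) or IDC-acquired/progressing
  # (late), using the canonical 10% threshold and 2-point constancy band
  slot_dir <- rep(NA_character_, n)
  slot_early <- rep(FALSE, n)
  slot_late <- rep(FALSE, n)
  plan <- spec$prototype_plan
  if (!is.null(plan)) {
    mid <- (start + end) / 2
    for (k in seq_len(nrow(plan))) {
      hit <- chrom == plan$chrom[k] & mid >= plan$start[k] & mid < plan$end[k]
      slot_dir[hit] <- plan$direction[k]
      aber_d <- plan$dcis_freq[k] > 0.1
      aber_i <- plan$idc_freq[k] > 0.1
      slot_early[hit] <- aber_d
      slot_late[hit] <- aber_i &&
        (!aber_d || plan$idc_freq[k] - plan$dcis_freq[k] > 0.02)
    }
  }
  w <- spec$placement_weights
  planted_class <- rep("null", n)
  direction <- integer(n)
  avail <- rep(TRUE, n)
  place <- function(cl, d, count) {
    if (count == 0) return(invisible())
    wt <- rep(1, n)
    match_dir <- !is.na(slot_dir) &
      ((slot_dir == "gain") == (d > 0))
    mismatch <- !is.na(slot_dir) & !match_dir
    if (cl == "common") {
      wt[match_dir & slot_early] <- w[["common_conc"]]
      wt[mismatch] <- w[["common_disc"]]
    } else if (cl == "disparate") {
      wt[match_dir & slot_late] <- w[["disparate_conc"]]
      wt[mismatch] <- w[["disparate_disc"]]
    }
    wt[!avail] <- 0
    idx <- sample.int(n, count, prob = wt)
    planted_class[idx] <<- cl
    direction[idx] <<- d
    avail[idx] <<- FALSE
    invisible()
  }
  for (cl in c("common", "disparate", "dcis_only")) {
    total <- spec[[paste0("n_", if (cl == "dcis_only") "dcis_only" else cl)]]
    place(cl, +1L, ceiling(total / 2))
    place(cl, -1L, floor(total / 2))
  }
  is_planted <- planted_class != "null"
  data.frame(chrom = chrom, start = start, end = end,
             symbol = sprintf("G%04d", seq_len(n)),
             planted_class = planted_class,
             planted_direction = ifelse(is_planted, direction, 0L),
             stringsAsFactors = FALSE)
}

stage_shift <- function(class, direction, lfc) {
  # per-stage planted mean shifts; normal is always 0
  d <- direction * lfc
  switch(class,
         common    = c(normal = 0, dcis = 1, idc = 2, met = 2) * d,
         disparate = c(normal = 0, dcis = 0, idc = 1, met = 1) * d,
         dcis_only = c(normal = 0, dcis = 1, idc = 0.95, met = 0.95) * d,
         c(normal = 0, dcis = 0, idc = 0, met = 0))
}

make_expression_studies <- function(spec, genes) {
  set.seed(split_seed(spec$seed, 2L))
  n <- spec$n_genes
  baseline <- stats::rnorm(n, mean = 7, sd = 1)
  shifts <- t(vapply(seq_len(n), function(i) {
    stage_shift(genes$planted_class[i], genes$planted_direction[i],
                spec$effect_size_lfc)
  }, numeric(4)))
  colnames(shifts) <- c("normal", "dcis", "idc", "met")
  out <- vector("list", length(spec$studies))
  for (j in seq_along(spec$studies)) {
    set.seed(split_seed(spec$seed, 100L + j))
    sizes <- spec$studies[[j]]
    batch <- stats::rnorm(1, 0, 0.5)
    stages <- rep(names(sizes), times = sizes)
    ns <- length(stages)
    sample_id <- sprintf("S%d_%s_%02d", j, stages,
                         unlist(lapply(sizes, seq_len)))
    mu <- matrix(baseline + batch, n, ns) + shifts[, stages, drop = FALSE]
    expr <- mu + matrix(stats::rnorm(n * ns, 0, spec$noise_sd), n, ns)
    dimnames(expr) <- list(genes$symbol, sample_id)
    out[[j]] <- list(expr = expr,
                     samples = data.frame(sample = sample_id,
                                          study = paste0("study", j),
                                          stage = stages,
                                          stringsAsFactors = FALSE))
  }
  names(out) <- paste0("study", seq_along(out))
  out
}

make_cna_profile <- function(spec) {
  plan <- spec$prototype_plan
  chroms <- paste0("chr", seq_len(spec$n_chromosomes))
  rows <- list()
  for (chr in chroms) {
    p <- if (is.null(plan)) {
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 direction = character(), dcis_freq = numeric(),
                 idc_freq = numeric())
    } else plan[plan$chrom == chr, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    pos <- 0
    add <- function(start, end, gain_d, gain_i, loss_d, loss_i) {
      rbind(data.frame(chrom = chr, start = start, end = end, stage = "dcis",
                       gain_fraction = gain_d, loss_fraction = loss_d),
            data.frame(chrom = chr, start = start, end = end, stage = "idc",
                       gain_fraction = gain_i, loss_fraction = loss_i))
    }
    if (nrow(p)) {
      for (k in seq_len(nrow(p))) {
        if (p$start[k] > pos) rows <- c(rows, list(add(pos, p$start[k], 0, 0, 0, 0)))
        g <- p$direction[k] == "gain"
        rows <- c(rows, list(add(p$start[k], p$end[k],
                                 if (g) p$dcis_freq[k] else 0,
                                 if (g) p$idc_freq[k] else 0,
                                 if (g) 0 else p$dcis_freq[k],
                                 if (g) 0 else p$idc_freq[k])))
        pos <- p$end[k]
      }
    }
    if (pos < spec$chromosome_length_bp) {
      rows <- c(rows, list(add(pos, spec$chromosome_length_bp, 0, 0, 0, 0)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

make_mutation_table <- function(spec) {
  if (is.null(spec$mutation_plan)) {
    return(data.frame(gene = character(), stage = character(),
                      frequency = numeric(), stringsAsFactors = FALSE))
  }
  out <- spec$mutation_plan
  rownames(out) <- NULL
  out
}

make_survival_component <- function(spec) {
  set.seed(split_seed(spec$seed, 3L))
  ng <- spec$n_survival_genes
  ns <- spec$n_survival_subjects
  w <- stats::rnorm(ng, 0, spec$survival_effect_sd)
  x <- matrix(stats::rnorm(ng * ns), ng, ns,
              dimnames = list(sprintf("SV%03d", seq_len(ng)),
                              sprintf("P%03d", seq_len(ns))))
  risk <- as.numeric(crossprod(x, w))
  time <- stats::rexp(ns, rate = 0.02 * exp(risk))
  cens <- stats::runif(ns, 0, 120)
  data_time <- pmin(time, cens)
  list(records = data.frame(subject = colnames(x),
                            time_months = data_time,
                            event = as.integer(time <= cens),
                            risk_score = risk,
                            stringsAsFactors = FALSE),
       expr = x, weights = w)
}

#' Write a cohort bundle to TSV files
#'
#' Emits the bundle in the plain-text exchange formats used throughout the
#' package: BED-style gene annotation, one expression matrix and sample sheet
#' per study, the CNA frequency table, the mutation table and the survival
#' records. All intervals are 0-based half-open.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(cohort$genes, file.path(dir, "genes.tsv"))
  for (nm in names(cohort$studies)) {
    st <- cohort$studies[[nm]]
    em <- data.frame(symbol = rownames(st$expr), st$expr, check.names = FALSE)
    write_tsv(em, file.path(dir, paste0("expr_", nm, ".tsv")))
    write_tsv(st$samples, file.path(dir, paste0("samples_", nm, ".tsv")))
  }
  write_tsv(cohort$cna, file.path(dir, "cna_frequencies.tsv"))
  write_tsv(cohort$mutations, file.path(dir, "mutations.tsv"))
  write_tsv(cohort$survival$records, file.path(dir, "survival.tsv"))
  invisible(dir)
}

#' Generate a protein-interaction network with planted homogeneous hubs
#'
#' Produces an undirected edge list over labeled nodes in which exactly
#' `n_planted_hubs` nodes reach degree `hub_degree`, each wired to its own
#' disjoint set of spoke nodes whose expression-direction labels are set so
#' that a fraction `hub_homogeneity_fraction` of the hub's neighbors share one
#' direction (the majority share is therefore
#' `max(f, 1 - f)`). Background noise edges are added between non-hub nodes
#' with probability `background_edge_prob`, capped so that no background node
#' reaches hub degree.
#'
#' @param n_nodes total nodes.
#' @param n_planted_hubs number of hub nodes.
#' @param hub_degree degree of every planted hub (>= 4).
#' @param hub_homogeneity_fraction fraction in `[0, 1]` of each hub's
#'   neighbors labeled `"up"`.
#' @param background_edge_prob probability of a noise edge between two
#'   non-hub nodes.
#' @param direction_labels labels to draw for nodes outside planted spokes.
#' @param seed integer seed.
#' @return list with `edges` (data frame `node_a`, `node_b`) and `directions`
#'   (named character vector).
#' @export
generate_ppin <- function(n_nodes, n_planted_hubs, hub_degree,
                          hub_homogeneity_fraction = 1,
                          background_edge_prob = 0,
                          direction_labels = c("up", "down"),
                          seed = 1L) {
  stopifnot(hub_degree >= 4, hub_homogeneity_fraction >= 0,
            hub_homogeneity_fraction <= 1)
  if (hub_degree > n_nodes - 1) stop("hub_degree exceeds n_nodes - 1")
  if (n_planted_hubs * hub_degree > n_nodes - n_planted_hubs) {
    stop("not enough nodes for disjoint hub spokes")
  }
  set.seed(split_seed(seed, 7L))
  nodes <- sprintf("N%04d", seq_len(n_nodes))
  hubs <- nodes[seq_len(n_planted_hubs)]
  pool <- nodes[-seq_len(n_planted_hubs)]
  directions <- stats::setNames(sample(direction_labels, n_nodes, replace = TRUE),
                                nodes)
  edges <- list()
  used <- 0L
  n_up <- round(hub_homogeneity_fraction * hub_degree)
  for (h in hubs) {
    spokes <- pool[used + seq_len(hub_degree)]
    used <- used + hub_degree
    directions[spokes] <- c(rep("up", n_up), rep("down", hub_degree - n_up))
    edges[[h]] <- data.frame(node_a = h, node_b = spokes,
                             stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges) %||%
    data.frame(node_a = character(), node_b = character())
  if (background_edge_prob > 0 && length(pool) > 1) {
    cand <- utils::combn(pool, 2)
    keep <- stats::runif(ncol(cand)) < background_edge_prob
    bg <- data.frame(node_a = cand[1, keep], node_b = cand[2, keep],
                     stringsAsFactors = FALSE)
    # cap background degree below hub_degree so planted hubs stay the only hubs
    deg <- table(c(edges$node_a, edges$node_b, bg$node_a, bg$node_b))
    ok <- rep(TRUE, nrow(bg))
    running <- table(c(edges$node_a, edges$node_b))
    degc <- stats::setNames(rep(0L, n_nodes), nodes)
    degc[names(running)] <- as.integer(running)
    for (i in seq_len(nrow(bg))) {
      a <- bg$node_a[i]; b <- bg$node_b[i]
      if (degc[a] >= hub_degree - 1L || degc[b] >= hub_degree - 1L) {
        ok[i] <- FALSE
      } else {
        degc[a] <- degc[a] + 1L; degc[b] <- degc[b] + 1L
      }
    }
    edges <- rbind(edges, bg[ok, , drop = FALSE])
  }
  rownames(edges) <- NULL
  list(edges = edges, directions = directions)
}

#' Generate random signed pathway topologies
#'
#' Each pathway is a random acyclic signed digraph: gene `j` (for `j >= 2`)
#' receives one regulating edge from a uniformly drawn earlier gene, with sign
#' drawn from `edge_signs`. Seeded draws are reproducible.
#'
#' @param n_pathways number of pathways.
#' @param genes_per_pathway genes per pathway (>= 2).
#' @param edge_signs candidate signs (`+1` activation, `-1` inhibition).
#' @param seed integer seed.
#' @return list of [pathway_topology()] objects.
#' @export
generate_pathways <- function(n_pathways, genes_per_pathway,
                              edge_signs = c(1, -1), seed = 1L) {
  stopifnot(genes_per_pathway >= 2)
  set.seed(split_seed(seed, 8L))
  lapply(seq_len(n_pathways), function(i) {
    genes <- sprintf("P%02d_g%02d", i, seq_len(genes_per_pathway))
    src <- vapply(2:genes_per_pathway,
                  function(j) sample.int(j - 1L, 1L), integer(1))
    edges <- data.frame(source = genes[src], target = genes[-1],
                        sign = sample(edge_signs, genes_per_pathway - 1,
                                      replace = TRUE),
                        stringsAsFactors = FALSE)
    pathway_topology(sprintf("pathway%02d", i), edges, genes)
  })
}

#' Generate a planted density scenario
#'
#' Builds a prototype map plus SGA density table directly at the level the
#' directional evolution tests operate on: per prototype region, gene counts
#' are drawn as Poisson with planted per-Mbp rates for every (gene class,
#' concordance) cell, and converted to densities. `"conc"` rates apply to the
#' expression direction matching the region's copy-number direction (up in
#' gains, down in losses), `"disc"` to the opposite. Outside-of-CNA rows are
#' included for the backward-test reference.
#'
#' Equal rates everywhere give the exchangeable null used for type-I
#' calibration.
#'
#' @param n_prototypes number of prototype regions (alternating gain/loss).
#' @param length_mbp length of each region in Mbp.
#' @param rates named list with elements `common_conc`, `common_disc`,
#'   `disparate_conc`, `disparate_disc`: expected genes per Mbp.
#' @param outside_rate expected genes per Mbp outside all regions (every
#'   class/direction cell).
#' @param outside_length_mbp genomic length outside regions.
#' @param proto_class prototype class label(s), recycled over regions.
#' @param seed integer seed.
#' @return list with `prototype_map` and `density_table`.
#' @export
generate_density_scenario <- function(n_prototypes = 20, length_mbp = 10,
                                      rates = list(common_conc = 1,
                                                   common_disc = 1,
                                                   disparate_conc = 1,
                                                   disparate_disc = 1),
                                      outside_rate = 1,
                                      outside_length_mbp = 500,
                                      proto_class = "idc_specific",
                                      seed = 1L) {
  set.seed(split_seed(seed, 9L))
  dirs <- rep(c("gain", "loss"), length.out = n_prototypes)
  map <- data.frame(region_id = sprintf("R%03d", seq_len(n_prototypes)),
                    chrom = "chr1",
                    start = (seq_len(n_prototypes) - 1) * length_mbp * 1e6,
                    end = seq_len(n_prototypes) * length_mbp * 1e6,
                    direction = dirs,
                    klass = rep(proto_class, length.out = n_prototypes),
                    stringsAsFactors = FALSE)
  class(map) <- c("prototype_map", "data.frame")
  rows <- list()
  for (i in seq_len(n_prototypes)) {
    for (cl in c("common", "disparate")) {
      for (dd in c("up", "down")) {
        conc <- (dirs[i] == "gain") == (dd == "up")
        rate <- rates[[paste0(cl, if (conc) "_conc" else "_disc")]]
        cnt <- stats::rpois(1, rate * length_mbp)
        rows[[length(rows) + 1L]] <- data.frame(
          region_id = map$region_id[i], klass = map$klass[i],
          cna_direction = dirs[i], gene_class = cl, direction = dd,
          count = cnt, length_mbp = length_mbp,
          density = cnt / length_mbp, stringsAsFactors = FALSE)
      }
    }
  }
  for (cl in c("common", "disparate")) {
    for (dd in c("up", "down")) {
      cnt <- stats::rpois(1, outside_rate * outside_length_mbp)
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = "outside", klass = "outside", cna_direction = NA_character_,
        gene_class = cl, direction = dd, count = cnt,
        length_mbp = outside_length_mbp,
        density = cnt / outside_length_mbp, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("density_table", "data.frame")
  list(prototype_map = map, density_table = tab)
}
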