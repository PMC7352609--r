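toy_map <- function(...) {
  df <- data.frame(...)
  class(df) <- c("prototype_map", "data.frame")
  df
}

test_that("gene-to-region assignment follows the overlap rules", {
  map <- toy_map(region_id = c("R1", "R2"), chrom = "chr1",
                 start = c(0, 1e7), end = c(1e7, 2e7),
                 direction = "gain", klass = "constant")
  genes <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(5e6, 9.3e6, 1e6),
                      end = c(5.1e6, 1.03e7, 2e6),
                      symbol = c("inside", "straddle", "offmap"))
  a <- assign_genes_to_regions(genes, map)
  expect_equal(unname(a["inside"]), "R1")
  expect_equal(unname(a["straddle"]), "R1")  # 70% of it sits in R1
  expect_equal(unname(a["offmap"]), "outside")
  empty <- assign_genes_to_regions(genes, map[0, ])
  expect_true(all(empty == "outside"))
})

test_that("density table equals a quadratic-scan recount", {
  set.seed(21)
  genes <- data.frame(chrom = "chr1",
                      start = sort(sample.int(2e8, 200)) , end = NA,
                      symbol = sprintf("g%03d", 1:200))
  genes$end <- genes$start + 1000
  map <- toy_map(region_id = sprintf("R%02d", 1:10), chrom = "chr1",
                 start = seq(0, 9e7, 1e7) + 1e6,
                 end = seq(0, 9e7, 1e7) + 8e6,
                 direction = rep(c("gain", "loss"), 5), klass = "constant")
  sets <- list(common = data.frame(gene = genes$symbol[1:120],
                                   direction = sample(c("up", "down"), 120,
                                                      TRUE)),
               disparate = data.frame(gene = genes$symbol[121:200],
                                      direction = sample(c("up", "down"), 80,
                                                         TRUE)))
  tab <- compute_density_table(sets, map, genes)
  # brute force: scan every gene against every region
  for (r in seq_len(nrow(map))) {
    for (cl in names(sets)) {
      for (dd in c("up", "down")) {
        g <- sets[[cl]]$gene[sets[[cl]]$direction == dd]
        pos <- genes[match(g, genes$symbol), ]
        cnt <- sum(pos$end > map$start[r] & pos$start < map$end[r])
        row <- tab[tab$region_id == map$region_id[r] & tab$gene_class == cl &
                     tab$direction == dd, ]
        expect_equal(row$count, cnt)
        expect_equal(row$density, cnt / ((map$end[r] - map$start[r]) / 1e6))
      }
    }
  }
  # conservation: counts sum to the class totals
  expect_equal(sum(tab$count[tab$gene_class == "common"]), 120)
  expect_equal(sum(tab$count[tab$gene_class == "disparate"]), 80)
})

test_that("density scales inversely with region length", {
  genes <- data.frame(chrom = "chr1", start = c(1e6, 2e6), end = c(1.1e6, 2.1e6),
                      symbol = c("a", "b"))
  sets <- list(common = data.frame(gene = c("a", "b"), direction = "up"))
  short <- toy_map(region_id = "R1", chrom = "chr1", start = 0, end = 1e7,
                   direction = "gain", klass = "constant")
  long <- toy_map(region_id = "R1", chrom = "chr1", start = 0, end = 2e7,
                  direction = "gain", klass = "constant")
  d_short <- compute_density_table(sets, short, genes,
                                   genome_length_bp = 1e8)
  d_long <- compute_density_table(sets, long, genes, genome_length_bp = 1e8)
  up <- function(t) t$density[t$region_id == "R1" & t$direction == "up"]
  expect_equal(up(d_short), 2 / 10)
  expect_equal(up(d_long), up(d_short) / 2)
})

test_that("four-way partition conserves the gene classes", {
  co <- small_cohort()
  map <- build_prototype_map(co$cna)
  common <- co$genes$symbol[co$genes$planted_class == "common"]
  disparate <- co$genes$symbol[co$genes$planted_class == "disparate"]
  part <- sga_partition(common, disparate, map, co$genes)
  expect_equal(length(part$cwc) + length(part$coc), length(common))
  expect_equal(length(part$dwc) + length(part$doc), length(disparate))
  expect_length(intersect(part$cwc, part$coc), 0)
})

test_that("enriched-region scan obeys the 5 Mb gap rule", {
  genes <- data.frame(chrom = "chr1", start = c(1, 4, 8, 20) * 1e6 - 5e5,
                      end = c(1, 4, 8, 20) * 1e6 + 5e5,
                      symbol = letters[1:4])
  out <- find_sga_enriched_regions(genes)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_genes, 3)
  expect_equal(c(out$start, out$end), c(1e6, 8e6))
  # all genes farther apart than the gap: nothing reported
  sparse <- data.frame(chrom = "chr1", start = seq(0, 5) * 6e6,
                       end = seq(0, 5) * 6e6 + 1000, symbol = letters[1:6])
  expect_equal(nrow(find_sga_enriched_regions(sparse)), 0)
})

test_that("enriched regions match a brute-force scan and are maximal", {
  set.seed(8)
  for (rep in 1:5) {
    pos <- sort(sample.int(1.5e8, 50))
    genes <- data.frame(chrom = "chr1", start = pos, end = pos + 10,
                        symbol = sprintf("g%02d", 1:50))
    out <- find_sga_enriched_regions(genes, max_gap_bp = 5e6, min_genes = 2)
    mid <- sort((genes$start + genes$end) / 2)
    # brute force over all contiguous index runs
    runs <- list()
    for (i in 1:49) for (j in (i + 1):50) {
      if (all(diff(mid[i:j]) <= 5e6) &&
          (i == 1 || mid[i] - mid[i - 1] > 5e6) &&
          (j == 50 || mid[j + 1] - mid[j] > 5e6)) {
        runs[[length(runs) + 1]] <- c(mid[i], mid[j], j - i + 1)
      }
    }
    brute <- do.call(rbind, runs)
    if (is.null(brute)) {
      expect_equal(nrow(out), 0)
    } else {
      expect_equal(nrow(out), nrow(brute))
      expect_equal(out$start, brute[, 1])
      expect_equal(out$end, brute[, 2])
      expect_equal(out$n_genes, brute[, 3])
    }
  }
})
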