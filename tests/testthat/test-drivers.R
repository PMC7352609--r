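test_that("mutation filtering applies inclusive stage cutoffs", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    stage = c("dcis", "idc", "idc", "met"),
                    frequency = c(0.06, 0.02, 0.025, 0.05))
  sets <- filter_frequent_mutations(tab)
  expect_equal(sets$dcis, "a")
  expect_equal(sets$idc, "c")   # 2.5% kept, 2% dropped
  expect_equal(sets$met, "d")
  expect_error(filter_frequent_mutations(
    data.frame(gene = "x", stage = "lobular", frequency = 0.5)), "unknown")
})

test_that("driver detection returns the engineered hubs and obeys its gates", {
  hubs <- c("HUB1", "HUB2", "HUB3")
  hub_nbrs <- sprintf("nb%02d", 1:25)
  ppin <- rbind(expand.grid(node_a = hubs, node_b = hub_nbrs,
                            stringsAsFactors = FALSE),
                data.frame(node_a = "lone1", node_b = "lone2"))
  pw_hit <- chain_pathway(c(hubs, hub_nbrs[1:8]), name = "hit")
  misses <- lapply(1:8, function(i) {
    chain_pathway(sprintf("z%d_%02d", i, 1:10), name = paste0("miss", i))
  })
  spia <- data.frame(pathway = c("hit", paste0("miss", 1:8)),
                     significant = c(TRUE, rep(FALSE, 8)))
  res <- detect_drivers(stage_deg = hub_nbrs, stage_mutations = hubs,
                        ppin = ppin, spia_results = spia,
                        pathways = c(list(pw_hit), misses),
                        degree_cutoff = 20)
  expect_setequal(res$drivers, hubs)
  # cutoff above the maximum degree: nothing
  res2 <- detect_drivers(hub_nbrs, hubs, ppin, spia, c(list(pw_hit), misses),
                         degree_cutoff = 100)
  expect_length(res2$drivers, 0)
  # hubs whose pathway is not perturbed are excluded
  spia_off <- spia
  spia_off$significant <- FALSE
  res3 <- detect_drivers(hub_nbrs, hubs, ppin, spia_off,
                         c(list(pw_hit), misses), degree_cutoff = 20)
  expect_length(res3$drivers, 0)
  expect_error(detect_drivers("absent", character(), ppin, spia,
                              list(pw_hit), 20), "empty")
})

test_that("raising the degree cutoff never adds drivers", {
  hubs <- c("HUB1", "HUB2", "HUB3")
  # unequal hub degrees so the cutoff actually thins the set
  ppin <- rbind(expand.grid(node_a = hubs[1:2], node_b = sprintf("nb%02d", 1:25),
                            stringsAsFactors = FALSE),
                data.frame(node_a = hubs[3], node_b = sprintf("nb%02d", 1:12)))
  pw_hit <- chain_pathway(c(hubs, sprintf("nb%02d", 1:8)), name = "hit")
  misses <- lapply(1:8, function(i) {
    chain_pathway(sprintf("z%d_%02d", i, 1:10), name = paste0("miss", i))
  })
  spia <- data.frame(pathway = c("hit", paste0("miss", 1:8)),
                     significant = c(TRUE, rep(FALSE, 8)))
  res <- lapply(c(5, 15, 20, 30), function(cutoff) {
    detect_drivers(sprintf("nb%02d", 1:25), hubs, ppin, spia,
                   c(list(pw_hit), misses), degree_cutoff = cutoff)
  })
  expect_setequal(res[[1]]$hubs, hubs)      # all three hubs qualify
  expect_setequal(res[[2]]$hubs, hubs[1:2]) # the degree-12 hub drops out
  expect_setequal(res[[1]]$drivers, hubs)
  expect_length(res[[4]]$hubs, 0)           # nobody reaches degree 30
  expect_length(res[[4]]$drivers, 0)
  for (k in 2:4) {
    expect_true(all(res[[k]]$hubs %in% res[[k - 1]]$hubs))
    expect_true(all(res[[k]]$drivers %in% res[[k - 1]]$drivers))
  }
})

test_that("driver-set comparison reports shared/unique counts", {
  sets <- list(dcis = c("a", "b", "c"), idc = c("a", "b", "c"),
               met = c("x", "y"))
  cmp <- compare_driver_sets(sets)
  di <- cmp[cmp$stage_a == "dcis" & cmp$stage_b == "idc", ]
  expect_equal(di$shared, 3)
  expect_equal(di$unique_a + di$unique_b, 0)
  dm <- cmp[cmp$stage_a == "dcis" & cmp$stage_b == "met", ]
  expect_equal(dm$shared, 0)
  # planted overlap structure
  sets2 <- list(dcis = letters[1:4], idc = letters[1:8],
                met = c(letters[1:2], "q", "r"))
  cmp2 <- compare_driver_sets(sets2)
  expect_equal(cmp2$shared[cmp2$stage_a == "dcis" & cmp2$stage_b == "idc"], 4)
  expect_equal(cmp2$shared[cmp2$stage_a == "idc" & cmp2$stage_b == "met"], 2)
})

test_that("binary character matrix encodes stages with an outgroup", {
  m <- binary_character_matrix(list(dcis = c("a", "b"), idc = c("b", "c")))
  expect_equal(rownames(m), c("normal", "dcis", "idc"))
  expect_true(all(m["normal", ] == 0))
  expect_equal(unname(m["dcis", c("a", "b", "c")]), c(1L, 1L, 0L))
  m2 <- binary_character_matrix(list(dcis = "a", idc = "a"),
                                add_outgroup = FALSE)
  expect_equal(rownames(m2), c("dcis", "idc"))
})

test_that("Fitch score equals hand passes and brute-force enumeration", {
  taxa <- c("normal", "dcis", "idc", "met")
  trunk <- matrix(c(0, 1, 1, 1), 4, 1, dimnames = list(taxa, "g"))
  all4 <- phangorn::allTrees(4, rooted = FALSE, tip.label = taxa)
  for (i in seq_along(all4)) {
    expect_equal(fitch_score(all4[[i]], trunk), 1)
  }
  flat <- matrix(1, 4, 3, dimnames = list(taxa, c("a", "b", "c")))
  expect_equal(fitch_score(ape::read.tree(text = "((normal,dcis),(idc,met));"),
                           flat), 0)
  split <- matrix(c(0, 1, 0, 1), 4, 1, dimnames = list(taxa, "g"))
  expect_equal(fitch_score(ape::read.tree(text = "((normal,idc),(dcis,met));"),
                           split), 1)
  expect_equal(fitch_score(ape::read.tree(text = "((normal,dcis),(idc,met));"),
                           split), 2)
  expect_error(fitch_score(ape::read.tree(text = "((a,b),(c,d));"), split),
               "differ")
})

test_that("Fitch score matches exhaustive labeling and phangorn on random data", {
  set.seed(51)
  for (i in 1:15) {
    n_taxa <- sample(4:5, 1)
    taxa <- sprintf("t%d", seq_len(n_taxa))
    m <- matrix(sample(0:1, n_taxa * 6, TRUE), n_taxa, 6,
                dimnames = list(taxa, sprintf("c%d", 1:6)))
    trees <- phangorn::allTrees(n_taxa, rooted = FALSE, tip.label = taxa)
    tr <- trees[[sample(length(trees), 1)]]
    score <- fitch_score(tr, m)
    expect_equal(score, brute_force_parsimony(tr, m))
    pd <- phangorn::phyDat(m, type = "USER", levels = c(0, 1))
    expect_equal(score, phangorn::parsimony(tr, pd))
  }
})

test_that("exhaustive parsimony search finds the planted topology", {
  taxa <- c("normal", "dcis", "idc", "met")
  # metastasis sharing most derived characters with the in situ stage
  m <- cbind(matrix(c(0, 1, 0, 1), 4, 5, dimnames = list(taxa, NULL)),
             matrix(c(0, 1, 1, 1), 4, 2, dimnames = list(taxa, NULL)))
  colnames(m) <- sprintf("g%d", 1:7)
  best <- best_parsimony_tree(m)
  expect_equal(length(best$trees), 1)
  part <- ape::prop.part(best$trees[[1]])
  expect_true(any(vapply(part, function(p) {
    setequal(attr(part, "labels")[p], c("dcis", "met")) ||
      setequal(attr(part, "labels")[p], c("normal", "idc"))
  }, logical(1))))
  expect_equal(best$length, min(best$scores))
  expect_true(all(best$length <= best$scores))
  # three taxa: the single unrooted topology
  expect_equal(length(best_parsimony_tree(m[1:3, ])$trees), 1)
  # all-zero matrix: every topology ties at zero
  zero <- matrix(0L, 4, 3, dimnames = list(taxa, c("a", "b", "c")))
  bz <- best_parsimony_tree(zero)
  expect_equal(bz$length, 0)
  expect_equal(length(bz$trees), 3)
  expect_error(best_parsimony_tree(matrix(0L, 9, 2,
                                          dimnames = list(letters[1:9],
                                                          c("a", "b")))),
               "8 taxa")
})
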