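# shared fixtures, all built in code

# small three-study cohort with planted classes (memoized per session)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(n_genes = 300, n_chromosomes = 5,
                         studies = rep(list(c(normal = 20, dcis = 20,
                                              idc = 20)), 3),
                         n_common = 30, n_disparate = 30, n_dcis_only = 5,
                         prototype_plan = default_prototype_plan(),
                         seed = 101L)
      cache <<- generate_cohort(spec)
    }
    cache
  }
})

# chain pathway a -> b -> ... all-activation
chain_pathway <- function(genes, signs = 1, name = "chain") {
  pathway_topology(name,
                   data.frame(source = genes[-length(genes)],
                              target = genes[-1],
                              sign = rep(signs, length.out = length(genes) - 1),
                              stringsAsFactors = FALSE),
                   genes)
}

# independent signed-rank oracle: full enumeration of sign assignments
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  p_le <- mean(v_all <= v_obs + 1e-9)
  min(1, 2 * min(p_ge, p_le))
}

# independent AUC oracle: O(n^2) pair counting
pair_count_auc <- function(scores, labels, positive) {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# independent concordance oracle: explicit pair loop
pair_count_ci <- function(time, event, risk) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    }
  }
  num / den
}

# independent Fitch oracle: minimize changes over all internal labelings
brute_force_parsimony <- function(tree, matrix) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  internal <- ntip + seq_len(tree$Nnode)
  tips <- matrix[tree$tip.label, , drop = FALSE]
  total <- 0
  for (ch in seq_len(ncol(matrix))) {
    best <- Inf
    labelings <- expand.grid(rep(list(c(0L, 1L)), tree$Nnode))
    for (k in seq_len(nrow(labelings))) {
      state <- integer(ntip + tree$Nnode)
      state[seq_len(ntip)] <- tips[, ch]
      state[internal] <- as.integer(labelings[k, ])
      cost <- sum(state[tree$edge[, 1]] != state[tree$edge[, 2]])
      best <- min(best, cost)
    }
    total <- total + best
  }
  total
}
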