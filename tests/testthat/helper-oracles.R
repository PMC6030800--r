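# Brute-force oracles and small corpus builders shared by the tests.
# Oracles deliberately use naive enumeration, independent of the
# package's level-wise / aggregated implementations.

# Count transactions containing every member of `items`.
bruteItemsetCount <- function(sets, items) {
  sum(vapply(sets, function(t) all(items %in% t), NA))
}

# All itemsets of size <= maxLen with count >= 1, by exhaustive
# enumeration of subsets of the full herb universe.
bruteAllCounts <- function(sets, maxLen) {
  herbs <- sort(unique(unlist(sets, use.names = FALSE)))
  out <- list()
  for (k in seq_len(maxLen)) {
    if (length(herbs) < k) break
    for (items in combn(herbs, k, simplify = FALSE)) {
      cnt <- bruteItemsetCount(sets, items)
      if (cnt > 0L) out[[length(out) + 1L]] <- list(items = items,
                                                    count = cnt)
    }
  }
  out
}

# Rule metrics from raw transactions, straight from the definitions.
bruteRuleMetrics <- function(sets, X, Y) {
  N <- length(sets)
  cXY <- bruteItemsetCount(sets, c(X, Y))
  cX <- bruteItemsetCount(sets, X)
  cY <- bruteItemsetCount(sets, Y)
  conf <- cXY / cX
  list(support = cXY / N, confidence = conf, lift = conf / (cY / N),
       frequency = cXY)
}

# Modularity by a naive double loop over the dense adjacency matrix.
naiveModularity <- function(edges, assignment, gamma = 1) {
  nodes <- names(assignment)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    A[edges$from[r], edges$to[r]] <- A[edges$from[r], edges$to[r]] +
      edges$weight[r]
    A[edges$to[r], edges$from[r]] <- A[edges$to[r], edges$from[r]] +
      edges$weight[r]
  }
  m <- sum(A) / 2
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (assignment[i] == assignment[j])
      q <- q + A[i, j] - gamma * k[i] * k[j] / (2 * m)
  }
  unname(q / (2 * m))
}

# Exact rejection probability of the add-one one-sided permutation test
# at level alpha, for K-herb modules drawn from N herbs whose flags are
# iid Bernoulli(p), with B permutations: the module count is
# hypergeometric given the total flag count, and the permutation tally
# is binomial in the true tail probability. Closed form, independent of
# the package implementation.
exactPermutationSize <- function(N, K, B, p, alpha = 0.05,
                                 tail = c("high", "low")) {
  tail <- match.arg(tail)
  gmax <- ceiling(alpha * (1 + B)) - 1L   # (1+G)/(1+B) < alpha
  size <- 0
  for (T in 0:N) {
    pT <- dbinom(T, N, p)
    if (pT < 1e-14) next
    ks <- 0:min(K, T)
    pX <- dhyper(ks, T, N - T, K)
    q <- if (tail == "high")
      phyper(ks - 1, T, N - T, K, lower.tail = FALSE)  # P(X' >= k)
    else phyper(ks, T, N - T, K)                        # P(X' <= k)
    size <- size + pT * sum(pX * pbinom(gmax, B, q))
  }
  size
}

# Best modularity over every assignment of <= maxLabels labels
# (exhaustive search; only for tiny graphs). Q is evaluated straight
# from its definition, independent of the package implementation:
# Q = sum_c [ W_in(c)/m - gamma * (K(c)/(2m))^2 ], W_in counting each
# internal edge once.
exhaustiveBestQ <- function(network, gamma = 1, maxLabels = 3L) {
  nodes <- networkNodes(network)
  n <- length(nodes)
  stopifnot(n <= 10L)
  e <- edgeTable(network)
  ei <- match(e$from, nodes); ej <- match(e$to, nodes)
  w <- e$weight
  m <- sum(w)
  k <- numeric(n)
  for (r in seq_along(w)) {
    k[ei[r]] <- k[ei[r]] + w[r]
    k[ej[r]] <- k[ej[r]] + w[r]
  }
  best <- -Inf
  labs <- as.matrix(expand.grid(rep(list(seq_len(maxLabels)), n)))
  for (r in seq_len(nrow(labs))) {
    a <- labs[r, ]
    win <- sum(w[a[ei] == a[ej]])
    ktot <- tapply(k, a, sum)
    q <- win / m - gamma * sum((ktot / (2 * m))^2)
    if (q > best) best <- q
  }
  best
}

# Seeded random corpus for oracle-equivalence checks.
randomCorpus <- function(seed, nHerbs = 20L, nTrans = 50L,
                         sizeRange = c(2L, 6L)) {
  withr::with_seed(seed, {
    herbs <- sprintf("h%02d", seq_len(nHerbs))
    sets <- lapply(seq_len(nTrans), function(i) {
      k <- sample(seq(sizeRange[1], sizeRange[2]), 1L)
      sample(herbs, k)
    })
    names(sets) <- sprintf("t%03d", seq_len(nTrans))
    herbCorpus(sets)
  })
}

# Minimal annotation table: meridian sets given as a named list.
makeAnnotations <- function(meridianSets, category = 1L) {
  ids <- names(meridianSets)
  ann <- data.frame(herb_id = ids,
                    latin_name = paste("Herba", ids),
                    category = rep_len(category, length(ids)),
                    stringsAsFactors = FALSE)
  for (m in MERIDIANS)
    ann[[m]] <- unname(vapply(meridianSets, function(s) m %in% s, NA))
  ann
}

# Corpus from an unnamed list of herb sets.
namedCorpus <- function(sets) {
  names(sets) <- sprintf("p%02d", seq_along(sets))
  herbCorpus(sets)
}

# Two 5-cliques joined by a single weight-1 bridge, as a corpus whose
# co-occurrence network is exactly that graph.
cliqueBridgeCorpus <- function() {
  xs <- paste0("x", 1:5); ys <- paste0("y", 1:5)
  sets <- c(combn(xs, 2, simplify = FALSE),
            combn(ys, 2, simplify = FALSE),
            list(c("x1", "y1")))
  names(sets) <- sprintf("p%02d", seq_along(sets))
  herbCorpus(sets)
}
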