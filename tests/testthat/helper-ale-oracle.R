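# Independent brute-force first-order ALE implementation, written directly
# from the estimator's definition with explicit loops. Deliberately shares no
# code with compute_ale(); used as the oracle in equivalence tests.
naive_ale <- function(predict_fn, data, feature, k_bins) {
  x <- data[[feature]]
  n <- nrow(data)
  # same quantile grid definition as the estimator under test (seq() and
  # (0:k)/k can differ by one ULP, which moves edge-tied rows across bins);
  # the accumulation algorithm below remains independent
  edges <- unique(as.numeric(quantile(x, probs = seq(0, 1, length.out = k_bins + 1),
                                      type = 7)))
  K <- length(edges) - 1
  # assign each row to a bin: the interval [edges[j], edges[j+1])
  bin <- integer(n)
  for (i in seq_len(n)) {
    j <- K
    for (k in seq_len(K)) {
      if (x[i] >= edges[k] && (x[i] < edges[k + 1] || k == K)) { j <- k; break }
    }
    bin[i] <- j
  }
  means <- numeric(K)
  counts <- integer(K)
  for (j in seq_len(K)) {
    rows <- which(bin == j)
    counts[j] <- length(rows)
    if (length(rows) == 0) next
    tot <- 0
    for (i in rows) {
      hi <- data[i, , drop = FALSE]; hi[[feature]] <- edges[j + 1]
      lo <- data[i, , drop = FALSE]; lo[[feature]] <- edges[j]
      tot <- tot + (predict_fn(hi) - predict_fn(lo))
    }
    means[j] <- tot / length(rows)
  }
  acc <- numeric(K + 1)
  for (j in seq_len(K)) acc[j + 1] <- acc[j] + means[j]
  ctr <- 0
  for (j in seq_len(K)) ctr <- ctr + counts[j] * (acc[j] + acc[j + 1]) / 2
  ctr <- ctr / n
  list(edges = edges, effect = acc - ctr, counts = counts)
}

# random covariate table with correlated columns for oracle comparisons
random_table <- function(n, seed) {
  withr::with_seed(seed, {
    z <- rnorm(n)
    tibble::tibble(
      x1 = z + rnorm(n, sd = 0.6),
      x2 = 0.7 * z + rnorm(n, sd = 0.8),
      x3 = runif(n, -2, 2)
    )
  })
}

# exact noise-free zone curve: injected effect evaluated on a fine depth
# grid with synthetic per-bin counts, for delineation round-trips
exact_zone_curve <- function(params = gw_effect_params(), step = 0.05,
                             d_max = 4) {
  edges <- seq(0, d_max, by = step)
  eff <- true_effect(edges, deficit = -60, params = params)
  counts <- rep(50L, length(edges) - 1L)
  curve <- gwyield:::new_ale_curve(edges, eff, counts, "wt_depth_jul",
                                   center = 0)
  # recenter the way a real ALE curve is centred
  K <- length(edges) - 1L
  ctr <- sum(counts * (eff[1:K] + eff[2:(K + 1)]) / 2) / sum(counts)
  curve$effect <- eff - ctr
  curve
}
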