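# Small-scale config used throughout the unit tests; two strains keep the
# array count down, everything else mirrors the full study design.
small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_genes = 400L, n_spikeins = 12L,
               n_replicates = 3L, strains = c("wt", "top1top2"),
               n_conditions = 20L, n_chromosomes = 4L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# Brute-force trailing moving average: explicit double loop, no shared code
# with the implementation.
brute_moving_average <- function(x, y, w) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(xs)
  xp <- yp <- numeric(n - w + 1)
  for (i in seq_len(n - w + 1)) {
    xp[i] <- mean(xs[i:(i + w - 1)])
    yp[i] <- mean(ys[i:(i + w - 1)])
  }
  list(x = xp, y = yp)
}

# All permutations of 1..n, built by a different scheme than the package's
# (iterative insertion rather than recursion over the leading element).
oracle_permutations <- function(n) {
  perms <- matrix(1L, 1, 1)
  for (k in 2:n) {
    out <- matrix(0L, nrow(perms) * k, k)
    r <- 0L
    for (i in seq_len(nrow(perms))) {
      for (pos in seq_len(k)) {
        r <- r + 1L
        out[r, ] <- append(perms[i, ], k, after = pos - 1L)
      }
    }
    perms <- out
  }
  perms
}

# Direct combinatorial-sum oracle for the upper-tail hypergeometric
# probability, independent of phyper.
oracle_hyper_upper <- function(k, a, b, n) {
  js <- k:min(a, b)
  js <- js[js >= max(0, a + b - n)]
  if (!length(js)) return(0)
  sum(choose(a, js) * choose(n - a, b - js)) / choose(n, b)
}
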