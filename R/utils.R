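# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's RNG stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Apportion integer `total` across categories with real quotas by the
# largest-remainder rule; each result differs from its quota by < 1.
largest_remainder <- function(quotas, total) {
  base <- floor(quotas)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quotas - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  } else if (rem < 0) {
    cut <- order(quotas - base, decreasing = FALSE)
    i <- 1
    while (rem < 0 && i <= length(cut)) {
      if (base[cut[i]] > 0) { base[cut[i]] <- base[cut[i]] - 1; rem <- rem + 1 }
      i <- i + 1
    }
  }
  as.integer(base)
}

# Full pairwise Euclidean distance matrix (rows of `m`), zero diagonal.
pairwise_distances <- function(m) {
  as.matrix(stats::dist(m, method = "euclidean"))
}
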