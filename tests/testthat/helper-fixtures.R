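`%||%` <- function(a, b) if (is.null(a)) b else a

# Small shared configuration and dataset used across test files.
small_config <- function(seed = 7L, ...) {
  args <- utils::modifyList(
    list(n_discovery = 150L, n_validation = 110L, n_cpgs = 10L,
         snps_per_cpg = 6L, n_batches = 3L, n_cell_types = 3L,
         dirichlet_alpha = c(12, 4, 4), n_ref_cpgs = 20L, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# memoise the default small dataset so test files don't re-simulate it
.small_ds_cache <- new.env(parent = emptyenv())
small_dataset <- function() {
  if (is.null(.small_ds_cache$ds))
    .small_ds_cache$ds <- simulate_dataset(small_config())
  .small_ds_cache$ds
}

# independent enumeration oracle for the HWE exact test: exact conditional
# probabilities of all heterozygote counts via choose(), no log tricks
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  n_A <- 2 * n_AA + n_Aa
  if (n_a == 0 || n_A == 0) return(1)
  rare <- min(n_a, n_A)
  het <- seq(rare %% 2, rare, by = 2)
  prob <- vapply(het, function(h) {
    homr <- (rare - h) / 2
    homc <- n - homr - h
    exp(lfactorial(n) - lfactorial(homr) - lfactorial(h) - lfactorial(homc) +
          h * log(2) + lfactorial(n_a) + lfactorial(n_A) - lfactorial(2 * n))
  }, numeric(1))
  obs <- prob[het == n_Aa]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# sort-based step-up BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- min(1, prev)
  }
  q
}

# minimal valid cohort for model-level tests (single batch unless asked)
toy_cohort <- function(n, seed = 1, n_batches = 1L) {
  set.seed(seed)
  simulate_cohort(small_config(), n, panel = "discovery")$cohort |>
    (\(d) {
      d$batch <- sprintf("b%02d", ((seq_len(n) - 1L) %% n_batches) + 1L)
      d
    })()
}
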