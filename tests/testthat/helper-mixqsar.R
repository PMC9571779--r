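# shared fixtures built in code

# random descriptor table with named columns
random_table <- function(n, p, seed, prefix = "d", positive = FALSE) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * p), n, p)
  if (positive) m <- exp(m / 2)
  out <- as.data.frame(m)
  names(out) <- paste0(prefix, seq_len(p))
  out
}

# binary-mixture composition table over n compounds with log-spread ratios
random_mixtures <- function(n_compounds, n_mixtures, seed, equimolar = FALSE) {
  set.seed(seed)
  a <- sample.int(n_compounds, n_mixtures, replace = TRUE)
  b <- ((a + sample.int(n_compounds - 1L, n_mixtures, replace = TRUE) - 1L) %%
          n_compounds) + 1L
  x_a <- if (equimolar) rep(0.5, n_mixtures) else {
    e <- stats::runif(n_mixtures, -2, 2); 10^e / (1 + 10^e)
  }
  data.frame(mixture_no = seq_len(n_mixtures), component_a = a,
             component_b = b, x_a = x_a, x_b = 1 - x_a)
}

# configuration of the RBF-surface recovery fixture: 3 planted centres with
# fixed weights on 3 descriptors, 80/20 train/test, noise SD 0.05
rbf_recovery_config <- function(seed) {
  sim_config(n_compounds = 100L, n_descriptors = 3L, response_model = "rbf",
             rbf = list(n_centers = 3L, width = 1.6, weights = c(3, -2, 2.5)),
             noise_sd = 0.05, seed = seed)
}
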