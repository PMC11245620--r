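# shared fixtures: small generative models and sweep settings used across
# test files; everything is built in code at test time

tiny_model <- function(method = "cca", p = 4L, a = -1, r_true = 0.3,
                       seed = 1L) {
  generate_model(p, p, a, a, r_true, method, seed = seed)
}

# a null model: flat spectra, zero between-set block
null_model <- function(p = 4L, seed = 1L) {
  generate_model(p, p, 0, 0, 0, "cca", seed = seed)
}

# mean metric over repeated draws from one model
mean_over_reps <- function(model, n, n_reps, seed, fun) {
  model <- precompute_sampler(model)
  mean(vapply(seq_len(n_reps), function(i) {
    d <- sample_dataset(model, n, seed = child_seed(seed, i))
    fun(d)
  }, numeric(1)))
}
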