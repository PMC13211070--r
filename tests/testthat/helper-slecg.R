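# Shared fixtures: a miniature extractor profile and miniature datasets so
# unit tests run in seconds. The stride arithmetic (and so every shape
# contract) is width-independent, which is what makes the miniature profile
# a faithful stand-in.

tiny_spec <- function(in_leads = 1L, dropout = 0) {
  extractor_spec(in_leads = in_leads, oscnn_kernels = c(1L, 3L, 5L),
                 oscnn_out_channels = 6L,
                 block_channels = c(8L, 8L, 12L, 12L, 16L),
                 block_expansion = 2L, d_model = 16L,
                 n_transformer_layers = 1L, n_heads = 2L, se_reduction = 2L,
                 ffn_mult = 2L, dropout = dropout)
}

# quick two-class dataset (regular vs irregular rhythm), preprocessed to a
# short window; used by training-level tests
tiny_dataset <- function(seed = 1L, n_patients = 8L, records_per_patient = 2L) {
  sim <- sim_spec(n_patients = n_patients,
                  records_per_patient = records_per_patient,
                  fs = 250, duration_s = c(4, 5), n_classes = 2L,
                  snr_db = 25, wander_amp = 0.02, seed = seed)
  pre <- preprocess_config(band_low = 0.5, band_high = 40, target_fs = 125,
                           target_len_s = 4)
  prepare_dataset(sim, pre, seed = seed)
}

# central-difference gradient of a scalar-valued function of a matrix
num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# max relative error between the engine's gradient and finite differences
grad_err <- function(make_loss, x0) {
  p <- slecg:::ag_param(x0)
  slecg:::ag_reset()
  loss <- make_loss(p)
  slecg:::ag_backward(loss)
  ana <- p$grad
  num <- num_grad(function(v) {
    q <- slecg:::ag_param(v)
    slecg:::ag_reset()
    make_loss(q)$value[1L]
  }, x0)
  max(abs(ana - num)) / max(1e-8, max(abs(num)))
}
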