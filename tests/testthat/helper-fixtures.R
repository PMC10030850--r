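# Shared fixtures. Heavy pipeline artifacts (the n = 300 recovery run) are
# built once per test session and memoized, because both the consensus
# invariants and the acceptance criteria consume them.

toy_omic <- function(values, kind = "F1_mrna",
                     ids = sprintf("S%02d", seq_len(nrow(values))),
                     feats = sprintf("f%02d", seq_len(ncol(values)))) {
  rownames(values) <- ids
  colnames(values) <- feats
  omic_matrix(values, kind)
}

random_prob_matrix <- function(n, k) {
  p <- matrix(rexp(n * k), n, k)
  p / rowSums(p)
}

.recovery_cache <- new.env(parent = emptyenv())

# The stated recovery world: n = 300, 5 clusters, effect size 3, default
# block widths; AE [64, 32] -> 16; consensus at 100 resamples (precision
# knob scaled from 1000 for the CPU budget), K swept over 2..8.
recovery_fixture <- function() {
  if (!is.null(.recovery_cache$fix)) return(.recovery_cache$fix)
  cfg <- sim_config(n_samples = 300L, seed = 20260910L)
  sim <- simulate_multiomics(cfg)
  proc <- lapply(sim$omics, preprocess_omic,
                 config = preprocess_config(top_n_variable = 200L))
  stack <- stack_omics(proc)
  enc <- train_autoencoder(
    stack, ae_architecture(c(64L, 32L), 16L),
    ae_train_config(max_epochs = 100L, patience = 5L, seed = 3L))
  latent <- encode(enc, stack)
  profile <- build_pac_profile(latent, 2:8, n_resamples = 100L, seed = 11L)
  K <- select_k(profile)
  labels <- final_labels(profile$records[[paste0("K", K)]]$consensus, K,
                         seed = 2L)
  .recovery_cache$fix <- list(cfg = cfg, sim = sim, proc = proc,
                              stack = stack, enc = enc, latent = latent,
                              profile = profile, K = K, labels = labels)
  .recovery_cache$fix
}
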