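# small in-code fixtures shared across the suite

test_montage <- function(n = 8) {
  structure(list(channels = paste0("ch", seq_len(n)), reference = NA,
                 mastoids = character(0), groups = list()),
            class = "montage")
}

# epochs with a class-dependent Gaussian bump on the first two channels
make_separable_epochs <- function(n_trials = 120, n_channels = 8,
                                  n_samples = 64, amplitude = 2.5,
                                  n_subjects = 2, seed = 1, sd = 1) {
  set.seed(seed)
  lab <- rep(c("a", "b"), length.out = n_trials)
  x <- array(stats::rnorm(n_trials * n_channels * n_samples, sd = sd),
             c(n_trials, n_channels, n_samples))
  bump <- exp(-((seq_len(n_samples)) - n_samples / 3)^2 / 18)
  for (i in which(lab == "b"))
    x[i, 1:2, ] <- x[i, 1:2, ] + matrix(rep(amplitude * bump, each = 2), 2)
  md <- tibble::tibble(
    participant_id = rep(seq_len(n_subjects), length.out = n_trials),
    label = lab,
    trial_id = sprintf("t%04d", seq_len(n_trials)))
  epoch_set(x, md, test_montage(n_channels), 250, 1)
}

tiny_model_config <- function(n_classes = 2, n_channels = 8,
                              n_samples = 64, seed = 1, ...) {
  model_config(n_classes, n_channels = n_channels, n_samples = n_samples,
               F1 = 2, temporal_kernel_len = 9, D = 1, F2 = 4,
               pool_sizes = c(2, 4), sep_kernel_len = 5,
               dropout_rate = 0.1, seed = seed, ...)
}

quick_train_config <- function(max_epochs = 20, patience = 4,
                               batch_size = 32, learning_rate = 3e-3,
                               seed = 1, ...) {
  train_config(max_epochs = max_epochs, patience = patience,
               batch_size = batch_size, learning_rate = learning_rate,
               seed = seed, ...)
}
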