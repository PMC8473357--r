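# Independent brute-force oracles used to cross-check the fast paths.

# O(N * W) sliding RMS by direct per-window evaluation.
brute_rms <- function(x, w, step = 1L) {
  ends <- seq.int(w, length(x), by = step)
  vapply(ends, function(e) sqrt(mean(x[(e - w + 1L):e]^2)), numeric(1))
}

# O(N * agreement_n) re-scan implementation of the agreement vote with
# transition-legality constraints; the definitional trace.
naive_decide <- function(raw, agreement_n, initial_mode, rules = default_rules()) {
  raw <- as.character(raw)
  modes <- locomotion_modes()
  current <- initial_mode
  out <- character(length(raw))
  for (k in seq_along(raw)) {
    if (k >= agreement_n) {
      m <- raw[k]
      if (m != current && all(raw[(k - agreement_n + 1L):k] == m) &&
          rules[current, m]) {
        current <- m
      }
    }
    out[k] <- current
  }
  factor(out, levels = modes)
}

# Independent per-class tally of CA / SE / SP (one-vs-rest, percent).
tally_metrics <- function(truth, pred, classes) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  n <- length(truth)
  se <- sp <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    tn <- n - tp - fn - fp
    se[i] <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    sp[i] <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  }
  list(CA = 100 * sum(truth == pred) / n, SE = se, SP = sp)
}

# Balanced 7-class Gaussian blobs in 35 dimensions for classifier tests.
# Class centers depend only on centers_seed, so train/test draws with
# different noise seeds share the same class structure.
make_blobs <- function(n_per_class, sd = 0.05, seed = 1, d = 35L, k = 7L,
                       centers_seed = 99L) {
  set.seed(centers_seed)
  modes <- locomotion_modes()[seq_len(k)]
  centers <- matrix(stats::runif(k * d), k, d)
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(stats::rnorm(n_per_class * d, sd = sd), n_per_class, d,
           byrow = TRUE) + matrix(centers[i, ], n_per_class, d, byrow = TRUE)
  }))
  colnames(X) <- paste0("f", seq_len(d))
  list(X = X, y = factor(rep(modes, each = n_per_class), levels = modes))
}
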