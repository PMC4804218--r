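## Shared fixture builders: everything is generated in code at test time.

extdata <- function(f) system.file("extdata", f, package = "foldcep")

## small hand-specified similarity matrix; unspecified pairs stay NA
toy_matrix <- function(ids, scores, mode = "local") {
  m <- matrix(NA_real_, length(ids), length(ids))
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  for (r in seq_len(nrow(scores))) {
    m[scores$a[r], scores$b[r]] <- m[scores$b[r], scores$a[r]] <- scores$s[r]
  }
  tm_matrix(m, mode)
}

## fold profile straight from a score vector (bypasses matrix plumbing)
profile_from_x <- function(x, fold_id = "f", mode = "local") {
  structure(list(fold_id = fold_id,
                 member_ids = sprintf("%s_m%02d", fold_id, seq_along(x)),
                 x = setNames(x, sprintf("%s_m%02d", fold_id, seq_along(x))),
                 n = length(x), mean_x = mean(x), sd_x = sd(x),
                 r = max(x) - min(x), mode = mode),
            class = "fold_profile")
}

## random posterior-sample list for C3P estimator tests
random_samples <- function(n_samples, k_max = 3) {
  lapply(seq_len(n_samples), function(i) {
    k <- sample.int(k_max, 1)
    w <- rgamma(k, 1)
    list(k = k, pi = w / sum(w),
         mu = runif(k, 0.5, 0.95),
         sigma2 = runif(k, 0.01, 0.08)^2,
         beta = 1)
  })
}

short_mcmc <- function(seed, iterations = 2000, burn_in = 500) {
  mcmc_settings(iterations, burn_in, 5, seed = seed)
}
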