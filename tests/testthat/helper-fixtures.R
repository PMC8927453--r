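# shared fixtures, all built in code

# exact forward-model curve on a uniform strain grid
noiseless_curve <- function(mu, gamma, eps_max = 0.5, n = 200) {
  strain <- seq(0, eps_max, length.out = n)
  tibble::tibble(strain = strain, stress = vw_nominal_stress(mu, gamma, strain))
}

# small study config: default populations scaled down for speed
small_populations <- function(n = 8L) {
  dplyr::mutate(default_populations(), n_samples = n)
}

# reference ARI by brute-force pair counting over explicit label vectors
ari_bruteforce <- function(truth, pred) {
  n <- length(truth)
  same_t <- outer(truth, truth, "==")[upper.tri(diag(n))]
  same_p <- outer(pred, pred, "==")[upper.tri(diag(n))]
  a <- sum(same_t & same_p)           # agreements: together in both
  d <- sum(!same_t & !same_p)         # agreements: apart in both
  total <- choose(n, 2)
  exp_index <- sum(tapply(seq_len(n), truth, length) |> choose(2)) *
    sum(tapply(seq_len(n), pred, length) |> choose(2)) / total
  max_index <- (sum(tapply(seq_len(n), truth, length) |> choose(2)) +
                  sum(tapply(seq_len(n), pred, length) |> choose(2))) / 2
  (a - exp_index) / (max_index - exp_index)
}

# labels behind a confusion matrix (positive = 1)
labels_from_confusion <- function(tp, fp, fn, tn) {
  list(
    truth = c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn)),
    pred = c(rep(1, tp), rep(1, fp), rep(0, fn), rep(0, tn))
  )
}
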