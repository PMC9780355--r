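# Shared oracles and fixture builders (independent of package internals).

# Brute-force AUROC: enumerate every positive-negative pair, ties score 1/2.
auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(wins)
}

# Hanley-McNeil standard error of an empirical AUROC.
hanley_se <- function(A, n1, n0) {
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  sqrt((A * (1 - A) + (n1 - 1) * (q1 - A^2) + (n0 - 1) * (q2 - A^2)) /
         (n1 * n0))
}

# Two-class Gaussian scores with mean gap d (unit noise), n/2 per class.
gaussian_scores <- function(n, d, seed) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    list(scores = stats::rnorm(n, d * (y - 0.5)), labels = y)
  })
}

# Small population with a single signal on one view, for predictor tests.
small_population <- function(n, d_sex = 0, d_age = 0, d_race = 0, seed = 1,
                             feature_dim = 8) {
  generate_population(
    population_spec(n, feature_dim = feature_dim, views = "a4c",
                    d_sex = d_sex, d_age = d_age, d_race = d_race,
                    seed = seed),
    comorbidities = FALSE
  )
}
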