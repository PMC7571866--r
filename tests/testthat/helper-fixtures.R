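# Shared fixtures, computed lazily and cached for the whole run so the
# expensive default cohort is only generated once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_chirp <- function() cached("chirp", chirp_spec())

clean_chirp_rec <- function() {
  cached("clean_rec", generate_chirp(default_chirp()))
}

default_cohort <- function() {
  cached("cohort", generate_cohort(cohort_config()))
}

default_features <- function() {
  cached("features", cohort_feature_table(default_cohort()))
}

# small cohort for fast unit-level checks
small_cohort <- function() {
  cached("small_cohort",
         generate_cohort(cohort_config(n_healthy = 20, n_acs = 6, seed = 7)))
}

small_features <- function() {
  cached("small_features", cohort_feature_table(small_cohort()))
}

# a linearly separable imbalanced toy problem in 2 features
toy_separable <- function(n_major = 20, n_minor = 4) {
  feats <- data.frame(
    x = c(seq(-2, -1, length.out = n_major), seq(1, 2, length.out = n_minor)),
    y = c(seq(0, 1, length.out = n_major), seq(0, 1, length.out = n_minor)))
  list(features = feats,
       labels = rep(c("healthy", "acs"), c(n_major, n_minor)))
}

# brute-force Mann-Whitney AUC: fraction of (positive, negative) pairs the
# positive wins, half credit for ties
auc_brute <- function(scores, labels, positive = "acs") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
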