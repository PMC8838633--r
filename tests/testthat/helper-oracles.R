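# Shared helpers and independent oracles for the test suite.

# Brute-force repeated-measures correlation: explicit dummy-coded least
# squares, kept independent of the package's lm-based implementation.
# Projections are computed from normal equations on hand-built design
# matrices.
oracle_rmcorr <- function(participant, x, y) {
  ids <- unique(participant)
  D <- sapply(ids, function(id) as.numeric(participant == id)) # n x k dummies
  fit_rss <- function(X) {
    beta <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% beta)^2)
  }
  rss0 <- fit_rss(D)
  X1 <- cbind(D, x)
  beta1 <- solve(crossprod(X1), crossprod(X1, y))
  rss1 <- sum((y - X1 %*% beta1)^2)
  ss_x <- rss0 - rss1
  n <- length(y)
  df <- n - length(ids) - 1
  slope <- beta1[length(beta1)]
  f <- ss_x / (rss1 / df)
  list(r_rm = sign(slope) * sqrt(ss_x / (ss_x + rss1)),
       p = stats::pf(f, 1, df, lower.tail = FALSE),
       common_slope = slope, df = df)
}

# Random balanced repeated-measures instance for oracle comparisons.
random_rm_instance <- function(seed) {
  set.seed(seed)
  n_p <- sample(3:8, 1)
  k <- sample(3:6, 1)
  participant <- rep(sprintf("P%d", seq_len(n_p)), each = k)
  x <- stats::rnorm(n_p * k)
  y <- stats::rnorm(n_p * k)
  data.frame(participant = participant, csa = x, jva = y)
}

# A deterministic single-participant row without sampling, for scene and
# optics unit tests where exact hand-computation matters.
manual_participant <- function(sex = "F", csa_baseline = 0.6, jva_gain = 0.05,
                               hb_scale = 1.0, scm_thickness = 0.8,
                               ijv_depth = 1.2, hdt_delta = 0.2,
                               heart_rate = 60, resp_rate = 12) {
  data.frame(id = "T01", sex = sex, age = 25, bsa = 1.7, bmi = 22,
             hb_scale = hb_scale, scm_thickness = scm_thickness,
             ijv_depth = ijv_depth, csa_baseline = csa_baseline,
             jva_gain = jva_gain, hdt_delta = hdt_delta,
             heart_rate = heart_rate, resp_rate = resp_rate,
             stringsAsFactors = FALSE)
}

# Wrap a plain T x H x W array as a frame stack for chain-stage unit tests.
as_stack <- function(a, fs = 30, i0 = 1) {
  list(data = a, fs = fs, i0 = i0, height = dim(a)[2], width = dim(a)[3])
}
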