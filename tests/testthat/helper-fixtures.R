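# Shared fixtures, built once per test run and memoised.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE)) {
    assign(name, builder(), envir = .fx)
  }
  get(name, envir = .fx, inherits = FALSE)
}

# A small, fast experiment for unit tests.
small_experiment <- function() {
  fx("small_experiment", function() {
    generate_experiment(synth_config(n_precursors = 60L, seed = 7L))
  })
}

# A compact trained representation model for pipeline-level unit tests
# (full-size architecture is exercised in the acceptance suite).
small_model <- function() {
  fx("small_model", function() {
    exp1 <- generate_experiment(
      synth_config(n_precursors = 250L, fraction_present = 0.9, seed = 17L))
    ts <- generate_rsm_training_set(exp1, n_rsms = 500L, seed = 18L)
    m <- build_rep_model(units = c(32L, 16L), seed = 19L)
    train_rep_model(m, ts$rsms, ts$labels, epochs = 8L, batch_size = 128L,
                    seed = 20L, groups = ts$groups)
  })
}

# A small analyzed experiment shared by discriminant/pipeline tests:
# 30% of library precursors absent.
small_analysis <- function() {
  fx("small_analysis", function() {
    exp1 <- generate_experiment(
      synth_config(n_precursors = 120L, fraction_present = 0.7, seed = 27L))
    m <- small_model()
    res <- dia_pipeline(exp1$run, exp1$library, m, n_rt_anchors = 80L,
                        seed = 28L)
    list(experiment = exp1, model = m, results = res)
  })
}

# Brute-force Pearson (independent of the package implementation).
naive_pearson <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2)) / sqrt(sum((y - my)^2))
}

# Brute-force correlation-weighted quantity: literal double loop over the
# printed double sum, trapezoidal areas.
naive_weighted_area <- function(mat, rt) {
  n <- nrow(mat)
  area <- function(v) {
    a <- 0
    for (i in seq_len(length(v) - 1L)) {
      a <- a + (v[i] + v[i + 1L]) / 2 * (rt[i + 1L] - rt[i])
    }
    a
  }
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      cc <- if (i == j) 1 else naive_pearson(mat[i, ], mat[j, ])
      q <- q + cc * area(mat[i, ])
    }
  }
  q
}

# AUC by rank statistic.
rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
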