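# RSM assembly: shape, block layout, sorting and alignment invariants.

rsm_fixture <- function() {
  fx("rsm_fixture", function() {
    exp1 <- small_experiment()
    truth <- exp1$truth
    i <- which(truth$present & truth$precursor_charge == 2L)[1L]
    e <- exp1$library$entries[[i]]
    list(run = exp1$run, entry = e, center = truth$apex_cycle[i])
  })
}

test_that("pearson correlation follows the zero-variance convention", {
  x <- c(1, 2, 3, 2, 1)
  expect_equal(xic_pearson(x, x), 1)
  expect_equal(xic_pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(xic_pearson(rep(0, 5), x), 0)
  expect_equal(xic_pearson(rep(7, 5), x), 0)
  expect_error(xic_pearson(1:3, 1:4), "lengths differ")
})

test_that("default assembly yields the full 170 x 12 layout", {
  f <- rsm_fixture()
  rsm <- assemble_rsm(f$run, f$entry, center_cycle = f$center)
  expect_equal(dim(rsm$matrix), c(170L, 12L))
  expect_equal(unname(rsm$layout),
               c(20L, 20L, 20L, 50L, 10L, 10L, 20L, 20L))
  expect_equal(names(rsm$layout),
               c("library_r", "library_02r", "library_045r", "self", "qt3",
                 "ms1", "iso", "light"))
  expect_true(all(rsm$matrix >= 0))
})

test_that("part exclusion reproduces the ablation row-count series", {
  f <- rsm_fixture()
  drops <- list(c("light"), c("light", "iso"), c("light", "iso", "qt3"),
                c("light", "iso", "qt3", "ms1"),
                c("light", "iso", "qt3", "ms1", "self"),
                c("light", "iso", "qt3", "ms1", "self", "library_045r"),
                c("light", "iso", "qt3", "ms1", "self", "library_045r",
                  "library_02r"))
  expected <- c(150L, 130L, 120L, 110L, 60L, 40L, 20L)
  for (k in seq_along(drops)) {
    p <- rsm_params(excluded_parts = drops[[k]])
    rsm <- assemble_rsm(f$run, f$entry, center_cycle = f$center, params = p)
    expect_equal(nrow(rsm$matrix), expected[k])
  }
  expect_error(rsm_params(excluded_parts = "library_r"), "cannot exclude")
})

test_that("few library fragments zero-fill aligned rows in all blocks", {
  f <- rsm_fixture()
  e <- f$entry
  e$fragments <- e$fragments[1:5, ]
  rsm <- assemble_rsm(f$run, e, center_cycle = f$center)
  b <- rsm_blocks(rsm)
  for (part in c("library_r", "library_02r", "library_045r", "iso", "light")) {
    block <- rsm$matrix[b[[part]], ]
    expect_true(all(block[6:20, ] == 0))
  }
})

test_that("library sorting is a permutation ordered by correlation sums", {
  f <- rsm_fixture()
  p <- rsm_params()
  bundle <- precursor_xic_bundle(f$run, f$entry, p)
  rsm <- assemble_rsm(bundle, center_cycle = f$center, params = p)
  b <- rsm_blocks(rsm)
  lib <- rsm$matrix[b$library_r, ]

  # multiset of rows unchanged: sorted rows are the raw window rows permuted
  cols <- diasense:::window_columns(f$center, p$n_cycles, bundle$n_total)
  raw <- diasense:::slice_window(bundle$lib_r, cols)
  expect_equal(lib[order(rsm$library_order), ], raw)

  # the first row attains the maximal correlation-sum
  key <- vapply(seq_len(nrow(lib)), function(i) {
    sum(vapply(seq_len(nrow(lib))[-i], function(j)
      naive_pearson(lib[i, ], lib[j, ]), numeric(1)))
  }, numeric(1))
  expect_equal(which.max(key), 1L)
  expect_true(all(diff(key[seq_len(sum(rowSums(raw) > 0))]) <= 1e-9))

  # iso/light and extra resolutions follow the library order
  iso_raw <- diasense:::slice_window(bundle$iso, cols)
  expect_equal(rsm$matrix[b$iso, ], iso_raw[rsm$library_order, ])
  r02_raw <- diasense:::slice_window(bundle$lib_02r, cols)
  expect_equal(rsm$matrix[b$library_02r, ], r02_raw[rsm$library_order, ])
})

test_that("self rows are sorted by correlation with the first library row", {
  f <- rsm_fixture()
  rsm <- assemble_rsm(f$run, f$entry, center_cycle = f$center)
  b <- rsm_blocks(rsm)
  lib1 <- rsm$matrix[b$library_r[1L], ]
  cors <- apply(rsm$matrix[b$self, ], 1L, naive_pearson, y = lib1)
  expect_true(all(diff(cors) <= 1e-9))
})

test_that("narrower extraction windows never gain intensity", {
  f <- rsm_fixture()
  rsm <- assemble_rsm(f$run, f$entry, center_cycle = f$center)
  b <- rsm_blocks(rsm)
  expect_true(all(rsm$matrix[b$library_02r, ] <=
                  rsm$matrix[b$library_r, ] + 1e-9))
  expect_true(all(rsm$matrix[b$library_045r, ] <=
                  rsm$matrix[b$library_r, ] + 1e-9))
})

test_that("windows clipped at run edges are zero-padded, not shifted", {
  f <- rsm_fixture()
  rsm <- assemble_rsm(f$run, f$entry, center_cycle = 2L)
  # columns before the run start are all zero
  expect_true(all(rsm$matrix[, 1:4] == 0))
  expect_equal(ncol(rsm$matrix), 12L)
})

test_that("normalization scales to [0, 1], is idempotent and keeps zeros", {
  f <- rsm_fixture()
  rsm <- assemble_rsm(f$run, f$entry, center_cycle = f$center)
  n1 <- normalize_rsm(rsm)
  expect_equal(max(n1$matrix), 1)
  expect_true(all(n1$matrix >= 0 & n1$matrix <= 1))
  n2 <- normalize_rsm(n1)
  expect_equal(n1$matrix, n2$matrix)
  z <- matrix(0, 4, 3)
  expect_equal(normalize_rsm(z), z)
  m <- matrix(c(0, 50, 200, 100), 2)
  expect_equal(normalize_rsm(m), m / 200)
})

test_that("entries with no fragments are rejected", {
  f <- rsm_fixture()
  e <- f$entry
  e$fragments <- e$fragments[0, ]
  expect_error(assemble_rsm(f$run, e, center_cycle = f$center),
               "no library fragments")
})

test_that("the batched scanner agrees with per-window assembly", {
  f <- rsm_fixture()
  m <- small_model()
  p <- rsm_params()
  centers <- (f$center - 5L):(f$center + 5L)
  sc <- diasense:::scan_entries(f$run, list(f$entry), list(centers), m, p,
                                return_features = TRUE)[[1L]]
  for (k in c(1L, 6L, 11L)) {
    rsm <- normalize_rsm(assemble_rsm(f$run, f$entry,
                                      center_cycle = centers[k], params = p))
    out <- embed_rsm(m, rsm)
    expect_equal(sc$dds[k], out$dds, tolerance = 1e-10)
    expect_equal(as.numeric(sc$features[k, ]), as.numeric(out$features),
                 tolerance = 1e-10)
  }
})
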