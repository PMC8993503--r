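test_that("QRS cluster detection matches the worked examples", {
  labs <- rep(0L, 5000)
  labs[101:140] <- 3L   # [100, 140) 0-based
  labs[601:645] <- 3L   # [600, 645)
  cl <- find_qrs_clusters(labs, fs = 500)
  expect_equal(cl$onset, c(100L, 600L))
  expect_equal(cl$offset, c(140L, 645L))

  expect_equal(nrow(find_qrs_clusters(rep(0L, 1000), fs = 500)), 0)

  labs2 <- rep(0L, 500)
  labs2[101:110] <- 3L  # [100, 110)
  labs2[113:150] <- 3L  # [112, 150); 2-sample gap < 10-sample merge window
  cl2 <- find_qrs_clusters(labs2, fs = 500, merge_gap = 20)
  expect_equal(cl2$onset, 100L)
  expect_equal(cl2$offset, 150L)

  expect_error(find_qrs_clusters(c(0L, 9L), fs = 500),
               class = "ecgforge_invalid_argument")
})

test_that("cluster detection agrees with a naive run-length oracle", {
  set.seed(101)
  for (k in 1:200) {
    labs <- random_label_sequence(1500)
    got <- find_qrs_clusters(labs, fs = 500)
    want <- naive_qrs_oracle(labs, fs = 500)
    expect_equal(got$onset, want$onset)
    expect_equal(got$offset, want$offset)
  }
})

test_that("R-R dispersion is the population sd of onset intervals in ms", {
  cl <- tibble::tibble(onset = c(0L, 500L, 1000L), offset = c(40L, 540L, 1040L))
  expect_equal(rr_sd(cl, fs = 500), 0)

  # intervals 700 and 900 ms
  cl2 <- tibble::tibble(onset = c(0L, 350L, 800L), offset = cl$offset)
  expect_equal(rr_sd(cl2, fs = 500), 100)

  set.seed(7)
  onsets <- sort(sample.int(50000, 10))
  cl3 <- tibble::tibble(onset = onsets, offset = onsets + 40L)
  rr <- diff(onsets) / 500 * 1000
  expect_equal(rr_sd(cl3, fs = 500), sqrt(mean((rr - mean(rr))^2)))

  expect_error(rr_sd(cl[1:2, ], fs = 500), class = "ecgforge_insufficient_beats")
})

test_that("P-preceded fraction searches the pre-QRS window", {
  fs <- 500
  win <- round(0.25 * fs)
  make_seq <- function(p_flags) {
    labs <- rep(0L, 6000)
    onsets <- seq(500, by = 1000, length.out = length(p_flags))
    for (i in seq_along(onsets)) {
      q <- onsets[i]
      labs[(q + 1):(q + 40)] <- 3L
      if (p_flags[i]) {
        # 60 ms P run ending 120 ms before the onset
        labs[(q - 60 - 30 + 1):(q - 60)] <- 1L
      }
    }
    labs
  }
  labs_all <- make_seq(c(TRUE, TRUE, TRUE, TRUE))
  cl <- find_qrs_clusters(labs_all, fs)
  expect_equal(p_preceded_fraction(labs_all, cl, fs), 1.0)

  labs_none <- make_seq(c(FALSE, FALSE, FALSE, FALSE))
  expect_equal(p_preceded_fraction(labs_none, find_qrs_clusters(labs_none, fs), fs), 0.0)

  labs_half <- make_seq(c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(p_preceded_fraction(labs_half, find_qrs_clusters(labs_half, fs), fs), 0.5)

  # a cluster whose window precedes sample 0 is skipped
  labs_early <- rep(0L, 2000)
  labs_early[51:90] <- 3L     # window would start at -35
  labs_early[1001:1040] <- 3L
  cl_early <- find_qrs_clusters(labs_early, fs)
  expect_equal(p_preceded_fraction(labs_early, cl_early, fs), 0.0)

  expect_error(
    p_preceded_fraction(labs_early, cl_early[1, ], fs),
    class = "ecgforge_no_eligible_clusters"
  )
})

test_that("the rhythm rule is a strict conjunction", {
  th <- af_thresholds(0.5, 120)
  expect_identical(classify_rhythm(1.0, 5, th), "SR")
  expect_identical(classify_rhythm(0.0, 200, th), "AF")
  expect_identical(classify_rhythm(0.0, 120, th), "SR")  # boundary: not > Y
  expect_identical(classify_rhythm(0.5, 200, th), "SR")  # boundary: not < X
  expect_identical(classify_rhythm(c(0, 1), c(200, 200), th), c("AF", "SR"))
})

test_that("threshold fitting is exhaustive, deterministic, and correct on a separable set", {
  sep <- tibble::tibble(
    p_fraction = c(rep(0, 5), rep(1, 5)),
    rr_sd = c(rep(200, 5), rep(10, 5)),
    truth = c(rep("AF", 5), rep("SR", 5))
  )
  fit <- fit_thresholds(sep)
  pred <- classify_rhythm(sep$p_fraction, sep$rr_sd, fit)
  expect_identical(pred, sep$truth)
  expect_equal(fit$f1, 1.0)

  expect_identical(unclass(fit_thresholds(sep))[c("x_min_p_fraction", "y_rr_sd")],
                   unclass(fit_thresholds(sep))[c("x_min_p_fraction", "y_rr_sd")])

  expect_error(fit_thresholds(dplyr::filter(sep, truth == "AF")),
               class = "ecgforge_invalid_argument")
})

test_that("the fitted pair attains the maximum of the full 651-cell grid", {
  set.seed(31)
  feats <- tibble::tibble(
    p_fraction = c(stats::runif(20, 0, 0.6), stats::runif(20, 0.4, 1)),
    rr_sd = c(stats::runif(20, 60, 280), stats::runif(20, 5, 120)),
    truth = rep(c("AF", "SR"), each = 20)
  )
  fit <- fit_thresholds(feats)
  grid <- naive_grid_enumeration(feats, seq(0, 1, by = 0.05), seq(0, 300, by = 10))
  expect_equal(nrow(grid), 651)
  expect_equal(fit$f1, max(grid$f1))
  best <- grid[grid$f1 >= max(grid$f1) - 1e-15, ][1, ]  # same tie-break order
  expect_equal(fit$x_min_p_fraction, best$x)
  expect_equal(fit$y_rr_sd, best$y)
})

test_that("AF calls are monotone in the thresholds", {
  set.seed(5)
  p <- stats::runif(50)
  s <- stats::runif(50, 0, 300)
  n_calls <- function(x, y) sum(classify_rhythm(p, s, af_thresholds(x, y)) == "AF")
  for (y in c(0, 60, 150)) {
    counts <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(x) n_calls(x, y))
    expect_true(all(diff(counts) >= 0))  # lowering X never increases calls
  }
  for (x in c(0.3, 0.7, 1)) {
    counts <- sapply(c(0, 100, 200, 300), function(y) n_calls(x, y))
    expect_true(all(diff(counts) <= 0))  # raising Y never increases calls
  }
})

test_that("tidy and glance expose the fitted thresholds", {
  sep <- tibble::tibble(p_fraction = c(0, 0, 1, 1), rr_sd = c(200, 180, 10, 20),
                        truth = c("AF", "AF", "SR", "SR"))
  fit <- fit_thresholds(sep)
  td <- tidy(fit)
  expect_identical(td$term, c("x_min_p_fraction", "y_rr_sd"))
  gl <- glance(fit)
  expect_equal(gl$f1, 1.0)
  expect_equal(gl$n_grid, 651L)
})
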