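test_that("confusion-count metrics follow their definitions", {
  expect_equal(sensitivity(list(tp = 9, fn = 1)), 0.9)
  expect_equal(specificity(list(tn = 99, fp = 1)), 0.99)
  expect_equal(ppv(list(tp = 8, fp = 2)), 0.8)
  expect_error(ppv(list(tp = 0, fp = 0)), class = "ecgforge_undefined_metric")
  expect_error(sensitivity(list(tp = 0, fn = 0)),
               class = "ecgforge_undefined_metric")

  counts <- confusion_counts(c("AF", "AF", "SR", "SR", "AF"),
                             c("AF", "SR", "SR", "AF", "AF"), positive = "AF")
  expect_equal(unlist(counts), c(tp = 2, fp = 1, tn = 1, fn = 1))

  # invariant to simultaneous scaling of all four counts
  base <- list(tp = 3, fp = 2, tn = 10, fn = 1)
  scaled <- lapply(base, `*`, 7)
  expect_equal(sensitivity(base), sensitivity(scaled))
  expect_equal(specificity(base), specificity(scaled))
  expect_equal(ppv(base), ppv(scaled))
})

test_that("F1 is the harmonic mean of sensitivity and PPV", {
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0, 0), 0)
  # published operating points reproduce their published F1 values
  ops <- reference_operating_points()
  expect_equal(f1_score(ops$sensitivity, ops$ppv), ops$f1_published,
               tolerance = 1e-4)

  grid <- seq(0.01, 1, length.out = 100)
  for (s in grid[c(1, 25, 50, 99)]) {
    hm <- 2 / (1 / s + 1 / grid)  # harmonic mean from first principles
    expect_equal(f1_score(rep(s, 100), grid), hm)
  }
})

test_that("dice and jaccard follow the smoothed formulas and their identity", {
  a <- matrix(0L, 10, 10); b <- matrix(0L, 10, 10)
  a[1:2, 1:5] <- 1L; b[1:2, 1:5] <- 1L
  same <- dice_jaccard(a, b, class_id = 1, smooth = 0)
  expect_equal(same$dice, 1)
  expect_equal(same$iou, 1)

  # disjoint, |A| = |B| = 10, smooth = 1
  b2 <- matrix(0L, 10, 10); b2[5:6, 1:5] <- 1L
  disjoint <- dice_jaccard(a, b2, class_id = 1, smooth = 1)
  expect_equal(disjoint$dice, 1 / 21)
  expect_equal(disjoint$iou, 1 / 21)

  # |A∩B| = 5, |A| = |B| = 10, smooth = 0
  b3 <- matrix(0L, 10, 10); b3[1, 1:5] <- 1L; b3[5, 1:5] <- 1L
  partial <- dice_jaccard(a, b3, class_id = 1, smooth = 0)
  expect_equal(partial$dice, 0.5)
  expect_equal(partial$iou, 1 / 3)

  expect_error(dice_jaccard(a, matrix(0L, 5, 5)),
               class = "ecgforge_invalid_argument")

  # dice = 2*iou/(1+iou) at smooth = 0, across random masks
  set.seed(9)
  for (k in 1:20) {
    pa <- matrix(sample(0:3, 400, replace = TRUE), 20)
    pb <- matrix(sample(0:3, 400, replace = TRUE), 20)
    dj <- dice_jaccard(pa, pb, class_id = 1:3, smooth = 0)
    expect_equal(dj$dice, 2 * dj$iou / (1 + dj$iou))
  }

  # macro average attribute over the scored classes
  dj <- dice_jaccard(pa, pb, class_id = 1:3, smooth = 1)
  expect_equal(attr(dj, "macro")[["dice"]], mean(dj$dice))
})

test_that("splitting is deterministic, exact, and stratified", {
  manifest <- tibble::tibble(id = sprintf("r%03d", 1:100),
                             rhythm = rep(c("SR", "AF"), each = 50))
  s1 <- split_dataset(manifest, seed = 4)
  s2 <- split_dataset(manifest, seed = 4)
  expect_identical(s1, s2)
  expect_equal(unname(table(s1$split)["train"]), 60, ignore_attr = TRUE)
  expect_equal(unname(table(s1$split)["val"]), 20, ignore_attr = TRUE)
  expect_equal(unname(table(s1$split)["test"]), 20, ignore_attr = TRUE)
  expect_setequal(s1$id, manifest$id)
  expect_false(any(duplicated(s1$id)))

  small <- split_dataset(tibble::tibble(id = letters[1:10]), seed = 1)
  expect_equal(as.vector(table(small$split)), c(6, 2, 2))

  # stratified: per-class proportions within 2 records of the global ones
  strat <- split_dataset(manifest, seed = 11, stratify_by = "rhythm")
  joined <- dplyr::left_join(strat, manifest, by = "id")
  per_class <- table(joined$rhythm, joined$split)
  expected <- matrix(rep(c(30, 10, 10), each = 2), nrow = 2)
  expect_true(all(abs(per_class - expected) <= 2))

  expect_error(split_dataset(tibble::tibble(id = letters[1:4]), seed = 1),
               class = "ecgforge_invalid_argument")
})

test_that("group-aware splitting never straddles a group across folds", {
  manifest <- tibble::tibble(
    id = sprintf("r%03d", 1:60),
    subject = rep(sprintf("s%02d", 1:20), each = 3)
  )
  sp <- split_dataset(manifest, seed = 2, group_by = "subject")
  joined <- dplyr::left_join(sp, manifest, by = "id")
  per_subject <- tapply(joined$split, joined$subject,
                        function(x) length(unique(x)))
  expect_true(all(per_subject == 1))
})

test_that("classification_report produces the four standard rows", {
  rep_ <- classification_report(c("AF", "SR", "AF", "SR"),
                                c("AF", "SR", "SR", "AF"), positive = "AF")
  expect_identical(rep_$metric, c("Sensitivity", "Specificity", "PPV", "F1"))
  expect_equal(rep_$value[1], 0.5)
  expect_equal(rep_$value[4], f1_score(0.5, 0.5))
})
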