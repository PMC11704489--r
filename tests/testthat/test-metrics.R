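# Evaluation metrics: spot values, symmetry/triangle properties, spacing,
# and case aggregation consistency with the brute-force oracles.

test_that("dice coefficient spot values and empty-mask policy", {
  a <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(dice_coefficient(a, a), 1)
  t <- matrix(0, 4, 4); t[1:2, 1:2] <- 1          # |T| = 4
  p <- matrix(0, 4, 4); p[1:2, 1:3] <- 1          # |P| = 6, overlap 3
  p[2, 2] <- 0                                    # now |P|=5, overlap 3
  p[3, 4] <- 1                                    # |P|=6 again, overlap 3
  expect_equal(sum(p), 6); expect_equal(sum(p & t), 3)
  expect_equal(dice_coefficient(p, t), 0.6)
  expect_equal(dice_coefficient(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_error(dice_coefficient(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes")
})

test_that("hausdorff distance spot values, symmetry and spacing", {
  a <- matrix(0, 5, 6); a[1, 1] <- 1
  b <- matrix(0, 5, 6); b[4, 5] <- 1
  expect_equal(hausdorff_distance(a, b), 5)       # 3-4-5 triangle
  expect_equal(hausdorff_distance(b, a), 5)
  expect_equal(hausdorff_distance(a, a), 0)
  expect_equal(hausdorff_distance(a, b, spacing = c(2, 1)), sqrt(36 + 16))
  expect_error(hausdorff_distance(a, matrix(0, 5, 6)), "empty")
  expect_error(hausdorff_distance(a, b, spacing = c(0, 1)), "spacing")
})

test_that("boundary extraction drops interior pixels and keeps border foreground", {
  m <- matrix(0, 6, 6); m[2:5, 2:5] <- 1
  bp <- boundary_pixels(m)
  expect_equal(nrow(bp), 12)                      # ring of a 4x4 square
  expect_false(any(bp[, 1] %in% 3:4 & bp[, 2] %in% 3:4))
  edge <- matrix(1, 3, 3)  # perimeter pixels touch the border, centre does not
  expect_equal(nrow(boundary_pixels(edge)), 8)
})

test_that("confusion metrics spot values and undefined flags", {
  p <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  t <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  cm <- confusion_metrics(p, t)
  expect_equal(unname(cm$counts), c(3, 5, 1, 1))
  expect_equal(cm$AC, 0.8)
  expect_equal(cm$PR, 0.75)
  expect_equal(cm$SP, 5 / 6, tolerance = 1e-12)

  perfect <- confusion_metrics(t, t)
  expect_equal(c(perfect$AC, perfect$PR, perfect$SP), c(1, 1, 1))

  none <- confusion_metrics(rep(0, 5), c(1, 1, 0, 0, 0))
  expect_true(is.na(none$PR))
})

test_that("hausdorff symmetry and triangle-style sanity on random masks", {
  set.seed(40)
  for (i in 1:20) {
    a <- random_mask_nonempty(10)
    b <- random_mask_nonempty(10)
    c <- random_mask_nonempty(10)
    hab <- hausdorff_distance(a, b)
    expect_equal(hab, hausdorff_distance(b, a))
    expect_lte(hausdorff_distance(a, c),
               hab + hausdorff_distance(b, c) + 1e-9)
  }
})

test_that("case evaluation averages per class over cases where the class occurs", {
  t1 <- matrix(0L, 8, 8); t1[2:4, 2:4] <- 1L
  cases <- list(list(pred = t1, truth = t1))
  rep1 <- evaluate_cases(cases)
  expect_equal(rep1$mean_dsc, 1)
  expect_equal(rep1$mean_hd, 0)
  expect_equal(rep1$AC, 1)

  # two cases engineered to Dice 0.6 and 1.0 -> mean 0.8
  t2 <- matrix(0L, 4, 4); t2[1:2, 1:2] <- 1L
  p2 <- matrix(0L, 4, 4); p2[1:2, 1:3] <- 1L; p2[2, 2] <- 0L; p2[3, 4] <- 1L
  rep2 <- evaluate_cases(list(list(pred = p2, truth = t2),
                              list(pred = t2, truth = t2)))
  expect_equal(rep2$per_class$mean_dsc, 0.8)

  # class absent from ground truth is excluded
  rep3 <- evaluate_cases(list(list(pred = t1, truth = t1),
                              list(pred = matrix(0L, 8, 8),
                                   truth = matrix(0L, 8, 8))),
                         classes = 1L)
  expect_equal(rep3$per_class$n_cases, 1L)
})

test_that("multi-class stacks agree with per-class oracle recomputation", {
  set.seed(41)
  mk_stack <- function() {
    s <- array(0L, c(12, 12, 2))
    for (sl in 1:2) {
      s[2:5, 2:5, sl] <- 1L
      s[7:10, 3:6, sl] <- 2L
      s[3:6, 8:11, sl] <- 3L
    }
    s
  }
  truth <- mk_stack()
  pred <- truth
  pred[2, 2, 1] <- 0L; pred[6, 2, 1] <- 1L        # perturb class 1
  pred[7, 3, 2] <- 0L
  rep <- evaluate_cases(list(list(pred = pred, truth = truth,
                                  spacing = c(1, 1, 2.5))))
  for (k in 1:3) {
    od <- oracle_dice(pred == k, truth == k)
    expect_equal(rep$per_class$mean_dsc[k], od, info = paste("class", k))
  }
  # per-slice boundaries with slice spacing: check class 1 against the oracle
  bp_p <- rbind(cbind(oracle_boundary(pred[, , 1] == 1), 1),
                cbind(oracle_boundary(pred[, , 2] == 1), 2))
  bp_t <- rbind(cbind(oracle_boundary(truth[, , 1] == 1), 1),
                cbind(oracle_boundary(truth[, , 2] == 1), 2))
  sc <- c(1, 1, 2.5)
  dm <- matrix(0, nrow(bp_p), nrow(bp_t))
  for (i in seq_len(nrow(bp_p))) for (j in seq_len(nrow(bp_t))) {
    dm[i, j] <- sqrt(sum(((bp_p[i, ] - bp_t[j, ]) * sc)^2))
  }
  ref_hd <- max(max(apply(dm, 1, min)), max(apply(dm, 2, min)))
  expect_equal(rep$per_class$mean_hd[1], ref_hd)
})

test_that("metrics files round-trip through JSON and CSV", {
  t1 <- matrix(0L, 8, 8); t1[2:4, 2:4] <- 1L
  rep <- evaluate_cases(list(list(pred = t1, truth = t1)))
  dir <- tempfile("metrics")
  paths <- write_metrics(rep, dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(js$summary$mean_dsc, 1)
  csv <- utils::read.csv(paths[["csv"]])
  expect_equal(nrow(csv), 2)                      # one class + summary row
})

test_that("NIfTI round trip preserves labels and spacing for HD in mm", {
  skip_if_not_installed("RNifti")
  m <- array(0L, c(12, 12, 3))
  m[3:6, 3:6, ] <- 1L
  path <- tempfile(fileext = ".nii.gz")
  write_mask_nifti(m, path, spacing = c(0.8, 0.8, 2.5))
  back <- read_mask_nifti(path)
  expect_identical(back$mask, m)
  expect_equal(back$spacing, c(0.8, 0.8, 2.5))
  rep <- evaluate_cases(list(list(pred = back$mask, truth = m,
                                  spacing = back$spacing)))
  expect_equal(rep$mean_hd, 0)
})
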