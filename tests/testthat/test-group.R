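test_that("one-sample t-tests match hand computation and stats::t.test", {
  r <- one_sample_ttest(c(1, -1, 1, -1))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r2 <- one_sample_ttest(1:5)
  expect_equal(r2$t, 3 / (sqrt(2.5) / sqrt(5)))
  expect_equal(r2$df, 4)
  set.seed(10)
  x <- rnorm(24)
  r3 <- one_sample_ttest(x)
  tt <- t.test(x)
  expect_equal(r3$t, unname(tt$statistic))
  expect_equal(r3$p, tt$p.value)
  expect_equal(r3$df, 23)  # n = 24 gives the t(23) convention
})

test_that("zero-variance effects give an infinite t with warning", {
  expect_warning(r <- one_sample_ttest(rep(2, 5)), "zero variance")
  expect_equal(r$t, Inf)
  expect_equal(r$p, 0)
  expect_silent(r0 <- one_sample_ttest(rep(0, 5)))
  expect_equal(r0$t, 0)
})

# literal Benjamini-Hochberg step-up, as an independent oracle
bh_brute <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(below)) reject[o[seq_len(max(below))]] <- TRUE
  reject
}

test_that("FDR control matches the step-up definition", {
  expect_true(all(fdr_bh(c(0.01, 0.02, 0.03, 0.04), 0.05)))
  expect_false(any(fdr_bh(rep(1, 10), 0.05)))
  expect_true(fdr_bh(0.04, 0.05))
  set.seed(20)
  for (i in 1:50) {
    m <- sample(1:400, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(fdr_bh(p, q), bh_brute(p, q))
  }
})

test_that("FDR rejections are monotone in q", {
  set.seed(21)
  p <- runif(300)^2
  r1 <- fdr_bh(p, 0.02)
  r2 <- fdr_bh(p, 0.1)
  expect_true(all(r2[r1]))
})

test_that("cluster extent filtering removes small components", {
  mask <- array(FALSE, c(8, 8, 8))
  mask[4, 4, 4] <- TRUE                       # isolated voxel
  mask[1:3, 1:3, 1:3] <- TRUE                 # 27-voxel block
  out <- cluster_extent_filter(mask, k = 20)
  expect_false(out[4, 4, 4])
  expect_true(all(out[1:3, 1:3, 1:3]))
  expect_identical(cluster_extent_filter(mask, k = 1), mask)
})

test_that("cluster filtering is monotone non-increasing in k and respects connectivity", {
  set.seed(22)
  mask <- array(runif(10 * 10 * 6) < 0.3, c(10, 10, 6))
  prev <- mask
  for (k in c(2, 5, 10, 25)) {
    cur <- cluster_extent_filter(mask, k = k)
    expect_true(all(prev[cur]))  # cur is a subset of prev
    prev <- cur
  }
  # diagonal pair: disconnected at 6-connectivity, connected at 26
  m2 <- array(FALSE, c(4, 4, 4))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE
  expect_false(any(cluster_extent_filter(m2, k = 2, connectivity = 6)))
  expect_true(all(cluster_extent_filter(m2, k = 2, connectivity = 26)[
    cbind(c(1, 2), c(1, 2), c(1, 2))]))
})

test_that("conjunction is set intersection with space checking", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  b <- c(FALSE, TRUE, TRUE, FALSE)
  expect_equal(conjunction(a, b), c(FALSE, TRUE, FALSE, FALSE))
  expect_false(any(conjunction(c(TRUE, FALSE), c(FALSE, TRUE))))
  sub <- c(TRUE, FALSE, FALSE, FALSE)
  expect_equal(conjunction(sub, a), sub)  # A subset of B returns A
  set.seed(23)
  x <- runif(50) < 0.5; y <- runif(50) < 0.5
  j <- conjunction(x, y)
  expect_true(all(!j | x) && all(!j | y))
  expect_error(conjunction(array(TRUE, c(2, 2, 2)), array(TRUE, c(2, 2, 3))),
               "different unit spaces")
})

test_that("sphere ROI averaging matches exhaustive distance enumeration", {
  dm <- c(12, 12, 10)
  vox <- c(3.44, 3.44, 4.5)
  affine <- diag(c(vox, 1))
  affine[1:3, 4] <- -c(6, 6, 5) * vox  # center the grid near the origin
  set.seed(24)
  values <- array(rnorm(prod(dm)), dm)
  center_idx <- c(7, 7, 6)
  center_mm <- (affine %*% c(center_idx - 1, 1))[1:3]
  roi <- roi_spec("test", center_mm, radius = 6)
  # brute-force voxel enumeration oracle
  hits <- c(); tot <- 0
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    mm <- (affine %*% c(i - 1, j - 1, k - 1, 1))[1:3]
    if (sqrt(sum((mm - center_mm)^2)) <= 6) {
      hits <- c(hits, values[i, j, k]); tot <- tot + 1
    }
  }
  expect_gt(tot, 1)
  expect_equal(sphere_roi_average(values, affine, roi), mean(hits))
  # radius below half a voxel picks out exactly the center voxel
  tiny <- roi_spec("tiny", center_mm, radius = 1)
  expect_equal(sphere_roi_average(values, affine, tiny),
               values[center_idx[1], center_idx[2], center_idx[3]])
  # uniform field averages to the field value
  expect_equal(sphere_roi_average(array(3, dm), affine, roi), 3)
  far <- roi_spec("far", c(500, 500, 500), radius = 1)
  expect_error(sphere_roi_average(values, affine, far), "no voxel center")
})

test_that("the interference-network ROI set carries the published coordinates", {
  rois <- default_rois()
  expect_equal(rois[[1]]$center, c(2, 16, 46))
  expect_equal(vapply(rois, `[[`, "", "name"),
               c("pMFC", "IFG_L", "IFG_R", "IPL_L", "IPL_R"))
  expect_true(all(vapply(rois, `[[`, 0, "radius") == 6))
})

test_that("group thresholding combines t-tests, FDR and extent filtering", {
  set.seed(25)
  effects <- cbind(matrix(rnorm(24 * 10, 1), 24, 10),   # active units
                   matrix(rnorm(24 * 10, 0), 24, 10))   # null units
  g <- group_threshold(effects, method = "fdr", q = 0.05)
  expect_equal(g$df, 23)
  expect_gt(sum(g$mask[1:10]), 5)
  expect_lt(sum(g$mask[11:20]), 5)
})

test_that("identical congruent and incongruent values give a zero original t", {
  est <- do.call(rbind, lapply(1:6, function(s)
    data.frame(subject_id = sprintf("sub-%02d", s), unit = "pMFC",
               congruent = 1 + s / 10, incongruent = 1 + s / 10, simple = 0.5,
               beta_rt_congruent = 0.1 * s, beta_rt_incongruent = 0.1,
               beta_rt_simple = 0.1 + 0.05 * s, mean_rt_congruent = 650,
               mean_rt_incongruent = 850, mean_rt_simple = 370)))
  tab <- congruency_table(est)
  expect_equal(tab$t_original, 0)
  expect_equal(tab$df, 5)
  expect_true(all(c("t_eq_congruent", "t_eq_simple", "t_slope_msit",
                    "t_slope_simple", "t_slope_diff") %in% names(tab)))
})

test_that("volumetric maps round-trip through NIfTI with their affine", {
  skip_if_not_installed("RNifti")
  dm <- c(6, 6, 4)
  affine <- diag(c(3.44, 3.44, 4.5, 1)); affine[1:3, 4] <- c(-10, -10, -7)
  set.seed(30)
  vals <- array(rnorm(prod(dm)), dm)
  p <- tempfile(fileext = ".nii.gz")
  write_nifti(vals, affine, p)
  back <- read_nifti(p)
  expect_equal(back$values, vals, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unname(back$affine[1:3, 1:3]), unname(affine[1:3, 1:3]),
               tolerance = 1e-5)
  roi <- roi_spec("probe", c(0, 0, 0), 6)
  expect_equal(sphere_roi_average(back$values, back$affine, roi),
               sphere_roi_average(vals, affine, roi))
})
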