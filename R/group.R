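#' One-sample t-test against zero
#'
#' Random-effects group inference: per-subject effects are treated as
#' draws from a population and tested against zero with df = n - 1 and a
#' two-tailed p. A zero-variance sample with nonzero mean yields an
#' infinite t (p = 0) with a warning; an all-zero sample yields t = 0,
#' p = 1.
#'
#' @param effects numeric vector, one value per subject.
#' @return list with t, p, df, mean, se.
#' @export
one_sample_ttest <- function(effects) {
  effects <- effects[!is.na(effects)]
  n <- length(effects)
  if (n < 2) stopf("need at least 2 subjects")
  m <- mean(effects)
  s <- stats::sd(effects)
  df <- n - 1
  if (s == 0) {
    if (m == 0) return(list(t = 0, p = 1, df = df, mean = m, se = 0))
    warnf("zero variance across subjects; t is infinite")
    return(list(t = sign(m) * Inf, p = 0, df = df, mean = m, se = 0))
  }
  se <- s / sqrt(n)
  t <- m / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df, mean = m, se = se)
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up FDR control at level `q` over all supplied units.
#'
#' @param p numeric p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return logical rejection mask, same length as `p`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p values must be in [0,1]")
  stats::p.adjust(p, method = "BH") <= q
}

# 3-D neighbour offsets for the given connectivity
connectivity_offsets <- function(connectivity) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- switch(as.character(connectivity),
                 "6"  = d == 1,
                 "18" = d >= 1 & pmax(abs(off$dx), abs(off$dy), abs(off$dz)) == 1 & d <= 2,
                 "26" = d >= 1,
                 stopf("connectivity must be 6, 18 or 26"))
  as.matrix(off[keep, ])
}

#' Remove small clusters from a volumetric mask
#'
#' Labels connected components of a 3-D logical mask (default face
#' connectivity, 6 neighbours; 18 and 26 supported) and removes components
#' with fewer than `k` voxels.
#'
#' @param mask 3-D logical array.
#' @param k minimum cluster extent in voxels (default 20).
#' @param connectivity 6, 18 or 26.
#' @return logical array of the same dimension.
#' @export
cluster_extent_filter <- function(mask, k = 20, connectivity = 6) {
  dm <- dim(mask)
  if (length(dm) != 3) stopf("mask must be a 3-D array")
  if (k <= 1) return(mask)
  offs <- connectivity_offsets(connectivity)
  out <- mask
  visited <- array(FALSE, dm)
  idx_all <- which(mask)
  for (start in idx_all) {
    if (visited[start]) next
    # BFS flood fill from this seed
    comp <- integer(0)
    queue <- start
    visited[start] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      ai <- arrayInd(v, dm)
      nb <- sweep(offs, 2, as.integer(ai), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
        nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dm[1] + (nb[, 3] - 1L) * dm[1] * dm[2]
      lin <- lin[mask[lin] & !visited[lin]]
      if (length(lin)) {
        visited[lin] <- TRUE
        queue <- c(queue, lin)
      }
    }
    if (length(comp) < k) out[comp] <- FALSE
  }
  out
}

#' Conjunction of two thresholded masks
#'
#' Voxels (or units) significant in each of two independently thresholded
#' maps: the set intersection.
#'
#' @param mask_a,mask_b logical arrays/vectors in the same unit space.
#' @return logical intersection mask.
#' @export
conjunction <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a) %||% length(mask_a),
                 dim(mask_b) %||% length(mask_b)))
    stopf("masks are in different unit spaces")
  mask_a & mask_b
}

#' Sphere ROI specification
#'
#' @param name ROI label.
#' @param center numeric length-3 MNI mm coordinates.
#' @param radius sphere radius in mm (> 0).
#' @return list of class `roi_spec`.
#' @export
roi_spec <- function(name, center, radius = 6) {
  if (radius <= 0) stopf("radius must be > 0")
  if (length(center) != 3) stopf("center must be length 3 (mm)")
  structure(list(name = name, center = as.numeric(center), radius = radius),
            class = "roi_spec")
}

#' Interference-network ROI set
#'
#' The five 6-mm spheres used for orthogonal ROI analyses: posterior
#' medial frontal cortex and bilateral inferior frontal gyrus and inferior
#' parietal lobule, at coordinates from a meta-analysis of interference
#' tasks.
#'
#' @return list of [roi_spec()] objects.
#' @export
default_rois <- function() {
  list(roi_spec("pMFC", c(2, 16, 46)),
       roi_spec("IFG_L", c(-36, 16, 4)),
       roi_spec("IFG_R", c(44, 14, 8)),
       roi_spec("IPL_L", c(-36, -56, 44)),
       roi_spec("IPL_R", c(40, -52, 42)))
}

#' Average voxel values within a sphere ROI
#'
#' Unweighted mean over voxels whose center-to-center Euclidean distance
#' from the ROI center is at most the radius. Voxel centers in mm are
#' obtained from the affine (voxel indices are 0-based, as in NIfTI).
#'
#' @param values 3-D numeric array.
#' @param affine 4x4 voxel-to-mm affine.
#' @param roi a [roi_spec()].
#' @return scalar mean; error if the sphere contains no voxel center.
#' @export
sphere_roi_average <- function(values, affine, roi) {
  dm <- dim(values)
  if (length(dm) != 3) stopf("values must be a 3-D array")
  g <- expand.grid(i = 0:(dm[1] - 1), j = 0:(dm[2] - 1), k = 0:(dm[3] - 1))
  mm <- t(affine %*% rbind(t(as.matrix(g)), 1))[, 1:3]
  d2 <- (mm[, 1] - roi$center[1])^2 + (mm[, 2] - roi$center[2])^2 +
    (mm[, 3] - roi$center[3])^2
  inside <- d2 <= roi$radius^2
  if (!any(inside)) stopf("sphere ROI '%s' contains no voxel center", roi$name)
  mean(values[as.matrix(g[inside, ]) + 1L])
}

#' Group-level threshold of a unit map
#'
#' One-sample t-tests per unit, FDR (Benjamini-Hochberg) or uncorrected
#' height threshold, optional cluster-extent filtering on a voxel grid.
#'
#' @param effects subjects x units matrix of per-subject effects.
#' @param method "fdr" or "uncorrected".
#' @param q FDR level (when method = "fdr").
#' @param alpha height threshold (when method = "uncorrected").
#' @param extent_k minimum cluster size; applied only when `grid_dim` is
#'   given.
#' @param grid_dim optional 3-D dimension to reshape the unit mask into a
#'   voxel grid for extent filtering.
#' @param connectivity cluster connectivity.
#' @return list of class `group_result`: per-unit mean, t, p, df, the
#'   threshold spec and the rejection mask.
#' @export
group_threshold <- function(effects, method = c("fdr", "uncorrected"),
                            q = 0.05, alpha = 0.05, extent_k = 20,
                            grid_dim = NULL, connectivity = 6) {
  method <- match.arg(method)
  tests <- apply(effects, 2, one_sample_ttest)
  t <- vapply(tests, `[[`, 0.0, "t")
  p <- vapply(tests, `[[`, 0.0, "p")
  m <- vapply(tests, `[[`, 0.0, "mean")
  mask <- if (method == "fdr") fdr_bh(p, q) else p <= alpha
  if (!is.null(grid_dim)) {
    mask <- cluster_extent_filter(array(mask, grid_dim), k = extent_k,
                                  connectivity = connectivity)
  }
  structure(list(mean = m, t = t, p = p, df = nrow(effects) - 1,
                 mask = mask,
                 threshold = list(method = method, q = q, alpha = alpha,
                                  extent_k = extent_k)),
            class = "group_result")
}

#' Three-column congruency table with slope tests
#'
#' For each unit (ROI), random-effects t-tests of the congruency effect
#' (a) in the original data, (b) after correcting for the RT-BOLD
#' relationship in congruent trials, and (c) after correcting for the
#' RT-BOLD relationship in simple-RT trials; plus t-tests of the
#' MSIT-average and simple-task RT-BOLD slopes and of their paired
#' difference.
#'
#' @param estimates data.frame of per-subject, per-unit condition
#'   estimates (rows from [fit_subject()] stacked across subjects).
#' @return data.frame, one row per unit, with t/p columns for the three
#'   congruency contrasts and the slope tests.
#' @export
congruency_table <- function(estimates) {
  eff_con <- corrected_congruency_effect(estimates, "congruent")
  eff_sim <- corrected_congruency_effect(estimates, "simple")
  units <- unique(estimates$unit)
  rows <- lapply(units, function(u) {
    i <- estimates$unit == u
    t_orig <- one_sample_ttest(eff_con$effect_uncorrected[i])
    t_eqc <- one_sample_ttest(eff_con$effect_corrected[i])
    t_eqs <- one_sample_ttest(eff_sim$effect_corrected[i])
    sl_msit <- msit_average_slope(estimates[i, ])
    sl_simple <- estimates$beta_rt_simple[i]
    t_sl_m <- one_sample_ttest(sl_msit)
    t_sl_s <- one_sample_ttest(sl_simple)
    t_sl_d <- one_sample_ttest(sl_msit - sl_simple)
    data.frame(unit = u,
               t_original = t_orig$t, p_original = t_orig$p,
               t_eq_congruent = t_eqc$t, p_eq_congruent = t_eqc$p,
               t_eq_simple = t_eqs$t, p_eq_simple = t_eqs$p,
               t_slope_msit = t_sl_m$t, p_slope_msit = t_sl_m$p,
               t_slope_simple = t_sl_s$t, p_slope_simple = t_sl_s$p,
               t_slope_diff = t_sl_d$t, p_slope_diff = t_sl_d$p,
               df = t_orig$df, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read / write a 3-D or 4-D NIfTI image
#'
#' Thin wrappers over RNifti for the volumetric code paths (group maps and
#' sphere ROIs). RNifti must be installed.
#'
#' @param values numeric array.
#' @param affine 4x4 voxel-to-mm affine.
#' @param path file path (.nii or .nii.gz).
#' @return `read_nifti` returns a list with `values` and `affine`.
#' @export
write_nifti <- function(values, affine, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("RNifti is required for NIfTI output")
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("RNifti is required for NIfTI input")
  img <- RNifti::readNifti(path)
  list(values = as.array(img), affine = unclass(RNifti::xform(img)))
}
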