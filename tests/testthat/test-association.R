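# Build a small stack of BP_ND images: constant amygdala level + voxel noise,
# optionally with the left-amygdala mean tied to a covariate.
make_images <- function(n, atlas, seed, link = NULL, voxel_sd = 0.1) {
  withr::with_seed(seed, {
    x <- rnorm(n, 50, 10)
    imgs <- lapply(seq_len(n), function(i) {
      bp <- c(amygdala_l = 1, amygdala_r = 1)
      if (!is.null(link)) {
        # subject-level regional signal with the configured population R^2
        sd_b <- 0.15
        bp["amygdala_l"] <- 1 + sd_b * scale(x)[i] * sqrt(link) +
          sd_b * sqrt(1 - link) * rnorm(1)
      }
      simulate_bpnd_image(bp, atlas, voxel_sd = voxel_sd,
                          seed = sample.int(2^30, 1))
    })
    list(images = imgs, covariate = x)
  })
}

test_that("voxel-wise GLM t-values follow the t distribution under the null", {
  atlas <- fx_atlas()
  mask <- atlas_mask(atlas, "amygdala_l") | atlas_mask(atlas, "amygdala_r")
  d <- make_images(12, atlas, seed = 5)
  map <- voxelwise_glm(d$images, d$covariate, mask)
  tvals <- map$t[mask]
  expect_equal(map$df, 10)
  ks <- stats::ks.test(tvals, function(q) stats::pt(q, df = 10))
  expect_gt(ks$p.value, 0.01)
  # Z conversion preserves sign and order
  expect_equal(order(map$z[mask]), order(tvals))
})

test_that("the GLM is invariant to permuting subjects with their covariates", {
  atlas <- fx_atlas()
  mask <- atlas_mask(atlas, "amygdala_l")
  d <- make_images(8, atlas, seed = 6)
  m1 <- voxelwise_glm(d$images, d$covariate, mask)
  perm <- c(3, 1, 2, 8, 4, 6, 5, 7)
  m2 <- voxelwise_glm(d$images[perm], d$covariate[perm], mask)
  expect_equal(m1$t, m2$t, tolerance = 1e-12)
  expect_error(voxelwise_glm(d$images, rep(1, 8), mask), "degenerate")
  expect_error(voxelwise_glm(d$images[1:3], d$covariate[1:3], mask),
               "at least 4")
})

test_that("a linked region's signal places the peak inside its label", {
  atlas <- fx_atlas()
  mask <- atlas_mask(atlas, "amygdala_l") | atlas_mask(atlas, "amygdala_r")
  d <- make_images(20, atlas, seed = 7, link = 0.8, voxel_sd = 0.05)
  map <- voxelwise_glm(d$images, d$covariate, mask)
  peak <- which.max(abs(map$t))
  expect_true(atlas_mask(atlas, "amygdala_l")[peak])
})

test_that("permutation small-volume correction controls and degenerates sanely", {
  atlas <- fx_atlas()
  mask <- atlas_mask(atlas, "amygdala_l")
  d <- make_images(10, atlas, seed = 8)
  expect_error(fwe_smallvolume(d$images, d$covariate, mask, n_perm = 10,
                               alpha = 0.05), "n_perm too small")
  # alpha = 1: every in-mask voxel is significant
  res1 <- fwe_smallvolume(d$images, d$covariate, mask, n_perm = 100,
                          alpha = 1, seed = 2)
  expect_equal(res1$n_significant, sum(mask))
  # corrected p is monotone non-increasing in |t|
  res <- fwe_smallvolume(d$images, d$covariate, mask, n_perm = 500,
                         alpha = 0.05, seed = 2)
  tv <- abs(res$map$t[mask]); pv <- res$corrected_p[mask]
  ord <- order(tv)
  expect_true(all(diff(pv[ord]) <= 1e-12))
})

test_that("in a 1-voxel mask the corrected p matches the analytic two-tailed p", {
  atlas <- fx_atlas()
  mask <- array(FALSE, dim(atlas$labels))
  mask[which(atlas_mask(atlas, "amygdala_l"))[1]] <- TRUE
  d <- make_images(10, atlas, seed = 9)
  res <- fwe_smallvolume(d$images, d$covariate, mask, n_perm = 4000,
                         alpha = 0.5, seed = 3)
  t_obs <- res$map$t[mask]
  analytic <- 2 * stats::pt(abs(t_obs), df = 8, lower.tail = FALSE)
  expect_lt(abs(res$corrected_p[mask] - analytic), 0.03)
})

test_that("a strong amygdala link is detected in most small female cohorts", {
  atlas <- fx_atlas()
  mask <- atlas_mask(atlas, "amygdala_l") | atlas_mask(atlas, "amygdala_r")
  hits <- vapply(1:30, function(i) {
    d <- make_images(10, atlas, seed = 200 + i, link = 0.8, voxel_sd = 0.05)
    res <- fwe_smallvolume(d$images, d$covariate, mask, n_perm = 500,
                           alpha = 0.05, seed = i)
    res$n_significant > 0 &&
      any(res$clusters$direction == "positive")
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("cluster extent thresholding applies the 80 mm^3 rule at 2 mm voxels", {
  atlas <- fx_atlas()
  dims <- dim(atlas$labels)
  mask <- array(TRUE, dims)
  build_map <- function(n_supra) {
    tmap <- array(0, dims)
    # a straight run of contiguous suprathreshold voxels
    tmap[1:n_supra, 1, 1] <- 10
    zmap <- tmap
    structure(list(t = tmap, z = zmap, df = 19, n = 21, mask = mask,
                   affine = atlas$affine), class = "association_map")
  }
  ten <- cluster_threshold(build_map(10), 0.001, min_extent_mm3 = 80)
  expect_equal(nrow(ten), 1)
  expect_equal(ten$size_mm3, 80)   # 10 voxels x 8 mm^3
  expect_equal(ten$direction, "positive")
  nine <- cluster_threshold(build_map(9), 0.001, min_extent_mm3 = 80)
  expect_equal(nrow(nine), 0)      # 72 mm^3 < 80
  empty <- cluster_threshold(build_map(0), 0.001, 80)
  expect_equal(nrow(empty), 0)
})

test_that("cluster volume equals voxel count times the affine voxel volume", {
  atlas <- fx_atlas()
  dims <- dim(atlas$labels)
  tmap <- array(0, dims)
  tmap[3:5, 3:4, 3] <- -10           # 6-voxel negative cluster
  map <- structure(list(t = tmap, z = tmap, df = 19, n = 21,
                        mask = array(TRUE, dims), affine = atlas$affine),
                   class = "association_map")
  rec <- cluster_threshold(map, 0.001, min_extent_mm3 = 0)
  expect_equal(rec$size_mm3, 6 * abs(det(atlas$affine[1:3, 1:3])))
  expect_equal(rec$direction, "negative")
  # peak world coordinate maps through the affine (0-based indices)
  peak_ijk <- which(abs(tmap) == 10, arr.ind = TRUE)
  worlds <- t(atlas$affine %*% rbind(t(peak_ijk - 1), 1))[, 1:3]
  expect_true(any(abs(worlds[, 1] - rec$x) < 1e-9 &
                  abs(worlds[, 2] - rec$y) < 1e-9 &
                  abs(worlds[, 3] - rec$z) < 1e-9))
})

test_that("coincident peaks are grouped exactly and chance coincidence stays rare", {
  rec <- function(x, y, z, dir, zsc) data.frame(
    x = x, y = y, z = z, peak_z = zsc, size_mm3 = 8, direction = dir,
    p = 0.001)
  maps <- list(
    novelty = rbind(rec(8, 2, -14, "negative", 4.0), rec(0, 0, 0, "positive", 3.3)),
    persistence = rec(8, 2, -14, "negative", 3.6),
    reward = rec(-10, 4, 2, "positive", 3.4))
  co <- subthreshold_coincidence(maps)
  # only the exactly shared peak is reported, with both traits' records
  expect_equal(unique(co[, c("x", "y", "z")]), data.frame(x = 8, y = 2, z = -14))
  expect_setequal(co$trait, c("novelty", "persistence"))
  expect_equal(unique(co$n_traits), 2)
  expect_error(subthreshold_coincidence(maps[1]), "at least 2")
})

test_that("two traits driven by one regional signal share a peak within a voxel or two", {
  atlas <- fx_atlas()
  mask <- atlas$labels > 0
  d <- withr::with_seed(15, {
    x <- rnorm(12)
    imgs <- lapply(seq_len(12), function(i)
      simulate_bpnd_image(c(amygdala_l = 1 + 0.3 * x[i], amygdala_r = 1),
                          atlas, voxel_sd = 0.02, seed = 1000 + i))
    list(imgs = imgs, t1 = x + rnorm(12, 0, 0.2), t2 = -x + rnorm(12, 0, 0.2))
  })
  recs <- lapply(list(t1 = d$t1, t2 = d$t2), function(cv)
    cluster_threshold(voxelwise_glm(d$imgs, cv, mask), 0.01,
                      min_extent_mm3 = 0))
  # opposite directions, both peaking inside the left amygdala label; peak
  # voxels may differ by the voxel noise, so allow the label's extent
  co <- subthreshold_coincidence(recs, tolerance_mm = 4)
  expect_gt(nrow(co), 0)
  expect_setequal(unique(co$trait), c("t1", "t2"))
  lin <- which(atlas_mask(atlas, "amygdala_l"), arr.ind = TRUE)
  world <- t(atlas$affine %*% rbind(t(lin - 1), 1))[, 1:3, drop = FALSE]
  hit <- any(apply(world, 1, function(w)
    all(abs(w - c(co$x[1], co$y[1], co$z[1])) < 1e-9)))
  expect_true(hit)
  expect_setequal(unique(co$direction[co$trait == "t1"]), "positive")
  expect_setequal(unique(co$direction[co$trait == "t2"]), "negative")
})
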