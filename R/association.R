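# Vectorized per-voxel simple-regression t statistics: Y is V x n (voxels by
# subjects), x the covariate. t = r sqrt(df) / sqrt(1 - r^2) with df = n - 2.
voxel_t_stats <- function(Y, x) {
  n <- length(x)
  cx <- x - mean(x)
  Yc <- Y - rowMeans(Y)
  sxx <- sum(cx^2)
  sxy <- Yc %*% cx
  syy <- rowSums(Yc^2)
  r <- as.vector(sxy) / sqrt(sxx * syy)
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -1), 1)
  df <- n - 2
  t <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  list(t = t, df = df)
}

t_to_z <- function(t, df) {
  # probability-integral transform, done on the upper tail for precision
  sign(t) * stats::qnorm(stats::pt(abs(t), df, lower.tail = FALSE),
                         lower.tail = FALSE)
}

#' Voxel-wise GLM of BP_ND on a trait covariate
#'
#' At every in-mask voxel, ordinary least squares of subject BP_ND on
#' `[1, trait]`; the t statistic of the trait slope is returned along with
#' its Z-score equivalent (probability-integral transform of the t
#' distribution with n - 2 degrees of freedom).
#'
#' @param images Named list of [parametric_image]s on one grid, one per
#'   subject, in the same order as `covariate`.
#' @param covariate Numeric trait scores, one per image.
#' @param mask Logical 3D array restricting the analysis.
#' @return An object of class `association_map`: t and Z 3D arrays (0 outside
#'   the mask), `df`, `n`, the mask, and the affine.
#' @export
voxelwise_glm <- function(images, covariate, mask) {
  n <- length(images)
  if (n < 4) stop("need at least 4 subjects")
  if (length(covariate) != n)
    stop("covariate length must equal the number of images")
  if (stats::sd(covariate) == 0)
    stop("degenerate design: covariate has zero variance")
  dims <- dim(images[[1]]$values)
  for (im in images)
    check_same_grid(dims, images[[1]]$affine, dim(im$values), im$affine,
                    what = "image")
  if (!all(dim(mask) == dims)) stop("mask must match the image grid")
  idx <- which(mask)
  Y <- vapply(images, function(im) im$values[idx], numeric(length(idx)))
  Y <- matrix(Y, nrow = length(idx))
  st <- voxel_t_stats(Y, covariate)
  tmap <- array(0, dims); zmap <- array(0, dims)
  tmap[idx] <- st$t
  zmap[idx] <- t_to_z(st$t, st$df)
  structure(list(t = tmap, z = zmap, df = st$df, n = n, mask = mask,
                 affine = images[[1]]$affine),
            class = "association_map")
}

cluster_record_row <- function(peak_ijk, peak_z, size_mm3, direction, p) {
  data.frame(x = peak_ijk[1], y = peak_ijk[2], z = peak_ijk[3],
             peak_z = peak_z, size_mm3 = size_mm3, direction = direction,
             p = p)
}

# Connected components of a logical 3D array under 6- or 18-connectivity,
# via the adjacency graph of the suprathreshold voxels.
connected_components <- function(flag, connectivity = 6) {
  idx <- which(flag, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list())
  lin <- which(flag)
  dims <- dim(flag)
  key <- function(ijk) (ijk[, 3] - 1) * dims[1] * dims[2] +
    (ijk[, 2] - 1) * dims[1] + ijk[, 1]
  offsets <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  if (connectivity == 18) {
    offsets <- c(offsets, list(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
                               c(1, 0, -1), c(0, 1, 1), c(0, 1, -1)))
  } else if (connectivity != 6) stop("connectivity must be 6 or 18")
  edges <- list()
  for (off in offsets) {
    nb <- sweep(idx, 2, off, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    pos <- match(key(nb[ok, , drop = FALSE]), lin)
    src <- which(ok)[!is.na(pos)]
    dst <- pos[!is.na(pos)]
    if (length(src)) edges[[length(edges) + 1L]] <- cbind(src, dst)
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(integer(0), 0, 2),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(k) lin[comp$membership == k])
}

#' Cluster-extent thresholding of an association map
#'
#' Thresholds the map at a two-tailed uncorrected p-value (positive and
#' negative associations separately), finds connected components (default
#' 6-connectivity), drops clusters smaller than the extent threshold, and
#' reports each surviving cluster's peak in world (mm) coordinates with its
#' Z-score and volume.
#'
#' @param map An `association_map` from [voxelwise_glm()].
#' @param p_uncorrected Two-tailed voxel threshold (default 0.001).
#' @param min_extent_mm3 Minimum cluster volume (default 80 mm^3, i.e. 10
#'   voxels at 2 mm isotropic).
#' @param connectivity 6 (default) or 18.
#' @return Data frame of cluster records: peak `x`, `y`, `z` (mm), `peak_z`,
#'   `size_mm3`, `direction`, `p` (the voxel threshold used). Empty when no
#'   cluster survives.
#' @export
cluster_threshold <- function(map, p_uncorrected = 0.001,
                              min_extent_mm3 = 80, connectivity = 6) {
  stopifnot(inherits(map, "association_map"))
  tcrit <- stats::qt(1 - p_uncorrected / 2, map$df)
  vol <- voxel_volume_mm3(map$affine)
  rows <- list()
  for (dir in c("positive", "negative")) {
    flag <- if (dir == "positive") map$t > tcrit & map$mask
            else map$t < -tcrit & map$mask
    for (comp in connected_components(flag, connectivity)) {
      size <- length(comp) * vol
      if (size < min_extent_mm3 * (1 - 1e-9)) next
      zv <- map$z[comp]
      peak_lin <- comp[which.max(abs(zv))]
      ijk0 <- arrayInd(peak_lin, dim(map$t)) - 1L
      world <- voxel_to_world(map$affine, ijk0)
      rows[[length(rows) + 1L]] <- cluster_record_row(
        world[1, ], zv[which.max(abs(zv))], size, dir, p_uncorrected)
    }
  }
  if (length(rows) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      peak_z = numeric(0), size_mm3 = numeric(0),
                      direction = character(0), p = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(-abs(out$peak_z)), , drop = FALSE]
}

#' Small-volume FWE correction by max-statistic permutation
#'
#' Family-wise error control over a volume of interest: the covariate is
#' permuted across subjects `n_perm` times (seeded), the maximum |t| over the
#' VOI is recorded for each permutation, and each voxel's corrected p-value
#' is the fraction of permuted maxima at or above its observed |t| (with the
#' usual +1 correction). Exact FWER control under exchangeability, with no
#' smoothness estimation.
#'
#' @param images,covariate,mask As in [voxelwise_glm()]; `mask` is the VOI.
#' @param n_perm Number of permutations, >= 1000 recommended; must satisfy
#'   `1/n_perm <= alpha`.
#' @param alpha Corrected significance level.
#' @param seed Integer seed for the permutations.
#' @return List: `threshold` (the 1 - alpha quantile of the permutation null
#'   of max |t|), `corrected_p` (3D array, 1 outside the VOI), `n_significant`,
#'   `clusters` (records of significant-voxel clusters with corrected peak p),
#'   and the observed `map`.
#' @export
fwe_smallvolume <- function(images, covariate, mask, n_perm = 1000,
                            alpha = 0.05, seed = 1L) {
  if (sum(mask) == 0) stop("VOI mask is empty")
  if (1 / n_perm > alpha)
    stop("configuration error: n_perm too small to resolve alpha = ", alpha)
  map <- voxelwise_glm(images, covariate, mask)
  idx <- which(mask)
  dims <- dim(images[[1]]$values)
  Y <- vapply(images, function(im) im$values[idx], numeric(length(idx)))
  Y <- matrix(Y, nrow = length(idx))
  n <- length(covariate)
  perm_x <- withr::with_seed(seed,
    vapply(seq_len(n_perm), function(i) sample(covariate), numeric(n)))
  # all permutations at once through the correlation form of the t statistic
  df <- n - 2
  Xc <- sweep(perm_x, 2, colMeans(perm_x))
  Yc <- Y - rowMeans(Y)
  r <- (Yc %*% Xc) / sqrt(outer(rowSums(Yc^2), colSums(Xc^2)))
  r[!is.finite(r)] <- 0
  tperm <- abs(r) * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  max_null <- apply(tperm, 2, max)

  t_obs <- abs(map$t[idx])
  corrected_p <- vapply(t_obs, function(tv)
    (1 + sum(max_null >= tv)) / (n_perm + 1), numeric(1))
  pmap <- array(1, dims)
  pmap[idx] <- corrected_p
  sig <- array(FALSE, dims)
  sig[idx] <- corrected_p <= alpha

  rows <- list()
  vol <- voxel_volume_mm3(map$affine)
  for (comp in connected_components(sig, 6)) {
    zv <- map$z[comp]
    pk <- which.max(abs(zv))
    world <- voxel_to_world(map$affine, arrayInd(comp[pk], dims) - 1L)
    rows[[length(rows) + 1L]] <- cluster_record_row(
      world[1, ], zv[pk], length(comp) * vol,
      if (map$t[comp[pk]] >= 0) "positive" else "negative",
      pmap[comp[pk]])
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               peak_z = numeric(0), size_mm3 = numeric(0),
               direction = character(0), p = numeric(0))
  list(threshold = unname(stats::quantile(max_null, 1 - alpha, type = 1)),
       corrected_p = pmap, n_significant = sum(sig), significant = sig,
       clusters = clusters, map = map)
}

#' Coincident sub-threshold peaks across trait maps
#'
#' Groups cluster records from several trait analyses whose peak world
#' coordinates agree within a tolerance (default exact match) and reports
#' peaks shared by at least two traits, with each trait's direction and
#' Z-score. Used for the below-extent-threshold clusters that recur at
#' identical coordinates across traits.
#'
#' @param maps Named list (by trait) of cluster-record data frames, as
#'   returned by [cluster_threshold()] (typically with `min_extent_mm3 = 0`
#'   so sub-extent clusters are retained).
#' @param tolerance_mm Maximum coordinate-wise distance for two peaks to
#'   count as identical (default 0).
#' @return Data frame: one row per (shared peak, trait) with `x`, `y`, `z`,
#'   `n_traits`, `trait`, `direction`, `peak_z`.
#' @export
subthreshold_coincidence <- function(maps, tolerance_mm = 0) {
  if (length(maps) < 2) stop("need cluster records from at least 2 traits")
  all_rows <- do.call(rbind, lapply(names(maps), function(tr) {
    d <- maps[[tr]]
    if (nrow(d) == 0) return(NULL)
    cbind(trait = tr, d)
  }))
  if (is.null(all_rows) || nrow(all_rows) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      n_traits = integer(0), trait = character(0),
                      direction = character(0), peak_z = numeric(0)))
  coords <- as.matrix(all_rows[, c("x", "y", "z")])
  groups <- rep(NA_integer_, nrow(coords))
  g <- 0L
  for (i in seq_len(nrow(coords))) {
    if (!is.na(groups[i])) next
    g <- g + 1L
    near <- apply(abs(sweep(coords, 2, coords[i, ])), 1, max) <= tolerance_mm
    groups[near & is.na(groups)] <- g
  }
  all_rows$group <- groups
  out <- do.call(rbind, lapply(split(all_rows, groups), function(d) {
    traits <- unique(d$trait)
    if (length(traits) < 2) return(NULL)
    data.frame(x = d$x[1], y = d$y[1], z = d$z[1], n_traits = length(traits),
               trait = d$trait, direction = d$direction, peak_z = d$peak_z)
  }))
  if (is.null(out))
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      n_traits = integer(0), trait = character(0),
                      direction = character(0), peak_z = numeric(0))
  rownames(out) <- NULL
  out
}
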