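#' Mean regional time-activity curve from a dynamic image
#'
#' Averages the voxel curves of one atlas region into a single [tac] at the
#' frame midpoints.
#'
#' @param image A [dynamic_image].
#' @param atlas A [voi_atlas] on the same grid.
#' @param region Region name.
#' @return A [tac] labelled with the region name.
#' @export
region_tac <- function(image, atlas, region) {
  stopifnot(inherits(image, "dynamic_image"))
  check_same_grid(dim(image$voxels)[1:3], image$affine,
                  dim(atlas$labels), atlas$affine)
  idx <- which(atlas_mask(atlas, region))
  if (length(idx) == 0) stop("empty atlas label: ", region)
  nk <- dim(image$voxels)[4]
  flat <- matrix(image$voxels, prod(dim(image$voxels)[1:3]), nk)
  tac(frame_midpoints(image$schedule),
      colMeans(flat[idx, , drop = FALSE]), label = region)
}

region_side <- function(region) {
  if (grepl("_l$", region)) "L" else if (grepl("_r$", region)) "R" else ""
}

#' Extract regional BP_ND means from a parametric image
#'
#' Mean BP_ND over the voxels of every atlas label, one row per region, plus
#' a composite `thalamus` row (mean over the voxels of the 5 thalamic
#' subregions) when those are present. Empty labels are dropped with a
#' warning.
#'
#' @param image A [parametric_image].
#' @param atlas A [voi_atlas] on the same grid.
#' @param stat Summary over voxels: `"mean"` (standard VOI practice, default)
#'   or `"median"`.
#' @return Data frame with columns `region`, `side`, `bpnd`, `n_voxels`.
#' @export
extract_regional_bpnd <- function(image, atlas, stat = c("mean", "median")) {
  stopifnot(inherits(image, "parametric_image"), inherits(atlas, "voi_atlas"))
  stat <- match.arg(stat)
  check_same_grid(dim(image$values), image$affine,
                  dim(atlas$labels), atlas$affine)
  fun <- if (stat == "mean") mean else stats::median
  rows <- lapply(atlas_regions(atlas), function(r) {
    idx <- which(atlas$labels == atlas$name_map[[r]])
    if (length(idx) == 0) {
      warning("empty atlas label: ", r, "; row omitted")
      return(NULL)
    }
    data.frame(region = r, side = region_side(r),
               bpnd = fun(image$values[idx]), n_voxels = length(idx))
  })
  out <- do.call(rbind, rows)
  sub <- intersect(thalamus_subregions(), out$region)
  if (length(sub) == length(thalamus_subregions())) {
    idx <- which(atlas$labels %in% atlas$name_map[sub])
    out <- rbind(out, data.frame(region = "thalamus", side = "",
                                 bpnd = fun(image$values[idx]),
                                 n_voxels = length(idx)))
  }
  rownames(out) <- NULL
  out
}

#' Assemble a cohort regional BP_ND table
#'
#' Binds per-subject regional extractions into the long table used by the
#' statistical layers: one row per subject x region.
#'
#' @param images Named list of [parametric_image]s, names = subject ids.
#' @param atlas A [voi_atlas].
#' @param cohort Cohort data frame with `id` and `sex`.
#' @return Data frame `id`, `sex`, `region`, `side`, `bpnd`, `n_voxels`.
#' @export
cohort_regional_table <- function(images, atlas, cohort) {
  stopifnot(all(names(images) %in% cohort$id))
  rows <- lapply(names(images), function(sid) {
    tab <- extract_regional_bpnd(images[[sid]], atlas)
    cbind(id = sid, sex = cohort$sex[match(sid, cohort$id)], tab)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-region sex-difference t-tests
#'
#' Two-sample t-test (Welch by default) of regional BP_ND between females and
#' males, two-tailed, flagged at P < 0.05.
#'
#' @param table Regional table from [cohort_regional_table()].
#' @param var_equal Use the pooled-variance (Student) t-test instead of
#'   Welch's.
#' @param alpha Significance level for the flag.
#' @return Data frame: `region`, group means, `t`, `df`, `p`, `significant`.
#' @export
sex_difference_tests <- function(table, var_equal = FALSE, alpha = 0.05) {
  if (length(setdiff(c("F", "M"), unique(as.character(table$sex)))) > 0)
    stop("configuration error: both sexes must be present")
  regions <- unique(table$region)
  rows <- lapply(regions, function(r) {
    d <- table[table$region == r, ]
    f <- d$bpnd[d$sex == "F"]; m <- d$bpnd[d$sex == "M"]
    if (stats::sd(c(f, m)) == 0) {
      return(data.frame(region = r, mean_f = mean(f), mean_m = mean(m),
                        t = 0, df = length(f) + length(m) - 2, p = 1,
                        significant = FALSE))
    }
    tt <- stats::t.test(m, f, var.equal = var_equal)
    data.frame(region = r, mean_f = mean(f), mean_m = mean(m),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, significant = tt$p.value < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' VOI-level trait regression
#'
#' Simple OLS of a trait score on regional BP_ND over the (optionally
#' sex-filtered) cohort, reporting slope, intercept, R^2, the association
#' direction, and the two-tailed p-value of the slope.
#'
#' @param table Regional table from [cohort_regional_table()].
#' @param cohort Cohort covariate data frame.
#' @param trait Trait column name in `cohort` (e.g. `"baq_total"`).
#' @param region Region name in `table`.
#' @param sex `"F"`, `"M"`, or `NULL` (pooled).
#' @return A one-row data frame of class `regression_result`.
#' @export
voi_trait_regression <- function(table, cohort, trait, region, sex = NULL) {
  if (!trait %in% names(cohort)) stop("trait not in cohort table: ", trait)
  d <- table[table$region == region, c("id", "bpnd")]
  if (nrow(d) == 0) stop("region not in table: ", region)
  d <- merge(d, cohort[, c("id", "sex", trait)], by = "id")
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  if (nrow(d) < 3) stop("insufficient data: fewer than 3 subjects after filtering")
  if (stats::sd(d$bpnd) == 0)
    stop("degenerate predictor: regional BP_ND is constant")
  fit <- stats::lm(d[[trait]] ~ d$bpnd)
  sm <- summary(fit)
  beta <- unname(stats::coef(fit)[2])
  out <- data.frame(trait = trait, region = region,
                    sex = if (is.null(sex)) "all" else sex,
                    slope = beta, intercept = unname(stats::coef(fit)[1]),
                    r2 = sm$r.squared,
                    direction = if (beta >= 0) "positive" else "negative",
                    p = sm$coefficients[2, 4], n = nrow(d))
  class(out) <- c("regression_result", class(out))
  out
}

#' Regional association check for plasma hormone levels
#'
#' Regresses a hormone level (estradiol for females, free testosterone for
#' males, measured in plasma) on regional BP_ND for every region, within the
#' sex the hormone is quantifiable in, with Bonferroni control over regions.
#' Regions with fewer than `min_n` quantifiable values are skipped with a
#' warning (small-n guard).
#'
#' @param table Regional table from [cohort_regional_table()].
#' @param cohort Cohort covariate data frame containing `hormone` column.
#' @param hormone Hormone column name.
#' @param sex Sex to analyse (the sex the hormone is quantifiable in).
#' @param min_n Minimum quantifiable sample size per region.
#' @param adjust Multiplicity adjustment over regions (see
#'   [stats::p.adjust()]).
#' @param alpha Significance level after adjustment.
#' @return List with `results` (per-region data frame including adjusted
#'   p-values) and `any_significant`.
#' @export
hormone_association_check <- function(table, cohort, hormone, sex,
                                      min_n = 3, adjust = "bonferroni",
                                      alpha = 0.05) {
  if (!hormone %in% names(cohort)) stop("hormone column not found: ", hormone)
  sub <- cohort[cohort$sex == sex & !is.na(cohort[[hormone]]), ]
  if (nrow(sub) == 0)
    stop("configuration error: no quantifiable ", hormone, " values for sex ", sex)
  rows <- list()
  for (r in unique(table$region)) {
    d <- merge(table[table$region == r, c("id", "bpnd")],
               sub[, c("id", hormone)], by = "id")
    if (nrow(d) < min_n) {
      warning("insufficient data for region ", r, " (n = ", nrow(d),
              "); skipped")
      next
    }
    if (stats::sd(d$bpnd) == 0) next
    fit <- summary(stats::lm(d[[hormone]] ~ d$bpnd))
    rows[[r]] <- data.frame(region = r, slope = fit$coefficients[2, 1],
                            r2 = fit$r.squared, p = fit$coefficients[2, 4],
                            n = nrow(d))
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(list(results = NULL, any_significant = FALSE))
  res$p_adj <- stats::p.adjust(res$p, method = adjust)
  res$significant <- res$p_adj < alpha
  rownames(res) <- NULL
  list(results = res, any_significant = any(res$significant))
}
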