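#' Voxel-wise DICE similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks return 1 with a warning.
#'
#' @param a,b logical arrays of identical dimension.
#' @return DICE fraction in `[0, 1]`.
#' @export
voxel_dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    warning("both masks empty; DICE defined as 1")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' Compartment volumes of a label map
#'
#' Voxel counts times voxel volume; the wall is myocardium plus scar.
#'
#' @param labels an `lv_labelmap`.
#' @return list with `cavity_ml`, `wall_ml`, `scar_ml`, `scar_fraction`.
#' @export
compartment_volumes <- function(labels) {
  stopifnot(inherits(labels, "lv_labelmap"))
  vv <- labels$voxel^3 / 1000
  cav <- sum(labels$data == LBL[["cavity"]]) * vv
  scar <- sum(labels$data == LBL[["scar"]]) * vv
  wall <- sum(labels$data == LBL[["myocardium"]]) * vv + scar
  list(cavity_ml = cav, wall_ml = wall, scar_ml = scar,
       scar_fraction = if (wall > 0) scar / wall else 0)
}

#' Paired ratio test on log-ratios
#'
#' Per-subject ratios `x_ex / x_in` are tested on the log scale (two-tailed
#' paired t-test of log-ratios against zero), which treats the two
#' conditions symmetrically; the geometric mean ratio and its 95% CI are
#' reported on the ratio scale.
#'
#' @param x_in,x_ex paired positive measurements.
#' @return list with `mean_ratio`, `ci` (length 2), `p`, `t`, `df`.
#' @export
paired_ratio_test <- function(x_in, x_ex) {
  stopifnot(length(x_in) == length(x_ex), all(x_in > 0), all(x_ex > 0))
  lr <- log(x_ex / x_in)
  if (length(lr) < 2 || sd(lr) == 0) {
    warning("zero variance of log-ratios; p undefined")
    r <- exp(mean(lr))
    return(list(mean_ratio = r, ci = c(r, r), p = NA_real_, t = NA_real_,
                df = length(lr) - 1))
  }
  tt <- t.test(lr)
  list(mean_ratio = exp(mean(lr)), ci = exp(tt$conf.int), p = tt$p.value,
       t = unname(tt$statistic), df = unname(tt$parameter))
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' @param values numeric response.
#' @param groups factor (or coercible) of group labels.
#' @return list with `F`, `df` (length 2), `p`, `tukey` (matrix of pairwise
#'   differences, CIs and adjusted p values).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  if (sd(values) == 0)  # all observations identical: no effect by definition
    return(list(F = 0, df = c(nlevels(groups) - 1,
                              length(values) - nlevels(groups)),
                p = 1, tukey = NULL))
  fit <- aov(values ~ groups)
  an <- summary(fit)[[1]]
  Fv <- an[["F value"]][1]
  if (!is.finite(Fv)) Fv <- 0  # all groups constant
  p <- an[["Pr(>F)"]][1]
  if (!is.finite(p)) p <- 1
  tk <- tryCatch(TukeyHSD(fit)$groups, error = function(e) NULL)
  list(F = Fv, df = an[["Df"]], p = p, tukey = tk)
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x`; a constant response yields slope 0
#' and R-squared 0.
#'
#' @param x,y numeric vectors.
#' @return list with `slope`, `intercept`, `r_squared`, `p`.
#' @export
regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (sd(y) == 0)
    return(list(slope = 0, intercept = mean(y), r_squared = 0, p = NA_real_))
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))  # exact fits trigger a precision warning
  r2 <- s$r.squared
  if (!is.finite(r2)) r2 <- 0
  p <- if (nrow(s$coefficients) < 2) NA_real_ else s$coefficients[2, 4]
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, p = p)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard W statistic.
#'
#' @param x numeric sample (3 <= n <= 5000).
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3) stop("need at least 3 observations")
  sw <- shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Per-bin proportional wall-thickness change between conditions
#'
#' Nodes of the in-vivo endocardial mesh are paired by nearest neighbour
#' with the (aligned) comparison mesh; the per-node change is
#' `100 * (t_cmp - t_in) / t_in` and is aggregated over the in-vivo
#' transmurality bins: healthy (scar flag false), low transmurality
#' `(0, 0.5]` and high transmurality `(0.5, 1]`.
#'
#' @param invivo_mesh attributed in-vivo endocardial mesh (needs
#'   `thickness_mm`, `transmurality`, `scar_flag`).
#' @param cmp_mesh attributed comparison mesh, already aligned into the
#'   in-vivo frame (native comparison: transformed through the inverse of
#'   the landmark rigid transform; post-registration comparison: extracted
#'   from the registered label map).
#' @return data frame with one row per bin: `bin`, `n`, `mean_pct`,
#'   `sd_pct`; per-node values attached as attribute `per_node`.
#' @export
thickness_change_by_bin <- function(invivo_mesh, cmp_mesh) {
  ain <- invivo_mesh$attributes
  acm <- cmp_mesh$attributes
  stopifnot(!is.null(ain$thickness_mm), !is.null(acm$thickness_mm),
            !is.null(ain$transmurality), !is.null(ain$scar_flag))
  idx <- cpp_nn_index(invivo_mesh$vertices, cmp_mesh$vertices)
  t_in <- ain$thickness_mm
  t_cmp <- acm$thickness_mm[idx]
  dpct <- 100 * (t_cmp - t_in) / t_in
  tau <- ain$transmurality
  bin <- ifelse(!ain$scar_flag, "healthy", ifelse(tau <= 0.5, "low", "high"))
  bin <- factor(bin, levels = c("healthy", "low", "high"))
  ok <- is.finite(dpct)
  out <- data.frame(
    bin = levels(bin),
    n = as.integer(tapply(ok, bin, sum, default = 0L)),
    mean_pct = as.numeric(tapply(dpct[ok], bin[ok], mean)),
    sd_pct = as.numeric(tapply(dpct[ok], bin[ok], sd))
  )
  attr(out, "per_node") <- data.frame(delta_pct = dpct, bin = bin)
  out
}
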