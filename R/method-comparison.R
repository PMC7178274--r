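# Interchangeability statistics for marker-based vs EGS migration:
# Bland-Altman agreement against the RSA accuracy thresholds, one-sample
# t-test on intermethod differences, and Pearson correlation of differences
# against head-taper migration with Fisher-Z inference.

#' Bland-Altman agreement analysis
#'
#' Paired differences `a - b`, limits of agreement `mean +- 1.96 sd`
#' (sample SD, divisor n-1). The two methods are declared within the RSA
#' agreement threshold when both limits lie inside it; defaults are the
#' upper limit of RSA accuracy, 0.5 mm for translations and 1.15 degrees
#' for rotations.
#'
#' @param a,b paired measurement series of equal length, n >= 2.
#' @param threshold agreement threshold in the unit of `a` and `b`.
#' @return list of class `bland_altman`: `mean_difference`,
#'   `sd_difference`, `loa_lower`, `loa_upper`, `n`, `threshold`,
#'   `within_threshold`.
#' @export
bland_altman <- function(a, b, threshold = 0.5) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("paired series must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  loa <- m + c(-1, 1) * 1.96 * s
  structure(list(mean_difference = m, sd_difference = s,
                 loa_lower = loa[1], loa_upper = loa[2],
                 n = length(d), threshold = threshold,
                 within_threshold = max(abs(loa)) <= threshold),
            class = "bland_altman")
}

#' One-sample t-test
#'
#' `t = (mean - mu0) / (sd / sqrt(n))` with `n - 1` degrees of freedom,
#' two-sided p-value.
#'
#' @param differences numeric vector, n >= 2 with nonzero variance.
#' @param mu0 null value (default 0).
#' @return list with `t`, `dof`, `p`, `mean`, `n`.
#' @export
one_sample_t <- function(differences, mu0 = 0) {
  x <- as.numeric(differences)
  n <- length(x)
  if (n < 2L) stop("need at least 2 values")
  s <- stats::sd(x)
  if (s <= 0) stop("undefined statistic: zero variance")
  t <- (mean(x) - mu0) / (s / sqrt(n))
  list(t = t, dof = n - 1L, p = 2 * stats::pt(-abs(t), n - 1L),
       mean = mean(x), n = n)
}

#' Pearson correlation with Fisher-Z inference
#'
#' Correlation between the intermethod migration difference and the
#' head-taper migration; the null `r = 0` is tested through Fisher's Z
#' transformation, `z = atanh(r) * sqrt(n - 3)`, against a standard normal
#' (two-sided).
#'
#' @param intermethod_differences,head_taper_migrations paired numeric
#'   vectors, n >= 4.
#' @return list of class `correlation_result`: `r`, `n`, `fisher_z`,
#'   `z_statistic`, `p_value`, `degenerate` (TRUE when `|r| = 1`, p
#'   reported as 0).
#' @export
correlate_diff_vs_slip <- function(intermethod_differences, head_taper_migrations) {
  x <- as.numeric(intermethod_differences)
  y <- as.numeric(head_taper_migrations)
  if (length(x) != length(y)) stop("paired series must have equal length")
  n <- length(x)
  if (n < 4L) stop("Fisher's Z test needs n > 3")
  if (stats::sd(x) <= 0 || stats::sd(y) <= 0) {
    stop("undefined correlation: constant input")
  }
  r <- stats::cor(x, y)
  degenerate <- abs(r) >= 1 - 1e-15
  if (degenerate) {
    fz <- sign(r) * Inf; zs <- sign(r) * Inf; p <- 0
  } else {
    fz <- atanh(r)
    zs <- fz * sqrt(n - 3)
    p <- 2 * stats::pnorm(-abs(zs))
  }
  structure(list(r = r, n = n, fisher_z = fz, z_statistic = zs,
                 p_value = p, degenerate = degenerate),
            class = "correlation_result")
}

#' Marker vs EGS interchangeability analysis of a study
#'
#' For each migration axis and follow-up group, compares the marker-based
#' and EGS (reference-point-corrected for translations, by default) results:
#' Bland-Altman against the RSA thresholds (0.5 mm translations, 1.15
#' degrees rotations), a one-sample t-test of the intermethod differences
#' against zero, and the Pearson/Fisher-Z correlation between intermethod
#' translation differences and head-taper migration along the same taper
#' axis (x with dx, y with dy, z with dz; rotations have no slip
#' counterpart and get `NA`).
#'
#' @param mig a [migration_table()] data.frame containing both methods.
#' @param ht a [headtaper_table()] data.frame for the same study.
#' @param egs_method which EGS variant to compare (`"egs"` keeps the
#'   slip-sensitive raw virtual-marker result; `"egs_corrected"` is the
#'   translation-comparable variant).
#' @param groups named list of visit-month vectors defining follow-up
#'   groups; default the early (3-6) and late (12-120) pools.
#' @param thresholds translation / rotation agreement thresholds.
#' @param gated_only drop records failing the RSA quality gates first.
#' @return data.frame with one row per axis and group: `axis`, `group`,
#'   `n`, `mean_diff`, `loa_lower`, `loa_upper`, `within_threshold`, `t`,
#'   `p_t`, `r`, `p_fisher`.
#' @export
interchangeability_analysis <- function(mig, ht, egs_method = "egs",
                                        groups = list(`3-6` = c(3, 6),
                                                      `12-120` = c(12, 24, 60, 120)),
                                        thresholds = c(translation = 0.5, rotation = 1.15),
                                        gated_only = TRUE) {
  if (gated_only) mig <- mig[mig$pass, ]
  axes <- c("Tx", "Ty", "Tz", "Rx", "Ry", "Rz")
  slip_of <- c(Tx = "dx", Ty = "dy", Tz = "dz")
  rows <- list()
  for (gname in names(groups)) {
    months <- groups[[gname]]
    a <- mig[mig$method == "marker" & mig$visit_months %in% months, ]
    b <- mig[mig$method == egs_method & mig$visit_months %in% months, ]
    key <- function(d) paste(d$patient_id, d$visit_months)
    common <- intersect(key(a), key(b))
    a <- a[match(common, key(a)), ]; b <- b[match(common, key(b)), ]
    h <- ht[match(common, paste(ht$patient_id, ht$visit_months)), ]
    for (ax in axes) {
      is_rot <- ax %in% c("Rx", "Ry", "Rz")
      th <- if (is_rot) thresholds[["rotation"]] else thresholds[["translation"]]
      ba <- bland_altman(b[[ax]], a[[ax]], th)
      tt <- one_sample_t(b[[ax]] - a[[ax]])
      if (!is_rot && nrow(h) >= 4 && !anyNA(h$dx)) {
        cr <- correlate_diff_vs_slip(b[[ax]] - a[[ax]], h[[slip_of[[ax]]]])
        r <- cr$r; pf <- cr$p_value
      } else {
        r <- NA_real_; pf <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        axis = ax, group = gname, n = ba$n,
        mean_diff = ba$mean_difference,
        loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
        within_threshold = ba$within_threshold,
        t = tt$t, p_t = tt$p, r = r, p_fisher = pf)
    }
  }
  do.call(rbind, rows)
}
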