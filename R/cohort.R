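#' Two-sample t test
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom (default), or Student's pooled-variance variant; two-sided p from
#' the t distribution.
#'
#' @param a,b numeric vectors, each of length >= 2 with finite variance.
#' @param variant `"welch"` (default) or `"student"`.
#' @param variable optional label carried into the result.
#' @return a `group_comparison`: list with `variable`, `group_means`
#'   (two rows of mean, sd, n), `t_statistic`, `dof`, `p_value`.
#' @export
welch_ttest <- function(a, b, variant = c("welch", "student"), variable = "") {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    abort_validation("each group needs at least 2 observations")
  if (anyNA(a) || anyNA(b)) abort_validation("missing values in input")
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  if (!is.finite(va) || !is.finite(vb) || (va == 0 && vb == 0))
    abort_validation("zero variance in both groups")
  d <- mean(a) - mean(b)
  if (variant == "welch") {
    se2 <- va / na + vb / nb
    t_stat <- d / sqrt(se2)
    dof <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t_stat <- d / sqrt(sp2 * (1 / na + 1 / nb))
    dof <- na + nb - 2
  }
  p <- 2 * pt(-abs(t_stat), dof)
  structure(list(variable = variable,
                 group_means = data.frame(mean = c(mean(a), mean(b)),
                                          sd = c(sqrt(va), sqrt(vb)),
                                          n = c(na, nb)),
                 t_statistic = t_stat, dof = dof, p_value = p),
            class = "group_comparison")
}

#' Pearson correlation with two-sided p value
#'
#' Sample Pearson r; the p value comes from `t = r sqrt((n - 2) / (1 - r^2))`
#' on `n - 2` degrees of freedom. Perfect correlations give p = 0.
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @param labels optional character pair naming `x` and `y` in the result.
#' @return a `correlation_result`: list with `x`, `y`, `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y, labels = c("x", "y")) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) abort_validation("x and y must have equal length")
  n <- length(x)
  if (n < 3) abort_validation("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) abort_validation("missing values in input")
  if (var(x) == 0 || var(y) == 0)
    abort_validation("correlation undefined for a constant input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- min(max(r, -1), 1)
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  structure(list(x = labels[1], y = labels[2], r = r, p_value = p, n = n),
            class = "correlation_result")
}

#' Cohort statistics: group table and extent correlations
#'
#' Produces the group-summary table of the emulated study — per-group mean
#' and SD of age, BCVA, CMT and of FD and LAC at each plexus, with a
#' two-group t test per row — plus the four Pearson correlations of FD and
#' LAC (per plexus) against the extent of peripheral non-perfusion.
#'
#' @param eyes eye table with `eye_id`, `npa_quadrants`, `group` and the
#'   clinical covariates (see [read_eye_table()]).
#' @param features data.frame with one row per eye and plexus: `eye_id`,
#'   `plexus`, `fd`, `lac`.
#' @param ttest `"welch"` or `"student"`.
#' @param extent_coding `"quadrants"` (correlate against the 0-4 quadrant
#'   count, default) or `"binary"` (against the NPA indicator).
#' @return a `cohort_summary`: list with `summary` (the group table),
#'   `correlations` (4-row data.frame), `n_eyes`, `n_npa`, `n_well_perfused`.
#' @export
run_cohort_analysis <- function(eyes, features, ttest = c("welch", "student"),
                                extent_coding = c("quadrants", "binary")) {
  ttest <- match.arg(ttest)
  extent_coding <- match.arg(extent_coding)
  if (!"group" %in% names(eyes)) eyes <- validate_eye_table(eyes)
  need <- expand.grid(eye_id = eyes$eye_id, plexus = c("SCP", "DCP"),
                      stringsAsFactors = FALSE)
  have <- paste(features$eye_id, features$plexus)
  miss <- need[!paste(need$eye_id, need$plexus) %in% have, , drop = FALSE]
  if (nrow(miss))
    abort_validation(sprintf("missing plexus results for: %s",
                             paste(unique(miss$eye_id), collapse = ", ")))

  wide <- eyes
  for (plx in c("SCP", "DCP")) {
    f <- features[features$plexus == plx, c("eye_id", "fd", "lac")]
    names(f) <- c("eye_id", paste0(c("fd_", "lac_"), tolower(plx)))
    wide <- merge(wide, f, by = "eye_id", sort = FALSE)
  }
  wide <- wide[match(eyes$eye_id, wide$eye_id), ]
  is_npa <- wide$group == "NPA"

  vars <- c(age_years = "Age (years)", bcva_letters = "BCVA (ETDRS letters)",
            cmt_um = "CMT (um)", fd_scp = "FD SCP", lac_scp = "LAC SCP",
            fd_dcp = "FD DCP", lac_dcp = "LAC DCP")
  rows <- lapply(names(vars), function(v) {
    cmp <- welch_ttest(wide[[v]][is_npa], wide[[v]][!is_npa],
                       variant = ttest, variable = vars[[v]])
    data.frame(variable = vars[[v]],
               npa_mean = cmp$group_means$mean[1], npa_sd = cmp$group_means$sd[1],
               wp_mean = cmp$group_means$mean[2], wp_sd = cmp$group_means$sd[2],
               t_statistic = cmp$t_statistic, dof = cmp$dof,
               p_value = cmp$p_value, stringsAsFactors = FALSE)
  })
  summary_df <- do.call(rbind, rows)

  extent <- if (extent_coding == "quadrants") wide$npa_quadrants else as.integer(is_npa)
  cors <- lapply(c("fd_scp", "fd_dcp", "lac_scp", "lac_dcp"), function(v) {
    ct <- pearson_cor(wide[[v]], extent, labels = c(v, "npa_extent"))
    data.frame(x = v, y = "npa_extent", r = ct$r, p_value = ct$p_value,
               n = ct$n, stringsAsFactors = FALSE)
  })
  structure(list(summary = summary_df,
                 correlations = do.call(rbind, cors),
                 n_eyes = nrow(wide), n_npa = sum(is_npa),
                 n_well_perfused = sum(!is_npa)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d eyes (%d NPA / %d well-perfused)\n",
              x$n_eyes, x$n_npa, x$n_well_perfused))
  df <- x$summary
  df[, -1] <- lapply(df[, -1], function(v) round(v, 4))
  print(df, row.names = FALSE)
  cat("\nCorrelations with non-perfusion extent:\n")
  cr <- x$correlations
  cr$r <- round(cr$r, 3); cr$p_value <- signif(cr$p_value, 3)
  print(cr, row.names = FALSE)
  invisible(x)
}
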