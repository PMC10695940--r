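# Per-procedure aggregation of sensitivity charts, between-group tests, and
# the agreement statistics used for model validation.

#' Group-averaged sensitivities with between-group comparisons
#'
#' Averages the per-case local sensitivities within each procedure group
#' (sample mean and n-1 standard deviation) and compares every pair of groups
#' per parameter with the two-sided Wilcoxon rank-sum test.  Parameters that
#' a procedure does not use (e.g. S_L for T2) are reported as absent for that
#' group, not as zero.
#'
#' @param charts list of [local_sensitivity()] charts, each labelled with a
#'   `procedure`.
#' @return object of class `group_summary`: data frames `summary`
#'   (group, parameter, mean, sd, n) and `comparisons` (parameter, group1,
#'   group2, p_value).
#' @export
group_average <- function(charts) {
  stopifnot(length(charts) > 0)
  labs <- vapply(charts, function(ch) as.character(ch$procedure), character(1))
  if (any(is.na(labs) | labs == "")) {
    stop("every sensitivity chart must carry a procedure label", call. = FALSE)
  }
  long <- do.call(rbind, lapply(seq_along(charts), function(i) {
    data.frame(group = labs[i], charts[[i]]$sensitivities,
               stringsAsFactors = FALSE)
  }))
  agg <- do.call(rbind, lapply(split(long, list(long$group, long$parameter),
                                     drop = TRUE), function(d) {
    data.frame(group = d$group[1], parameter = d$parameter[1],
               mean = mean(d$sensitivity_pct),
               sd = sd(d$sensitivity_pct),       # NA for single-case groups
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  groups <- unique(labs)
  comp <- NULL
  if (length(groups) >= 2) {
    for (par in unique(long$parameter)) {
      for (i in seq_len(length(groups) - 1)) {
        for (j in seq((i + 1), length(groups))) {
          a <- long$sensitivity_pct[long$group == groups[i] & long$parameter == par]
          b <- long$sensitivity_pct[long$group == groups[j] & long$parameter == par]
          if (length(a) >= 1 && length(b) >= 1) {
            p <- tryCatch(wilcoxon_rank(a, b), error = function(e) NA_real_)
            comp <- rbind(comp, data.frame(parameter = par,
                                           group1 = groups[i], group2 = groups[j],
                                           p_value = p, stringsAsFactors = FALSE))
          }
        }
      }
    }
  }
  structure(list(summary = agg, comparisons = comp, values = long),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("<group_summary> mean +/- sd local sensitivity (%) per group\n")
  print(x$summary, row.names = FALSE, digits = 4)
  if (!is.null(x$comparisons)) {
    cat("between-group Wilcoxon rank-sum p-values:\n")
    print(x$comparisons, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Independent-samples rank-sum test between two groups (the procedure groups
#' are disjoint patients).  Exact enumeration is used for small untied
#' samples (total n <= 12); otherwise mid-ranks with the normal approximation
#' and continuity correction.
#'
#' @param a,b numeric vectors (each non-empty).
#' @param paired set `TRUE` for the signed-rank variant on paired data.
#' @return the two-sided p-value.
#' @export
wilcoxon_rank <- function(a, b, paired = FALSE) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (length(unique(c(a, b))) == 1L) {
    stop("degenerate test: all values identical in both groups", call. = FALSE)
  }
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && !paired && (length(a) + length(b)) <= 12
  suppressWarnings(
    stats::wilcox.test(a, b, paired = paired, exact = exact,
                       correct = TRUE)$p.value
  )
}

#' Agreement between predicted and observed ICV
#'
#' Bland-Altman statistics (differences follow the predicted-minus-observed
#' convention), 1.96-sd limits of agreement, Pearson correlation with its
#' two-sided p-value, and the mean absolute relative error.
#'
#' @param pred predicted ICVs, ml.
#' @param obs observed ICVs, ml (same length, >= 3).
#' @return object of class `agreement_report`.
#' @export
agreement <- function(pred, obs) {
  if (length(pred) != length(obs) || length(pred) < 3) {
    stop("pred and obs must have equal length >= 3", call. = FALSE)
  }
  if (sd(pred) == 0 || sd(obs) == 0) {
    stop("zero variance in one series: correlation undefined", call. = FALSE)
  }
  diffs <- pred - obs
  md <- mean(diffs)
  sdd <- sd(diffs)
  ct <- stats::cor.test(pred, obs)
  structure(list(mean_difference = md, sd_difference = sdd,
                 limits = c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd),
                 r = unname(ct$estimate), p_value = ct$p.value,
                 mean_abs_rel_error_pct = mean(abs(diffs) / obs) * 100,
                 differences = diffs, means = (pred + obs) / 2),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("<agreement_report> mean difference %+.2f +/- %.2f ml ",
                     "(LoA %.2f to %.2f), r = %.3f (p = %.2g), ",
                     "mean |rel err| %.1f%%\n"),
              x$mean_difference, x$sd_difference, x$limits[1], x$limits[2],
              x$r, x$p_value, x$mean_abs_rel_error_pct))
  invisible(x)
}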