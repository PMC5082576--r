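# VOI quantification and cohort statistics: apply ROI templates to S/BG
# images, tabulate per-subject regional means, and run paired Wilcoxon
# signed-rank contrasts between regions or ROI sources.

#' Apply an ROI template to an S/BG image
#'
#' Per region and side, the unweighted mean of all voxel values inside
#' the mask; the bilateral value is the arithmetic mean of the two side
#' means (sides are averaged after the per-side means are computed, not
#' pooled by volume). An empty mask yields `NA` with a warning.
#'
#' @param subject a `volume3d` of kind `"sbg_ratio"`.
#' @param template an [roi_template()] on the same grid.
#' @param subject_id identifier recorded in the report.
#' @return An object of class `sbr_report`: fields `subject_id`,
#'   `per_region_side` (3 x 2 matrix, regions x R/L),
#'   `per_region_bilateral` (named vector) and `roi_source`.
#' @export
apply_rois <- function(subject, template, subject_id = "subject") {
  stopifnot(inherits(subject, "volume3d"), inherits(template, "roi_template"))
  if (subject$kind != "sbg_ratio")
    stop("quantification operates on S/BG ratio images; normalize first",
         call. = FALSE)
  check_same_grid(subject$grid, template$grid)
  prs <- matrix(NA_real_, nrow = length(REGIONS), ncol = 2,
                dimnames = list(REGIONS, SIDES))
  for (r in REGIONS) for (s in SIDES) {
    m <- template$masks[[r]][[s]]
    if (!any(m)) {
      warning("region ", r, " side ", s, " has an empty mask; reported as NA",
              call. = FALSE)
    } else {
      prs[r, s] <- mean(subject$data[m])
    }
  }
  bilateral <- rowMeans(prs)
  structure(list(subject_id = subject_id, per_region_side = prs,
                 per_region_bilateral = bilateral,
                 roi_source = template$source),
            class = "sbr_report")
}

#' @export
print.sbr_report <- function(x, ...) {
  cat(sprintf("S/BG report for %s (%s ROIs)\n", x$subject_id, x$roi_source))
  tab <- cbind(x$per_region_side, bilateral = x$per_region_bilateral)
  print(round(tab, 3))
  invisible(x)
}

#' Quantify a whole cohort through one ROI template
#'
#' Normalizes nothing — subjects must already be S/BG images. Returns
#' one [apply_rois()] report per subject.
#'
#' @param subjects list of `volume3d` S/BG images.
#' @param template an [roi_template()].
#' @return List of `sbr_report` objects.
#' @export
quantify_cohort <- function(subjects, template) {
  reports <- vector("list", length(subjects))
  ids <- names(subjects)
  if (is.null(ids)) ids <- sprintf("subj%02d", seq_along(subjects))
  for (i in seq_along(subjects))
    reports[[i]] <- apply_rois(subjects[[i]], template, ids[i])
  reports
}

#' Tabulate per-subject bilateral S/BG values for a cohort
#'
#' Long-format table of bilateral regional S/BG values, one row per
#' subject and region, with a per-region mean and sample-SD summary
#' available through [summary()].
#'
#' @param reports nonempty list of [apply_rois()] reports sharing one
#'   ROI source.
#' @return A data frame of class `sbr_cohort` with columns `subject`,
#'   `region`, `sbg` and attribute `roi_source`.
#' @export
cohort_table <- function(reports) {
  if (!is.list(reports) || length(reports) == 0)
    stop("'reports' must be a nonempty list", call. = FALSE)
  stopifnot(all(vapply(reports, inherits, TRUE, "sbr_report")))
  src <- unique(vapply(reports, `[[`, "", "roi_source"))
  if (length(src) != 1)
    stop("reports mix ROI sources (", paste(src, collapse = ", "),
         "); tabulate each source separately", call. = FALSE)
  out <- do.call(rbind, lapply(reports, function(rep)
    data.frame(subject = rep$subject_id, region = REGIONS,
               sbg = unname(rep$per_region_bilateral))))
  rownames(out) <- NULL
  attr(out, "roi_source") <- src
  class(out) <- c("sbr_cohort", "data.frame")
  out
}

#' @export
summary.sbr_cohort <- function(object, ...) {
  agg <- do.call(rbind, lapply(split(object$sbg, object$region), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))))
  agg <- data.frame(region = rownames(agg), agg, row.names = NULL)
  agg[match(REGIONS, agg$region), ]
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test. With no zero differences, no tied
#' absolute differences and n at most `exact_max_n`, the p-value comes
#' from the exact null distribution of the positive-rank sum
#' ([stats::psignrank()]); otherwise a normal approximation is used with
#' Pratt handling of zero differences (zeros are ranked, then dropped
#' from the statistic and from the null moments), tie correction, and
#' continuity correction. If every difference is zero the test is
#' degenerate and p = 1 is returned with a warning.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max_n largest n for the exact path.
#' @return List with `statistic` (positive-rank sum V), `p_value`, `n`
#'   (number of pairs, zeros included) and `method`.
#' @export
signed_rank_test <- function(x, y, exact_max_n = 25) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- x - y
  n <- length(d)
  zeros <- d == 0
  if (all(zeros)) {
    warning("all paired differences are zero; p = 1", call. = FALSE)
    return(list(statistic = 0, p_value = 1, n = n, method = "degenerate"))
  }
  has_ties <- any(duplicated(abs(d[!zeros])))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (!any(zeros) && !has_ties && n <= exact_max_n) {
    p <- min(1, 2 * min(stats::psignrank(W, n),
                        1 - stats::psignrank(W - 1, n)))
    return(list(statistic = W, p_value = p, n = n, method = "exact"))
  }
  z <- sum(zeros)
  EW <- (n * (n + 1) - z * (z + 1)) / 4
  tiecor <- 0
  av <- abs(d[!zeros])
  tt <- table(av)
  tiecor <- sum(tt^3 - tt) / 48
  VarW <- (n * (n + 1) * (2 * n + 1) - z * (z + 1) * (2 * z + 1)) / 24 - tiecor
  if (VarW <= 0) {
    warning("degenerate variance in signed-rank approximation; p = 1",
            call. = FALSE)
    return(list(statistic = W, p_value = 1, n = n, method = "normal"))
  }
  num <- W - EW
  num <- num - sign(num) * 0.5          # continuity correction
  p <- min(1, 2 * stats::pnorm(-abs(num) / sqrt(VarW)))
  list(statistic = W, p_value = p, n = n, method = "normal")
}

#' Contrast two regions across a cohort
#'
#' Paired two-sided Wilcoxon signed-rank test on per-subject bilateral
#' S/BG values of two regions (or of the same region quantified through
#' two ROI sources, if `table_b` is given). No multiple-testing
#' correction is applied.
#'
#' @param table an [cohort_table()] data frame.
#' @param region_a,region_b region names.
#' @param table_b optional second cohort table (same subjects, same
#'   order) for cross-source contrasts of `region_a`.
#' @return An object of class `region_contrast` with fields `region_a`,
#'   `region_b`, `statistic`, `p_value`, `n`, `method`.
#' @export
region_contrast <- function(table, region_a, region_b = region_a,
                            table_b = NULL) {
  pick <- function(tab, region) {
    v <- tab$sbg[tab$region == region]
    if (!length(v)) stop("region not found in table: ", region, call. = FALSE)
    v
  }
  a <- pick(table, region_a)
  b <- if (is.null(table_b)) pick(table, region_b) else pick(table_b, region_b)
  if (length(a) != length(b))
    stop("unequal numbers of paired subjects", call. = FALSE)
  if (length(a) < 5)
    warning("fewer than 5 paired subjects; the signed-rank test has little ",
            "meaning", call. = FALSE)
  res <- signed_rank_test(a, b)
  structure(list(region_a = region_a, region_b = region_b,
                 statistic = res$statistic, p_value = res$p_value,
                 n = res$n, method = res$method),
            class = "region_contrast")
}

#' @export
print.region_contrast <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): %s vs %s, n = %d, V = %g, p = %.4g\n",
              x$method, x$region_a, x$region_b, x$n, x$statistic, x$p_value))
  invisible(x)
}

#' Classify the rostrocaudal S/BG gradient of one subject
#'
#' `"rostrocaudal_decline"` if caudate exceeds anterior putamen and
#' anterior exceeds posterior putamen, each by more than a relative
#' tolerance `tau` (relative to the pair mean); `"flat"` if all pairwise
#' relative differences are within `tau`; `"other"` otherwise.
#'
#' @param report an [apply_rois()] report with all three regions.
#' @param tau relative tolerance (default 0.05).
#' @return One of `"rostrocaudal_decline"`, `"flat"`, `"other"`.
#' @export
gradient_summary <- function(report, tau = 0.05) {
  stopifnot(inherits(report, "sbr_report"))
  v <- report$per_region_bilateral[REGIONS]
  if (any(is.na(v)))
    stop("all three regions must be present", call. = FALSE)
  rel <- function(a, b) (a - b) / ((a + b) / 2)
  d12 <- rel(v[1], v[2]); d23 <- rel(v[2], v[3]); d13 <- rel(v[1], v[3])
  if (d12 > tau && d23 > tau) return("rostrocaudal_decline")
  if (all(abs(c(d12, d23, d13)) <= tau)) return("flat")
  "other"
}
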