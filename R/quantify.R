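#' Histogram of condensate areas on fixed micrometre bins
#'
#' Counts accepted objects into half-open bins `[lo, hi)` over the given
#' edges, with a final open bin `[last_edge, Inf)`. Objects below the first
#' edge are excluded from the bins and reported as a sub-threshold tally;
#' `total_count` is the number of accepted objects at or above the first
#' edge.
#'
#' @param records records data frame (only rows with `accepted == TRUE`
#'   count; rows with `accepted` NA are treated as accepted).
#' @param bin_edges_um2 strictly increasing vector of at least 2 edges.
#' @param roi_name,subject_id,group labels carried into the result.
#' @return an `area_histogram` list: `bin_edges_um2`, `bin_labels`,
#'   `counts`, `sub_threshold`, `total_count`, plus the labels.
#' @export
histogram_areas <- function(records, bin_edges_um2 = 1:5,
                            roi_name = "field", subject_id = "",
                            group = "") {
  if (length(bin_edges_um2) < 2 || any(diff(bin_edges_um2) <= 0)) {
    stop("bin_edges_um2 must be strictly increasing with >= 2 edges")
  }
  areas <- if (nrow(records) > 0) {
    keep <- is.na(records$accepted) | records$accepted
    records$area_um2[keep]
  } else numeric(0)
  k <- length(bin_edges_um2)
  edges <- c(bin_edges_um2, Inf)
  counts <- integer(k)
  for (i in seq_len(k)) {
    counts[i] <- sum(areas >= edges[i] & areas < edges[i + 1])
  }
  labels <- c(sprintf("[%g,%g)", bin_edges_um2[-k], bin_edges_um2[-1]),
              sprintf("[%g,Inf)", bin_edges_um2[k]))
  structure(list(roi_name = roi_name, subject_id = subject_id, group = group,
                 bin_edges_um2 = bin_edges_um2, bin_labels = labels,
                 counts = counts,
                 sub_threshold = sum(areas < bin_edges_um2[1]),
                 total_count = sum(counts)),
            class = "area_histogram")
}

#' Mean intensity within a region of interest
#'
#' @param raw a `plane`.
#' @param roi logical matrix (TRUE = inside), or NULL for the full field.
#' @return arithmetic mean of the intensities over the ROI pixels.
#' @export
mean_intensity <- function(raw, roi = NULL) {
  m <- as_matrix(raw)
  if (is.null(roi)) return(mean(m))
  if (!all(dim(roi) == dim(m))) stop("roi must match the image shape")
  if (!any(roi)) stop("roi is empty")
  mean(m[roi])
}

#' Two-sample unpaired t-test
#'
#' Student's pooled-variance t by default, matching the convention of an
#' unadorned "unpaired t-test"; Welch's unequal-variance form on request.
#'
#' @param a,b numeric vectors, each with >= 2 finite values and positive
#'   variance.
#' @param welch use Welch's t instead of the pooled form.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2 || !all(is.finite(c(a, b)))) {
    stop("each group needs >= 2 finite values")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("degenerate groups: both have zero variance")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Holm-Sidak step-down multiple-testing adjustment
#'
#' Sorts the raw p-values ascending, sets adjusted p at rank j to
#' `1 - (1 - p_j)^(m - j + 1)`, enforces monotonicity by a running maximum,
#' caps at 1, and returns the values in the original input order.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as `p`.
#' @export
holm_sidak_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  ord <- order(p)
  adj_sorted <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj_sorted <- pmin(cummax(adj_sorted), 1)
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

#' Compare two groups of per-subject area histograms
#'
#' Treats the subject (animal / field) as the statistical unit. For each
#' area bin the per-subject counts of the two groups are compared with an
#' unpaired t-test and the p-values are Holm-Sidak-adjusted across bins;
#' the per-subject total counts are tested separately without correction.
#' Bins in which both groups are constant get `t = 0, p = 1` when the
#' constants agree and `p = 0` when they differ.
#'
#' @param histograms list of `area_histogram` objects covering exactly two
#'   groups with >= 2 subjects each, all on identical bin edges.
#' @param welch use Welch's t instead of the pooled form.
#' @return a `group_comparison` list: `per_bin` data frame (bin label, per-
#'   group mean and SEM, t, df, raw p, adjusted p), `total` (list t/df/p and
#'   per-group means), `groups`, `n_per_group`.
#' @export
compare_groups <- function(histograms, welch = FALSE) {
  edges <- histograms[[1]]$bin_edges_um2
  for (h in histograms) {
    if (!identical(h$bin_edges_um2, edges)) stop("histograms use different bins")
  }
  groups <- vapply(histograms, `[[`, character(1), "group")
  glev <- unique(groups)
  if (length(glev) != 2) stop("exactly two group labels are required")
  if (any(table(groups) < 2)) stop("need >= 2 subjects per group")

  counts <- t(vapply(histograms, `[[`, numeric(length(histograms[[1]]$counts)),
                     "counts"))
  totals <- vapply(histograms, `[[`, numeric(1), "total_count")
  ia <- groups == glev[1]; ib <- groups == glev[2]

  test_counts <- function(a, b) {
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      same <- mean(a) == mean(b)
      return(list(t = 0, df = length(a) + length(b) - 2,
                  p = if (same) 1 else 0))
    }
    two_sample_t(a, b, welch = welch)
  }

  per_bin <- lapply(seq_len(ncol(counts)), function(j) {
    a <- counts[ia, j]; b <- counts[ib, j]
    tt <- test_counts(a, b)
    data.frame(bin = histograms[[1]]$bin_labels[j],
               mean_a = mean(a), sem_a = stats::sd(a) / sqrt(length(a)),
               mean_b = mean(b), sem_b = stats::sd(b) / sqrt(length(b)),
               t = tt$t, df = tt$df, p_raw = tt$p,
               stringsAsFactors = FALSE)
  })
  per_bin <- do.call(rbind, per_bin)
  per_bin$p_adj <- holm_sidak_adjust(per_bin$p_raw)

  tt_total <- test_counts(totals[ia], totals[ib])
  structure(list(per_bin = per_bin,
                 total = c(tt_total,
                           list(mean_a = mean(totals[ia]),
                                mean_b = mean(totals[ib]))),
                 groups = glev,
                 n_per_group = c(sum(ia), sum(ib))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison: %s (n = %d) vs %s (n = %d)\n",
              x$groups[1], x$n_per_group[1], x$groups[2], x$n_per_group[2]))
  cat(sprintf("Total count: %s %.1f vs %s %.1f, t = %.3f, df = %.1f, p = %.4g\n",
              x$groups[1], x$total$mean_a, x$groups[2], x$total$mean_b,
              x$total$t, x$total$df, x$total$p))
  cat("Per-bin tests (Holm-Sidak adjusted):\n")
  print(format(x$per_bin, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Flatten histograms into a data frame
#'
#' One row per subject x bin, plus the sub-threshold tally and total as
#' extra columns, convenient for CSV export.
#'
#' @param histograms list of `area_histogram` objects.
#' @return data frame.
#' @export
histograms_to_df <- function(histograms) {
  do.call(rbind, lapply(histograms, function(h) {
    data.frame(subject_id = h$subject_id, group = h$group,
               roi_name = h$roi_name, bin = h$bin_labels,
               count = h$counts, sub_threshold = h$sub_threshold,
               total_count = h$total_count, stringsAsFactors = FALSE)
  }))
}
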