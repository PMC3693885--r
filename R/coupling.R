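#' Per-miRNA mean-rank profile of a P-value table
#'
#' Within each subject column the P-values are ranked ascending across
#' miRNAs (average ranks for ties). Missing entries are excluded and the
#' ranks rescaled to (0, 1] by dividing by the number of non-missing
#' miRNAs in that subject, so subjects with different missingness remain
#' comparable. The profile is the per-miRNA mean of the rescaled ranks
#' over subjects.
#'
#' @param table a `pvalue_table`
#' @param direction which directional channel to rank: `"greater"` or
#'   `"less"`
#' @return named numeric vector over miRNAs (NA for all-missing miRNAs)
#' @export
mean_rank_profile <- function(table, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(inherits(table, "pvalue_table"))
  p <- if (direction == "greater") table$p_greater else table$p_less
  rr <- apply(p, 2L, function(col) {
    ok <- !is.na(col)
    out <- rep(NA_real_, length(col))
    if (any(ok)) out[ok] <- rank(col[ok]) / sum(ok)
    out
  })
  prof <- rowMeans(rr, na.rm = TRUE)
  prof[!is.finite(prof)] <- NA_real_
  names(prof) <- table$mirna_ids
  prof
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks; invariant under strictly
#' increasing transforms of either argument.
#'
#' @param x,y numeric vectors of equal length >= 3 (pairs with a missing
#'   value are dropped first)
#' @return rho in \[-1, 1\]; NA with a warning when either vector is
#'   constant after pair removal
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 complete pairs for a rank correlation")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' P-value of a Spearman correlation via the t approximation
#'
#' Two-sided P from t = rho * sqrt((M - 2) / (1 - rho^2)) against
#' Student t with M - 2 degrees of freedom.
#'
#' @param rho correlation coefficient
#' @param M number of paired observations (>= 4)
#' @return two-sided P-value; exactly 0 (with attribute `degenerate`)
#'   when |rho| = 1
#' @export
correlation_pvalue <- function(rho, M) {
  if (is.na(rho)) return(NA_real_)
  stopifnot(M >= 4L, abs(rho) <= 1)
  if (abs(rho) == 1) {
    return(structure(0, degenerate = TRUE))
  }
  tstat <- rho * sqrt((M - 2) / (1 - rho^2))
  2 * stats::pt(abs(tstat), df = M - 2, lower.tail = FALSE)
}

#' Coupling between target-gene regulation and promoter methylation
#'
#' Correlates the mRNA-regulation and methylation P-value tables of one
#' region pair across miRNAs. `rho_mean_rank` is the Spearman correlation
#' of the two per-miRNA mean-rank profiles (means of within-subject
#' P ranks over subjects). `rho_per_subject` holds, for each subject, the
#' Spearman correlation between the two tables' P columns; `delta_rho` is
#' their root mean square, which by Jensen's inequality is always at
#' least |mean(rho_j)| — per-subject correlations can be strong even when
#' positive and negative signs cancel in the aggregate.
#'
#' @param mrna_table,methyl_table `pvalue_table`s sharing miRNA set,
#'   subjects and region pair
#' @param direction directional channel used on both layers (default
#'   `"greater"`)
#' @return a `coupling_summary` list: `region_pair`, `direction`,
#'   `rho_mean_rank`, `p_value`, `rho_per_subject`, `delta_rho`, `M`,
#'   `n_subjects`
#' @export
coupling_correlation <- function(mrna_table, methyl_table,
                                 direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(inherits(mrna_table, "pvalue_table"),
            inherits(methyl_table, "pvalue_table"))
  if (!identical(mrna_table$mirna_ids, methyl_table$mirna_ids)) {
    stop("the two tables do not share the same miRNA set/order")
  }
  if (!identical(mrna_table$subject_ids, methyl_table$subject_ids)) {
    stop("the two tables do not share the same subjects")
  }
  if (!identical(mrna_table$region_pair, methyl_table$region_pair)) {
    stop("the two tables are for different region pairs")
  }
  prof_a <- mean_rank_profile(mrna_table, direction)
  prof_b <- mean_rank_profile(methyl_table, direction)
  ok <- is.finite(prof_a) & is.finite(prof_b)
  M_used <- sum(ok)
  rho <- spearman_rho(prof_a[ok], prof_b[ok])

  pa <- if (direction == "greater") mrna_table$p_greater else mrna_table$p_less
  pb <- if (direction == "greater") methyl_table$p_greater else methyl_table$p_less
  rho_j <- vapply(seq_len(ncol(pa)), function(j) {
    okj <- is.finite(pa[, j]) & is.finite(pb[, j])
    if (sum(okj) < 3L) return(NA_real_)
    suppressWarnings(spearman_rho(pa[okj, j], pb[okj, j]))
  }, 0)
  names(rho_j) <- mrna_table$subject_ids
  delta_rho <- sqrt(mean(rho_j^2, na.rm = TRUE))

  structure(list(
    region_pair = mrna_table$region_pair,
    direction = direction,
    rho_mean_rank = rho,
    p_value = correlation_pvalue(rho, M_used),
    rho_per_subject = rho_j,
    delta_rho = delta_rho,
    M = M_used,
    n_subjects = length(rho_j)
  ), class = "coupling_summary")
}

#' @export
print.coupling_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<coupling_summary> %s vs %s (direction=%s)\n",
    "  rho_mean_rank = %.4f (P = %.3g, M = %d)\n",
    "  delta_rho (RMS of %d per-subject rho_j) = %.4f\n"),
    x$region_pair[1L], x$region_pair[2L], x$direction,
    x$rho_mean_rank, x$p_value, x$M, x$n_subjects, x$delta_rho))
  invisible(x)
}
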