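#' Directional P-value table container
#'
#' Holds, for one layer and one ordered region pair, the per-miRNA,
#' per-subject one-sided P-values in both directions: `p_greater` tests
#' whether the miRNA's target genes are shifted up in region `ell`
#' relative to `ellprime` (against the non-targets), `p_less` the
#' opposite tail. Missing entries (miRNAs without usable targets for a
#' subject) are NA.
#'
#' @param layer `"mrna"` or `"methylation"`
#' @param region_pair character `c(ell, ellprime)`
#' @param p_less,p_greater numeric matrices, miRNAs x subjects, identical
#'   dimnames
#' @param method test method label
#' @return a `pvalue_table`
#' @export
new_pvalue_table <- function(layer, region_pair, p_less, p_greater, method) {
  stopifnot(identical(dim(p_less), dim(p_greater)),
            identical(dimnames(p_less), dimnames(p_greater)),
            !is.null(rownames(p_less)), !is.null(colnames(p_less)))
  ok <- function(p) all(is.na(p) | (p > 0 & p <= 1))
  if (!ok(p_less) || !ok(p_greater)) stop("P-values must lie in (0, 1]")
  structure(list(layer = layer,
                 region_pair = as.character(region_pair),
                 mirna_ids = rownames(p_less),
                 subject_ids = colnames(p_less),
                 p_less = p_less, p_greater = p_greater,
                 method = method),
            class = "pvalue_table")
}

#' @export
print.pvalue_table <- function(x, ...) {
  cat(sprintf("<pvalue_table> layer=%s  %s vs %s  %d miRNAs x %d subjects  method=%s\n",
              x$layer, x$region_pair[1L], x$region_pair[2L],
              length(x$mirna_ids), length(x$subject_ids), x$method))
  invisible(x)
}

#' Per-gene between-region difference for one subject
#'
#' For expression layers, the per-gene natural-log ratio
#' Delta_g = log(x_g,ell) - log(x_g,ellprime), with signals floored at
#' 1e-8 before the log (processed array signals can be <= 0 after
#' background correction). For methylation, the plain beta difference.
#'
#' @param study an `aligned_study`
#' @param layer layer name
#' @param region_pair `c(ell, ellprime)`
#' @param subject subject id (must be paired in both regions)
#' @return named numeric vector over the layer's features (NA where either
#'   sample value is missing)
#' @export
per_gene_delta <- function(study, layer = c("mrna", "methylation", "mirna"),
                           region_pair, subject) {
  layer <- match.arg(layer)
  if (!subject %in% paired_subjects(study, region_pair)) {
    stop("subject '", subject, "' is not paired in regions ",
         region_pair[1L], "/", region_pair[2L])
  }
  ann <- study$annotation
  s1 <- .sample_of(ann, subject, region_pair[1L])
  s2 <- .sample_of(ann, subject, region_pair[2L])
  v <- study$layers[[layer]]$values
  if (layer == "methylation") {
    v[, s1] - v[, s2]
  } else {
    .log_floor(v[, s1]) - .log_floor(v[, s2])
  }
}

# Core directional two-sample comparison on a split of delta values.
# Returns c(p_less, p_greater); NA pair when the comparison is degenerate.
.directional_test <- function(delta_t, delta_o,
                              method = c("ranksum_normal", "ranksum_exact",
                                         "ttest")) {
  method <- match.arg(method)
  nt <- length(delta_t); no <- length(delta_o)
  if (nt == 0L || no == 0L) return(c(NA_real_, NA_real_))
  if (method == "ttest") {
    mt <- mean(delta_t); mo <- mean(delta_o)
    vt <- stats::var(delta_t); vo <- stats::var(delta_o)
    if (nt < 2L || no < 2L) return(c(NA_real_, NA_real_))
    se2 <- vt / nt + vo / no
    if (se2 == 0) {
      if (mt == mo) return(c(0.5, 0.5))
      p_g <- if (mt > mo) .Machine$double.xmin else 1
      return(c(1 - p_g + .Machine$double.xmin, p_g))
    }
    tstat <- (mt - mo) / sqrt(se2)
    df <- se2^2 / ((vt / nt)^2 / (nt - 1L) + (vo / no)^2 / (no - 1L))
    p_greater <- stats::pt(tstat, df, lower.tail = FALSE)
    p_less <- stats::pt(tstat, df, lower.tail = TRUE)
  } else {
    all_r <- rank(c(delta_t, delta_o))
    u <- sum(all_r[seq_len(nt)]) - nt * (nt + 1) / 2
    ties <- any(duplicated(c(delta_t, delta_o)))
    n <- nt + no
    if (method == "ranksum_exact" && !ties && nt * no <= 40000) {
      # exact null distribution of the Mann-Whitney U statistic; both tails
      # via the lower-tail CDF and the U <-> nt*no - U reflection so that
      # negating the deltas swaps the two P-values bit-for-bit
      p_greater <- stats::pwilcox(nt * no - u, nt, no)
      p_less <- stats::pwilcox(u, nt, no)
    } else {
      if (method == "ranksum_exact") {
        warning("ranksum_exact infeasible (ties or group sizes too large); ",
                "using tie-corrected normal approximation")
      }
      mu <- nt * no / 2
      tie_tab <- table(c(delta_t, delta_o))
      tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
      sigma2 <- nt * no / 12 * ((n + 1) - tie_term)
      if (sigma2 <= 0) return(c(NA_real_, NA_real_))
      s <- sqrt(sigma2)
      cstat <- u - mu  # exact in floating point (both are multiples of 0.5)
      p_greater <- stats::pnorm((0.5 - cstat) / s)
      p_less <- stats::pnorm((0.5 + cstat) / s)
    }
  }
  c(max(min(p_less, 1), .Machine$double.xmin),
    max(min(p_greater, 1), .Machine$double.xmin))
}

#' One-sided target-set shift test
#'
#' Tests whether the per-gene differences of a miRNA's target genes are
#' stochastically greater (or less) than those of all non-target genes —
#' the per-miRNA, per-subject statistic at the core of the analysis.
#'
#' Methods: `ranksum_exact` uses the exact Mann-Whitney null distribution
#' (no ties; falls back to the normal approximation with a warning when
#' infeasible); `ranksum_normal` uses the tie- and continuity-corrected
#' normal approximation; `ttest` is one-sided Welch.
#'
#' @param delta named per-gene difference vector (see [per_gene_delta()])
#' @param targets character vector of target gene ids
#' @param direction `"greater"` or `"less"`
#' @param method test method
#' @return one-sided P-value in (0, 1], or NA when the target set or its
#'   complement is empty after removing non-finite values
#' @export
target_set_test <- function(delta, targets,
                            direction = c("greater", "less"),
                            method = c("ranksum_normal", "ranksum_exact",
                                       "ttest")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  stopifnot(!is.null(names(delta)))
  delta <- delta[is.finite(delta)]
  is_t <- names(delta) %in% targets
  p <- .directional_test(delta[is_t], delta[!is_t], method)
  if (direction == "greater") p[2L] else p[1L]
}

#' Directional P-value table for one layer and region pair
#'
#' Computes both one-sided P-values for every (miRNA, paired subject).
#' With `method = "auto"` (the default) the exact rank-sum null is used
#' whenever the smaller group has at most 10 members, the total at most
#' 200 and the differences are tie-free; otherwise the tie- and
#' continuity-corrected normal approximation. The normal path is
#' vectorised: each subject's genes are ranked once and every miRNA's
#' rank sum is read off that ranking.
#'
#' @param study an `aligned_study`
#' @param layer `"mrna"` or `"methylation"`
#' @param region_pair `c(ell, ellprime)`
#' @param method `"auto"`, `"ranksum_normal"`, `"ranksum_exact"` or
#'   `"ttest"`
#' @return a `pvalue_table`
#' @export
compute_pvalue_table <- function(study, layer = c("mrna", "methylation"),
                                 region_pair,
                                 method = c("auto", "ranksum_normal",
                                            "ranksum_exact", "ttest")) {
  layer <- match.arg(layer)
  method <- match.arg(method)
  subjects <- paired_subjects(study, region_pair)
  if (length(subjects) == 0L) {
    stop("no paired subjects for region pair ",
         .pair_key(region_pair[1L], region_pair[2L]))
  }
  tm <- study$target_map
  mirnas <- names(tm)
  M <- length(mirnas)
  S <- length(subjects)
  p_less <- matrix(NA_real_, M, S, dimnames = list(mirnas, subjects))
  p_greater <- p_less

  for (j in seq_len(S)) {
    delta <- per_gene_delta(study, layer, region_pair, subjects[j])
    delta <- delta[is.finite(delta)]
    n <- length(delta)
    if (n < 2L) next
    fast <- method %in% c("auto", "ranksum_normal")
    if (fast) {
      r <- rank(delta)
      tie_tab <- table(delta)
      tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
      has_ties <- tie_term > 0
    }
    for (i in seq_len(M)) {
      idx <- which(names(delta) %in% tm[[i]])
      nt <- length(idx); no <- n - nt
      if (nt == 0L || no == 0L) next
      use_exact <- method == "ranksum_exact" ||
        (method == "auto" && min(nt, no) <= 10L && n <= 200L &&
           (!fast || !has_ties))
      if (method == "ttest" || use_exact) {
        p <- .directional_test(delta[idx], delta[-idx],
                               if (method == "ttest") "ttest" else "ranksum_exact")
      } else {
        u <- sum(r[idx]) - nt * (nt + 1) / 2
        mu <- nt * no / 2
        sigma2 <- nt * no / 12 * ((n + 1) - tie_term)
        if (sigma2 <= 0) next
        s <- sqrt(sigma2)
        cstat <- u - mu
        pg <- stats::pnorm((0.5 - cstat) / s)
        pl <- stats::pnorm((0.5 + cstat) / s)
        p <- c(max(min(pl, 1), .Machine$double.xmin),
               max(min(pg, 1), .Machine$double.xmin))
      }
      p_less[i, j] <- p[1L]
      p_greater[i, j] <- p[2L]
    }
  }
  new_pvalue_table(layer, region_pair, p_less, p_greater, method)
}

#' Direction-count summary of a P-value table
#'
#' Aggregates each miRNA's per-subject directional P-values by their
#' median, applies a multiple-testing correction across miRNAs within
#' each direction, counts miRNAs significant in each direction and calls
#' the net direction by the larger count (the miRNA-centric arrow logic
#' of the region-graph summaries).
#'
#' @param table a `pvalue_table`
#' @param alpha significance level (default 0.05)
#' @param correction `"BH"` (default) or `"none"`
#' @return list with `n_up`, `n_down`, `net_direction` and the per-miRNA
#'   data.frame `per_mirna` (median and adjusted P per direction)
#' @export
summarize_direction_counts <- function(table, alpha = 0.05,
                                       correction = c("BH", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(table, "pvalue_table"))
  med <- function(m) apply(m, 1L, stats::median, na.rm = TRUE)
  p_up <- med(table$p_greater)
  p_down <- med(table$p_less)
  adj <- function(p) if (correction == "BH") stats::p.adjust(p, "BH") else p
  adj_up <- adj(p_up)
  adj_down <- adj(p_down)
  n_up <- sum(adj_up <= alpha, na.rm = TRUE)
  n_down <- sum(adj_down <= alpha, na.rm = TRUE)
  list(
    n_up = n_up, n_down = n_down,
    net_direction = net_direction_from_counts(n_up, n_down),
    per_mirna = data.frame(
      mirna_id = table$mirna_ids,
      p_up_median = unname(p_up), p_up_adj = unname(adj_up),
      p_down_median = unname(p_down), p_down_adj = unname(adj_down),
      stringsAsFactors = FALSE
    )
  )
}

#' Write a P-value table in long TSV form
#'
#' One row per miRNA x subject with columns layer, region_ell,
#' region_ellprime, mirna_id, subject_id, p_less, p_greater, method.
#' @param table a `pvalue_table`
#' @param path output path
#' @export
write_pvalue_table <- function(table, path) {
  stopifnot(inherits(table, "pvalue_table"))
  M <- length(table$mirna_ids); S <- length(table$subject_ids)
  df <- data.frame(
    layer = table$layer,
    region_ell = table$region_pair[1L],
    region_ellprime = table$region_pair[2L],
    mirna_id = rep(table$mirna_ids, times = S),
    subject_id = rep(table$subject_ids, each = M),
    p_less = as.vector(table$p_less),
    p_greater = as.vector(table$p_greater),
    method = table$method,
    stringsAsFactors = FALSE
  )
  .write_tsv(df, path)
}

#' Read a long-form P-value table TSV back into a `pvalue_table`
#' @param path TSV written by [write_pvalue_table()]
#' @return a `pvalue_table`
#' @export
read_pvalue_table <- function(path) {
  df <- .read_tsv(path)
  need <- c("layer", "region_ell", "region_ellprime", "mirna_id",
            "subject_id", "p_less", "p_greater", "method")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("P-value table missing column(s): ",
                         paste(miss, collapse = ", "))
  mids <- unique(df$mirna_id)
  sids <- unique(df$subject_id)
  shape <- function(col) {
    m <- matrix(NA_real_, length(mids), length(sids),
                dimnames = list(mids, sids))
    m[cbind(match(df$mirna_id, mids), match(df$subject_id, sids))] <- df[[col]]
    m
  }
  new_pvalue_table(df$layer[1L], c(df$region_ell[1L], df$region_ellprime[1L]),
                   shape("p_less"), shape("p_greater"), df$method[1L])
}
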