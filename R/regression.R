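#' Signed normal-quantile score of a directional P-value pair
#'
#' Maps the one-sided pair (p_less, p_greater) to a single signed,
#' linear-model-friendly variable: z = qnorm(p_less) - qnorm(p_greater),
#' each quantile clamped to \[-8, 8\]. Positive when the target set is
#' upregulated (small p_greater), negative when downregulated, zero when
#' the two tails agree; swapping the inputs flips the sign exactly.
#'
#' @param p_less,p_greater P-values in (0, 1] (vectorised; NA propagates)
#' @param clamp per-term quantile clamp (default 8)
#' @return signed score in \[-2 clamp, 2 clamp\]
#' @export
signed_regulation_score <- function(p_less, p_greater, clamp = 8) {
  q <- function(p) pmin(pmax(stats::qnorm(p), -clamp), clamp)
  q(p_less) - q(p_greater)
}

#' Per-miRNA regression designs for one region pair
#'
#' For each miRNA present in both the P-value tables and the miRNA
#' expression layer, builds the design relating miRNA-mediated regulation
#' to its candidate drivers over the paired subjects:
#' response `y` = signed regulation score from the mRNA table; predictors
#' `meth` = signed score from the methylation table, `dmir` = the
#' subject's miRNA log-ratio log(x_m,ell / x_m,ellprime) (signals floored
#' at 1e-8), `gender` (female = 1) and centred `age`. Subjects with any
#' missing column are dropped per miRNA. miRNAs absent from the miRNA
#' layer are skipped with a warning.
#'
#' @param study an `aligned_study`
#' @param mrna_table,methyl_table `pvalue_table`s for the same region
#'   pair and subjects
#' @param region_pair `c(ell, ellprime)`
#' @return named list of per-miRNA data.frames
#'   (columns y, meth, dmir, gender, age), class `regression_design_set`
#' @export
build_design <- function(study, mrna_table, methyl_table, region_pair) {
  stopifnot(inherits(mrna_table, "pvalue_table"),
            inherits(methyl_table, "pvalue_table"),
            identical(mrna_table$subject_ids, methyl_table$subject_ids),
            identical(mrna_table$mirna_ids, methyl_table$mirna_ids))
  subjects <- mrna_table$subject_ids
  ann <- study$annotation
  mir_v <- study$layers$mirna$values

  s_ell <- vapply(subjects, function(s) .sample_of(ann, s, region_pair[1L]), "")
  s_ellp <- vapply(subjects, function(s) .sample_of(ann, s, region_pair[2L]), "")
  age <- ann$age[match(s_ell, ann$sample_id)]
  age_c <- age - mean(age)
  gender <- as.numeric(ann$gender[match(s_ell, ann$sample_id)] == "female")

  designs <- list()
  skipped <- character()
  for (m in mrna_table$mirna_ids) {
    if (!m %in% rownames(mir_v)) {
      skipped <- c(skipped, m)
      next
    }
    y <- signed_regulation_score(mrna_table$p_less[m, ],
                                 mrna_table$p_greater[m, ])
    meth <- signed_regulation_score(methyl_table$p_less[m, ],
                                    methyl_table$p_greater[m, ])
    dmir <- .log_floor(mir_v[m, s_ell]) - .log_floor(mir_v[m, s_ellp])
    df <- data.frame(y = unname(y), meth = unname(meth),
                     dmir = unname(dmir), gender = gender, age = age_c,
                     row.names = subjects)
    df <- df[stats::complete.cases(df), , drop = FALSE]
    designs[[m]] <- df
  }
  if (length(skipped)) {
    warning(length(skipped), " miRNA(s) absent from the miRNA expression ",
            "layer were skipped: ",
            paste(utils::head(skipped, 3L), collapse = ", "))
  }
  structure(designs, class = "regression_design_set",
            region_pair = as.character(region_pair))
}

#' Ordinary least squares fit of one miRNA's design
#'
#' Fits y ~ meth + dmir + gender + age by OLS; coefficient P-values are
#' two-sided t tests with n - p - 1 degrees of freedom.
#'
#' @param design one per-miRNA data.frame from [build_design()]
#' @param mirna_id identifier carried into the result
#' @return one-row data.frame: mirna_id, n, r_squared, then coefficient
#'   estimates `coef_*` and two-sided P-values `p_*` for intercept, meth,
#'   dmir, gender, age
#' @export
fit_mirna_regression <- function(design, mirna_id = NA_character_) {
  need <- c("y", "meth", "dmir", "gender", "age")
  stopifnot(all(need %in% colnames(design)))
  n <- nrow(design)
  if (n < 7L) stop("need at least p + 2 = 7 subjects to fit 5 coefficients")
  fit <- stats::lm(y ~ meth + dmir + gender + age, data = design)
  if (fit$rank < 5L) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design (collinear column(s): ",
         paste(dropped, collapse = ", "), ")")
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  est <- ct[, "Estimate"]
  pv <- ct[, "Pr(>|t|)"]
  out <- data.frame(
    mirna_id = mirna_id, n = n, r_squared = sm$r.squared,
    coef_intercept = est[["(Intercept)"]], coef_meth = est[["meth"]],
    coef_dmir = est[["dmir"]], coef_gender = est[["gender"]],
    coef_age = est[["age"]],
    p_intercept = pv[["(Intercept)"]], p_meth = pv[["meth"]],
    p_dmir = pv[["dmir"]], p_gender = pv[["gender"]], p_age = pv[["age"]],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Fit every design in a design set
#' @param designs a `regression_design_set`
#' @return data.frame, one row per successfully fitted miRNA
#' @export
fit_all_regressions <- function(designs) {
  rows <- lapply(names(designs), function(m) {
    tryCatch(fit_mirna_regression(designs[[m]], m), error = function(e) NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no miRNA design could be fitted")
  out
}

#' Select miRNAs whose differential expression predicts regulation
#'
#' Adjusts each coefficient's P-values across miRNAs (BH by default),
#' flags miRNAs whose adjusted `dmir` P-value (or, with
#' `criterion = "dmir_or_meth"`, either the dmir or the meth one) is at
#' most `alpha`, and labels each selected miRNA `reciprocal` when its
#' dmir coefficient is negative (miRNA up implies targets down — the
#' canonical suppressive mode) and `nonreciprocal` otherwise.
#'
#' @param results data.frame from [fit_all_regressions()]
#' @param alpha selection level (default 0.05)
#' @param correction `"BH"` (default) or `"none"`
#' @param criterion `"dmir"` (default) or `"dmir_or_meth"`
#' @return `results` with added columns `p_dmir_adj`, `p_meth_adj`,
#'   `selected`, `label`
#' @export
select_mirnas <- function(results, alpha = 0.05,
                          correction = c("BH", "none"),
                          criterion = c("dmir", "dmir_or_meth")) {
  correction <- match.arg(correction)
  criterion <- match.arg(criterion)
  if (is.null(results) || nrow(results) == 0L) {
    results$selected <- logical(0)
    results$label <- character(0)
    return(results)
  }
  adj <- function(p) if (correction == "BH") stats::p.adjust(p, "BH") else p
  results$p_dmir_adj <- adj(results$p_dmir)
  results$p_meth_adj <- adj(results$p_meth)
  results$selected <- if (criterion == "dmir") {
    results$p_dmir_adj <= alpha
  } else {
    results$p_dmir_adj <= alpha | results$p_meth_adj <= alpha
  }
  results$label <- ifelse(results$coef_dmir < 0, "reciprocal", "nonreciprocal")
  results$label[!results$selected] <- NA_character_
  results
}
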