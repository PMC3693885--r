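test_that("the signed regulation score is symmetric, antisymmetric and clamped", {
  expect_equal(signed_regulation_score(0.5, 0.5), 0)
  expect_equal(signed_regulation_score(0.999, 0.001),
               2 * qnorm(0.999), tolerance = 1e-12)
  set.seed(4)
  pl <- runif(50, 0.001, 0.999)
  pg <- runif(50, 0.001, 0.999)
  expect_equal(signed_regulation_score(pl, pg),
               -signed_regulation_score(pg, pl))
  # extreme tails saturate at the per-term clamp
  expect_equal(signed_regulation_score(1, 1e-300), 16)
  expect_true(is.na(signed_regulation_score(NA, 0.5)))
})

test_that("a noiseless linear response is recovered exactly", {
  set.seed(8)
  d <- data.frame(meth = rnorm(20), dmir = rnorm(20),
                  gender = rep(0:1, 10), age = rnorm(20))
  d$y <- 2 * d$dmir
  res <- suppressWarnings(fit_mirna_regression(d, "mirX"))  # perfect fit
  expect_equal(res$coef_dmir, 2, tolerance = 1e-10)
  expect_equal(res$coef_meth, 0, tolerance = 1e-10)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
})

test_that("OLS coefficients match the normal-equations oracle on a fixed design", {
  set.seed(12)
  d <- data.frame(meth = rnorm(8), dmir = rnorm(8),
                  gender = c(0, 1, 0, 1, 0, 1, 0, 1), age = rnorm(8))
  d$y <- 1 + 0.5 * d$meth - 1.2 * d$dmir + rnorm(8)
  res <- fit_mirna_regression(d, "mirY")
  X <- cbind(1, d$meth, d$dmir, d$gender, d$age)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(unname(c(res$coef_intercept, res$coef_meth, res$coef_dmir,
                        res$coef_gender, res$coef_age)),
               as.vector(beta), tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  set.seed(14)
  d <- data.frame(meth = rnorm(12), dmir = rnorm(12),
                  gender = rep(0:1, 6), age = rnorm(12))
  d$y <- rnorm(12)
  d$age <- d$meth  # perfectly collinear
  expect_error(fit_mirna_regression(d), "collinear.*age")
  expect_error(fit_mirna_regression(d[1:5, ]), "at least")
})

test_that("rescaling dmir rescales its coefficient and preserves its P-value", {
  set.seed(15)
  d <- data.frame(meth = rnorm(30), dmir = rnorm(30),
                  gender = rep(0:1, 15), age = rnorm(30))
  d$y <- 0.7 * d$dmir + rnorm(30)
  r1 <- fit_mirna_regression(d)
  d2 <- d
  d2$dmir <- 10 * d2$dmir
  r2 <- fit_mirna_regression(d2)
  expect_equal(r2$coef_dmir, r1$coef_dmir / 10, tolerance = 1e-10)
  expect_equal(r2$p_dmir, r1$p_dmir, tolerance = 1e-10)
})

test_that("designs are built per paired subject and skip absent miRNAs with a warning", {
  planted <- "mir0001"
  gen <- generate_study(synthetic_config(
    n_genes = 800, n_mirnas = 10, n_subjects = 50,
    region_labels = c("A", "B"), targets_per_mirna = c(20L, 30L),
    coupling_effects = data.frame(mirna_id = planted, ell = "A",
                                  ellprime = "B", beta = 1.5,
                                  sigma_beta = 0.5),
    seed = 33))
  st <- gen$study
  mt <- compute_pvalue_table(st, "mrna", c("A", "B"))
  ht <- compute_pvalue_table(st, "methylation", c("A", "B"))
  des <- build_design(st, mt, ht, c("A", "B"))
  expect_length(des, 10L)
  expect_equal(nrow(des[[planted]]), 50L)
  expect_named(des[[planted]], c("y", "meth", "dmir", "gender", "age"))
  expect_equal(mean(des[[planted]]$age), 0, tolerance = 1e-10)

  # the planted slope shows up as the covariance ratio of y on dmir
  d <- des[[planted]]
  slope <- cov(d$y, d$dmir) / var(d$dmir)
  expect_gt(slope, 0.5)

  # a miRNA missing from the expression layer is skipped with a warning
  st2 <- st
  keep <- setdiff(rownames(st2$layers$mirna$values), "mir0002")
  st2$layers$mirna <- omics_matrix(st2$layers$mirna$values[keep, ], "mirna")
  expect_warning(des2 <- build_design(st2, mt, ht, c("A", "B")), "mir0002")
  expect_length(des2, 9L)
})

test_that("selection controls the criterion and labels by the dmir sign", {
  base <- data.frame(
    mirna_id = paste0("m", 1:4), n = 50, r_squared = 0.5,
    coef_intercept = 0, coef_meth = 0,
    coef_dmir = c(-2, 1.5, -0.1, 0.2), coef_gender = 0, coef_age = 0,
    p_intercept = 1, p_meth = c(1, 1, 1e-6, 1),
    p_dmir = c(1e-6, 1e-5, 0.9, 1), p_gender = 1, p_age = 1,
    stringsAsFactors = FALSE)
  sel <- select_mirnas(base)
  expect_identical(sel$selected, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(sel$label[1:2], c("reciprocal", "nonreciprocal"))
  expect_true(all(is.na(sel$label[3:4])))

  # the alternate criterion also admits methylation-driven miRNAs
  sel2 <- select_mirnas(base, criterion = "dmir_or_meth")
  expect_true(sel2$selected[3])

  # no signal, nothing selected
  null_res <- base
  null_res$p_dmir <- null_res$p_meth <- 1
  expect_equal(sum(select_mirnas(null_res)$selected), 0L)
})
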