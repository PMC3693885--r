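test_that("per-gene deltas follow the log-ratio and beta-difference definitions", {
  gen <- tiny_study(n_genes = 20, n_mirnas = 2, n_subjects = 3, seed = 1)
  st <- gen$study
  subj <- paired_subjects(st, c("A", "B"))[1]
  ann <- st$annotation
  s1 <- ann$sample_id[ann$subject_id == subj & ann$region == "A"]
  s2 <- ann$sample_id[ann$subject_id == subj & ann$region == "B"]

  # identical expression -> zero; e-fold -> exactly 1
  st$layers$mrna$values[, s1] <- st$layers$mrna$values[, s2]
  expect_equal(unname(per_gene_delta(st, "mrna", c("A", "B"), subj)),
               rep(0, 20))
  st$layers$mrna$values[, s1] <- exp(1) * st$layers$mrna$values[, s2]
  expect_equal(unname(per_gene_delta(st, "mrna", c("A", "B"), subj)),
               rep(1, 20))

  # methylation is a plain difference
  st$layers$methylation$values[, s1] <- 0.8
  st$layers$methylation$values[, s2] <- 0.3
  expect_equal(unname(per_gene_delta(st, "methylation", c("A", "B"), subj)),
               rep(0.5, 20))

  expect_error(per_gene_delta(st, "mrna", c("A", "B"), "not_a_subject"),
               "not paired")
})

test_that("exact rank-sum matches exhaustive enumeration on the hand example", {
  delta <- c(t1 = 2, t2 = 3, t3 = 4, o1 = -1, o2 = 0, o3 = 1)
  tg <- c("t1", "t2", "t3")
  expect_equal(target_set_test(delta, tg, "greater", "ranksum_exact"), 1 / 20)
  expect_equal(target_set_test(delta, tg, "less", "ranksum_exact"), 1)
  expect_equal(ranksum_enum_oracle(delta[1:3], delta[4:6], "greater"), 1 / 20)
})

test_that("exact rank-sum equals the enumeration oracle on random small instances", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(4:10, 1)
    nt <- sample(seq_len(n - 1), 1)
    vals <- sample(100, n)  # distinct: tie-free
    delta <- stats::setNames(as.numeric(vals), paste0("g", seq_len(n)))
    tg <- paste0("g", seq_len(nt))
    for (dir in c("greater", "less")) {
      expect_equal(target_set_test(delta, tg, dir, "ranksum_exact"),
                   ranksum_enum_oracle(delta[seq_len(nt)],
                                       delta[-seq_len(nt)], dir),
                   tolerance = 1e-12)
    }
  }
})

test_that("Welch one-sided tails are complementary and rank methods are antisymmetric", {
  set.seed(7)
  for (rep in 1:50) {
    delta <- stats::setNames(rnorm(30), paste0("g", 1:30))
    tg <- paste0("g", 1:10)
    pg <- target_set_test(delta, tg, "greater", "ttest")
    pl <- target_set_test(delta, tg, "less", "ttest")
    expect_equal(pg + pl, 1, tolerance = 1e-12)
    # negating deltas (the region swap) exchanges the two rank-test tails
    for (m in c("ranksum_exact", "ranksum_normal")) {
      expect_identical(target_set_test(-delta, tg, "greater", m),
                       target_set_test(delta, tg, "less", m))
    }
  }
})

test_that("normal approximation converges to the exact rank-sum for groups >= 30", {
  set.seed(31)
  worst <- 0
  for (rep in 1:200) {
    nt <- sample(30:40, 1); no <- sample(30:60, 1)
    delta <- stats::setNames(rnorm(nt + no), paste0("g", seq_len(nt + no)))
    tg <- paste0("g", seq_len(nt))
    d <- abs(target_set_test(delta, tg, "greater", "ranksum_normal") -
             target_set_test(delta, tg, "greater", "ranksum_exact"))
    worst <- max(worst, d)
  }
  expect_lt(worst, 0.01)
})

test_that("adding a positive constant to target deltas never increases P_greater", {
  set.seed(13)
  for (rep in 1:30) {
    delta <- stats::setNames(rnorm(40), paste0("g", 1:40))
    tg <- paste0("g", 1:12)
    shifted <- delta
    shifted[tg] <- shifted[tg] + runif(1, 0.1, 2)
    for (m in c("ranksum_exact", "ranksum_normal")) {
      expect_lte(target_set_test(shifted, tg, "greater", m),
                 target_set_test(delta, tg, "greater", m))
    }
  }
})

test_that("the P-value table has the contracted shape and handles degenerate rows", {
  gen <- tiny_study(n_genes = 120, n_mirnas = 8, n_subjects = 6, seed = 3)
  st <- gen$study
  tab <- compute_pvalue_table(st, "mrna", c("A", "B"))
  expect_equal(dim(tab$p_less), c(8L, 6L))
  expect_equal(dim(tab$p_greater), c(8L, 6L))
  expect_true(all(is.na(tab$p_less) | (tab$p_less > 0 & tab$p_less <= 1)))

  # a miRNA whose targets are all missing in one subject gets NA there
  subj <- tab$subject_ids[1]
  tg <- st$target_map[[1]]
  sid <- st$annotation$sample_id[st$annotation$subject_id == subj &
                                 st$annotation$region == "A"]
  st$layers$mrna$values[tg, sid] <- NA_real_
  tab2 <- compute_pvalue_table(st, "mrna", c("A", "B"))
  expect_true(is.na(tab2$p_greater[1, subj]))
  expect_false(anyNA(tab2$p_greater[-1, subj]))
})

test_that("region swap exchanges the two directional matrices exactly", {
  gen <- tiny_study(n_genes = 150, n_mirnas = 10, n_subjects = 5, seed = 17)
  fwd <- compute_pvalue_table(gen$study, "mrna", c("A", "B"))
  rev <- compute_pvalue_table(gen$study, "mrna", c("B", "A"))
  expect_identical(fwd$p_less, rev$p_greater)
  expect_identical(fwd$p_greater, rev$p_less)
})

test_that("direction counts follow the larger-count arrow logic", {
  # all P at 1: nothing significant, no net direction
  m <- matrix(1, 4, 3, dimnames = list(paste0("m", 1:4), paste0("s", 1:3)))
  s0 <- summarize_direction_counts(new_pvalue_table("mrna", c("A", "B"),
                                                    m, m, "fixed"))
  expect_equal(c(s0$n_up, s0$n_down), c(0L, 0L))
  expect_identical(s0$net_direction, "none")

  expect_identical(net_direction_from_counts(889, 173), "up")
  expect_identical(net_direction_from_counts(173, 889), "down")
  expect_identical(net_direction_from_counts(5, 5), "none")
})

test_that("planted up/down regulation is recovered with the right net direction", {
  up <- sprintf("mir%04d", 1:20)
  down <- sprintf("mir%04d", 21:25)
  cfg <- synthetic_config(
    n_genes = 2000, n_mirnas = 60, n_subjects = 25,
    region_labels = c("A", "B"), targets_per_mirna = c(15L, 25L),
    regulation_effects = data.frame(
      mirna_id = c(up, down), ell = "A", ellprime = "B",
      delta = c(rep(2, 20), rep(-2, 5))),
    seed = 19)
  gen <- generate_study(cfg)
  tab <- compute_pvalue_table(gen$study, "mrna", c("A", "B"))
  sm <- summarize_direction_counts(tab)
  expect_gt(sm$n_up, sm$n_down)
  expect_identical(sm$net_direction, "up")
  recovered_up <- sm$per_mirna$mirna_id[sm$per_mirna$p_up_adj <= 0.05]
  expect_gte(sum(up %in% recovered_up), 18L)
})

test_that("P-value tables round trip through the long TSV schema", {
  gen <- tiny_study(n_genes = 80, n_mirnas = 5, n_subjects = 4, seed = 23)
  tab <- compute_pvalue_table(gen$study, "methylation", c("A", "B"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pvalue_table(tab, path)
  back <- read_pvalue_table(path)
  expect_equal(back$p_less, tab$p_less)
  expect_equal(back$p_greater, tab$p_greater)
  expect_identical(back$layer, tab$layer)
  expect_identical(back$region_pair, tab$region_pair)
})
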