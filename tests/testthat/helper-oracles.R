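# Independent oracles and tiny fixture builders shared across tests.

# Exhaustive rank-split oracle for the one-sided rank-sum test: enumerates
# every C(n, n_t) assignment of the pooled ranks to the target group and
# returns the tail probability of the observed rank sum.
ranksum_enum_oracle <- function(delta_t, delta_o, direction) {
  pooled <- c(delta_t, delta_o)
  r <- rank(pooled)
  nt <- length(delta_t)
  obs <- sum(r[seq_len(nt)])
  splits <- utils::combn(length(pooled), nt)
  sums <- apply(splits, 2L, function(idx) sum(r[idx]))
  if (direction == "greater") mean(sums >= obs) else mean(sums <= obs)
}

# Upper-tail hypergeometric probability from log factorials only.
hyper_logfact_oracle <- function(k, K, n, N) {
  i <- seq(k, min(K, n))
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Small fully crossed study with a hand-buildable layout.
tiny_study <- function(n_genes = 60, n_mirnas = 6, n_subjects = 5,
                       regions = c("A", "B"), seed = 42, ...) {
  generate_study(synthetic_config(
    n_genes = n_genes, n_mirnas = n_mirnas, n_subjects = n_subjects,
    region_labels = regions, targets_per_mirna = c(5L, 10L),
    seed = seed, ...))
}

# P-value table with fully specified matrices.
table_from_matrix <- function(p_greater, layer = "mrna",
                              region_pair = c("A", "B")) {
  p_less <- pmin(pmax(1 - p_greater, 1e-15), 1)
  new_pvalue_table(layer, region_pair, p_less, p_greater, method = "fixed")
}

# A small but complete synthetic run: 4 regions (6 pairs), planted
# coupling so the selection and enrichment stages have work to do.
small_pipeline_config <- function(seed = 7) {
  list(
    seed = seed,
    simulate = list(
      n_genes = 300L, n_mirnas = 25L, n_subjects = 12L,
      region_labels = c("CRBLM", "FCTX", "PONS", "TCTX"),
      targets_per_mirna = c(10L, 20L),
      coupling_effects = list(
        list(mirna_id = "mir0001", ell = "CRBLM", ellprime = "FCTX",
             beta = 2.5, sigma_beta = 0.3),
        list(mirna_id = "mir0002", ell = "CRBLM", ellprime = "FCTX",
             beta = -2.5, sigma_beta = 0.3),
        list(mirna_id = "mir0003", ell = "PONS", ellprime = "TCTX",
             beta = 2.5, sigma_beta = 0.3))
    ),
    n_synthetic_pathways = 25L
  )
}

expect_file_trees_identical <- function(dir1, dir2) {
  f1 <- sort(list.files(dir1, recursive = TRUE))
  f2 <- sort(list.files(dir2, recursive = TRUE))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = paste("md5 of", f))
  }
}
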