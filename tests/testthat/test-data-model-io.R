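test_that("omics matrix TSV round trip is value-identical and errors carry context", {
  vals <- matrix(round(rnorm(15), 6), 3, 5,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:5)))
  om <- omics_matrix(vals, "mrna")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_omics_matrix(om, path)
  back <- read_omics_matrix(path, "mrna")
  expect_identical(back$values, om$values)

  # direct parse of a hand-written 2x2 file
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tsA\tsB", "g1\t1.5\t2", "g2\t-0.25\t4"), p2)
  m2 <- read_omics_matrix(p2, "mrna")
  expect_equal(unname(m2$values), matrix(c(1.5, -0.25, 2, 4), 2, 2))

  # duplicated feature id names the id
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tsA", "gX\t1", "gX\t2"), p3)
  expect_error(read_omics_matrix(p3, "mrna"), "gX")

  # non-numeric cell names feature and sample
  p4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tsA\tsB", "g1\t1\toops"), p4)
  expect_error(read_omics_matrix(p4, "mrna"), "g1.*sB|sB.*g1")

  # methylation range check
  bad <- matrix(c(0.2, 1.4), 2, 1, dimnames = list(c("g1", "g2"), "sA"))
  expect_error(omics_matrix(bad, "methylation"), "\\[0,1\\]")
})

test_that("sample annotation validation enforces the cohort invariants", {
  full <- expand.grid(subject_id = sprintf("sub%03d", 1:150),
                      region = c("CRBLM", "FCTX", "PONS", "TCTX"),
                      stringsAsFactors = FALSE)
  full$sample_id <- paste(full$subject_id, full$region, sep = ".")
  full$age <- 60
  full$gender <- "female"
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(full, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- read_sample_annotation(path)
  expect_equal(nrow(ann), 600L)

  expect_error(validate_sample_annotation(transform(full, age = -1)), "age")
  dup <- rbind(full, full[1, ])
  dup$sample_id[nrow(dup)] <- "extra"
  expect_error(validate_sample_annotation(dup), "sub001.*CRBLM")
  expect_error(validate_sample_annotation(full[, setdiff(names(full), "region")]),
               "region")
  dup2 <- rbind(full, full[1, ])
  expect_error(validate_sample_annotation(dup2), "duplicate sample_id")
})

test_that("target map intersects with the universe, drops empties and deduplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\tgene_id", "m1\tg1", "m1\tg2", "m1\tg2", "m2\tg9"),
             path)
  expect_warning(tm <- read_target_map(path, gene_universe = c("g1", "g2")),
                 "dropped")
  expect_named(tm, "m1")
  expect_identical(tm$m1, c("g1", "g2"))
  expect_identical(attr(tm, "M"), 1L)

  # headerless variant and M bookkeeping without a universe
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mA\tg1", "mB\tg2"), p2)
  tm2 <- read_target_map(p2)
  expect_identical(attr(tm2, "M"), 2L)

  p3 <- withr::local_tempfile(fileext = ".tsv")
  file.create(p3)
  expect_error(read_target_map(p3), "empty")
})

test_that("target map count matches the generator over a large random map", {
  genes <- sprintf("g%04d", 1:800)
  set.seed(9)
  mid <- rep(sprintf("m%03d", 1:500), each = 4)
  gid <- sample(genes, length(mid), replace = TRUE)
  tm <- target_map(mid, gid, gene_universe = genes)
  expect_identical(attr(tm, "M"), 500L)
  # oracle: independent split/unique count
  expect_identical(length(unique(mid)), 500L)
})

test_that("GMT files round trip", {
  sets <- list(pwA = c("g1", "g2", "g3"), pwB = c("g2", "g9"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_identical(read_gmt(path), sets)
})

test_that("assemble_study enumerates C(R,2) pairs and pairs subjects deterministically", {
  gen <- tiny_study(n_subjects = 8, regions = c("CRBLM", "FCTX", "PONS", "TCTX"))
  st <- gen$study
  expect_equal(nrow(st$pairs), choose(4, 2))
  expect_true(all(st$pairs$n_paired == 8L))
  for (R in 2:5) expect_equal(nrow(region_pairs(letters[1:R])), choose(R, 2))

  # permuting annotation rows and layer columns yields the same object
  ann <- st$annotation
  perm <- sample(nrow(ann))
  layers2 <- lapply(st$layers, function(ly) {
    omics_matrix(ly$values[, sample(ncol(ly$values))], ly$layer_name)
  })
  st2 <- assemble_study(layers2, ann[perm, ], st$target_map)
  expect_identical(st2$pairs, st$pairs)
  expect_identical(st2$paired_subjects, st$paired_subjects)
})

test_that("subjects missing from a region are excluded from every pair", {
  gen <- tiny_study(n_subjects = 6, regions = c("A", "B", "C"))
  st <- gen$study
  ann <- st$annotation
  drop_subj <- "sub0001"
  ann2 <- ann[!(ann$subject_id == drop_subj & ann$region == "B"), ]
  layers2 <- lapply(st$layers, function(ly) {
    omics_matrix(ly$values[, ann2$sample_id], ly$layer_name)
  })
  st2 <- assemble_study(layers2, ann2, st$target_map)
  expect_false(drop_subj %in% paired_subjects(st2, c("A", "B")))
  expect_false(drop_subj %in% paired_subjects(st2, c("B", "C")))
  expect_true(drop_subj %in% paired_subjects(st2, c("A", "C")))
})

test_that("assembly rejects layer samples unknown to the annotation and flags thin pairs", {
  gen <- tiny_study(n_subjects = 4)
  st <- gen$study
  bad <- st$layers$mrna$values
  colnames(bad)[1] <- "phantom_sample"
  expect_error(
    assemble_study(list(mrna = omics_matrix(bad, "mrna"),
                        mirna = st$layers$mirna,
                        methylation = st$layers$methylation),
                   st$annotation, st$target_map),
    "phantom_sample")

  # keep only 2 subjects in region B of one layer -> pair unusable
  ann <- st$annotation
  keep <- !(ann$region == "B" & ann$subject_id %in% c("sub0001", "sub0002"))
  ann2 <- ann[keep, ]
  layers2 <- lapply(st$layers, function(ly) {
    omics_matrix(ly$values[, ann2$sample_id], ly$layer_name)
  })
  st2 <- assemble_study(layers2, ann2, st$target_map)
  expect_false(st2$pairs$usable[st2$pairs$ell == "A" & st2$pairs$ellprime == "B"])
})
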