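#' Configuration for the synthetic multi-omics generator
#'
#' The generator emulates a paired-brain-region array study: one shared
#' subject cohort sampled in every region (fully crossed by default), with
#' mRNA and miRNA expression emitted on a positive signal scale
#' (log-normal around a baseline) and promoter methylation on the beta
#' scale in \[0, 1\]. Planted effects are specified per miRNA and region
#' pair and define the ground truth that recovery tests check.
#'
#' Effect tables (all optional, `NULL` means none):
#' \describe{
#'   \item{regulation_effects}{data.frame(mirna_id, ell, ellprime, delta):
#'     the miRNA's target genes are shifted by `delta` (log scale, signed)
#'     in region `ell`, so the per-subject log-ratio ell vs ellprime is
#'     elevated when `delta > 0`.}
#'   \item{methylation_effects}{data.frame(mirna_id, ell, ellprime, delta):
#'     target-gene promoter betas shifted by `delta` in region `ell`
#'     (clipped to \[0,1\]).}
#'   \item{mirna_de_effects}{data.frame(mirna_id, ell, ellprime, delta):
#'     the miRNA's own log-expression shifted by `delta` in region `ell`.}
#'   \item{coupling_effects}{data.frame(mirna_id, ell, ellprime, beta,
#'     sigma_beta): the per-subject shift applied to the miRNA's targets in
#'     region `ell` is `beta` times the subject's realized miRNA log-ratio
#'     plus Gaussian noise with sd `sigma_beta` — the mechanism that makes
#'     regulation depend on differential miRNA expression.}
#' }
#'
#' @param n_genes,n_mirnas,n_subjects problem sizes (positive integers)
#' @param region_labels region label set (default the four brain regions)
#' @param targets_per_mirna integer range (min, max) of targets per miRNA
#' @param baseline_log_mean,baseline_log_sd gene/miRNA baseline
#'   log-expression distribution
#' @param noise_sd named vector of per-layer noise sds: `mrna` and `mirna`
#'   on the log scale, `methylation` on the beta scale
#' @param regulation_effects,methylation_effects,mirna_de_effects,coupling_effects
#'   planted-effect tables, see Details
#' @param age_effect,gender_effect covariate effect sizes on gene
#'   log-expression (age effect per standardised year; gender effect for
#'   female vs male)
#' @param dropout fraction of (subject, region) samples removed at random
#'   (default 0: fully crossed)
#' @param seed mandatory integer seed
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(n_genes = 2000L, n_mirnas = 200L,
                             n_subjects = 50L,
                             region_labels = c("CRBLM", "FCTX", "PONS", "TCTX"),
                             targets_per_mirna = c(10L, 30L),
                             baseline_log_mean = 6, baseline_log_sd = 1,
                             noise_sd = c(mrna = 0.5, mirna = 0.5,
                                          methylation = 0.05),
                             regulation_effects = NULL,
                             methylation_effects = NULL,
                             mirna_de_effects = NULL,
                             coupling_effects = NULL,
                             age_effect = 0, gender_effect = 0,
                             dropout = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  if (n_genes < 2L || n_mirnas < 1L || n_subjects < 1L) {
    stop("n_genes, n_mirnas, n_subjects must be positive (n_genes >= 2)")
  }
  if (length(region_labels) < 2L || anyDuplicated(region_labels)) {
    stop("need >= 2 distinct region labels")
  }
  targets_per_mirna <- as.integer(targets_per_mirna)
  if (length(targets_per_mirna) != 2L || targets_per_mirna[1L] < 1L ||
      targets_per_mirna[2L] < targets_per_mirna[1L]) {
    stop("targets_per_mirna must be an increasing positive range (min, max)")
  }
  if (targets_per_mirna[2L] >= n_genes) {
    stop("targets_per_mirna exceeds n_genes: infeasible config")
  }
  stopifnot(all(c("mrna", "mirna", "methylation") %in% names(noise_sd)))
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")

  mirna_ids <- sprintf("mir%04d", seq_len(n_mirnas))
  check_fx <- function(fx, cols, what) {
    if (is.null(fx)) return(NULL)
    fx <- as.data.frame(fx, stringsAsFactors = FALSE)
    miss <- setdiff(cols, colnames(fx))
    if (length(miss)) stop(what, " effects missing column(s): ",
                           paste(miss, collapse = ", "))
    bad <- setdiff(fx$mirna_id, mirna_ids)
    if (length(bad)) stop(what, " effects name unknown miRNA id(s): ",
                          paste(utils::head(bad, 3L), collapse = ", "))
    if (!all(fx$ell %in% region_labels) || !all(fx$ellprime %in% region_labels)) {
      stop(what, " effects reference unknown region labels")
    }
    fx
  }
  cfg <- list(
    n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
    n_subjects = as.integer(n_subjects),
    region_labels = as.character(region_labels),
    targets_per_mirna = targets_per_mirna,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    noise_sd = noise_sd,
    regulation_effects = check_fx(regulation_effects,
                                  c("mirna_id", "ell", "ellprime", "delta"),
                                  "regulation"),
    methylation_effects = check_fx(methylation_effects,
                                   c("mirna_id", "ell", "ellprime", "delta"),
                                   "methylation"),
    mirna_de_effects = check_fx(mirna_de_effects,
                                c("mirna_id", "ell", "ellprime", "delta"),
                                "miRNA differential-expression"),
    coupling_effects = check_fx(coupling_effects,
                                c("mirna_id", "ell", "ellprime", "beta",
                                  "sigma_beta"),
                                "coupling"),
    age_effect = age_effect, gender_effect = gender_effect,
    dropout = dropout, seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

#' All-null configuration for type-I-error studies
#'
#' Same structure as [synthetic_config()] with every planted effect table
#' empty, so downstream per-miRNA directional P-values are Uniform(0, 1).
#'
#' @param n_mirnas,n_subjects,seed see [synthetic_config()]
#' @param ... further arguments forwarded to [synthetic_config()]
#' @return a `synthetic_config` with empty planted truth
#' @export
default_null_config <- function(n_mirnas = 200L, n_subjects = 50L, seed, ...) {
  if (n_mirnas < 1L || n_subjects < 1L) {
    stop("n_mirnas and n_subjects must be positive")
  }
  synthetic_config(n_mirnas = n_mirnas, n_subjects = n_subjects,
                   seed = seed, ...)
}

#' Generate a synthetic aligned study with planted ground truth
#'
#' Per subject and region, gene log-expression = gene baseline + planted
#' target shifts + age/gender terms + Gaussian noise, exponentiated to the
#' signal scale. Methylation beta = per-gene baseline + planted shifts +
#' Gaussian noise, clipped to \[0, 1\] (a clipping fraction above 1% is
#' reported). miRNA log-expression gets its own planted shifts. When
#' coupling effects are present, the miRNA layer is generated first and
#' each subject's realized miRNA log-ratio drives that subject's
#' target-gene shift.
#'
#' @param config a [synthetic_config()]
#' @return list with elements `study` (an `aligned_study`) and `truth`
#'   (a `planted_truth` data.frame: mirna_id, ell, ellprime, effect_type,
#'   sign, magnitude)
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cfg <- config

  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  mirna_ids <- sprintf("mir%04d", seq_len(cfg$n_mirnas))
  subject_ids <- sprintf("sub%04d", seq_len(cfg$n_subjects))
  regions <- sort(cfg$region_labels)

  age <- stats::runif(cfg$n_subjects, 20, 90)
  gender <- ifelse(stats::rbinom(cfg$n_subjects, 1L, 0.5) == 1L,
                   "female", "male")

  # annotation: fully crossed, then optional dropout
  ann <- expand.grid(subject_id = subject_ids, region = regions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ann <- ann[order(ann$subject_id, ann$region), ]
  ann$sample_id <- paste(ann$subject_id, ann$region, sep = ".")
  ann$age <- age[match(ann$subject_id, subject_ids)]
  ann$gender <- gender[match(ann$subject_id, subject_ids)]
  if (cfg$dropout > 0) {
    keep <- stats::runif(nrow(ann)) >= cfg$dropout
    ann <- ann[keep, , drop = FALSE]
  }
  ann <- validate_sample_annotation(
    ann[, c("sample_id", "subject_id", "region", "age", "gender")])

  # target map
  n_t <- sample(seq(cfg$targets_per_mirna[1L], cfg$targets_per_mirna[2L]),
                cfg$n_mirnas, replace = TRUE)
  tmap <- lapply(seq_len(cfg$n_mirnas),
                 function(i) sort(sample(gene_ids, n_t[i])))
  names(tmap) <- mirna_ids
  tm <- target_map(rep(mirna_ids, lengths(tmap)),
                   unlist(tmap, use.names = FALSE))

  ns <- nrow(ann)
  sidx <- match(ann$subject_id, subject_ids)

  # --- miRNA layer (first: coupling reads realized log-ratios from it) ---
  mir_base <- stats::rnorm(cfg$n_mirnas, cfg$baseline_log_mean,
                           cfg$baseline_log_sd)
  mir_log <- matrix(mir_base, nrow = cfg$n_mirnas, ncol = ns) +
    matrix(stats::rnorm(cfg$n_mirnas * ns, 0, cfg$noise_sd[["mirna"]]),
           cfg$n_mirnas, ns)
  dimnames(mir_log) <- list(mirna_ids, ann$sample_id)
  if (!is.null(cfg$mirna_de_effects)) {
    fx <- cfg$mirna_de_effects
    for (i in seq_len(nrow(fx))) {
      cols <- which(ann$region == fx$ell[i])
      mir_log[fx$mirna_id[i], cols] <- mir_log[fx$mirna_id[i], cols] + fx$delta[i]
    }
  }

  # --- mRNA layer ---
  gene_base <- stats::rnorm(cfg$n_genes, cfg$baseline_log_mean,
                            cfg$baseline_log_sd)
  age_z <- (ann$age - 55) / 20
  gend <- as.numeric(ann$gender == "female")
  mrna_log <- matrix(gene_base, cfg$n_genes, ns) +
    matrix(cfg$age_effect * age_z + cfg$gender_effect * gend,
           cfg$n_genes, ns, byrow = TRUE) +
    matrix(stats::rnorm(cfg$n_genes * ns, 0, cfg$noise_sd[["mrna"]]),
           cfg$n_genes, ns)
  dimnames(mrna_log) <- list(gene_ids, ann$sample_id)
  if (!is.null(cfg$regulation_effects)) {
    fx <- cfg$regulation_effects
    for (i in seq_len(nrow(fx))) {
      tg <- tmap[[fx$mirna_id[i]]]
      cols <- which(ann$region == fx$ell[i])
      mrna_log[tg, cols] <- mrna_log[tg, cols] + fx$delta[i]
    }
  }
  if (!is.null(cfg$coupling_effects)) {
    fx <- cfg$coupling_effects
    for (i in seq_len(nrow(fx))) {
      tg <- tmap[[fx$mirna_id[i]]]
      cols <- which(ann$region == fx$ell[i])
      for (cc in cols) {
        subj <- ann$subject_id[cc]
        other <- ann$sample_id[ann$subject_id == subj &
                               ann$region == fx$ellprime[i]]
        if (length(other) != 1L) next  # unpaired subject: no coupling shift
        dmir <- mir_log[fx$mirna_id[i], ann$sample_id[cc]] -
                mir_log[fx$mirna_id[i], other]
        shift <- fx$beta[i] * dmir + stats::rnorm(1L, 0, fx$sigma_beta[i])
        mrna_log[tg, cc] <- mrna_log[tg, cc] + shift
      }
    }
  }

  # --- methylation layer ---
  beta_base <- stats::runif(cfg$n_genes, 0.2, 0.8)
  meth <- matrix(beta_base, cfg$n_genes, ns) +
    matrix(stats::rnorm(cfg$n_genes * ns, 0, cfg$noise_sd[["methylation"]]),
           cfg$n_genes, ns)
  dimnames(meth) <- list(gene_ids, ann$sample_id)
  if (!is.null(cfg$methylation_effects)) {
    fx <- cfg$methylation_effects
    for (i in seq_len(nrow(fx))) {
      tg <- tmap[[fx$mirna_id[i]]]
      cols <- which(ann$region == fx$ell[i])
      meth[tg, cols] <- meth[tg, cols] + fx$delta[i]
    }
  }
  clipped <- mean(meth < 0 | meth > 1)
  if (clipped > 0.01) {
    message(sprintf("methylation clipping affected %.2f%% of entries (> 1%%)",
                    100 * clipped))
  }
  meth[meth < 0] <- 0
  meth[meth > 1] <- 1

  layers <- list(
    mrna = omics_matrix(exp(mrna_log), "mrna"),
    mirna = omics_matrix(exp(mir_log), "mirna"),
    methylation = omics_matrix(meth, "methylation")
  )
  study <- assemble_study(layers, ann, tm)

  truth_rows <- list()
  add_truth <- function(fx, type, magcol) {
    if (is.null(fx) || nrow(fx) == 0L) return(NULL)
    data.frame(mirna_id = fx$mirna_id, ell = fx$ell, ellprime = fx$ellprime,
               effect_type = type, sign = sign(fx[[magcol]]),
               magnitude = abs(fx[[magcol]]), stringsAsFactors = FALSE)
  }
  truth <- rbind(
    add_truth(cfg$regulation_effects, "regulation", "delta"),
    add_truth(cfg$methylation_effects, "methylation", "delta"),
    add_truth(cfg$mirna_de_effects, "mirna_de", "delta"),
    add_truth(cfg$coupling_effects, "coupling", "beta")
  )
  if (is.null(truth)) {
    truth <- data.frame(mirna_id = character(), ell = character(),
                        ellprime = character(), effect_type = character(),
                        sign = numeric(), magnitude = numeric(),
                        stringsAsFactors = FALSE)
  }
  class(truth) <- c("planted_truth", "data.frame")
  list(study = study, truth = truth)
}

#' Write the full TSV input set (plus truth) for a generated study
#'
#' Emits mrna.tsv, mirna.tsv, methylation.tsv, annotation.tsv,
#' target_map.tsv and planted_truth.tsv into `dir`.
#'
#' @param generated result of [generate_study()]
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_study_inputs <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- generated$study
  write_omics_matrix(st$layers$mrna, file.path(dir, "mrna.tsv"))
  write_omics_matrix(st$layers$mirna, file.path(dir, "mirna.tsv"))
  write_omics_matrix(st$layers$methylation, file.path(dir, "methylation.tsv"))
  .write_tsv(as.data.frame(st$annotation), file.path(dir, "annotation.tsv"))
  write_target_map(st$target_map, file.path(dir, "target_map.tsv"))
  .write_tsv(as.data.frame(generated$truth),
             file.path(dir, "planted_truth.tsv"))
  invisible(dir)
}

#' Read back a study written by [write_study_inputs()] (or user TSVs)
#' @param dir directory holding mrna.tsv, mirna.tsv, methylation.tsv,
#'   annotation.tsv, target_map.tsv
#' @return an `aligned_study`
#' @export
read_study_inputs <- function(dir) {
  mrna <- read_omics_matrix(file.path(dir, "mrna.tsv"), "mrna")
  mirna <- read_omics_matrix(file.path(dir, "mirna.tsv"), "mirna")
  meth <- read_omics_matrix(file.path(dir, "methylation.tsv"), "methylation")
  ann <- read_sample_annotation(file.path(dir, "annotation.tsv"))
  tm <- read_target_map(file.path(dir, "target_map.tsv"),
                        gene_universe = feature_ids(mrna))
  assemble_study(list(mrna = mrna, mirna = mirna, methylation = meth),
                 ann, tm)
}

#' Simulate a coupled pair of directional P-value tables
#'
#' A direct generator for the coupling stage: a latent per-miRNA Gaussian
#' pair (z_m^A, z_m^B) with Pearson correlation r = 2 sin(pi * rho_star / 6)
#' — the value at which the population Spearman correlation of a bivariate
#' normal equals `rho_star` — drives both tables. Each subject's P column
#' is Phi(sqrt(1 - w^2) z_m + w eps_mj) with independent subject noise
#' eps, so the per-miRNA mean ranks of either table track the latent
#' scores while individual subjects fluctuate.
#'
#' @param M number of miRNAs
#' @param n_subjects number of subjects (columns)
#' @param rho_star target Spearman correlation between the two tables'
#'   mean-rank profiles; 0 gives independent tables
#' @param seed integer seed
#' @param noise_weight subject-noise weight w in (0, 1)
#' @param region_pair labels attached to the emitted tables
#' @return list with `mrna` and `methyl` `pvalue_table`s and the latent
#'   scores
#' @export
simulate_coupled_tables <- function(M, n_subjects, rho_star, seed,
                                    noise_weight = 0.3,
                                    region_pair = c("A", "B")) {
  stopifnot(M >= 4L, n_subjects >= 1L, abs(rho_star) <= 1,
            noise_weight > 0, noise_weight < 1)
  set.seed(seed)
  r <- 2 * sin(pi * rho_star / 6)
  z_a <- stats::rnorm(M)
  z_b <- r * z_a + sqrt(1 - r^2) * stats::rnorm(M)
  w <- noise_weight
  make_table <- function(z, layer) {
    lat <- sqrt(1 - w^2) * matrix(z, M, n_subjects) +
      w * matrix(stats::rnorm(M * n_subjects), M, n_subjects)
    p_greater <- stats::pnorm(lat)
    p_less <- 1 - p_greater
    mids <- sprintf("mir%04d", seq_len(M))
    sids <- sprintf("sub%04d", seq_len(n_subjects))
    dimnames(p_greater) <- dimnames(p_less) <- list(mids, sids)
    new_pvalue_table(layer, region_pair, p_less, p_greater,
                     method = "synthetic_copula")
  }
  list(mrna = make_table(z_a, "mrna"),
       methyl = make_table(z_b, "methylation"),
       latent = data.frame(z_mrna = z_a, z_methyl = z_b))
}
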