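#' Build a validated run configuration
#'
#' Exactly one of `inputs` (paths to mrna/mirna/methylation/annotation/
#' target_map TSVs) or `simulate` (arguments for [synthetic_config()],
#' effect tables given as lists of records) must be present. All analysis
#' constants live here with their defaults: test `method` ("auto"),
#' `alpha` (0.05), `correction` ("BH"), selection `criterion` ("dmir"),
#' coupling `direction` channel ("greater").
#'
#' @param config a named list (typically from [read_run_config()])
#' @return a `run_config`
#' @export
run_config <- function(config) {
  has_inputs <- !is.null(config$inputs)
  has_sim <- !is.null(config$simulate)
  if (has_inputs == has_sim) {
    stop("exactly one of `inputs` and `simulate` must be present in the config")
  }
  if (has_sim && is.null(config$seed) && is.null(config$simulate$seed)) {
    stop("`seed` is mandatory when simulating")
  }
  defaults <- list(method = "auto", alpha = 0.05, correction = "BH",
                   criterion = "dmir", direction = "greater",
                   pairs = "all", pathways = NULL,
                   n_synthetic_pathways = 50L, log_level = "info")
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config$method <- match.arg(config$method,
                             c("auto", "ranksum_normal", "ranksum_exact",
                               "ttest"))
  config$correction <- match.arg(config$correction, c("BH", "none"))
  config$criterion <- match.arg(config$criterion, c("dmir", "dmir_or_meth"))
  config$direction <- match.arg(config$direction, c("greater", "less"))
  stopifnot(config$alpha > 0, config$alpha < 1)
  class(config) <- "run_config"
  config
}

#' Read a YAML run configuration
#' @param path YAML file
#' @return a `run_config`
#' @export
read_run_config <- function(path) run_config(yaml::read_yaml(path))

.fx_df <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NULL)
  if (is.data.frame(x)) return(x)
  do.call(rbind, lapply(x, function(rec) as.data.frame(rec, stringsAsFactors = FALSE)))
}

.sim_config_from <- function(config) {
  sim <- config$simulate
  args <- sim[setdiff(names(sim), c("regulation_effects", "methylation_effects",
                                    "mirna_de_effects", "coupling_effects",
                                    "seed"))]
  args$regulation_effects <- .fx_df(sim$regulation_effects)
  args$methylation_effects <- .fx_df(sim$methylation_effects)
  args$mirna_de_effects <- .fx_df(sim$mirna_de_effects)
  args$coupling_effects <- .fx_df(sim$coupling_effects)
  args$seed <- sim$seed %||% config$seed
  if (!is.null(args$region_labels)) args$region_labels <- unlist(args$region_labels)
  if (!is.null(args$targets_per_mirna)) args$targets_per_mirna <- unlist(args$targets_per_mirna)
  if (!is.null(args$noise_sd)) args$noise_sd <- unlist(args$noise_sd)
  do.call(synthetic_config, args)
}

#' Random gene sets over a gene universe (synthetic pathway database)
#'
#' @param gene_ids gene universe
#' @param n_pathways number of sets
#' @param size_range integer range of set sizes
#' @param seed integer seed
#' @return named list of gene sets
#' @export
make_synthetic_pathways <- function(gene_ids, n_pathways = 50L,
                                    size_range = c(20L, 100L), seed) {
  stopifnot(n_pathways >= 1L, size_range[1L] >= 1L,
            size_range[2L] <= length(gene_ids))
  set.seed(seed)
  sizes <- sample(seq(size_range[1L], size_range[2L]), n_pathways,
                  replace = TRUE)
  sets <- lapply(sizes, function(k) sort(sample(gene_ids, k)))
  names(sets) <- sprintf("pathway%03d", seq_len(n_pathways))
  sets
}

.inputs_dir <- function(outdir) file.path(outdir, "inputs")
.stats_dir <- function(outdir) file.path(outdir, "stats")

.usable_pairs <- function(study, config) {
  pr <- study$pairs[study$pairs$usable, , drop = FALSE]
  if (!identical(config$pairs, "all")) {
    want <- vapply(config$pairs, function(p) .pair_key(p[[1L]], p[[2L]]), "")
    pr <- pr[.pair_key(pr$ell, pr$ellprime) %in% want, , drop = FALSE]
  }
  pr
}

.load_study <- function(config, outdir) {
  if (!is.null(config$simulate)) {
    read_study_inputs(.inputs_dir(outdir))
  } else {
    inp <- config$inputs
    mrna <- read_omics_matrix(inp$mrna, "mrna")
    assemble_study(
      list(mrna = mrna,
           mirna = read_omics_matrix(inp$mirna, "mirna"),
           methylation = read_omics_matrix(inp$methylation, "methylation")),
      read_sample_annotation(inp$annotation),
      read_target_map(inp$target_map, gene_universe = feature_ids(mrna)))
  }
}

#' Pipeline stage: materialise inputs
#'
#' With a `simulate` block, generates the synthetic study (and, when no
#' GMT is configured, a synthetic pathway database) and writes the full
#' TSV input set under `outdir/inputs/`. With explicit `inputs`, this
#' stage is a no-op.
#' @param config a `run_config`
#' @param outdir output directory
#' @export
stage_simulate <- function(config, outdir) {
  if (is.null(config$simulate)) return(invisible(NULL))
  dir.create(.inputs_dir(outdir), showWarnings = FALSE, recursive = TRUE)
  sim_cfg <- .sim_config_from(config)
  gen <- generate_study(sim_cfg)
  write_study_inputs(gen, .inputs_dir(outdir))
  if (is.null(config$pathways)) {
    sets <- make_synthetic_pathways(
      feature_ids(gen$study$layers$mrna),
      n_pathways = config$n_synthetic_pathways,
      seed = sim_cfg$seed + 1L)
    write_gmt(sets, file.path(.inputs_dir(outdir), "pathways.gmt"))
  }
  invisible(gen)
}

#' Pipeline stage: directional P-value tables
#'
#' Computes the mRNA and methylation P-value tables for every usable
#' region pair and writes them (long TSV) plus the per-pair
#' direction-count summary `direction_counts.tsv`.
#' @param config a `run_config`
#' @param outdir output directory
#' @export
stage_stats <- function(config, outdir) {
  study <- .load_study(config, outdir)
  sdir <- .stats_dir(outdir)
  dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
  pr <- .usable_pairs(study, config)
  if (nrow(pr) == 0L) stop("no usable region pair to analyse")
  counts <- list()
  for (i in seq_len(nrow(pr))) {
    rp <- c(pr$ell[i], pr$ellprime[i])
    for (layer in c("mrna", "methylation")) {
      tab <- compute_pvalue_table(study, layer, rp, method = config$method)
      write_pvalue_table(tab, file.path(
        sdir, sprintf("pvalues_%s_%s_%s.tsv", layer, rp[1L], rp[2L])))
      sm <- summarize_direction_counts(tab, alpha = config$alpha,
                                       correction = config$correction)
      counts[[length(counts) + 1L]] <- data.frame(
        layer = layer, region_ell = rp[1L], region_ellprime = rp[2L],
        n_up = sm$n_up, n_down = sm$n_down,
        net_direction = sm$net_direction, stringsAsFactors = FALSE)
    }
  }
  .write_tsv(do.call(rbind, counts), file.path(sdir, "direction_counts.tsv"))
  invisible(study)
}

.read_pair_tables <- function(config, outdir, rp) {
  sdir <- .stats_dir(outdir)
  list(
    mrna = read_pvalue_table(file.path(
      sdir, sprintf("pvalues_mrna_%s_%s.tsv", rp[1L], rp[2L]))),
    methyl = read_pvalue_table(file.path(
      sdir, sprintf("pvalues_methylation_%s_%s.tsv", rp[1L], rp[2L])))
  )
}

.pairs_from_stats <- function(outdir) {
  sdir <- .stats_dir(outdir)
  files <- sort(list.files(sdir, pattern = "^pvalues_mrna_.*\\.tsv$"))
  if (!length(files)) stop("no P-value tables found; run the stats stage first")
  t(vapply(files, function(f) {
    parts <- strsplit(sub("\\.tsv$", "", f), "_")[[1L]]
    c(parts[3L], parts[4L])
  }, c("", "")))
}

#' Pipeline stage: regulation-methylation coupling
#'
#' Reads each pair's P-value tables and writes `coupling.tsv` (one row
#' per pair: rho_mean_rank, delta_rho, p_value, M, n_subjects) plus the
#' long-format `coupling_subjects.tsv` with every per-subject rho_j.
#' @param config a `run_config`
#' @param outdir output directory
#' @export
stage_couple <- function(config, outdir) {
  pairs <- .pairs_from_stats(outdir)
  rows <- list(); subj_rows <- list()
  for (i in seq_len(nrow(pairs))) {
    rp <- pairs[i, ]
    tabs <- .read_pair_tables(config, outdir, rp)
    cs <- coupling_correlation(tabs$mrna, tabs$methyl,
                               direction = config$direction)
    rows[[i]] <- data.frame(
      region_ell = rp[1L], region_ellprime = rp[2L],
      direction = cs$direction, rho_mean_rank = cs$rho_mean_rank,
      delta_rho = cs$delta_rho, p_value = as.numeric(cs$p_value),
      M = cs$M, n_subjects = cs$n_subjects, stringsAsFactors = FALSE)
    subj_rows[[i]] <- data.frame(
      region_ell = rp[1L], region_ellprime = rp[2L],
      subject_id = names(cs$rho_per_subject),
      rho_j = unname(cs$rho_per_subject), stringsAsFactors = FALSE)
  }
  .write_tsv(do.call(rbind, rows), file.path(outdir, "coupling.tsv"))
  .write_tsv(do.call(rbind, subj_rows),
             file.path(outdir, "coupling_subjects.tsv"))
  invisible(NULL)
}

#' Pipeline stage: per-miRNA regression and selection
#'
#' For every pair, regresses the signed regulation score on the
#' methylation score, the miRNA log-ratio, gender and age, applies the
#' configured selection, and writes one TSV per pair plus the combined
#' `regression.tsv`.
#' @param config a `run_config`
#' @param outdir output directory
#' @export
stage_regress <- function(config, outdir) {
  study <- .load_study(config, outdir)
  pairs <- .pairs_from_stats(outdir)
  all_rows <- list()
  for (i in seq_len(nrow(pairs))) {
    rp <- pairs[i, ]
    tabs <- .read_pair_tables(config, outdir, rp)
    designs <- build_design(study, tabs$mrna, tabs$methyl, rp)
    res <- select_mirnas(fit_all_regressions(designs),
                         alpha = config$alpha,
                         correction = config$correction,
                         criterion = config$criterion)
    res <- cbind(data.frame(region_ell = rp[1L], region_ellprime = rp[2L],
                            stringsAsFactors = FALSE), res)
    .write_tsv(res, file.path(outdir,
                              sprintf("regression_%s_%s.tsv", rp[1L], rp[2L])))
    all_rows[[i]] <- res
  }
  .write_tsv(do.call(rbind, all_rows), file.path(outdir, "regression.tsv"))
  invisible(NULL)
}

#' Pipeline stage: pathway enrichment of selected target genes
#'
#' For every pair and reciprocal label, enriches the union of the
#' selected miRNAs' target genes against the configured (or synthetic)
#' GMT, writing one TSV per non-empty condition plus the presence/absence
#' matrix `enrichment_presence.tsv`.
#' @param config a `run_config`
#' @param outdir output directory
#' @export
stage_enrich <- function(config, outdir) {
  study <- .load_study(config, outdir)
  gmt_path <- config$pathways %||% file.path(.inputs_dir(outdir), "pathways.gmt")
  db <- pathway_db(read_gmt(gmt_path), feature_ids(study$layers$mrna))
  reg <- .read_tsv(file.path(outdir, "regression.tsv"))
  results <- list()
  key_of <- function(e, ep, lab) sprintf("%s_vs_%s_%s", e, ep,
                                         if (lab == "reciprocal") "R" else "N")
  pairs <- unique(reg[, c("region_ell", "region_ellprime")])
  for (i in seq_len(nrow(pairs))) {
    for (lab in c("reciprocal", "nonreciprocal")) {
      sel <- reg$mirna_id[reg$region_ell == pairs$region_ell[i] &
                          reg$region_ellprime == pairs$region_ellprime[i] &
                          reg$selected & !is.na(reg$label) & reg$label == lab]
      if (!length(sel)) next
      key <- key_of(pairs$region_ell[i], pairs$region_ellprime[i], lab)
      res <- enrich(union_targets(sel, study$target_map), db,
                    alpha = config$alpha, correction = config$correction)
      .write_tsv(res, file.path(outdir, sprintf("enrichment_%s.tsv", key)))
      results[[key]] <- res
    }
  }
  if (length(results)) {
    .write_tsv(enrichment_presence_matrix(results, threshold = config$alpha),
               file.path(outdir, "enrichment_presence.tsv"))
  } else {
    .write_tsv(data.frame(pathway_id = character(), stringsAsFactors = FALSE),
               file.path(outdir, "enrichment_presence.tsv"))
  }
  invisible(NULL)
}

#' Run the full pipeline
#'
#' Executes simulate/load, stats, couple, regress and enrich in order and
#' writes `summary.json` (parameters, seed, per-stage counts). Rerunning
#' with an identical config and seed produces a byte-identical output
#' tree.
#'
#' @param config a `run_config` (or plain list coerced by [run_config()])
#' @param outdir output directory (created if absent)
#' @return the run summary list, invisibly
#' @export
run_pipeline <- function(config, outdir) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage_simulate(config, outdir)
  study <- stage_stats(config, outdir)
  stage_couple(config, outdir)
  stage_regress(config, outdir)
  stage_enrich(config, outdir)

  coupling <- .read_tsv(file.path(outdir, "coupling.tsv"))
  reg <- .read_tsv(file.path(outdir, "regression.tsv"))
  counts <- .read_tsv(file.path(.stats_dir(outdir), "direction_counts.tsv"))
  sel <- reg[reg$selected & !is.na(reg$label), , drop = FALSE]
  summary <- list(
    seed = config$seed %||% config$simulate$seed,
    method = config$method, alpha = config$alpha,
    correction = config$correction, criterion = config$criterion,
    direction = config$direction,
    n_region_pairs = nrow(coupling),
    n_mirnas_tested = length(unique(reg$mirna_id)),
    n_selected = nrow(sel),
    n_reciprocal = sum(sel$label == "reciprocal"),
    n_nonreciprocal = sum(sel$label == "nonreciprocal"),
    selected_mirnas = lapply(split(sel$mirna_id,
                                   .pair_key(sel$region_ell, sel$region_ellprime)),
                             sort),
    coupling = lapply(seq_len(nrow(coupling)), function(i) as.list(coupling[i, ])),
    direction_counts = lapply(seq_len(nrow(counts)), function(i) as.list(counts[i, ]))
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
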