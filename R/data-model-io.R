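#' Construct and validate a single omics layer
#'
#' An `omics_matrix` is one numeric layer (mRNA expression, miRNA
#' expression, or promoter methylation) stored features x samples.
#' Expression layers are kept on their positive native scale (logs are
#' applied downstream, with a pseudo-floor); methylation is on the beta
#' scale in \[0, 1\].
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   unique row and column names
#' @param layer_name one of `"mrna"`, `"mirna"`, `"methylation"`
#' @return an `omics_matrix` object
#' @export
omics_matrix <- function(values, layer_name = c("mrna", "mirna", "methylation")) {
  layer_name <- match.arg(layer_name)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    stop("`values` must carry feature (row) and sample (column) names")
  }
  dup_f <- fid[duplicated(fid)]
  if (length(dup_f)) {
    stop("duplicate feature id(s): ", paste(unique(dup_f), collapse = ", "))
  }
  dup_s <- sid[duplicated(sid)]
  if (length(dup_s)) {
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  }
  if (any(is.infinite(values))) {
    stop("non-finite values in layer '", layer_name, "'")
  }
  if (layer_name == "methylation") {
    bad <- values < 0 | values > 1
    if (any(bad, na.rm = TRUE)) {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      stop("methylation beta value outside [0,1] at feature '",
           fid[idx[1L]], "', sample '", sid[idx[2L]], "'")
    }
  }
  structure(list(layer_name = layer_name, values = values),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> layer=%s  %d features x %d samples\n",
              x$layer_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Read an omics layer from TSV
#'
#' Expects a tab-delimited file whose header row holds sample ids (the
#' first header cell is ignored) and whose first column holds feature ids,
#' matching the GEO series-matrix convention. Non-numeric cells raise an
#' error naming the offending feature and sample; empty cells and literal
#' `NA` are treated as missing.
#'
#' @param path file path
#' @param layer_name one of `"mrna"`, `"mirna"`, `"methylation"`
#' @return an [omics_matrix()]
#' @export
read_omics_matrix <- function(path, layer_name = c("mrna", "mirna", "methylation")) {
  layer_name <- match.arg(layer_name)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "")
  if (ncol(raw) < 2L) stop("matrix file needs a feature-id column plus >=1 sample column: ", path)
  fid <- raw[[1L]]
  sid <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow = length(fid), ncol = length(sid),
                 dimnames = list(fid, sid))
  for (j in seq_along(sid)) {
    cell <- raw[[j + 1L]]
    missing <- is.na(cell) | cell == "" | cell == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !missing)
    if (length(bad)) {
      stop("non-numeric cell '", cell[bad[1L]], "' at feature '",
           fid[bad[1L]], "', sample '", sid[j], "' in ", path)
    }
    vals[, j] <- num
  }
  omics_matrix(vals, layer_name)
}

#' Write an omics layer to TSV (inverse of [read_omics_matrix()])
#' @param x an `omics_matrix`
#' @param path output file path
#' @export
write_omics_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read and validate the sample annotation table
#'
#' Required columns: `sample_id`, `subject_id`, `region`, `age`, `gender`.
#' Region labels are free-form (the label set is inferred); gender must be
#' `male` or `female`; ages must be non-negative. Each subject may carry at
#' most one sample per region.
#'
#' @param path TSV file path
#' @return a validated `sample_annotation` data.frame
#' @export
read_sample_annotation <- function(path) {
  df <- .read_tsv(path)
  validate_sample_annotation(df)
}

#' @rdname read_sample_annotation
#' @param df a data.frame with the annotation columns
#' @export
validate_sample_annotation <- function(df) {
  need <- c("sample_id", "subject_id", "region", "age", "gender")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  df$region <- as.character(df$region)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample_id(s): ", paste(unique(dup), collapse = ", "))
  if (!is.numeric(df$age)) df$age <- suppressWarnings(as.numeric(df$age))
  if (any(!is.finite(df$age)) || any(df$age < 0)) {
    stop("age must be finite and >= 0 for every sample")
  }
  if (!all(df$gender %in% c("male", "female"))) {
    stop("gender must be 'male' or 'female'")
  }
  key <- paste(df$subject_id, df$region, sep = "\r")
  dup2 <- which(duplicated(key))
  if (length(dup2)) {
    stop("subject '", df$subject_id[dup2[1L]], "' has more than one sample in region '",
         df$region[dup2[1L]], "'")
  }
  df <- df[order(df$sample_id), need, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sample_annotation", "data.frame")
  df
}

#' Read a miRNA -> target gene map
#'
#' Two-column TSV (`mirna_id`, `gene_id`). Duplicate pairs are collapsed.
#' Target sets are intersected with `gene_universe`; miRNAs whose sets
#' become empty are dropped with a warning. The retained count M is stored
#' as attribute `"M"`.
#'
#' @param path TSV file path
#' @param gene_universe character vector of admissible gene ids (typically
#'   the mRNA layer's feature ids); `NULL` keeps all genes
#' @return a `target_map`: named list of character vectors
#' @export
read_target_map <- function(path, gene_universe = NULL) {
  if (!file.exists(path) || file.size(path) == 0L) {
    stop("empty target map file: ", path)
  }
  df <- .read_tsv(path)
  if (nrow(df) == 0L) stop("empty target map file: ", path)
  if (!all(c("mirna_id", "gene_id") %in% colnames(df))) {
    # headerless two-column file: re-read
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "")
    colnames(df) <- c("mirna_id", "gene_id")
  }
  target_map(df$mirna_id, df$gene_id, gene_universe)
}

#' @rdname read_target_map
#' @param mirna_id,gene_id parallel character vectors of pairs
#' @export
target_map <- function(mirna_id, gene_id, gene_universe = NULL) {
  mirna_id <- as.character(mirna_id)
  gene_id <- as.character(gene_id)
  stopifnot(length(mirna_id) == length(gene_id), length(mirna_id) > 0L)
  tm <- lapply(split(gene_id, mirna_id), function(g) sort(unique(g)))
  if (!is.null(gene_universe)) {
    tm <- lapply(tm, function(g) g[g %in% gene_universe])
    empty <- vapply(tm, length, 0L) == 0L
    if (any(empty)) {
      warning(sum(empty), " miRNA(s) dropped: no targets left after ",
              "intersection with the gene universe")
      tm <- tm[!empty]
    }
  }
  if (length(tm) == 0L) stop("no miRNA retains a non-empty target set")
  tm <- tm[order(names(tm))]
  structure(tm, class = "target_map", M = length(tm))
}

#' Write a target map as a two-column TSV
#' @param tm a `target_map`
#' @param path output path
#' @export
write_target_map <- function(tm, path) {
  df <- data.frame(
    mirna_id = rep(names(tm), lengths(tm)),
    gene_id = unlist(tm, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  .write_tsv(df, path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-delimited fields name, description,
#' then member genes.
#' @param path GMT file path
#' @return named list of character vectors (gene sets)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line (need name, description, >=1 gene): ", ln)
    sort(unique(f[-(1:2)]))
  })
  names(sets) <- vapply(lines, function(ln) strsplit(ln, "\t", fixed = TRUE)[[1L]][1L], "")
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors
#' @param path output path
#' @param description description field (recycled)
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Assemble the subject-paired multi-layer study object
#'
#' Combines the three omics layers, the annotation and the target map into
#' an `aligned_study`. For every region pair, paired subjects are those
#' with a sample in both regions in all three layers; pairs with fewer
#' than three paired subjects are flagged unusable. Assembly is
#' deterministic: regions and paired subject lists are sorted, so row
#' permutations of the inputs yield the identical object.
#'
#' @param layers named list with elements `mrna`, `mirna`, `methylation`,
#'   each an [omics_matrix()]
#' @param annotation a `sample_annotation` (see [read_sample_annotation()])
#' @param tm a `target_map`; target sets are re-intersected with the mRNA
#'   layer's feature universe
#' @return an `aligned_study`
#' @export
assemble_study <- function(layers, annotation, tm) {
  stopifnot(all(c("mrna", "mirna", "methylation") %in% names(layers)))
  for (nm in c("mrna", "mirna", "methylation")) {
    if (!inherits(layers[[nm]], "omics_matrix")) {
      stop("layers$", nm, " is not an omics_matrix")
    }
    unknown <- setdiff(sample_ids(layers[[nm]]), annotation$sample_id)
    if (length(unknown)) {
      stop("sample id(s) in layer '", nm, "' missing from annotation: ",
           paste(utils::head(unknown, 3L), collapse = ", "))
    }
  }
  annotation <- validate_sample_annotation(as.data.frame(annotation))
  tm <- target_map(rep(names(tm), lengths(tm)), unlist(tm, use.names = FALSE),
                   gene_universe = feature_ids(layers$mrna))

  regions <- sort(unique(annotation$region))
  pairs <- region_pairs(regions)

  # subject x region -> sample id lookup
  akey <- .pair_key(annotation$subject_id, annotation$region)
  samp_of <- stats::setNames(annotation$sample_id, akey)

  subjects_in <- function(region) {
    subj <- annotation$subject_id[annotation$region == region]
    keep <- vapply(subj, function(s) {
      sid <- samp_of[[.pair_key(s, region)]]
      all(vapply(layers, function(ly) sid %in% sample_ids(ly), TRUE))
    }, TRUE)
    sort(subj[keep])
  }
  by_region <- lapply(stats::setNames(regions, regions), subjects_in)

  paired <- vector("list", nrow(pairs))
  names(paired) <- .pair_key(pairs$ell, pairs$ellprime)
  for (i in seq_len(nrow(pairs))) {
    paired[[i]] <- intersect(by_region[[pairs$ell[i]]],
                             by_region[[pairs$ellprime[i]]])
  }
  pairs$n_paired <- vapply(paired, length, 0L)
  pairs$usable <- pairs$n_paired >= 3L

  structure(list(
    layers = layers[c("mrna", "mirna", "methylation")],
    annotation = annotation,
    target_map = tm,
    region_labels = regions,
    pairs = pairs,
    paired_subjects = paired
  ), class = "aligned_study")
}

#' @export
print.aligned_study <- function(x, ...) {
  cat(sprintf(paste0(
    "<aligned_study> %d genes, %d miRNAs (M=%d with targets), %d methylation probes\n",
    "  %d samples / %d subjects across regions: %s\n"),
    nrow(x$layers$mrna$values), nrow(x$layers$mirna$values),
    attr(x$target_map, "M"), nrow(x$layers$methylation$values),
    nrow(x$annotation), length(unique(x$annotation$subject_id)),
    paste(x$region_labels, collapse = ", ")))
  print(x$pairs)
  invisible(x)
}

#' Sample id of a subject in a region
#' @keywords internal
.sample_of <- function(annotation, subject, region) {
  hit <- annotation$sample_id[annotation$subject_id == subject &
                              annotation$region == region]
  if (length(hit) != 1L) {
    stop("subject '", subject, "' has no unique sample in region '", region, "'")
  }
  hit
}

#' Paired subjects of a region pair
#' @param study an `aligned_study`
#' @param region_pair character vector `c(ell, ellprime)`
#' @export
paired_subjects <- function(study, region_pair) {
  key <- .pair_key(region_pair[1L], region_pair[2L])
  ps <- study$paired_subjects[[key]]
  if (is.null(ps)) {
    # allow the swapped orientation
    key2 <- .pair_key(region_pair[2L], region_pair[1L])
    ps <- study$paired_subjects[[key2]]
  }
  if (is.null(ps)) stop("unknown region pair: ", key)
  ps
}
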