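#' Pathway database restricted to a study's gene universe
#'
#' The testing universe is the union of all pathway genes intersected
#' with the study's gene universe — the conservative choice when the
#' original tool's universe is unknown. Pathways left empty after
#' intersection are dropped.
#'
#' @param sets named list of gene sets (e.g. from [read_gmt()])
#' @param gene_universe character vector of study gene ids
#' @return a `pathway_db`: list with `sets` and `universe`
#' @export
pathway_db <- function(sets, gene_universe) {
  stopifnot(length(sets) > 0L, !is.null(names(sets)))
  sets <- lapply(sets, function(g) sort(unique(g[g %in% gene_universe])))
  sets <- sets[vapply(sets, length, 0L) > 0L]
  if (!length(sets)) stop("no pathway retains any gene in the study universe")
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  structure(list(sets = sets[order(names(sets))], universe = universe),
            class = "pathway_db")
}

#' Union of the target sets of selected miRNAs
#' @param selected_mirnas character vector of miRNA ids
#' @param tm a `target_map`
#' @return character vector (sorted union of the target sets; empty for
#'   an empty selection)
#' @export
union_targets <- function(selected_mirnas, tm) {
  if (length(selected_mirnas) == 0L) return(character())
  miss <- setdiff(selected_mirnas, names(tm))
  if (length(miss)) {
    stop("selected miRNA(s) absent from the target map: ",
         paste(utils::head(miss, 3L), collapse = ", "))
  }
  sort(unique(unlist(tm[selected_mirnas], use.names = FALSE)))
}

#' Upper-tail hypergeometric enrichment P-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least k pathway genes when n query genes are drawn without
#' replacement from a universe of N genes of which K are in the pathway.
#'
#' @param k overlap count
#' @param K pathway size
#' @param n query size
#' @param N universe size
#' @return P-value in (0, 1\]
#' @export
hypergeometric_test <- function(k, K, n, N) {
  if (!(k >= 0 && K >= 0 && n >= 0 && N >= 0 &&
        k <= min(K, n) && K <= N && n <= N)) {
    stop("infeasible hypergeometric bounds: need 0 <= k <= min(K, n) <= N")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric enrichment of a gene set against a pathway database
#'
#' Query genes outside the universe are dropped (count reported via a
#' message). One result row per pathway, BH-adjusted across pathways,
#' sorted by adjusted then raw P then pathway id so the output is
#' invariant under pathway input order.
#'
#' @param query character vector of gene ids
#' @param db a [pathway_db()]
#' @param alpha significance level used for the `significant` flag
#' @param correction `"BH"` (default) or `"none"`
#' @return data.frame: pathway_id, k, K, n, N, p_value, p_adj,
#'   significant, overlap_genes (comma-separated)
#' @export
enrich <- function(query, db, alpha = 0.05, correction = c("BH", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(db, "pathway_db"))
  if (!length(db$universe)) stop("empty pathway universe")
  query <- unique(query)
  outside <- setdiff(query, db$universe)
  if (length(outside)) {
    .msg(length(outside), " query gene(s) outside the pathway universe dropped")
  }
  query <- intersect(query, db$universe)
  n <- length(query)
  N <- length(db$universe)
  ids <- names(db$sets)
  rows <- lapply(ids, function(pid) {
    pw <- db$sets[[pid]]
    ov <- intersect(query, pw)
    data.frame(pathway_id = pid, k = length(ov), K = length(pw),
               n = n, N = N,
               p_value = hypergeometric_test(length(ov), length(pw), n, N),
               overlap_genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (correction == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- out$p_adj <= alpha
  out <- out[order(out$p_adj, out$p_value, out$pathway_id), ]
  rownames(out) <- NULL
  out[, c("pathway_id", "k", "K", "n", "N", "p_value", "p_adj",
          "significant", "overlap_genes")]
}

#' Presence/absence matrix across enrichment runs
#'
#' Builds the pathway x condition matrix of significant calls (adjusted
#' P <= threshold) across several enrichment results — one run per
#' region pair and reciprocal label, mirroring a per-pair R/N layout.
#'
#' @param results named list of data.frames from [enrich()]; names become
#'   columns
#' @param threshold adjusted-P cutoff (default 0.05)
#' @return data.frame with `pathway_id` and one 0/1 column per condition,
#'   restricted to pathways significant in at least one condition
#' @export
enrichment_presence_matrix <- function(results, threshold = 0.05) {
  stopifnot(length(results) > 0L, !is.null(names(results)))
  all_pw <- sort(unique(unlist(lapply(results, `[[`, "pathway_id"))))
  m <- sapply(results, function(res) {
    hit <- res$pathway_id[res$p_adj <= threshold]
    as.integer(all_pw %in% hit)
  })
  m <- matrix(m, nrow = length(all_pw),
              dimnames = list(all_pw, names(results)))
  keep <- rowSums(m) > 0L
  out <- data.frame(pathway_id = all_pw[keep],
                    m[keep, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
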