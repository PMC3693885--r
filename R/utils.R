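#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pseudo-floor applied to positive-scale signals before taking logs
#'
#' Processed array signals can be zero or negative after background
#' correction; values are floored at `eps` before the natural log.
#' @keywords internal
.LOG_EPS <- 1e-8

.log_floor <- function(x, eps = .LOG_EPS) log(pmax(x, eps))

.pair_key <- function(ell, ellprime) paste(ell, ellprime, sep = "|")

#' Enumerate unordered region pairs in deterministic (sorted) order
#' @param labels character vector of region labels
#' @return data.frame with columns `ell`, `ellprime`
#' @export
region_pairs <- function(labels) {
  labels <- sort(unique(as.character(labels)))
  if (length(labels) < 2L) {
    stop("need at least two region labels to form pairs")
  }
  cmb <- utils::combn(labels, 2L)
  data.frame(ell = cmb[1L, ], ellprime = cmb[2L, ], stringsAsFactors = FALSE)
}

#' Net direction from up/down significance counts
#'
#' The miRNA-centric comparison used in the region-graph summaries: if more
#' miRNAs have significantly upregulated target sets than downregulated ones
#' (in region ell relative to ellprime), the net call is "up", and vice
#' versa; equal counts give "none".
#'
#' @param n_up number of miRNAs significant in the greater direction
#' @param n_down number of miRNAs significant in the less direction
#' @return one of "up", "down", "none"
#' @export
net_direction_from_counts <- function(n_up, n_down) {
  stopifnot(length(n_up) == 1L, length(n_down) == 1L,
            is.finite(n_up), is.finite(n_down))
  if (n_up > n_down) "up" else if (n_down > n_up) "down" else "none"
}

.msg <- function(..., verbose = getOption("miRegMet.verbose", FALSE)) {
  if (isTRUE(verbose)) message(...)
}

#' Deterministic TSV writer
#'
#' All pipeline outputs go through this single writer so that identical
#' inputs produce byte-identical files.
#' @keywords internal
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", ...)
}
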