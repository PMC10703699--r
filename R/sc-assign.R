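# Single-cell guide assignment and screen/single-cell concordance.
#
# Cells are assigned every guide whose capture UMI count exceeds the
# threshold (strictly; the conventional cutoff is UMI > 4); cell QC keeps
# boundary values because the discard rules are strict inequalities.

#' Filter cells on QC statistics
#'
#' Discards low-quality cells with fewer than `min_genes` detected genes,
#' more than `max_mito` percent mitochondrial reads, or less than `min_ribo`
#' percent ribosomal reads. Inequalities are strict for discarding, so cells
#' exactly at a threshold are kept.
#'
#' @param stats Data frame with columns `cell`, `n_genes_detected`,
#'   `pct_mito`, `pct_ribo` (percentages in \[0, 100\]).
#' @param min_genes,max_mito,min_ribo QC thresholds (defaults 200, 20, 5).
#' @return Character vector of kept cell barcodes.
#' @export
qc_filter_cells <- function(stats, min_genes = 200, max_mito = 20,
                            min_ribo = 5) {
  stopifnot(all(c("cell", "n_genes_detected", "pct_mito", "pct_ribo") %in%
                  names(stats)))
  keep <- stats$n_genes_detected >= min_genes &
    stats$pct_mito <= max_mito &
    stats$pct_ribo >= min_ribo
  stats$cell[keep]
}

#' Assign guides to cells from UMI counts
#'
#' A guide is assigned to a cell iff its UMI count is strictly greater than
#' `threshold`. Cells may carry zero, one, or several guides.
#'
#' @param umi Cells x guides integer matrix with cell barcodes as rownames
#'   and guide ids as colnames.
#' @param threshold UMI threshold (default 4, i.e. "UMI > 4").
#' @return A `guide_assignment`: list with `assignments` (named list cell ->
#'   character vector of guide ids) and a `summary` of
#'   unassigned/singlet/multiplet cell counts.
#' @export
assign_guides <- function(umi, threshold = 4L) {
  stopifnot(threshold >= 0)
  umi <- as.matrix(umi)
  hits <- umi > threshold
  assignments <- apply(hits, 1, function(r) colnames(umi)[r],
                       simplify = FALSE)
  n_per_cell <- vapply(assignments, length, integer(1))
  structure(list(
    assignments = assignments,
    summary = c(unassigned = sum(n_per_cell == 0),
                singlet = sum(n_per_cell == 1),
                multiplet = sum(n_per_cell >= 2)),
    threshold = threshold
  ), class = "guide_assignment")
}

#' @export
print.guide_assignment <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "guide_assignment (UMI > %d): %d singlets, %d multiplets, %d unassigned\n",
    x$threshold, s["singlet"], s["multiplet"], s["unassigned"]))
  invisible(x)
}

# Singlet cells only, as a named vector cell -> guide.
singlet_cells <- function(assignment) {
  a <- assignment$assignments
  n <- vapply(a, length, integer(1))
  stats::setNames(unlist(a[n == 1], use.names = FALSE), names(a)[n == 1])
}

#' Per-guide marker response versus NT-only cells
#'
#' Compares marker expression of cells carrying each guide with cells
#' carrying only NT guides, with a two-sided rank-sum test and Bonferroni
#' correction across guides. Multiplet cells are excluded by default; guides
#' with fewer than `min_cells` cells are excluded and reported. NT guides
#' themselves can be tested (against NT cells not carrying them), which
#' supplies the true-negative denominator for [concordance_rates()].
#'
#' @param expression Named numeric vector of per-cell marker values.
#' @param assignment A `guide_assignment` from [assign_guides()].
#' @param nt_guides Character vector of NT guide ids.
#' @param min_cells Minimum cells per guide group (default 5).
#' @param alpha Significance level applied to the Bonferroni-adjusted p
#'   (default 0.05).
#' @param test Test function `(x, y) -> list(p.value = ...)`; defaults to
#'   [stats::wilcox.test()] (the hurdle-model alternative is pluggable here).
#' @param include_multiplets Include cells with >= 2 assigned guides in the
#'   guide groups (default `FALSE`).
#' @return Data frame: `guide_id`, `n_cells`, `direction` (+1/-1 sign of the
#'   median shift), `pvalue`, `p_bonf`, `significant`, `tested`, `is_nt`.
#' @export
marker_response_test <- function(expression, assignment, nt_guides,
                                 min_cells = 5L, alpha = 0.05,
                                 test = stats::wilcox.test,
                                 include_multiplets = FALSE) {
  if (include_multiplets) {
    a <- assignment$assignments
    cells_of <- function(g) names(a)[vapply(a, function(v) g %in% v,
                                            logical(1))]
    nt_only <- names(a)[vapply(a, function(v) {
      length(v) >= 1 && all(v %in% nt_guides)
    }, logical(1))]
    guides <- unique(unlist(a, use.names = FALSE))
  } else {
    sing <- singlet_cells(assignment)
    cells_of <- function(g) names(sing)[sing == g]
    nt_only <- names(sing)[sing %in% nt_guides]
    guides <- unique(unname(sing))
  }
  if (length(nt_only) == 0) stop("no NT-only cells to compare against")
  guides <- sort(guides)
  res <- data.frame(guide_id = guides, n_cells = 0L, direction = NA_real_,
                    pvalue = NA_real_, p_bonf = NA_real_,
                    significant = NA, tested = FALSE,
                    is_nt = guides %in% nt_guides,
                    stringsAsFactors = FALSE)
  for (i in seq_along(guides)) {
    g <- guides[i]
    cells <- cells_of(g)
    ref <- setdiff(nt_only, cells)
    res$n_cells[i] <- length(cells)
    if (length(cells) < min_cells || length(ref) < min_cells) next
    x <- expression[cells]; y <- expression[ref]
    tt <- suppressWarnings(test(x, y))
    res$pvalue[i] <- tt$p.value
    res$direction[i] <- sign(stats::median(x) - stats::median(y))
    res$tested[i] <- TRUE
  }
  n_tested <- sum(res$tested)
  res$p_bonf <- pmin(res$pvalue * n_tested, 1)
  res$significant <- ifelse(res$tested, res$p_bonf < alpha, NA)
  res
}

#' Screen/single-cell concordance: TP and TN rates
#'
#' TP rate: fraction of tested screen-hit guides with a significant marker
#' change in the screen-concordant direction (set `directional = FALSE` to
#' drop the direction requirement). TN rate: fraction of tested NT guides
#' with no significant marker change.
#'
#' @param screen_hits Named numeric vector guide id -> expected direction
#'   (+1 or -1) for screen-hit guides.
#' @param responses Data frame from [marker_response_test()].
#' @param directional Require the response direction to match the screen
#'   direction (default `TRUE`).
#' @return A `concordance_report`: `tp_rate`, `tn_rate`, their denominators,
#'   and the per-guide call table.
#' @export
concordance_rates <- function(screen_hits, responses, directional = TRUE) {
  hit_ids <- names(screen_hits)
  nt_ids <- responses$guide_id[responses$is_nt]
  if (length(intersect(hit_ids, nt_ids))) {
    stop("screen-hit and NT guide sets must be disjoint")
  }
  hits <- responses[responses$guide_id %in% hit_ids & responses$tested, ,
                    drop = FALSE]
  nts <- responses[responses$is_nt & responses$tested, , drop = FALSE]
  concordant <- hits$significant &
    (!directional | hits$direction == screen_hits[hits$guide_id])
  structure(list(
    tp_rate = if (nrow(hits)) mean(concordant) else NA_real_,
    n_hits_tested = nrow(hits),
    tn_rate = if (nrow(nts)) mean(!nts$significant) else NA_real_,
    n_nt_tested = nrow(nts),
    calls = responses
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance: TP %.2f (n = %d hit guides), TN %.2f (n = %d NT guides)\n",
              x$tp_rate, x$n_hits_tested, x$tn_rate, x$n_nt_tested))
  invisible(x)
}

#' Write a cell x guide UMI matrix in MatrixMarket triplet format
#'
#' Writes `<prefix>.mtx` plus `<prefix>.barcodes.txt` and
#' `<prefix>.guides.txt`.
#'
#' @param umi Cells x guides integer matrix with dimnames.
#' @param prefix Output path prefix.
#' @export
write_cell_guide_mtx <- function(umi, prefix) {
  m <- Matrix::Matrix(as.matrix(umi), sparse = TRUE)
  Matrix::writeMM(m, paste0(prefix, ".mtx"))
  writeLines(rownames(umi), paste0(prefix, ".barcodes.txt"))
  writeLines(colnames(umi), paste0(prefix, ".guides.txt"))
  invisible(prefix)
}

#' Read a cell x guide UMI matrix written by [write_cell_guide_mtx()]
#'
#' @param prefix Path prefix.
#' @return Dense cells x guides integer matrix with dimnames.
#' @export
read_cell_guide_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(m) <- readLines(paste0(prefix, ".barcodes.txt"))
  colnames(m) <- readLines(paste0(prefix, ".guides.txt"))
  storage.mode(m) <- "integer"
  m
}
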