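# Gene-level inference for sort-bin screens: non-targeting-calibrated
# empirical p-value transformation, robust rank aggregation (RRA) per gene,
# a simulated uniform null for exact gene-level p-values, non-targeting
# pseudo-genes (NTCs) as a built-in false-positive gauge, joint BH FDR, and
# weighted directional effect sizes.

#' Build an empirical calibration map from non-targeting p-values
#'
#' Midpoint linear interpolation of the sorted NT p-values onto plotting
#' positions (i - 0.5)/n, anchored at (0, 0) and (1, 1). Applying the map to
#' p-values aligns them with the null hypothesis that NT p-values are
#' uniform on (0, 1): whatever miscalibration the NT guides display is
#' removed from every guide.
#'
#' @param nt_pvalues Numeric vector of at least 10 NT p-values in \[0, 1\].
#' @param direction One of `"two_sided"`, `"high"`, `"low"` — a tag recording
#'   which p-value family the map was built from.
#' @return A `calibration_map` with knots `x` (sorted NT p-values, ties
#'   collapsed to the mean plotting position) and `y`.
#' @export
build_calibration <- function(nt_pvalues,
                              direction = c("two_sided", "high", "low")) {
  direction <- match.arg(direction)
  p <- nt_pvalues[!is.na(nt_pvalues)]
  if (length(p) < 10) {
    stop("need at least 10 NT p-values to calibrate (got ", length(p), ")")
  }
  if (any(p < 0 | p > 1)) stop("NT p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p)
  x <- p[o]
  y <- (seq_len(n) - 0.5) / n
  # ties collapse to a single knot at the mean plotting position
  agg <- vapply(split(y, x), mean, numeric(1))
  x <- as.numeric(names(agg))
  y <- unname(agg)
  # keep observed knots strictly inside (0, 1) so the anchors always hold
  eps <- 1e-12
  x <- pmin(pmax(x, eps), 1 - eps)
  structure(list(x = c(0, x, 1), y = c(0, y, 1), n_nt = n,
                 direction = direction),
            class = "calibration_map")
}

#' Apply a calibration map to p-values
#'
#' Piecewise-linear interpolation through the calibration knots, clamped to
#' \[0, 1\].
#'
#' @param map A `calibration_map` from [build_calibration()].
#' @param p Numeric vector of p-values.
#' @return Transformed p-values; `NA`s propagate.
#' @export
calibrate <- function(map, p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::approx(map$x, map$y, xout = pmin(pmax(p[ok], 0), 1),
                           rule = 2, ties = "ordered")$y
  pmin(pmax(out, 0), 1)
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf("calibration_map (%s): %d NT p-values, %d knots\n",
              x$direction, x$n_nt, length(x$x)))
  invisible(x)
}

#' Robust rank aggregation statistic
#'
#' For p-values p(1) <= ... <= p(k), rho is the minimum over j of the Beta
#' CDF of p(j) with shape (j, k - j + 1) — the probability that the j-th
#' order statistic of k uniforms is at most p(j). Small rho means the
#' smallest p-values are smaller than uniformity predicts.
#'
#' @param transformed_p Numeric vector of (calibrated) p-values in \[0, 1\],
#'   length >= 1.
#' @return The rho statistic, in (0, 1\].
#' @export
rra_rho <- function(transformed_p) {
  p <- transformed_p[!is.na(transformed_p)]
  k <- length(p)
  if (k == 0) stop("rra_rho needs at least one p-value")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  ps <- sort(p)
  j <- seq_len(k)
  min(stats::pbeta(ps, j, k - j + 1))
}

# Sorted uniform order statistics for `n` draws of size k, via normalized
# exponential spacings (vectorised over draws); returns the n x k matrix.
sorted_uniforms <- function(n, k) {
  e <- matrix(stats::rexp(n * (k + 1)), n, k + 1)
  for (j in 2:(k + 1)) e[, j] <- e[, j] + e[, j - 1]
  e[, seq_len(k), drop = FALSE] / e[, k + 1]
}

rho_null_draws <- function(n, k) {
  u <- sorted_uniforms(n, k)
  rho <- stats::pbeta(u[, 1], 1, k)
  if (k > 1) {
    for (j in 2:k) rho <- pmin(rho, stats::pbeta(u[, j], j, k - j + 1))
  }
  rho
}

#' Simulate the null distribution of rho per gene size
#'
#' For each gene size k, draws `n_sim` sets of k independent uniforms and
#' stores the sorted rho values. Gene-level p-values are then empirical tail
#' probabilities against this table, which makes the inference exact under
#' the calibrated null regardless of the rho variant.
#'
#' @param sizes Integer vector of distinct gene sizes k to cover.
#' @param n_sim Number of null simulations per size (>= 10,000). The
#'   full-scale default used for reported analyses is 1e7; tests use 1e5.
#' @param seed Integer seed.
#' @param chunk Draws per block (memory control).
#' @return A `null_table`: list of sorted rho vectors, one per size.
#' @export
build_null_table <- function(sizes, n_sim = 1e5, seed = NULL, chunk = 1e6) {
  if (n_sim < 1e4) stop("n_sim must be at least 10,000")
  sizes <- sort(unique(as.integer(sizes)))
  stopifnot(all(sizes >= 1))
  with_seed(seed, {
    tabs <- lapply(sizes, function(k) {
      done <- 0
      parts <- list()
      while (done < n_sim) {
        m <- min(chunk, n_sim - done)
        parts[[length(parts) + 1]] <- rho_null_draws(m, k)
        done <- done + m
      }
      sort(unlist(parts))
    })
    structure(list(rho = stats::setNames(tabs, as.character(sizes)),
                   n_sim = n_sim, sizes = sizes, seed = seed),
              class = "null_table")
  })
}

#' Empirical gene-level p-value from the null table
#'
#' p = (1 + #\{null rho <= rho\}) / (n_sim + 1); never returns 0.
#'
#' @param null_table A `null_table` from [build_null_table()].
#' @param rho Observed rho value(s).
#' @param k Gene size (one of the table's sizes).
#' @return Empirical p-value(s) in \[1/(n_sim + 1), 1\].
#' @export
null_pvalue <- function(null_table, rho, k) {
  tab <- null_table$rho[[as.character(k)]]
  if (is.null(tab)) stop("null table does not cover gene size k = ", k)
  (1 + findInterval(rho, tab)) / (null_table$n_sim + 1)
}

#' Group non-targeting guides into NTC pseudo-genes
#'
#' Sizes are drawn with replacement from the screen's guides-per-gene
#' distribution until all NT guides are used; NT guides are assigned in a
#' seeded random order and only the final group may deviate from its drawn
#' size (it takes the remainder).
#'
#' @param nt_guide_ids Character vector of NT guide ids (>= 2).
#' @param gene_sizes Integer multiset of guides-per-gene in the screen.
#' @param seed Integer seed.
#' @return An `ntc_partition`: named list NTC id -> guide ids.
#' @export
partition_ntc <- function(nt_guide_ids, gene_sizes, seed = NULL) {
  if (length(nt_guide_ids) < 2) stop("need at least 2 NT guides")
  gene_sizes <- as.integer(gene_sizes)
  stopifnot(length(gene_sizes) >= 1, all(gene_sizes >= 1))
  with_seed(seed, {
    ids <- sample(nt_guide_ids)
    groups <- list()
    i <- 1L
    while (i <= length(ids)) {
      size <- gene_sizes[sample.int(length(gene_sizes), 1)]
      take <- min(size, length(ids) - i + 1L)
      groups[[length(groups) + 1]] <- ids[i:(i + take - 1L)]
      i <- i + take
    }
    names(groups) <- sprintf("NTC_%03d", seq_along(groups))
    structure(groups, class = "ntc_partition")
  })
}

#' Directional weighted gene effect sizes
#'
#' Weighted means of the per-guide unshrunk log2 fold changes, weighted in
#' each direction by w = 1 - p-tilde (the calibrated one-sided p-value of
#' that direction), so guides significant in a direction dominate that
#' direction's effect. `E_chosen` is the larger in absolute value, ties
#' broken toward `E_high`. `weight_mode = "literal_p"` uses w = p-tilde
#' instead.
#'
#' @param betas Per-guide unshrunk log2 fold changes.
#' @param p_high_tilde,p_low_tilde Calibrated one-sided p-values.
#' @param weight_mode `"one_minus_p"` (default) or `"literal_p"`.
#' @return List: `E_high`, `E_low`, `E_chosen`, `direction` ("high"/"low").
#' @export
gene_effect_sizes <- function(betas, p_high_tilde, p_low_tilde,
                              weight_mode = c("one_minus_p", "literal_p")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(length(betas) >= 1,
            length(betas) == length(p_high_tilde),
            length(betas) == length(p_low_tilde))
  wfun <- if (weight_mode == "one_minus_p") function(p) 1 - p else identity
  wmean <- function(w) {
    if (sum(w) <= 0) return(NA_real_)
    sum(w * betas) / sum(w)
  }
  E_high <- wmean(wfun(p_high_tilde))
  E_low <- wmean(wfun(p_low_tilde))
  if (is.na(E_high) && is.na(E_low)) {
    return(list(E_high = NA_real_, E_low = NA_real_, E_chosen = NA_real_,
                direction = NA_character_))
  }
  ah <- if (is.na(E_high)) -Inf else abs(E_high)
  al <- if (is.na(E_low)) -Inf else abs(E_low)
  if (ah >= al) {
    list(E_high = E_high, E_low = E_low, E_chosen = E_high,
         direction = "high")
  } else {
    list(E_high = E_high, E_low = E_low, E_chosen = E_low,
         direction = "low")
  }
}

#' Gene-level aggregation of per-guide screen statistics
#'
#' The full gene-level procedure: calibrate per-guide two-sided p-values on
#' the NT guides, aggregate within gene by [rra_rho()], compare with the
#' simulated uniform null to obtain an empirical gene p-value, analyze NTC
#' pseudo-genes identically, apply BH across genes and NTCs jointly, and
#' compute directional weighted effect sizes from the one-sided calibrations.
#' Hits are genes (never NTCs) with FDR below `fdr`.
#'
#' @param guide_stats Data frame from [guide_enrichment()] (needs
#'   `guide_id`, `target_gene`, `log2fc`, `pvalue`, `p_high`, `p_low`, `ok`).
#' @param null_table Optional pre-built [build_null_table()]; built on the
#'   fly (at `n_sim`) when `NULL`.
#' @param n_sim Null simulations per gene size when building the table.
#' @param seed Integer seed (NTC grouping and null table).
#' @param fdr Hit threshold on the BH FDR (default 0.05).
#' @param weight_mode Effect-size weighting, see [gene_effect_sizes()].
#' @param ntc_partition Optional pre-built [partition_ntc()].
#' @return Data frame with one row per gene/NTC: `gene`, `k`, `rho`,
#'   `p_gene`, `q_gene`, `E_high`, `E_low`, `E_chosen`, `direction`,
#'   `is_ntc`, `is_hit`. Genes whose guides were all excluded upstream are
#'   reported with missing statistics (`k = 0`).
#' @export
aggregate_genes <- function(guide_stats, null_table = NULL, n_sim = 1e5,
                            seed = NULL, fdr = 0.05,
                            weight_mode = c("one_minus_p", "literal_p"),
                            ntc_partition = NULL) {
  weight_mode <- match.arg(weight_mode)
  gs <- guide_stats
  usable <- gs$ok & !is.na(gs$pvalue)
  nt <- gs$target_gene == NON_TARGETING

  nt_ok <- gs[nt & usable, , drop = FALSE]
  cal2 <- build_calibration(nt_ok$pvalue, "two_sided")
  cal_h <- build_calibration(nt_ok$p_high, "high")
  cal_l <- build_calibration(nt_ok$p_low, "low")

  genes <- unique(gs$target_gene[!nt])
  gene_guides <- lapply(genes, function(g) {
    gs[!nt & usable & gs$target_gene == g, , drop = FALSE]
  })
  names(gene_guides) <- genes

  gene_sizes <- vapply(gene_guides, nrow, integer(1))
  if (is.null(ntc_partition)) {
    ntc_partition <- partition_ntc(nt_ok$guide_id,
                                   gene_sizes[gene_sizes >= 1],
                                   seed = seed)
  }
  ntc_guides <- lapply(ntc_partition, function(ids) {
    gs[gs$guide_id %in% ids, , drop = FALSE]
  })

  all_units <- c(gene_guides, ntc_guides)
  is_ntc <- c(rep(FALSE, length(gene_guides)), rep(TRUE, length(ntc_guides)))
  ks <- vapply(all_units, nrow, integer(1))

  if (is.null(null_table)) {
    null_table <- build_null_table(unique(ks[ks >= 1]), n_sim = n_sim,
                                   seed = if (is.null(seed)) NULL else
                                     seed + 1L)
  }

  res <- data.frame(
    gene = names(all_units), k = ks, rho = NA_real_, p_gene = NA_real_,
    q_gene = NA_real_, E_high = NA_real_, E_low = NA_real_,
    E_chosen = NA_real_, direction = NA_character_, is_ntc = is_ntc,
    is_hit = FALSE, stringsAsFactors = FALSE, row.names = NULL
  )
  for (i in seq_along(all_units)) {
    u <- all_units[[i]]
    if (nrow(u) == 0) next  # untestable: all guides excluded upstream
    pt <- calibrate(cal2, u$pvalue)
    res$rho[i] <- rra_rho(pt)
    res$p_gene[i] <- null_pvalue(null_table, res$rho[i], nrow(u))
    eff <- gene_effect_sizes(u$log2fc, calibrate(cal_h, u$p_high),
                             calibrate(cal_l, u$p_low),
                             weight_mode = weight_mode)
    res$E_high[i] <- eff$E_high
    res$E_low[i] <- eff$E_low
    res$E_chosen[i] <- eff$E_chosen
    res$direction[i] <- eff$direction
  }
  res$q_gene <- bh_adjust(res$p_gene)
  res$is_hit <- !res$is_ntc & !is.na(res$q_gene) & res$q_gene < fdr
  attr(res, "calibrations") <- list(two_sided = cal2, high = cal_h,
                                    low = cal_l)
  attr(res, "ntc_partition") <- ntc_partition
  res
}

#' Write the gene-level results table as tab-separated text
#'
#' @param gene_stats Data frame from [aggregate_genes()].
#' @param path Output path.
#' @export
write_gene_stats <- function(gene_stats, path) {
  utils::write.table(gene_stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full screen analysis: per-guide enrichment plus gene aggregation
#'
#' @inheritParams guide_enrichment
#' @inheritParams aggregate_genes
#' @param library A `guide_library` (needed for NT flags and gene mapping).
#' @return List with `guide_stats` and `gene_stats`.
#' @export
run_screen_analysis <- function(counts, samples, library, null_table = NULL,
                                n_sim = 1e5, seed = NULL, fdr = 0.05,
                                weight_mode = "one_minus_p") {
  guide_stats <- guide_enrichment(counts, samples, library)
  gene_stats <- aggregate_genes(guide_stats, null_table = null_table,
                                n_sim = n_sim, seed = seed, fdr = fdr,
                                weight_mode = weight_mode)
  list(guide_stats = guide_stats, gene_stats = gene_stats)
}
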