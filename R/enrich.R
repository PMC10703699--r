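# Per-guide paired differential abundance between LOW and HIGH sort bins:
# median-of-ratios normalization, NB dispersion estimation with a 1/mu trend
# and shrinkage toward it, and a donor-blocked negative-binomial Wald test.
#
# This is a self-contained reimplementation of the standard RNA-seq-style NB
# machinery specialised to paired two-bin sort screens: no fold-change
# shrinkage (the gene stage needs unshrunk log2FC), no independent filtering,
# no outlier refitting.

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over all-positive guides g
#' of count\[g,j\] divided by the geometric mean of guide g across samples.
#'
#' @param counts Guide x sample matrix of non-negative counts.
#' @return Positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no guide has all-positive counts; cannot form the median-of-ratios ",
         "reference (consider a pseudo-reference or filtering samples)")
  }
  gm <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  ratios <- counts[pos, , drop = FALSE] / gm
  sf <- apply(ratios, 2, stats::median)
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("degenerate size factors")
  sf
}

# Model matrix for the paired design: donor blocking + bin contrast
# (LOW is the reference level, so the bin coefficient is HIGH vs LOW).
paired_design_matrix <- function(design) {
  design$bin <- factor(design$bin, levels = c("LOW", "HIGH"))
  design$donor <- factor(design$donor)
  if (nlevels(design$donor) > 1) {
    stats::model.matrix(~ donor + bin, design)
  } else {
    stats::model.matrix(~ bin, design)
  }
}

# Maximize the Cox-Reid adjusted NB log-likelihood in log(alpha) for one
# guide given fitted means, optionally penalized toward a prior mean (normal
# in log alpha). The Cox-Reid term -0.5 log det(X' W X) corrects the downward
# bias of the dispersion MLE caused by fitting the mean parameters.
nb_disp_mle <- function(y, mu, alpha_floor, alpha_max = 200,
                        la_prior = NULL, prior_var = NULL, X = NULL) {
  nll <- function(la) {
    alpha <- exp(la)
    v <- -sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
    if (!is.null(X)) {
      w <- mu / (1 + alpha * mu)
      v <- v + 0.5 * determinant(crossprod(X * w, X))$modulus[1]
    }
    if (!is.null(la_prior)) v <- v + (la - la_prior)^2 / (2 * prior_var)
    v
  }
  lo <- log(alpha_floor); hi <- log(alpha_max)
  opt <- stats::optimize(nll, c(lo, hi), tol = 1e-6)
  cand <- c(opt$minimum, lo, hi)
  vals <- c(opt$objective, nll(lo), nll(hi))
  la <- cand[which.min(vals)]
  # boundary solutions (no detectable overdispersion) snap to the floor
  if (la <= lo + 1e-4) la <- lo
  exp(la)
}

#' Estimate per-guide NB dispersions with trend and shrinkage
#'
#' Per guide, the raw dispersion is the maximum-likelihood value given fitted
#' means from the paired design; a trend alpha(mu) = a0 + a1/mu is fitted
#' across guides; the final dispersion maximizes the NB likelihood penalized
#' by a normal prior on log dispersion centred on the trend with variance
#' `prior_var`. With few samples the likelihood in alpha is flat, so the
#' penalty dominates and per-guide estimates borrow strength from the trend;
#' when the whole screen is Poisson-like the trend itself collapses to the
#' floor and final dispersions sit there.
#'
#' @param counts Guide x sample count matrix.
#' @param sf Size factors from [size_factors()].
#' @param design Data frame with `donor` and `bin` columns, one row per
#'   sample in column order of `counts`.
#' @param prior_var Prior variance of log dispersion about the trend
#'   (default 0.25).
#' @param alpha_floor Minimum dispersion (default 1e-8).
#' @return A `dispersion_model`: per-guide table (`guide_id`, `base_mean`,
#'   `alpha_raw`, `alpha_trend`, `alpha_final`, `at_floor`, `ok`), trend
#'   coefficients, and the prior variance. All-zero guides have `ok = FALSE`
#'   and are excluded downstream.
#' @export
fit_dispersions <- function(counts, sf, design, prior_var = 0.25,
                            alpha_floor = 1e-8) {
  counts <- as.matrix(counts)
  X <- paired_design_matrix(design)
  m <- ncol(counts); p <- ncol(X)
  if (m - p < 1) stop("no residual degrees of freedom (need >= 1)")
  off <- log(sf)
  n <- nrow(counts)
  alpha_raw <- rep(NA_real_, n)
  base_mean <- rowMeans(sweep(counts, 2, sf, "/"))
  ok <- rowSums(counts) > 0
  mus <- vector("list", n)

  for (g in which(ok)) {
    y <- counts[g, ]
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = stats::poisson(),
                                      offset = off)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) { ok[g] <- FALSE; next }
    mus[[g]] <- fit$fitted.values
    alpha_raw[g] <- nb_disp_mle(y, fit$fitted.values, alpha_floor, X = X)
  }

  # trend over guides whose raw estimate is informative (off the floor)
  use <- ok & !is.na(alpha_raw) & alpha_raw > alpha_floor * 10 & base_mean > 0
  floor_frac <- sum(ok & !is.na(alpha_raw) &
                      alpha_raw <= alpha_floor * 10) / max(sum(ok), 1)
  if (sum(use) >= 5 && floor_frac < 0.5) {
    df <- data.frame(a = alpha_raw[use], x = 1 / base_mean[use])
    tf <- tryCatch(
      suppressWarnings(stats::glm(a ~ x, data = df,
                                  family = stats::Gamma(link = "identity"),
                                  start = c(stats::median(df$a), 0))),
      error = function(e) stats::lm(a ~ x, data = df)
    )
    a0 <- max(stats::coef(tf)[1], alpha_floor)
    a1 <- max(stats::coef(tf)[2], 0)
  } else {
    # mostly floor-level raw estimates: Poisson-like screen, flat trend at
    # the median (which is then itself at or near the floor)
    a0 <- max(stats::median(alpha_raw[ok], na.rm = TRUE), alpha_floor,
              na.rm = TRUE)
    a1 <- 0
  }
  alpha_trend <- pmax(a0 + a1 / pmax(base_mean, 1e-8), alpha_floor)

  at_floor <- ok & !is.na(alpha_raw) & alpha_raw <= alpha_floor * (1 + 1e-6)
  alpha_final <- rep(NA_real_, n)
  for (g in which(ok)) {
    a <- nb_disp_mle(counts[g, ], mus[[g]], alpha_floor,
                     la_prior = log(alpha_trend[g]), prior_var = prior_var,
                     X = X)
    # the penalized optimum lies between raw MLE and trend for unimodal
    # likelihoods; clamp to guarantee it
    lo <- min(alpha_raw[g], alpha_trend[g])
    hi <- max(alpha_raw[g], alpha_trend[g])
    alpha_final[g] <- min(max(a, lo), hi)
  }
  alpha_final <- pmax(alpha_final, alpha_floor)

  structure(list(
    table = data.frame(
      guide_id = rownames(counts) %||% as.character(seq_len(n)),
      base_mean = base_mean, alpha_raw = alpha_raw,
      alpha_trend = alpha_trend, alpha_final = alpha_final,
      at_floor = at_floor, ok = ok, stringsAsFactors = FALSE
    ),
    trend = c(a0 = unname(a0), a1 = unname(a1)),
    prior_var = prior_var, alpha_floor = alpha_floor
  ), class = "dispersion_model")
}

#' Paired negative-binomial Wald test per guide
#'
#' Fits, per guide, an NB log-link regression of counts on donor indicators
#' plus a HIGH-vs-LOW bin coefficient, with log size factors as offset and
#' the final shrunken dispersion held fixed. The bin coefficient (converted
#' to log2) is the unshrunk log2 fold change; its standard error comes from
#' the observed information; two-sided p from the standard normal reference;
#' one-sided p-values from the signed Wald statistic (`p_high` small when the
#' guide is enriched in the HIGH bin; `p_high + p_low = 1`).
#'
#' @inheritParams fit_dispersions
#' @param disp A `dispersion_model` from [fit_dispersions()].
#' @return Data frame with one row per guide: `guide_id`, `base_mean`,
#'   `log2fc`, `se`, `stat`, `pvalue`, `p_high`, `p_low`, `padj` (BH over
#'   converged guides), `ok`. Guides that are all-zero or fail to converge
#'   have `ok = FALSE` and missing statistics.
#' @export
paired_nb_wald <- function(counts, sf, disp, design) {
  counts <- as.matrix(counts)
  tab <- disp$table
  design$bin <- factor(design$bin, levels = c("LOW", "HIGH"))
  if (!all(table(design$donor, design$bin) >= 1)) {
    stop("every donor needs both bins")
  }
  X <- paired_design_matrix(design)
  j_bin <- which(colnames(X) == "binHIGH")
  off <- log(sf)
  n <- nrow(counts)
  out <- data.frame(
    guide_id = tab$guide_id, base_mean = tab$base_mean,
    log2fc = NA_real_, se = NA_real_, stat = NA_real_,
    pvalue = NA_real_, p_high = NA_real_, p_low = NA_real_,
    padj = NA_real_, ok = tab$ok, stringsAsFactors = FALSE
  )

  for (g in seq_len(n)) {
    if (!out$ok[g]) next
    alpha <- tab$alpha_final[g]
    fam <- if (alpha < 1e-6) {
      stats::poisson()
    } else {
      MASS::negative.binomial(theta = 1 / alpha)
    }
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, counts[g, ], family = fam,
                                      offset = off,
                                      control = list(maxit = 50))),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged || fit$rank < ncol(X) ||
        any(!is.finite(fit$coefficients))) {
      out$ok[g] <- FALSE
      next
    }
    pr <- fit$rank
    covm <- chol2inv(fit$qr$qr[seq_len(pr), seq_len(pr), drop = FALSE])
    pos <- match(j_bin, fit$qr$pivot[seq_len(pr)])
    beta <- fit$coefficients[j_bin]
    se <- sqrt(covm[pos, pos])
    if (!is.finite(se) || se <= 0) { out$ok[g] <- FALSE; next }
    W <- beta / se
    out$log2fc[g] <- beta / log(2)
    out$se[g] <- se / log(2)
    out$stat[g] <- W
    out$pvalue[g] <- 2 * stats::pnorm(-abs(W))
    out$p_high[g] <- stats::pnorm(W, lower.tail = FALSE)
    out$p_low[g] <- stats::pnorm(W)
  }
  out$padj <- bh_adjust(ifelse(out$ok, out$pvalue, NA_real_))
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p Numeric vector of p-values in \[0, 1\]; `NA`s are propagated and
#'   excluded from the family size.
#' @return Adjusted p-values, monotone and capped at 1.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Per-guide sort-bin enrichment analysis
#'
#' Convenience wrapper: size factors, dispersion fitting and the paired Wald
#' test in one call, with gene annotation when a library is supplied.
#'
#' @inheritParams fit_dispersions
#' @param samples Sample sheet data frame (`sample_id`, `donor`, `bin`) in
#'   column order of `counts`.
#' @param library Optional `guide_library` used to annotate `target_gene`.
#' @param prior_var Dispersion shrinkage prior variance.
#' @return The [paired_nb_wald()] table with a `target_gene` column.
#' @export
guide_enrichment <- function(counts, samples, library = NULL,
                             prior_var = 0.25) {
  validate_sample_sheet(samples)
  stopifnot(identical(colnames(counts), samples$sample_id))
  sf <- size_factors(counts)
  disp <- fit_dispersions(counts, sf, samples, prior_var = prior_var)
  res <- paired_nb_wald(counts, sf, disp, samples)
  if (!is.null(library)) {
    res$target_gene <- library$records$target_gene[
      match(res$guide_id, library$records$guide_id)]
  } else {
    res$target_gene <- NA_character_
  }
  res[, c("guide_id", "target_gene", "base_mean", "log2fc", "se", "stat",
          "pvalue", "p_high", "p_low", "padj", "ok")]
}

#' Write per-guide enrichment results as tab-separated text
#'
#' @param stats Data frame from [guide_enrichment()].
#' @param path Output path.
#' @export
write_guide_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
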