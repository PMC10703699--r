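# Synthetic sort-screen generator with known ground truth.
#
# Generative model: each cell carrying guide g has marker value
# Normal(delta_g, 1); cells below the null f-quantile are sorted into LOW and
# above the null (1-f)-quantile into HIGH. Capture probabilities are
# p_low = Phi(Phi^-1(f) - delta) and p_high = 1 - Phi(Phi^-1(1-f) - delta),
# so a guide's expected log2 fold change (HIGH vs LOW) is
# log2(p_high / p_low). Bin thresholds are the null quantiles: perturbed
# cells are assumed a small minority of the sorted population.

#' Configuration for the sort-screen simulator
#'
#' Defaults emulate a transcription-factor CRISPRi/a sort screen: 200 genes
#' at 8 guides each plus 120 NT guides, 3 donors, 10% expression tails,
#' 500x sequencing depth per sample, log-normal guide abundance (sd 0.5 on
#' the log scale) and NB dispersion 0.05.
#'
#' @param n_genes Number of targeted genes.
#' @param guides_per_gene Guides per gene (scalar or length `n_genes`).
#' @param n_nt Number of NT guides.
#' @param donors Number of paired donors (each sorted into both bins).
#' @param tail_fraction Sorted tail fraction f, 0 < f < 0.5 (default 0.10).
#' @param delta Per-gene marker shift in s.d. units (scalar or length
#'   `n_genes`); NT guides always have delta = 0.
#' @param sigma_abundance Log-normal s.d. of guide abundance per donor.
#' @param depth Sequencing depth per sample, in multiples of library size.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2); 0 gives
#'   Poisson counts.
#' @param seed Integer seed.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_genes = 200L, guides_per_gene = 8L,
                              n_nt = 120L, donors = 3L, tail_fraction = 0.10,
                              delta = 0, sigma_abundance = 0.5, depth = 500,
                              dispersion = 0.05, seed = NULL) {
  stopifnot(tail_fraction > 0, tail_fraction < 0.5, dispersion >= 0,
            depth > 0, n_genes >= 1, donors >= 1)
  gpg <- rep_len(as.integer(guides_per_gene), n_genes)
  structure(list(
    n_genes = as.integer(n_genes), guides_per_gene = gpg,
    n_nt = as.integer(n_nt), donors = as.integer(donors),
    tail_fraction = tail_fraction, delta = rep_len(delta, n_genes),
    sigma_abundance = sigma_abundance, depth = depth,
    dispersion = dispersion, seed = seed
  ), class = "screen_sim_config")
}

#' Expected log2 fold change of a guide between sort bins
#'
#' For a marker shift `delta` (s.d. units) and tail fraction `f`, the
#' capture probabilities into the LOW and HIGH 10%-style tails are
#' `Phi(Phi^-1(f) - delta)` and `1 - Phi(Phi^-1(1-f) - delta)`; the expected
#' log2 fold change is their log2 ratio. Antisymmetric in `delta`.
#'
#' @param delta Marker shift(s) in s.d. units.
#' @param f Tail fraction, 0 < f <= 0.5.
#' @return Expected log2 fold change (HIGH vs LOW).
#' @export
expected_log2fc <- function(delta, f = 0.1) {
  stopifnot(f > 0, f <= 0.5)
  p_high <- stats::pnorm(stats::qnorm(1 - f) - delta, lower.tail = FALSE)
  p_low <- stats::pnorm(stats::qnorm(f) - delta)
  log2(p_high / p_low)
}

# Deterministic unique dummy spacer for simulated guide i (base-4 encoding).
int_to_spacer <- function(i, L = 21L) {
  bases <- c("A", "C", "G", "T")
  vapply(i, function(x) {
    d <- integer(L)
    for (j in seq_len(L)) {
      d[j] <- x %% 4L
      x <- x %/% 4L
    }
    paste(bases[d + 1L], collapse = "")
  }, character(1))
}

#' Simulate a paired LOW/HIGH sort-bin screen
#'
#' Per donor, guide abundances are log-normal; the expected count of guide g
#' in a bin is proportional to abundance times the bin capture probability,
#' scaled so each sample's expected total is `depth` reads per library
#' guide; counts are NB (Poisson when `dispersion = 0`). NT guides have
#' delta = 0. Deterministic under the config seed.
#'
#' @param config A [screen_sim_config()].
#' @return List: `counts` (guide x sample matrix), `samples` (sample sheet),
#'   `truth` (per-guide `gene`, `delta`, `p_low`, `p_high`,
#'   `expected_log2fc`), and `library` (a `guide_library` with the simulated
#'   guide/gene structure).
#' @export
simulate_sort_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  f <- config$tail_fraction
  genes <- sprintf("gene%03d", seq_len(config$n_genes))
  gene_of <- rep(genes, config$guides_per_gene)
  gid <- unlist(lapply(seq_len(config$n_genes), function(i) {
    sprintf("%s_g%02d", genes[i], seq_len(config$guides_per_gene[i]))
  }))
  if (config$n_nt > 0) {
    gid <- c(gid, sprintf("NT_%04d", seq_len(config$n_nt)))
    gene_of <- c(gene_of, rep(NON_TARGETING, config$n_nt))
  }
  G <- length(gid)
  delta <- c(rep(config$delta, config$guides_per_gene),
             rep(0, config$n_nt))
  p_low <- stats::pnorm(stats::qnorm(f) - delta)
  p_high <- stats::pnorm(stats::qnorm(1 - f) - delta, lower.tail = FALSE)

  with_seed(config$seed, {
    counts <- matrix(0L, G, 2L * config$donors)
    sample_id <- character(2L * config$donors)
    donor <- character(2L * config$donors)
    bin <- character(2L * config$donors)
    col <- 0L
    for (d in seq_len(config$donors)) {
      a <- exp(stats::rnorm(G, 0, config$sigma_abundance))
      for (b in c("LOW", "HIGH")) {
        col <- col + 1L
        w <- a * (if (b == "LOW") p_low else p_high)
        mu <- config$depth * G * w / sum(w)
        y <- if (config$dispersion == 0) {
          stats::rpois(G, mu)
        } else {
          stats::rnbinom(G, mu = mu, size = 1 / config$dispersion)
        }
        counts[, col] <- as.integer(y)
        sample_id[col] <- sprintf("donor%d_%s", d, b)
        donor[col] <- sprintf("donor%d", d)
        bin[col] <- b
      }
    }
    dimnames(counts) <- list(gid, sample_id)
    is_nt <- gene_of == NON_TARGETING
    records <- data.frame(
      guide_id = gid, spacer = int_to_spacer(seq_len(G)),
      pam = ifelse(is_nt, NA_character_, "AAGGGT"),
      target_gene = gene_of,
      chrom = ifelse(is_nt, NA_character_, "sim"),
      start = ifelse(is_nt, NA_integer_, (seq_len(G) - 1L) * 30L),
      end = ifelse(is_nt, NA_integer_, (seq_len(G) - 1L) * 30L + 21L),
      strand = ifelse(is_nt, NA_character_, "+"),
      cut_window_offset = NA_integer_, stringsAsFactors = FALSE
    )
    list(
      counts = counts,
      samples = data.frame(sample_id = sample_id, donor = donor, bin = bin,
                           arm = "CRISPRi", marker = "CCR7",
                           stringsAsFactors = FALSE),
      truth = data.frame(guide_id = gid, gene = gene_of, delta = delta,
                         p_low = p_low, p_high = p_high,
                         expected_log2fc = log2(p_high / p_low),
                         stringsAsFactors = FALSE),
      library = guide_library(records, pam_pattern = "NNGRRT",
                              spacer_length = 21L)
    )
  })
}

#' Simulate screen reads embedding spacers in a constant scaffold
#'
#' Emits exactly `counts[g]` reads per guide, each carrying the guide's
#' spacer at the position the extraction spec expects, with independent
#' per-base substitution errors at `error_rate`. Read order is shuffled.
#' Deterministic under `seed`.
#'
#' @param counts Named integer vector guide id -> read count.
#' @param library A `guide_library` covering those guides.
#' @param spec A [read_extraction_spec()]; a numeric `spacer_offset` larger
#'   than the anchor prefix is honoured by random left-padding.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @param path Output FASTQ path (default a tempfile).
#' @return The FASTQ path, invisibly.
#' @export
simulate_fastq <- function(counts, library, spec = read_extraction_spec(0L),
                           error_rate = 0, seed = NULL,
                           path = tempfile(fileext = ".fastq")) {
  stopifnot(all(counts >= 0))
  rec <- library$records
  sp <- rec$spacer[match(names(counts), rec$guide_id)]
  if (anyNA(sp)) stop("counts name guides absent from the library")
  with_seed(seed, {
    reads <- rep(sp, counts)
    prefix <- spec$anchor_prefix
    if (!identical(spec$spacer_offset, "AUTO")) {
      pad <- spec$spacer_offset - nchar(prefix)
      if (pad < 0) stop("spacer_offset smaller than anchor prefix")
      if (pad > 0) {
        prefix <- paste0(paste(sample(c("A", "C", "G", "T"), pad,
                                      replace = TRUE), collapse = ""),
                         prefix)
      }
    }
    reads <- paste0(prefix, reads, spec$anchor_suffix)
    if (length(reads) > 1) reads <- sample(reads)
    if (error_rate > 0 && length(reads) > 0) {
      reads <- vapply(reads, function(r) {
        ch <- strsplit(r, "")[[1]]
        err <- stats::runif(length(ch)) < error_rate
        if (any(err)) {
          ch[err] <- vapply(ch[err], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
          }, character(1))
        }
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    x <- Biostrings::DNAStringSet(reads)
    names(x) <- sprintf("read_%06d", seq_along(reads))
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(reads)))
    )
  })
  invisible(path)
}

#' Simulate a cell x guide UMI capture matrix
#'
#' Per cell, the number of truly integrated guides is Poisson(`moi_mean`);
#' each true guide contributes Poisson(`signal_umi_mean`) UMIs on top of the
#' ambient Poisson(`ambient_umi_mean`) background every guide receives.
#'
#' @param n_cells Number of cells.
#' @param library A `guide_library`.
#' @param moi_mean Mean number of integrated guides per cell.
#' @param signal_umi_mean Mean UMI count of a truly present guide
#'   (default 20).
#' @param ambient_umi_mean Mean ambient UMI count per guide (default 0.2;
#'   keep well below the assignment threshold).
#' @param seed Integer seed.
#' @return List: `umi` (cells x guides integer matrix) and `truth` (named
#'   list cell -> character vector of truly present guides).
#' @export
simulate_cell_guide_umis <- function(n_cells, library, moi_mean = 1,
                                     signal_umi_mean = 20,
                                     ambient_umi_mean = 0.2, seed = NULL) {
  stopifnot(n_cells >= 1, signal_umi_mean > 0, ambient_umi_mean >= 0)
  guides <- library$records$guide_id
  with_seed(seed, {
    cells <- sprintf("cell_%05d", seq_len(n_cells))
    umi <- matrix(stats::rpois(n_cells * length(guides), ambient_umi_mean),
                  n_cells, length(guides),
                  dimnames = list(cells, guides))
    k <- stats::rpois(n_cells, moi_mean)
    truth <- vector("list", n_cells)
    names(truth) <- cells
    for (i in seq_len(n_cells)) {
      ki <- min(k[i], length(guides))
      tg <- if (ki > 0) sample(guides, ki) else character(0)
      truth[[i]] <- sort(tg)
      for (g in tg) {
        umi[i, g] <- umi[i, g] + stats::rpois(1, signal_umi_mean)
      }
    }
    storage.mode(umi) <- "integer"
    list(umi = umi, truth = truth)
  })
}

#' Simulate (possibly miscalibrated) NT p-values
#'
#' Independent Beta(a, b) draws; a = b = 1 is the uniform well-calibrated
#' case, a < 1 an anti-conservative null. Stress input for
#' [build_calibration()].
#'
#' @param n Number of draws (>= 10).
#' @param a,b Beta shape parameters (> 0).
#' @param seed Integer seed.
#' @return Numeric vector of p-values in (0, 1).
#' @export
simulate_nt_pvalues <- function(n, a = 1, b = 1, seed = NULL) {
  stopifnot(n >= 10, a > 0, b > 0)
  with_seed(seed, {
    p <- stats::rbeta(n, a, b)
    pmin(pmax(p, 1e-300), 1 - 1e-16)
  })
}
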