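# Guide library design: PAM scanning, off-target filtering, composition-matched
# non-targeting controls, auditing and serialization.
#
# Conventions: coordinates are 0-based half-open on the forward strand of the
# supplied design sequence, spacer only (PAM excluded); exported tables are
# 1-based inclusive. Spacers are reported 5'->3' on the protospacer strand.

#' Scan a sequence for candidate SaCas9 guides
#'
#' Finds every spacer of length `spacer_length` lying immediately 5' of a PAM
#' matching `pam_pattern` (IUPAC), on both strands, with the spacer fully
#' inside `window` (an interval relative to `anchor`, e.g. a TSS). dSaCas9
#' recognises the strict PAM `NNGRRT` and a relaxed variant `NNGRRN`; both are
#' supported, as is any other IUPAC pattern.
#'
#' @param sequence Character scalar or [Biostrings::DNAString] design sequence.
#' @param window Length-2 integer vector: 0-based half-open interval relative
#'   to `anchor` within which the spacer must lie entirely.
#' @param pam_pattern IUPAC PAM string (default `"NNGRRT"`).
#' @param spacer_length Spacer length in nt (default 21).
#' @param anchor 0-based position of the window anchor (TSS) in `sequence`.
#' @return A data frame of guide records: `guide_id`, `spacer`, `pam`,
#'   `target_gene` (`NA`), `chrom` (`NA`), `start`, `end` (0-based half-open,
#'   forward strand, spacer only), `strand`, and `cut_window_offset` (signed
#'   distance from the spacer 5' end to the anchor).
#' @details Positions containing non-ACGT characters yield no candidates.
#'   A window extending beyond the sequence is an error.
#' @export
scan_candidate_guides <- function(sequence, window, pam_pattern = "NNGRRT",
                                  spacer_length = 21L, anchor = 0L) {
  pam_pattern <- check_iupac(pam_pattern, 6L)
  seq_chr <- toupper(as.character(sequence))
  len <- nchar(seq_chr)
  win_lo <- anchor + window[1]
  win_hi <- anchor + window[2]
  if (win_hi <= win_lo) stop("window must be a non-empty interval")
  if (win_lo < 0 || win_hi > len) {
    stop(sprintf(
      "window [%d, %d) extends outside the sequence [0, %d) by %d bp",
      win_lo, win_hi, len, max(0 - win_lo, win_hi - len)
    ))
  }

  scan_strand <- function(s, strand) {
    subj <- Biostrings::DNAString(s)
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pam_pattern), subj,
                                     fixed = "subject")
    p0 <- Biostrings::start(hits) - 1L  # 0-based PAM starts on this strand
    if (length(p0) == 0) return(NULL)
    sp_start <- p0 - spacer_length
    keep <- sp_start >= 0L
    p0 <- p0[keep]; sp_start <- sp_start[keep]
    if (length(p0) == 0) return(NULL)
    spacer <- substring(s, sp_start + 1L, sp_start + spacer_length)
    pam <- substring(s, p0 + 1L, p0 + 6L)
    ok <- is_dna(spacer) & is_dna(pam) &
      vapply(pam, iupac_match, logical(1), pattern = pam_pattern)
    if (strand == "+") {
      fwd_start <- sp_start
    } else {
      # positions on the reverse-complement map back to forward coordinates
      fwd_start <- len - (sp_start + spacer_length)
    }
    data.frame(
      spacer = spacer[ok], pam = pam[ok],
      start = fwd_start[ok], end = fwd_start[ok] + spacer_length,
      strand = strand, stringsAsFactors = FALSE, row.names = NULL
    )
  }

  out <- rbind(scan_strand(seq_chr, "+"),
               scan_strand(revcomp(seq_chr), "-"))
  if (is.null(out) || nrow(out) == 0) {
    return(empty_guide_records())
  }
  out <- out[out$start >= win_lo & out$end <= win_hi, , drop = FALSE]
  if (nrow(out) == 0) return(empty_guide_records())
  out <- out[order(out$start, out$strand), , drop = FALSE]
  data.frame(
    guide_id = sprintf("cand_%s_%d", ifelse(out$strand == "+", "fwd", "rev"),
                       out$start),
    spacer = out$spacer, pam = out$pam,
    target_gene = NA_character_, chrom = NA_character_,
    start = out$start, end = out$end, strand = out$strand,
    cut_window_offset = ifelse(out$strand == "+",
                               out$start - anchor, out$end - 1L - anchor),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

empty_guide_records <- function() {
  data.frame(
    guide_id = character(), spacer = character(), pam = character(),
    target_gene = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    cut_window_offset = integer(), stringsAsFactors = FALSE
  )
}

# PAM start positions (0-based) on one concrete strand of one sequence.
pam_starts_0 <- function(s, pam_pattern) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pam_pattern),
                                   Biostrings::DNAString(s),
                                   fixed = "subject")
  p0 <- Biostrings::start(hits) - 1L
  if (length(p0)) {
    pam <- substring(s, p0 + 1L, p0 + nchar(pam_pattern))
    p0 <- p0[is_dna(pam) &
               vapply(pam, iupac_match, logical(1), pattern = pam_pattern)]
  }
  p0
}

#' Count PAM-adjacent near-matches of spacers in background sequence
#'
#' For each spacer, counts sites across both strands of `background` where a
#' spacer-length window immediately 5' of a PAM-pattern match lies within
#' Hamming distance `max_mismatch_excl - 1` (ungapped) of the spacer.
#'
#' @param spacers Character vector of spacer sequences.
#' @param background Character vector or [Biostrings::DNAStringSet] of
#'   background sequences.
#' @inheritParams scan_candidate_guides
#' @param max_mismatch_excl Sites with strictly fewer mismatches than this are
#'   counted (default 4: "fewer than four mismatches").
#' @return Integer vector of site counts, one per spacer.
#' @export
offtarget_site_counts <- function(spacers, background,
                                  pam_pattern = "NNGRRT",
                                  max_mismatch_excl = 4L) {
  bg <- toupper(as.character(background))
  if (length(bg) == 0) stop("background is empty: cannot assess specificity")
  L <- unique(nchar(spacers))
  if (length(L) != 1) stop("spacers must share one length")
  strands <- unlist(lapply(bg, function(s) c(s, revcomp(s))), use.names = FALSE)
  pam_pat <- check_iupac(pam_pattern, 6L)
  pam_sets <- lapply(strands, pam_starts_0, pam_pattern = pam_pat)

  counts <- integer(length(spacers))
  for (k in seq_along(strands)) {
    pams <- pam_sets[[k]]
    if (length(pams) == 0) next
    subj <- Biostrings::DNAString(strands[k])
    for (i in seq_along(spacers)) {
      m <- Biostrings::matchPattern(spacers[i], subj,
                                    max.mismatch = max_mismatch_excl - 1L,
                                    with.indels = FALSE, fixed = TRUE)
      if (length(m) == 0) next
      s0 <- Biostrings::start(m) - 1L
      counts[i] <- counts[i] + sum((s0 + L) %in% pams)
    }
  }
  counts
}

#' Remove guides with off-target near-matches in background sequence
#'
#' A candidate survives iff it has no background site (both strands, ungapped,
#' PAM-adjacent) within `max_mismatch_excl - 1` mismatches of its spacer other
#' than its own design site. The background must contain the design locus, so
#' every candidate has exactly one perfect self-match; candidates are kept iff
#' their total qualifying site count equals one.
#'
#' @param candidates Guide-record data frame from [scan_candidate_guides()].
#' @inheritParams offtarget_site_counts
#' @return The kept subset of `candidates`, with an `offtarget_sites`
#'   attribute giving the per-candidate site counts.
#' @export
filter_off_target <- function(candidates, background, pam_pattern = "NNGRRT",
                              max_mismatch_excl = 4L) {
  if (length(background) == 0) {
    stop("background is empty: cannot assess specificity")
  }
  if (nrow(candidates) == 0) return(candidates)
  hits <- offtarget_site_counts(candidates$spacer, background,
                                pam_pattern = pam_pattern,
                                max_mismatch_excl = max_mismatch_excl)
  kept <- candidates[hits == 1L, , drop = FALSE]
  attr(kept, "offtarget_sites") <- stats::setNames(hits, candidates$guide_id)
  kept
}

#' Generate composition-matched non-targeting control guides
#'
#' Draws spacers position-independently from the pooled mononucleotide
#' frequencies of the targeting spacers, rejecting any draw that (a) has a
#' PAM-adjacent background site within the off-target exclusion distance or
#' (b) duplicates an existing spacer. Deterministic under `seed`.
#'
#' @param targeting_spacers Character vector of targeting spacer sequences.
#' @param n Number of NT guides to generate (must be >= 1).
#' @param background Background sequences for the specificity check, or `NULL`
#'   to skip it (an NT guide has no design site, so any qualifying site is a
#'   rejection).
#' @inheritParams offtarget_site_counts
#' @param seed Integer seed.
#' @param max_draws Cap on rejection-sampling attempts (default
#'   `max(1000, 200 * n)`).
#' @return Guide-record data frame of `n` NT records (no coordinates, no PAM,
#'   `target_gene == "NON_TARGETING"`).
#' @export
generate_nt_guides <- function(targeting_spacers, n, background = NULL,
                               pam_pattern = "NNGRRT", seed = NULL,
                               max_mismatch_excl = 4L, max_draws = NULL) {
  if (length(targeting_spacers) == 0) stop("targeting_spacers is empty")
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  L <- unique(nchar(targeting_spacers))
  if (length(L) != 1) stop("targeting spacers must share one length")
  pooled <- table(factor(unlist(strsplit(targeting_spacers, "")),
                         levels = c("A", "C", "G", "T")))
  freqs <- as.numeric(pooled) / sum(pooled)
  # a fully degenerate pool (single letter) admits exactly one spacer, so
  # duplicate rejection would never terminate; duplicates are allowed there
  degenerate <- any(freqs == 1)
  max_draws <- max_draws %||% max(1000L, 200L * n)

  with_seed(seed, {
    seen <- unique(targeting_spacers)
    out <- character(0)
    draws <- 0L
    while (length(out) < n) {
      if (draws >= max_draws) {
        stop(sprintf(
          "could not generate %d NT guides in %d draws (%d accepted)",
          n, draws, length(out)
        ))
      }
      draws <- draws + 1L
      sp <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                         prob = freqs), collapse = "")
      if (!degenerate && sp %in% seen) next
      if (!is.null(background) && length(background) > 0 &&
          offtarget_site_counts(sp, background, pam_pattern = pam_pattern,
                                max_mismatch_excl = max_mismatch_excl) > 0) {
        next
      }
      out <- c(out, sp)
      seen <- c(seen, sp)
    }
    data.frame(
      guide_id = sprintf("NT_%04d", seq_len(n)),
      spacer = out, pam = NA_character_, target_gene = NON_TARGETING,
      chrom = NA_character_, start = NA_integer_, end = NA_integer_,
      strand = NA_character_, cut_window_offset = NA_integer_,
      stringsAsFactors = FALSE
    )
  })
}

#' Construct a guide library object
#'
#' Validates guide records and bundles them with the design parameters.
#' Duplicate spacers among targeting records are dropped (first kept) with a
#' warning; duplicate `guide_id`s are an error.
#'
#' @param records Guide-record data frame (targeting and/or NT rows).
#' @inheritParams scan_candidate_guides
#' @param design_windows Optional per-gene window table (gene, start_offset,
#'   end_offset), kept for provenance.
#' @param untargeted Character vector of genes whose windows yielded no
#'   surviving guides.
#' @return An object of class `guide_library`.
#' @export
guide_library <- function(records, pam_pattern = "NNGRRT",
                          spacer_length = 21L, design_windows = NULL,
                          untargeted = character(0)) {
  stopifnot(is.data.frame(records))
  need <- c("guide_id", "spacer", "target_gene")
  if (!all(need %in% names(records))) {
    stop("records must contain columns: ", paste(need, collapse = ", "))
  }
  for (col in c("pam", "chrom", "strand")) {
    if (is.null(records[[col]])) records[[col]] <- NA_character_
  }
  for (col in c("start", "end", "cut_window_offset")) {
    if (is.null(records[[col]])) records[[col]] <- NA_integer_
  }
  if (anyDuplicated(records$guide_id)) {
    stop("duplicate guide_id: ",
         paste(unique(records$guide_id[duplicated(records$guide_id)]),
               collapse = ", "))
  }
  if (!all(is_dna(records$spacer))) stop("spacers must be ACGT only")
  is_nt <- records$target_gene == NON_TARGETING
  if (any(is_nt & (!is.na(records$start) | !is.na(records$chrom)))) {
    stop("NT records must not carry genomic coordinates")
  }
  tg <- records[!is_nt, , drop = FALSE]
  dup <- duplicated(tg$spacer)
  if (any(dup)) {
    warning(sum(dup), " duplicate targeting spacer(s) dropped (first kept)")
    records <- rbind(tg[!dup, , drop = FALSE], records[is_nt, , drop = FALSE])
  }
  structure(
    list(records = records, pam_pattern = pam_pattern,
         spacer_length = as.integer(spacer_length),
         design_windows = design_windows,
         untargeted = untargeted),
    class = "guide_library"
  )
}

#' @export
print.guide_library <- function(x, ...) {
  a <- validate_library(x)
  cat(sprintf(
    "guide_library: %d guides (%d targeting %d genes, %d NT), PAM %s, spacer %d nt\n",
    a$n_total, a$n_targeting, a$n_genes_targeted, a$n_nt,
    x$pam_pattern, x$spacer_length
  ))
  if (length(x$untargeted)) {
    cat("untargeted genes:", paste(x$untargeted, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Design a TSS-tiling guide library for a set of genes
#'
#' For each gene, scans the supplied promoter sequence for PAM sites in the
#' design window, removes guides with off-target near-matches in the
#' background, then appends composition-matched NT controls. Genes whose
#' windows yield no surviving guides are recorded (not silently dropped) and
#' listed by the audit.
#'
#' @param tss_table Named list, one entry per gene:
#'   `list(sequence =, anchor =)` with `anchor` the 0-based TSS position in
#'   the sequence.
#' @inheritParams scan_candidate_guides
#' @param background Background sequences for off-target filtering; defaults
#'   to the design sequences themselves (which the filter requires to contain
#'   each design locus).
#' @param n_nt Number of NT guides to append (default 120).
#' @param seed Integer seed for NT generation.
#' @return A `guide_library` whose targeting records carry `chrom` set to the
#'   gene's design contig and coordinates local to that sequence.
#' @export
design_tiling_library <- function(tss_table, window = c(-500L, 500L),
                                  pam_pattern = "NNGRRT", spacer_length = 21L,
                                  background = NULL, n_nt = 120L,
                                  seed = NULL) {
  if (length(tss_table) == 0) stop("tss_table is empty")
  genes <- names(tss_table)
  if (is.null(genes) || anyDuplicated(genes)) {
    stop("tss_table must have unique gene names")
  }
  if (is.null(background)) {
    background <- vapply(tss_table, function(g) toupper(as.character(g$sequence)),
                         character(1))
  }
  rec_list <- list()
  untargeted <- character(0)
  attrition <- data.frame(gene = genes, n_candidates = 0L, n_kept = 0L)
  for (i in seq_along(genes)) {
    g <- genes[i]
    entry <- tss_table[[g]]
    cand <- scan_candidate_guides(entry$sequence, window = window,
                                  pam_pattern = pam_pattern,
                                  spacer_length = spacer_length,
                                  anchor = entry$anchor %||% 0L)
    cand <- cand[!duplicated(cand$spacer), , drop = FALSE]
    attrition$n_candidates[i] <- nrow(cand)
    kept <- filter_off_target(cand, background, pam_pattern = pam_pattern)
    attrition$n_kept[i] <- nrow(kept)
    if (nrow(kept) == 0) {
      untargeted <- c(untargeted, g)
      next
    }
    kept$target_gene <- g
    kept$chrom <- g
    kept$guide_id <- sprintf("%s_g%02d", g, seq_len(nrow(kept)))
    rec_list[[g]] <- kept
  }
  targeting <- if (length(rec_list)) do.call(rbind, rec_list) else
    empty_guide_records()
  rownames(targeting) <- NULL
  nt <- if (n_nt >= 1) {
    generate_nt_guides(if (nrow(targeting)) targeting$spacer else "ACGT",
                       n = n_nt, background = background,
                       pam_pattern = pam_pattern, seed = seed)
  } else {
    empty_guide_records()
  }
  lib <- guide_library(rbind(targeting, nt), pam_pattern = pam_pattern,
                       spacer_length = spacer_length,
                       design_windows = data.frame(
                         gene = genes, window_start = window[1],
                         window_end = window[2]
                       ),
                       untargeted = untargeted)
  attr(lib, "attrition") <- attrition
  lib
}

#' Audit the composition of a guide library
#'
#' @param library A `guide_library`.
#' @return A `library_audit` list: `n_total`, `n_nt`, `n_targeting`,
#'   `n_genes_targeted`, `guides_per_gene` (named integer),
#'   `mean_guides_per_gene`, `min_guides_per_gene`, `untargeted`.
#' @export
validate_library <- function(library) {
  rec <- library$records
  is_nt <- rec$target_gene == NON_TARGETING
  gpg <- table(rec$target_gene[!is_nt])
  gpg <- stats::setNames(as.integer(gpg), names(gpg))
  audit <- list(
    n_total = nrow(rec),
    n_nt = sum(is_nt),
    n_targeting = sum(!is_nt),
    n_genes_targeted = length(gpg),
    guides_per_gene = gpg,
    mean_guides_per_gene = if (length(gpg)) sum(!is_nt) / length(gpg) else NaN,
    min_guides_per_gene = if (length(gpg)) min(gpg) else NA_integer_,
    untargeted = library$untargeted %||% character(0)
  )
  structure(audit, class = "library_audit")
}

#' @export
print.library_audit <- function(x, ...) {
  cat(sprintf(
    "library audit: %d total = %d targeting (%d genes, mean %.2f/gene, min %s) + %d NT\n",
    x$n_total, x$n_targeting, x$n_genes_targeted, x$mean_guides_per_gene,
    x$min_guides_per_gene, x$n_nt
  ))
  if (length(x$untargeted)) {
    cat("untargeted:", paste(x$untargeted, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a guide library to a tab-separated file
#'
#' Columns: guide_id, spacer, pam, target_gene, chrom, start, end, strand.
#' Coordinates are written 1-based inclusive (header comment records this);
#' NT rows leave positional columns blank.
#'
#' @param library A `guide_library`.
#' @param path Output path.
#' @export
write_guide_library <- function(library, path) {
  rec <- library$records
  out <- rec[, c("guide_id", "spacer", "pam", "target_gene", "chrom",
                 "start", "end", "strand")]
  out$start <- out$start + 1L  # 1-based inclusive on disk
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# guide library | PAM %s | spacer %d nt | coordinates 1-based inclusive",
                     library$pam_pattern, library$spacer_length), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a guide library from a tab-separated file
#'
#' Inverse of [write_guide_library()]; converts coordinates back to 0-based
#' half-open.
#'
#' @param path Input path.
#' @inheritParams scan_candidate_guides
#' @return A `guide_library`.
#' @export
read_guide_library <- function(path, pam_pattern = "NNGRRT",
                               spacer_length = NULL) {
  df <- utils::read.delim(path, comment.char = "#", na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  df$start <- as.integer(df$start) - 1L
  df$end <- as.integer(df$end)
  df$cut_window_offset <- NA_integer_
  guide_library(df, pam_pattern = pam_pattern,
                spacer_length = spacer_length %||%
                  unique(nchar(df$spacer))[1])
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
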