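# Spacer counting: raw screen reads -> gRNA x sample count matrix.
#
# Counting is exact-match on the extracted spacer (optionally tolerating one
# substitution via the single-substitution neighborhood); reads that fail
# extraction or lookup increment the per-sample unassigned counter, so
# assigned + unassigned always equals reads processed.

#' Read-extraction settings for spacer counting
#'
#' @param spacer_offset 0-based offset of the spacer in each read, or
#'   `"AUTO"` to locate it by the first exact occurrence of `anchor_prefix`
#'   (the constant vector/scaffold sequence immediately 5' of the spacer).
#' @param anchor_prefix,anchor_suffix Constant scaffold sequence flanking the
#'   spacer in the read (prefix required when `spacer_offset = "AUTO"`).
#' @param max_mismatch Mismatches tolerated in the spacer lookup, 0 or 1.
#' @return A `read_extraction_spec` list.
#' @export
read_extraction_spec <- function(spacer_offset = "AUTO", anchor_prefix = "",
                                 anchor_suffix = "", max_mismatch = 0L) {
  if (!identical(spacer_offset, "AUTO")) {
    spacer_offset <- as.integer(spacer_offset)
    stopifnot(spacer_offset >= 0)
  } else if (nchar(anchor_prefix) == 0) {
    stop("AUTO offset requires a non-empty anchor_prefix")
  }
  if (!max_mismatch %in% c(0L, 1L)) stop("max_mismatch must be 0 or 1")
  structure(list(spacer_offset = spacer_offset,
                 anchor_prefix = toupper(anchor_prefix),
                 anchor_suffix = toupper(anchor_suffix),
                 max_mismatch = as.integer(max_mismatch)),
            class = "read_extraction_spec")
}

#' Build an exact-lookup spacer index from a guide library
#'
#' @param library A `guide_library`.
#' @return Named character vector mapping spacer -> guide_id.
#' @details Two guide ids sharing one spacer is an error (the library layer
#'   already deduplicates targeting spacers, but NT/targeting collisions or
#'   hand-built records could still collide).
#' @export
build_spacer_index <- function(library) {
  rec <- library$records
  dup <- duplicated(rec$spacer)
  if (any(dup)) {
    sp <- rec$spacer[dup][1]
    ids <- rec$guide_id[rec$spacer == sp]
    stop("spacer collision: '", sp, "' maps to ",
         paste(ids, collapse = " and "))
  }
  stats::setNames(rec$guide_id, rec$spacer)
}

# Validate FASTQ structure cheaply so malformed records can be reported by
# record number before Biostrings parses the file.
validate_fastq_lines <- function(lines) {
  n <- length(lines)
  if (n %% 4 != 0) {
    stop(sprintf("malformed FASTQ: truncated record %d (file has %d lines)",
                 n %/% 4 + 1, n))
  }
  idx <- seq(1, n, by = 4)
  bad_at <- !startsWith(lines[idx], "@")
  bad_plus <- !startsWith(lines[idx + 2], "+")
  bad_len <- nchar(lines[idx + 1]) != nchar(lines[idx + 3])
  bad <- which(bad_at | bad_plus | bad_len)
  if (length(bad)) {
    stop(sprintf("malformed FASTQ record %d near line %d",
                 bad[1], idx[bad[1]]))
  }
  invisible(TRUE)
}

#' Count guide spacers in a FASTQ file
#'
#' Extracts the spacer from each read per `spec` and looks it up in the index
#' (exactly, or through the single-substitution neighborhood when
#' `max_mismatch = 1`). Reads with no extractable or matchable spacer are
#' unassigned.
#'
#' @param fastq Path to a FASTQ file (optionally gzip-compressed).
#' @param index Spacer index from [build_spacer_index()].
#' @param spec A [read_extraction_spec()].
#' @return List with `counts` (named integer vector over all guide ids, in
#'   index order), `n_unassigned`, `n_reads`, and `n_short` (reads too short
#'   to contain a spacer, a subset of the unassigned).
#' @export
count_fastq <- function(fastq, index, spec = read_extraction_spec(0L)) {
  if (length(index) == 0) stop("empty spacer index")
  lines <- readLines(fastq)
  validate_fastq_lines(lines)
  reads <- toupper(lines[seq(2, length(lines), by = 4)])
  L <- unique(nchar(names(index)))
  if (length(L) != 1) stop("index spacers must share one length")

  if (identical(spec$spacer_offset, "AUTO")) {
    pos <- regexpr(spec$anchor_prefix, reads, fixed = TRUE)
    off <- ifelse(pos > 0, pos + nchar(spec$anchor_prefix) - 1L, NA_integer_)
  } else {
    off <- rep.int(spec$spacer_offset, length(reads))
  }
  too_short <- is.na(off) | nchar(reads) < off + L
  spacers <- rep(NA_character_, length(reads))
  spacers[!too_short] <- substring(reads[!too_short], off[!too_short] + 1L,
                                   off[!too_short] + L)

  guide <- unname(index[spacers])
  if (spec$max_mismatch == 1L) {
    miss <- which(is.na(guide) & !is.na(spacers))
    for (i in miss) {
      guide[i] <- match_one_substitution(spacers[i], index)
    }
  }
  counts <- table(factor(guide, levels = unname(index)))
  list(
    counts = stats::setNames(as.integer(counts), unname(index)),
    n_unassigned = sum(is.na(guide)),
    n_reads = length(reads),
    n_short = sum(too_short)
  )
}

# Look a spacer up through its single-substitution neighborhood; NA if no
# neighbor is indexed, and ambiguous multi-guide neighborhoods stay NA.
match_one_substitution <- function(spacer, index) {
  chars <- strsplit(spacer, "")[[1]]
  hits <- character(0)
  for (i in seq_along(chars)) {
    for (b in setdiff(c("A", "C", "G", "T"), chars[i])) {
      v <- chars
      v[i] <- b
      g <- index[paste(v, collapse = "")]
      if (!is.na(g)) hits <- c(hits, unname(g))
    }
  }
  hits <- unique(hits)
  if (length(hits) == 1) hits else NA_character_
}

#' Read a sample sheet
#'
#' Tab-separated with columns `sample_id`, `donor`, `bin` (LOW/HIGH), `arm`
#' (CRISPRi/CRISPRa/KO), `marker`, and optionally `fastq_path`.
#'
#' @param path Sample sheet path.
#' @return Data frame; errors if (donor, bin, arm) combinations repeat or a
#'   donor is missing one of the two bins.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate sample metadata for a paired sort-bin analysis
#'
#' @param df Data frame with at least `sample_id`, `donor`, `bin`.
#' @return The validated data frame (invisibly unchanged).
#' @export
validate_sample_sheet <- function(df) {
  need <- c("sample_id", "donor", "bin")
  if (!all(need %in% names(df))) {
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$bin %in% c("LOW", "HIGH"))) stop("bin must be LOW or HIGH")
  key <- paste(df$donor, df$bin, df$arm %||% "", sep = ":")
  if (anyDuplicated(key)) stop("duplicate (donor, bin, arm) combination")
  tab <- table(df$donor, df$bin)
  if (!all(tab[, "LOW"] >= 1 & tab[, "HIGH"] >= 1)) {
    stop("every donor must appear in both bins for a paired analysis")
  }
  df
}

#' Count several FASTQ samples into a count matrix
#'
#' @param samples Sample sheet data frame with a `fastq_path` column.
#' @param library A `guide_library`.
#' @param spec A [read_extraction_spec()].
#' @return List with `counts` (guide x sample integer matrix), `samples`, and
#'   `n_unassigned` (named per-sample vector).
#' @export
count_samples <- function(samples, library, spec = read_extraction_spec(0L)) {
  validate_sample_sheet(samples)
  index <- build_spacer_index(library)
  res <- lapply(samples$fastq_path, count_fastq, index = index, spec = spec)
  counts <- vapply(res, `[[`, integer(length(index)), "counts")
  colnames(counts) <- samples$sample_id
  list(counts = counts, samples = samples,
       n_unassigned = stats::setNames(
         vapply(res, `[[`, integer(1), "n_unassigned"), samples$sample_id))
}

#' Per-sample fold-coverage of the guide library
#'
#' Screens are maintained and sorted at a minimum fold-coverage (reads or
#' sorted cells per library guide); the conventional floor is 300x.
#'
#' @param counts Guide x sample count matrix.
#' @param library_size Number of guides in the library.
#' @param cells_sorted Optional named per-sample sorted-cell counts.
#' @param floor Coverage floor used for flagging (default 300).
#' @return Data frame: sample, coverage_reads, coverage_cells (NA when cell
#'   counts are absent), below_floor flag.
#' @export
coverage_report <- function(counts, library_size, cells_sorted = NULL,
                            floor = 300) {
  stopifnot(library_size > 0)
  cov_reads <- colSums(counts) / library_size
  cov_cells <- if (is.null(cells_sorted)) {
    rep(NA_real_, ncol(counts))
  } else {
    unname(cells_sorted[colnames(counts)]) / library_size
  }
  low <- cov_reads < floor | (!is.na(cov_cells) & cov_cells < floor)
  data.frame(sample = colnames(counts),
             coverage_reads = unname(cov_reads),
             coverage_cells = cov_cells,
             below_floor = unname(low),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a count matrix as tab-separated text
#'
#' Guides as rows, samples as columns, first column `guide_id`.
#'
#' @param counts Guide x sample integer matrix with dimnames.
#' @param path Output path.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(guide_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param path Input path.
#' @return Integer matrix with guide ids as rownames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}
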