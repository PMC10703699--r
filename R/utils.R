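# Internal helpers shared across modules.

#' @importFrom stats median pnorm qnorm rnorm runif rpois rnbinom rbeta rexp
#'   optimize lm coef pbeta p.adjust setNames ks.test wilcox.test
#'   model.matrix glm.fit poisson aggregate
#' @importFrom utils head read.delim write.table
NULL

# IUPAC nucleotide code -> the set of bases it stands for
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

NON_TARGETING <- "NON_TARGETING"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

is_dna <- function(x) {
  grepl("^[ACGT]+$", x)
}

check_iupac <- function(pattern, n = NULL) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  if (!all(chars %in% names(IUPAC_SETS))) {
    stop("PAM pattern contains non-IUPAC characters: ", pattern, call. = FALSE)
  }
  if (!is.null(n) && length(chars) != n) {
    stop("PAM pattern must have length ", n, ", got '", pattern, "'",
         call. = FALSE)
  }
  toupper(pattern)
}

# Does a concrete DNA string match an IUPAC pattern of equal length?
iupac_match <- function(x, pattern) {
  xs <- strsplit(x, "")[[1]]
  ps <- strsplit(pattern, "")[[1]]
  if (length(xs) != length(ps)) return(FALSE)
  all(mapply(function(b, p) b %in% IUPAC_SETS[[p]], xs, ps))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
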