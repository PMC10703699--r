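# Shared fixtures built in code at test time.

# Null table for rho at all gene sizes used in the suite, built once per run.
.fixture_env <- new.env(parent = emptyenv())

get_null_table <- function() {
  if (is.null(.fixture_env$null_table)) {
    .fixture_env$null_table <- build_null_table(1:16, n_sim = 1e5, seed = 99)
  }
  .fixture_env$null_table
}

# A uniform-null per-guide statistics table (guide-level inputs to the gene
# stage) with ng genes of k guides plus n_nt NT guides.
uniform_guide_stats <- function(ng, k, n_nt) {
  n <- ng * k + n_nt
  p <- runif(n)
  z <- rnorm(n)
  data.frame(
    guide_id = c(sprintf("g%05d", seq_len(ng * k)),
                 sprintf("NT_%04d", seq_len(n_nt))),
    target_gene = c(rep(sprintf("gene%03d", seq_len(ng)), each = k),
                    rep("NON_TARGETING", n_nt)),
    log2fc = z, pvalue = p,
    p_high = runif(n), ok = TRUE,
    stringsAsFactors = FALSE
  ) |> transform(p_low = 1 - p_high)
}

# Tiny hand-buildable guide library.
toy_library <- function() {
  rec <- data.frame(
    guide_id = c("A_g1", "A_g2", "B_g1", "NT_1", "NT_2"),
    spacer = c("ACGTACGTACGTACGTACGTA", "TTTTGGGGCCCCAAAATTTTG",
               "GATCGATCGATCGATCGATCG", "AAAACCCCGGGGTTTTACGTA",
               "CCGGAATTCCGGAATTCCGGA"),
    pam = c("AAGAGT", "CCGGGT", "TTGAAT", NA, NA),
    target_gene = c("A", "A", "B", "NON_TARGETING", "NON_TARGETING"),
    chrom = c("A", "A", "B", NA, NA),
    start = c(10L, 50L, 10L, NA, NA),
    end = c(31L, 71L, 31L, NA, NA),
    strand = c("+", "-", "+", NA, NA),
    cut_window_offset = c(-10L, 30L, -5L, NA, NA),
    stringsAsFactors = FALSE
  )
  guide_library(rec, pam_pattern = "NNGRRT", spacer_length = 21L)
}
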