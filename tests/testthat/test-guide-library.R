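test_that("a hand-placed PAM yields exactly the expected candidate", {
  s <- paste0(strrep("A", 21), "AAGAGT", strrep("A", 10))
  cand <- scan_candidate_guides(s, c(0, nchar(s)), "NNGRRT", 21)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$spacer, strrep("A", 21))
  expect_equal(cand$pam, "AAGAGT")
  expect_equal(cand$strand, "+")
  expect_equal(cand$start, 0L)
  expect_equal(cand$end, 21L)
  # the reverse complement holds no additional PAM: brute-force confirms
  oracle <- oracle_scan(s, 0, nchar(s), "NNGRRT", 21)
  expect_equal(nrow(oracle), 1L)
  expect_equal(oracle$strand, "+")
})

test_that("sequences without a PAM yield no candidates", {
  s <- strrep("AC", 25)  # no NNGRRT on either strand
  expect_equal(nrow(oracle_scan(s, 0, 50, "NNGRRT", 21)), 0L)
  expect_equal(nrow(scan_candidate_guides(s, c(0, 50), "NNGRRT", 21)), 0L)
})

test_that("windows outside the sequence are an error naming the overflow", {
  s <- strrep("A", 100)
  expect_error(scan_candidate_guides(s, c(-10, 50), "NNGRRT", 21), "outside")
  expect_error(scan_candidate_guides(s, c(0, 150), "NNGRRT", 21), "50 bp")
})

test_that("scanning equals the exhaustive both-strand oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
    for (pam in c("NNGRRT", "NNGRRN")) {
      got <- scan_candidate_guides(s, c(0, 500), pam, 21)
      want <- oracle_scan(s, 0, 500, pam, 21)
      expect_equal(nrow(got), nrow(want))
      key <- function(d) sort(paste(d$start, d$strand, d$spacer, d$pam))
      expect_equal(key(got), key(want))
    }
  }
  # windows relative to an anchor restrict the candidate set
  set.seed(4)
  s <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE), collapse = "")
  got <- scan_candidate_guides(s, c(-200, 150), "NNGRRN", 21, anchor = 400)
  want <- oracle_scan(s, 200, 550, "NNGRRN", 21)
  expect_equal(sort(paste(got$start, got$strand)),
               sort(paste(want$start, want$strand)))
  expect_equal(got$cut_window_offset,
               ifelse(got$strand == "+", got$start - 400, got$end - 1 - 400))
})

test_that("non-ACGT positions yield no candidates without failing", {
  s <- paste0(strrep("A", 21), "NAGAGT", strrep("A", 21), "AAGAGT", "AAAA")
  cand <- scan_candidate_guides(s, c(0, nchar(s)), "NNGRRT", 21)
  # the N-containing PAM is skipped; the clean downstream PAM survives
  expect_true(all(is_dna <- grepl("^[ACGT]+$", cand$spacer)))
  expect_true(all(grepl("^[ACGT]+$", cand$pam)))
  expect_true(any(cand$strand == "+" & cand$pam == "AAGAGT"))
})

test_that("off-target filtering keeps self-only candidates and matches the Hamming oracle", {
  set.seed(10)
  locus <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                 collapse = "")
  cand <- scan_candidate_guides(locus, c(0, 600), "NNGRRN", 21)
  cand <- cand[!duplicated(cand$spacer), ]
  expect_gt(nrow(cand), 3)

  # background = design locus only: every candidate has its one self-match
  kept_self <- filter_off_target(cand, locus, pam_pattern = "NNGRRN")
  expect_equal(nrow(kept_self), nrow(cand))

  # an exact second copy of one candidate's spacer+PAM removes it alone
  victim <- cand[1, ]
  copy <- paste0("TTTT", substr(locus, victim$start + 1, victim$end + 6),
                 "TTTT")
  if (victim$strand == "-") {
    copy <- paste0("TTTT", oracle_revcomp(
      substr(locus, victim$start - 5, victim$end)), "TTTT")
  }
  kept <- filter_off_target(cand, c(locus, copy), pam_pattern = "NNGRRN")
  expect_false(victim$guide_id %in% kept$guide_id)
  expect_equal(nrow(kept), nrow(cand) - 1L)

  # random 2-kb background: agreement with the exhaustive Hamming oracle
  set.seed(11)
  bg2 <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
  background <- c(locus, bg2)
  kept2 <- filter_off_target(cand, background, pam_pattern = "NNGRRN")
  oracle_counts <- vapply(cand$spacer, oracle_offtarget_sites, integer(1),
                          background = background, pam = "NNGRRN")
  expect_equal(kept2$guide_id, cand$guide_id[oracle_counts == 1])

  # monotonicity: enlarging the background never enlarges the kept set
  expect_true(all(kept2$guide_id %in% kept_self$guide_id))
  expect_error(filter_off_target(cand, character(0)), "empty")
})

test_that("NT guides match pooled composition and avoid the background", {
  set.seed(7)
  spacers <- random_dna(100, 21)  # ~25% each base in the pool
  nt <- generate_nt_guides(spacers, n = 120, background = NULL, seed = 7)
  expect_equal(nrow(nt), 120L)
  expect_true(all(nt$target_gene == "NON_TARGETING"))
  expect_true(all(is.na(nt$start)))
  freqs <- table(factor(unlist(strsplit(nt$spacer, "")),
                        levels = c("A", "C", "G", "T")))
  freqs <- as.numeric(freqs) / sum(freqs)
  expect_true(all(abs(freqs - 0.25) < 0.03))

  # with a background, every emitted NT has zero qualifying sites
  set.seed(8)
  bg <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
              collapse = "")
  nt2 <- generate_nt_guides(spacers, n = 10, background = bg, seed = 9)
  hits <- offtarget_site_counts(nt2$spacer, bg, pam_pattern = "NNGRRT")
  expect_true(all(hits == 0))

  # determinism under seed
  nt3 <- generate_nt_guides(spacers, n = 10, background = bg, seed = 9)
  expect_identical(nt2$spacer, nt3$spacer)

  # a fully degenerate pool admits only one spacer; with a collision-free
  # background all NT spacers equal it
  deg <- generate_nt_guides("AAAAAAAAAAAAAAAAAAAAA", n = 4,
                            background = NULL, seed = 1)
  expect_true(all(deg$spacer == strrep("A", 21)))

  # unreachable n errors and reports the draws attempted
  expect_error(generate_nt_guides(spacers, n = 50, background = NULL,
                                  seed = 1, max_draws = 10), "draws")
  expect_error(generate_nt_guides(spacers, n = 0), ">= 1")
})

test_that("tiling design composes scanning, filtering and NT generation", {
  # one strict-PAM site with a mixed-composition spacer (so NT controls can
  # be drawn from the pooled base frequencies without colliding)
  one_pam <- paste0(strrep("CT", 15), "ACGTACGTACGTACGTACGTA", "AAGAGT",
                    strrep("CT", 15))
  lib <- design_tiling_library(list(G1 = list(sequence = one_pam, anchor = 0)),
                               window = c(0, nchar(one_pam)),
                               pam_pattern = "NNGRRT", n_nt = 3, seed = 5)
  a <- validate_library(lib)
  expect_equal(a$n_targeting, 1L)
  expect_equal(a$n_nt, 3L)
  expect_equal(a$n_total, 4L)

  # a gene with no PAM site lands in the untargeted list, not dropped
  lib2 <- design_tiling_library(
    list(G1 = list(sequence = one_pam, anchor = 0),
         EMPTY = list(sequence = strrep("AC", 40), anchor = 0)),
    window = c(0, 60), pam_pattern = "NNGRRT", n_nt = 2, seed = 5)
  expect_true("EMPTY" %in% validate_library(lib2)$untargeted)

  expect_error(design_tiling_library(
    stats::setNames(list(list(sequence = one_pam, anchor = 0),
                         list(sequence = one_pam, anchor = 0)),
                    c("G1", "G1")),
    window = c(0, 50)), "unique")

  # multi-gene totals equal the composition of the two oracles
  set.seed(21)
  tss <- lapply(1:5, function(i) {
    list(sequence = paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                          collapse = ""), anchor = 200)
  })
  names(tss) <- sprintf("G%d", 1:5)
  lib3 <- design_tiling_library(tss, window = c(-150, 150),
                                pam_pattern = "NNGRRT", n_nt = 8, seed = 3)
  background <- vapply(tss, `[[`, character(1), "sequence")
  expected_targeting <- 0L
  for (g in names(tss)) {
    cand <- oracle_scan(tss[[g]]$sequence, 50, 350, "NNGRRT", 21)
    cand <- cand[!duplicated(cand$spacer), , drop = FALSE]
    if (nrow(cand) == 0) next
    counts <- vapply(cand$spacer, oracle_offtarget_sites, integer(1),
                     background = background, pam = "NNGRRT")
    expected_targeting <- expected_targeting + sum(counts == 1)
  }
  a3 <- validate_library(lib3)
  expect_equal(a3$n_targeting, expected_targeting)
  expect_equal(a3$n_total, expected_targeting + 8L)
})

test_that("library audit arithmetic and file round-trip are exact", {
  lib <- toy_library()
  a <- validate_library(lib)
  expect_equal(a$n_total, 5L)
  expect_equal(a$n_nt, 2L)
  expect_equal(a$n_targeting, 3L)
  expect_equal(a$n_genes_targeted, 2L)
  expect_equal(a$mean_guides_per_gene, 1.5)
  expect_equal(a$min_guides_per_gene, 1L)
  expect_equal(a$n_total, a$n_nt + a$n_targeting)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_guide_library(lib, path)
  lib2 <- read_guide_library(path)
  a2 <- validate_library(lib2)
  expect_equal(a2[c("n_total", "n_nt", "n_targeting", "n_genes_targeted",
                    "mean_guides_per_gene")],
               a[c("n_total", "n_nt", "n_targeting", "n_genes_targeted",
                   "mean_guides_per_gene")])
  expect_equal(lib2$records$spacer, lib$records$spacer)
  expect_equal(lib2$records$start, lib$records$start)

  # duplicate targeting spacers are dropped with a warning; ids must be unique
  rec <- lib$records
  rec$spacer[2] <- rec$spacer[1]
  expect_warning(guide_library(rec), "duplicate")
  rec2 <- lib$records
  rec2$guide_id[2] <- rec2$guide_id[1]
  expect_error(guide_library(rec2), "duplicate guide_id")
})
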