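# Brute-force oracles, independent of the package implementation: plain-R
# position-by-position scans and definitional statistics used to freeze
# expected values.

iupac_oracle <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_iupac_match <- function(x, pattern) {
  xs <- strsplit(x, "")[[1]]
  ps <- strsplit(pattern, "")[[1]]
  length(xs) == length(ps) &&
    all(mapply(function(b, p) b %in% iupac_oracle[[p]], xs, ps))
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Exhaustive both-strand scan: every offset is tested against the PAM
# pattern; returns (start, strand, spacer, pam) rows in forward coordinates.
oracle_scan <- function(seq, win_lo, win_hi, pam, L) {
  seq <- toupper(seq)
  len <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    for (sp_start in 0:(len - L - 6)) {
      spacer <- substr(s, sp_start + 1, sp_start + L)
      pam_seq <- substr(s, sp_start + L + 1, sp_start + L + 6)
      if (!grepl("^[ACGT]+$", spacer) || !grepl("^[ACGT]+$", pam_seq)) next
      if (!oracle_iupac_match(pam_seq, pam)) next
      fwd_start <- if (strand == "+") sp_start else len - (sp_start + L)
      if (fwd_start < win_lo || fwd_start + L > win_hi) next
      rows[[length(rows) + 1]] <- data.frame(
        start = fwd_start, strand = strand, spacer = spacer, pam = pam_seq,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), strand = character(),
                      spacer = character(), pam = character()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Hamming distance at every PAM-adjacent window on both strands of every
# background sequence; counts sites with distance < maxmm_excl.
oracle_offtarget_sites <- function(spacer, background, pam, maxmm_excl = 4) {
  L <- nchar(spacer)
  n <- 0L
  for (bg in toupper(background)) {
    for (s in c(bg, oracle_revcomp(bg))) {
      len <- nchar(s)
      if (len < L + 6) next
      for (sp_start in 0:(len - L - 6)) {
        pam_seq <- substr(s, sp_start + L + 1, sp_start + L + 6)
        if (!grepl("^[ACGT]+$", pam_seq) || !oracle_iupac_match(pam_seq, pam)) next
        window <- substr(s, sp_start + 1, sp_start + L)
        if (!grepl("^[ACGT]+$", window)) next
        if (oracle_hamming(spacer, window) < maxmm_excl) n <- n + 1L
      }
    }
  }
  n
}

# Benjamini-Hochberg step-up by definition: q_(i) = min over j >= i of
# min(1, m * p_(j) / j), NAs excluded from the family.
oracle_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  pv <- p[idx]
  m <- length(pv)
  if (m == 0) return(out)
  o <- order(pv)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * pv[o][i:m] / (i:m)))
  }
  out[idx[o]] <- q
  out
}

# Monte-Carlo oracle for the order-statistic aggregation statistic:
# estimate P(U_(j) <= p_(j)) for each j from draws of k sorted uniforms.
oracle_rho_mc <- function(p, n_draws = 1e6) {
  k <- length(p)
  ps <- sort(p)
  u <- matrix(runif(n_draws * k), n_draws, k)
  if (k > 1) u <- t(apply(u, 1, sort))
  comp <- vapply(seq_len(k), function(j) mean(u[, j] <= ps[j]), numeric(1))
  min(comp)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
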