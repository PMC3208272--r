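# Independent brute-force oracles used to verify the implementation paths.

# random RNA string
rand_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# position-by-position Hamming scan of query against subject, one strand;
# N never matches
naive_hamming_hits <- function(query, subject, max_mm) {
  m <- nchar(query)
  n <- nchar(subject)
  if (n < m) return(data.frame(start = integer(0), mm = integer(0)))
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  starts <- integer(0); mms <- integer(0)
  for (i in 1:(n - m + 1)) {
    win <- s[i:(i + m - 1)]
    mm <- sum(q != win | q == "N" | win == "N")
    if (mm <= max_mm) { starts <- c(starts, i); mms <- c(mms, mm) }
  }
  data.frame(start = starts, mm = mms)
}

# both-strand oracle mirroring gapless_scan output (est_start, strand, mm)
naive_scan_oracle <- function(query, subject, max_mm) {
  fwd <- naive_hamming_hits(query, subject, max_mm)
  rev <- naive_hamming_hits(revcomp(query), subject, max_mm)
  rbind(
    if (nrow(fwd)) data.frame(est_start = fwd$start, strand = "+", mm = fwd$mm),
    if (nrow(rev)) data.frame(est_start = rev$start, strand = "-", mm = rev$mm)
  )
}

# exact one-sided signed-rank p-value by enumeration over all 2^n sign
# assignments (lower tail of W+), mid-ranked ties
enumerate_signed_rank_p <- function(deltas) {
  d <- deltas[deltas != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  total <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    w <- sum(rk[signs])
    if (w <= w_obs + 1e-9) total <- total + 1
  }
  total / 2^n
}

# naive windowed target-site oracle (antiparallel duplex scoring)
naive_target_oracle <- function(mirna, transcript, max_wmm, gu_weight) {
  m <- nchar(mirna); n <- nchar(transcript)
  q <- strsplit(mirna, "")[[1]]
  tr <- strsplit(transcript, "")[[1]]
  hits <- list()
  if (n < m) return(data.frame(site_start = integer(0), wmm = numeric(0)))
  for (s in 1:(n - m + 1)) {
    site <- tr[(s + m - 1):s]
    cost <- 0
    for (k in 1:m) {
      pair <- paste0(q[k], site[k])
      if (pair %in% c("AU", "UA", "GC", "CG")) next
      if (pair %in% c("GU", "UG")) cost <- cost + gu_weight else cost <- cost + 1
    }
    if (cost <= max_wmm) hits[[length(hits) + 1]] <-
        data.frame(site_start = s, wmm = cost)
  }
  if (!length(hits)) return(data.frame(site_start = integer(0), wmm = numeric(0)))
  do.call(rbind, hits)
}

# Fisher p-value for a 2x2 table by direct hypergeometric enumeration
# (two-sided by summing probabilities <= observed)
hypergeom_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
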