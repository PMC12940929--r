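# Independent oracles used to check the package's fast paths.

# Semi-global edit distance oracle: row-wise DP, vectorized with the
# running-minimum (cummin) trick for insertions. Free end gaps for the
# longer sequence; the shorter must align end to end. Structured entirely
# differently from the package's C++ column DP.
oracle_sg_cost <- function(a, b) {
  q <- if (nchar(a) <= nchar(b)) a else b
  t <- if (nchar(a) <= nchar(b)) b else a
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  prev <- rep(0L, m + 1L)  # row 0: free leading target overhang
  for (i in seq_len(n)) {
    sub_cost <- as.integer(qc[i] != tc | qc[i] == "N" | tc == "N")
    # without insertions-in-target yet: diagonal and vertical moves
    row <- pmin(c(i, prev[-(m + 1L)] + sub_cost), c(i, prev[-1L] + 1L))
    row[1] <- i
    # gaps in target (horizontal): running min of row[k] + (j - k)
    j <- seq_len(m + 1L)
    row <- cummin(row - j) + j
    prev <- row
  }
  min(prev)  # free trailing target overhang
}

# tiny nested-loop DP used once to validate the oracle itself
oracle_sg_cost_naive <- function(a, b) {
  q <- if (nchar(a) <= nchar(b)) a else b
  t <- if (nchar(a) <= nchar(b)) b else a
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  dp <- matrix(0L, n + 1L, m + 1L)
  dp[, 1L] <- 0:n
  for (j in seq_len(m)) {
    for (i in seq_len(n)) {
      mis <- qc[i] != tc[j] || qc[i] == "N" || tc[j] == "N"
      dp[i + 1L, j + 1L] <- min(dp[i, j] + mis, dp[i, j + 1L] + 1L,
                                dp[i + 1L, j] + 1L)
    }
  }
  min(dp[n + 1L, ])
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
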