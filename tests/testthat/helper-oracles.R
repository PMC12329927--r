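# Independent oracles used by the tests. These re-derive expected values by
# brute force or plain-R dynamic programming, separately from the package's
# C++ kernels.

# Plain-R Gotoh alignment (three-matrix DP with traceback). free_ends = TRUE
# leaves terminal gaps unpenalised; tie preference during fill is M, then X
# (gap in b), then Y (gap in a), mirroring the production kernel.
r_align <- function(a, b, match = 1, mismatch = -1, gap_open = -2,
                    gap_ext = -1, free_ends = FALSE) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  pM <- pX <- pY <- matrix(NA_integer_, n + 1, m + 1)
  go <- gap_open + gap_ext
  M[1, 1] <- 0
  if (free_ends) {
    X[2:(n + 1), 1] <- 0
    Y[1, 2:(m + 1)] <- 0
  } else {
    if (n > 0) X[2:(n + 1), 1] <- gap_open + (1:n) * gap_ext
    if (m > 0) Y[1, 2:(m + 1)] <- gap_open + (1:m) * gap_ext
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      w <- which.max(cand)
      if (cand[w] > NEG / 2) { M[i, j] <- cand[w] + s; pM[i, j] <- w }
      cand <- c(M[i - 1, j] + go, X[i - 1, j] + gap_ext, Y[i - 1, j] + go)
      w <- which.max(cand)
      if (max(M[i - 1, j], X[i - 1, j], Y[i - 1, j]) > NEG / 2) {
        X[i, j] <- cand[w]; pX[i, j] <- w
      }
      cand <- c(M[i, j - 1] + go, X[i, j - 1] + go, Y[i, j - 1] + gap_ext)
      w <- which.max(cand)
      if (max(M[i, j - 1], X[i, j - 1], Y[i, j - 1]) > NEG / 2) {
        Y[i, j] <- cand[w]; pY[i, j] <- w
      }
    }
  }
  if (free_ends) {
    best <- NEG; bi <- n + 1; bj <- m + 1; bm <- 1
    for (j in 1:(m + 1)) {
      cand <- c(M[n + 1, j], X[n + 1, j], Y[n + 1, j])
      w <- which.max(cand)
      if (cand[w] > best) { best <- cand[w]; bi <- n + 1; bj <- j; bm <- w }
    }
    for (i in 1:(n + 1)) {
      cand <- c(M[i, m + 1], X[i, m + 1], Y[i, m + 1])
      w <- which.max(cand)
      if (cand[w] > best) { best <- cand[w]; bi <- i; bj <- m + 1; bm <- w }
    }
  } else {
    cand <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
    bm <- which.max(cand); best <- cand[bm]; bi <- n + 1; bj <- m + 1
  }
  # traceback (collected back-to-front, reversed at the end)
  out_a <- character(); out_b <- character()
  if (bi <= n) { out_a <- av[n:(bi)]; out_b <- rep("-", n - bi + 1) }
  if (bj <= m) { out_a <- c(out_a, rep("-", m - bj + 1)); out_b <- c(out_b, bv[m:(bj)]) }
  i <- bi; j <- bj; mat <- bm
  while (i > 1 || j > 1) {
    if (mat == 1) {
      if (i == 1 && j == 1) break
      p <- pM[i, j]
      out_a <- c(out_a, av[i - 1]); out_b <- c(out_b, bv[j - 1])
      i <- i - 1; j <- j - 1; mat <- p
      if (i == 1 && j == 1) break
      if (is.na(mat)) break
    } else if (mat == 2) {
      if (j == 1) {
        while (i > 1) { out_a <- c(out_a, av[i - 1]); out_b <- c(out_b, "-"); i <- i - 1 }
        break
      }
      p <- pX[i, j]
      out_a <- c(out_a, av[i - 1]); out_b <- c(out_b, "-")
      i <- i - 1; mat <- p
    } else {
      if (i == 1) {
        while (j > 1) { out_a <- c(out_a, "-"); out_b <- c(out_b, bv[j - 1]); j <- j - 1 }
        break
      }
      p <- pY[i, j]
      out_a <- c(out_a, "-"); out_b <- c(out_b, bv[j - 1])
      j <- j - 1; mat <- p
    }
    if (i == 1 && j == 1) break
    if (i == 1 && mat == 1) {
      while (j > 1) { out_a <- c(out_a, "-"); out_b <- c(out_b, bv[j - 1]); j <- j - 1 }
      break
    }
    if (j == 1 && mat == 1) {
      while (i > 1) { out_a <- c(out_a, av[i - 1]); out_b <- c(out_b, "-"); i <- i - 1 }
      break
    }
  }
  list(score = best,
       aln_a = paste(rev(out_a), collapse = ""),
       aln_b = paste(rev(out_b), collapse = ""))
}

# Distance dialect recount from a pair of aligned strings: end-trimmed
# columns, internal gap runs compressed to one difference.
r_dialect_distance <- function(aln_a, aln_b) {
  av <- strsplit(aln_a, "")[[1]]; bv <- strsplit(aln_b, "")[[1]]
  gap <- av == "-" | bv == "-"
  lo <- which(!gap)[1]
  hi <- rev(which(!gap))[1]
  av <- av[lo:hi]; bv <- bv[lo:hi]
  gap <- av == "-" | bv == "-"
  runs <- sum(diff(c(FALSE, gap)) == 1)
  matches <- sum(!gap & av == bv)
  mism <- sum(!gap & av != bv)
  den <- matches + mism + runs
  if (den == 0) return(1)
  (mism + runs) / den
}

# Oracle distance between two sequences (plain-R DP + recount).
r_distance <- function(a, b) {
  al <- r_align(a, b)
  r_dialect_distance(al$aln_a, al$aln_b)
}

rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                collapse = "")

genus_of <- function(x) sub("\\s.*$", "", x)

# Brute-force MCC of a partition (independent of partition_mcc).
r_mcc <- function(D, assign, cutoff = 0.03) {
  n <- nrow(D)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    close <- D[i, j] <= cutoff
    tog <- assign[i] == assign[j]
    if (close && tog) tp <- tp + 1
    else if (!close && tog) fp <- fp + 1
    else if (close && !tog) fn <- fn + 1
    else tn <- tn + 1
  }
  if (fp == 0 && fn == 0) return(1)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}
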