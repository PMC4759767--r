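# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and Biostrings): plain-R dynamic programming and
# enumeration at tiny problem sizes.

# Global affine-gap alignment score of two (short) strings under
# match +2 / mismatch -3 / gap of length L costs 5 + 2L; N is neutral (0).
# Three-state DP (match, gap-in-a, gap-in-b).
oracle_global_affine <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  sub <- function(x, y) if (x == "N" || y == "N") 0 else if (x == y) 2 else -3
  NEG <- -1e9
  M <- Ia <- Ib <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in seq_len(m)) Ib[1, j + 1] <- -5 - 2 * j
  for (i in seq_len(n)) Ia[i + 1, 1] <- -5 - 2 * i
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- sub(A[i], B[j])
    M[i + 1, j + 1] <- max(M[i, j], Ia[i, j], Ib[i, j]) + s
    Ia[i + 1, j + 1] <- max(M[i, j + 1] - 7, Ia[i, j + 1] - 2)
    Ib[i + 1, j + 1] <- max(M[i + 1, j] - 7, Ib[i + 1, j] - 2)
  }
  max(M[n + 1, m + 1], Ia[n + 1, m + 1], Ib[n + 1, m + 1])
}

# Best local alignment score = max global score over all substring pairs
# (plus the empty alignment, score 0). Exhaustive; only for short sequences.
oracle_local_align <- function(a, b) {
  best <- 0
  na <- nchar(a); nb <- nchar(b)
  for (i1 in seq_len(na)) for (i2 in i1:na) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(nb)) for (j2 in j1:nb) {
      sc <- oracle_global_affine(sa, substr(b, j1, j2))
      if (sc > best) best <- sc
    }
  }
  best
}

# Exact upper-tail fair-coin probability by direct enumeration.
oracle_binom_upper <- function(k, n) {
  sum(choose(n, k:n)) / 2^n
}

# Two-group log-rank statistic from first principles: at each distinct event
# time, observed minus hypergeometric-expected events in group 1, with the
# hypergeometric variance; statistic = (sum O-E)^2 / sum V.
oracle_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  o_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    o_e <- o_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_e^2 / v
}

# Deterministic synthetic label/matrix fixtures -------------------------------

make_labeled_matrix <- function(n_genes, n_sens, n_res, shift_rows = integer(),
                                shift = 0, seed = 1, noise_sd = 1) {
  withr::with_seed(seed, {
    n <- n_sens + n_res
    samples <- sprintf("S%02d", seq_len(n))
    v <- matrix(rnorm(n_genes * n, sd = noise_sd), n_genes, n,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)), samples))
    labels <- setNames(rep(c("sensitive", "resistant"), c(n_sens, n_res)),
                       samples)
    if (length(shift_rows))
      v[shift_rows, labels == "sensitive"] <-
        v[shift_rows, labels == "sensitive"] + shift
    list(m = expression_matrix(v), labels = labels)
  })
}

as_vanilla <- function(m) {
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  m
}
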