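# Independent brute-force oracles and random-input generators. These stay
# deliberately naive (double loops, direct formulas) so they share no code
# path with the implementation they check.

# Leftmost occurrence of pattern in subject with Hamming distance <= maxMM;
# returns list(start1, mismatches) with 1-based start, or NULL.
naiveHammingSearch <- function(subject, pattern, maxMM) {
  sc <- strsplit(subject, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  n <- length(sc); m <- length(pc)
  if (m > n) return(NULL)
  for (s in 1:(n - m + 1)) {
    mm <- 0L
    for (j in 1:m) if (sc[s + j - 1] != pc[j]) mm <- mm + 1L
    if (mm <= maxMM) return(list(start1 = s, mismatches = mm))
  }
  NULL
}

# Minimum Hamming distance of pattern over all placements (Inf if none fit).
naiveBestMismatch <- function(subject, pattern) {
  sc <- strsplit(subject, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  n <- length(sc); m <- length(pc)
  if (m > n) return(Inf)
  best <- Inf
  for (s in 1:(n - m + 1)) {
    mm <- 0L
    for (j in 1:m) if (sc[s + j - 1] != pc[j]) mm <- mm + 1L
    if (mm < best) best <- mm
  }
  best
}

# Pearson r and two-sided p from the covariance formula and t transform.
oraclePearson <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Pooled-variance two-sample t and two-sided p, direct formulas.
oracleStudentT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = na + nb - 2))
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small random composition over all five classes.
randomComposition <- function(gene = "Zc3h12a", maxPerClass = 8L) {
  counts <- sapply(c("none", "mono_U", "oligo_U", "C_add", "G_add"),
                   function(cls) sample(0:maxPerClass, 1))
  if (sum(counts) == 0) counts["none"] <- 1L
  TailComposition("random", gene, counts)
}

zcAnchor <- function() builtinAnchors()$Zc3h12a
il6Anchor <- function() builtinAnchors()$Il6
zcOnlyParam <- function() TailCallerParam(builtinAnchors()["Zc3h12a"])
bothParam <- function() TailCallerParam(builtinAnchors())
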