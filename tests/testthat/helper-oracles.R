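# Independent brute-force oracles. These deliberately share no code with the
# package implementations: plain loops and direct definitions only.

# random record over the canonical alphabet
random_record <- function(n, id = "r", prob = NULL) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  protein_record(id, paste(sample(aa, n, replace = TRUE, prob = prob),
                           collapse = ""))
}

# character tally by explicit loop
oracle_tally <- function(seq) {
  out <- integer(0)
  for (ch in strsplit(seq, "")[[1]]) {
    if (is.na(out[ch])) out[ch] <- 0L
    out[ch] <- out[ch] + 1L
  }
  out
}

oracle_entropy <- function(s) {
  chars <- strsplit(s, "")[[1]]
  h <- 0
  for (sym in unique(chars)) {
    p <- sum(chars == sym) / length(chars)
    h <- h - p * log(p, base = 2)
  }
  h
}

# low-complexity scan by testing every window independently, then applying
# the trigger/extend/merge definition with explicit loops
oracle_scan_lc <- function(seq, params) {
  n <- nchar(seq)
  w <- params$window
  if (n < w) return(data.frame(start = integer(0), end = integer(0)))
  H <- sapply(1:(n - w + 1), function(i)
    oracle_entropy(substr(seq, i, i + w - 1)))
  ext <- H <= params$k_extend
  trig <- H <= params$k_trigger
  segs <- list()
  i <- 1
  while (i <= length(ext)) {
    if (!ext[i]) { i <- i + 1; next }
    j <- i
    while (j < length(ext) && ext[j + 1]) j <- j + 1
    if (any(trig[i:j]))
      segs[[length(segs) + 1]] <- c(i - 1, j - 1 + w)
    i <- j + 1
  }
  oracle_merge(segs, params$merge_gap)
}

# residue-bias scan by testing every window independently with an exact
# binomial-pmf summation tail
oracle_scan_bias <- function(seq, residues, params) {
  n <- nchar(seq)
  w <- params$window
  if (n < w) return(data.frame(start = integer(0), end = integer(0)))
  residues <- strsplit(residues, "")[[1]]
  p0 <- sum(params$background[residues])
  chars <- strsplit(seq, "")[[1]]
  segs <- list()
  for (i in 1:(n - w + 1)) {
    obs <- sum(chars[i:(i + w - 1)] %in% residues)
    tail <- oracle_binom_tail(obs, w, p0)
    if (tail <= params$p_threshold)
      segs[[length(segs) + 1]] <- c(i - 1, i - 1 + w)
  }
  # union overlapping windows first (gap 0), then bridge merge_gap
  oracle_merge(segs, params$merge_gap)
}

# exact upper tail P(X >= k) by summing the pmf
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(sapply(k:n, function(x) choose(n, x) * p^x * (1 - p)^(n - x)))
}

oracle_merge <- function(segs, gap) {
  if (length(segs) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, segs)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- list(m[1, ])
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    last <- out[[length(out)]]
    if (m[i, 1] - last[2] <= gap) {
      out[[length(out)]] <- c(last[1], max(last[2], m[i, 2]))
    } else {
      out[[length(out) + 1]] <- m[i, ]
    }
  }
  m2 <- do.call(rbind, out)
  data.frame(start = as.integer(m2[, 1]), end = as.integer(m2[, 2]))
}

# grid-search mixture fraction at step 1e-3
oracle_mixture_grid <- function(m, cand, bg, step = 1e-3) {
  fs <- seq(0, 1, by = step)
  d <- sapply(fs, function(f) sqrt(sum((m - (f * cand + (1 - f) * bg))^2)))
  fs[which.min(d)]
}

# two-term KL-based Jensen-Shannon divergence straight from the definition
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  klterm <- function(a, b) if (a == 0) 0 else a * log2(a / b)
  0.5 * sum(mapply(klterm, p, m)) + 0.5 * sum(mapply(klterm, q, m))
}
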