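# Low-complexity and compositionally biased region scanning.
#
# Coordinates are 0-based half-open throughout; they are converted to
# 1-based closed form only in human-readable report tables.

#' Scan parameters for region detection
#'
#' Defaults follow a SEG-like two-threshold design: windows of 25 residues,
#' trigger entropy 2.2 bits, extension entropy 2.5 bits; binomial-tail
#' cutoff 1e-6 for residue-bias windows; segments separated by at most 10
#' residues are merged. The background is the uniform residue distribution
#' by default; a database-average background is available via
#' [aa_frequencies()]. Per-window tails are diagnostics, not hypothesis
#' tests — no multiple-testing correction is applied.
#'
#' @param window window length in residues (>= 2).
#' @param k_trigger,k_extend entropy thresholds in bits,
#'   `k_trigger <= k_extend`.
#' @param p_threshold binomial tail cutoff in (0, 1).
#' @param merge_gap maximum gap (residues) bridged when merging segments.
#' @param background named per-residue frequency vector summing to 1.
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(window = 25L, k_trigger = 2.2, k_extend = 2.5,
                        p_threshold = 1e-6, merge_gap = 10L,
                        background = aa_frequencies("uniform")) {
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2")
  if (k_trigger > k_extend) stop("k_trigger must be <= k_extend")
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must lie in (0, 1)")
  if (merge_gap < 0L) stop("merge_gap must be >= 0")
  if (is.null(names(background)) ||
      !setequal(names(background), AA_ALPHABET))
    stop("background must be named over the 20 residues")
  if (abs(sum(background) - 1) > 1e-6)
    stop("background frequencies must sum to 1")
  structure(list(window = window, k_trigger = k_trigger, k_extend = k_extend,
                 p_threshold = p_threshold, merge_gap = as.integer(merge_gap),
                 background = background[AA_ALPHABET]),
            class = "scan_params")
}

#' Reference amino-acid frequency backgrounds
#'
#' `"uniform"` gives 1/20 per residue. `"database"` gives the long-run
#' average residue frequencies of the curated protein sequence universe
#' (UniProtKB/Swiss-Prot release statistics), renormalized to sum to 1.
#'
#' @param source `"uniform"` or `"database"`.
#' @return Named numeric vector over the 20 residues, summing to 1.
#' @export
aa_frequencies <- function(source = c("uniform", "database")) {
  source <- match.arg(source)
  if (source == "uniform")
    return(stats::setNames(rep(1 / 20, 20), AA_ALPHABET))
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93,
         E = 6.72, G = 7.07, H = 2.27, I = 5.91, L = 9.65, K = 5.80,
         M = 2.41, F = 3.86, P = 4.74, S = 6.64, T = 5.35, W = 1.10,
         Y = 2.92, V = 6.86)
  (f / sum(f))[AA_ALPHABET]
}

#' Shannon entropy of a sequence window
#'
#' @param window_seq non-empty string of residues.
#' @return Entropy in bits, `-sum(p * log2(p))` over observed characters;
#'   lies in `[0, log2(20)]` for residue windows.
#' @examples
#' window_entropy("SSSSSSSSSS")  # 0
#' window_entropy("SGSGSGSGSG")  # 1
#' @export
window_entropy <- function(window_seq) {
  chars <- strsplit(as.character(window_seq), "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) stop("empty window")
  p <- as.numeric(table(chars)) / length(chars)
  -sum(p * log2(p))
}

# Entropy of every length-w window, vectorized over positions.
all_window_entropies <- function(chars, w) {
  n <- length(chars)
  levs <- unique(chars)
  # running counts per symbol via cumulative sums
  H <- numeric(n - w + 1L)
  cum <- sapply(levs, function(s) cumsum(chars == s))
  cum <- rbind(0, cum)
  for (i in seq_len(n - w + 1L)) {
    cnt <- cum[i + w, ] - cum[i, ]
    p <- cnt[cnt > 0] / w
    H[i] <- -sum(p * log2(p))
  }
  H
}

# Merge sorted 0-based half-open intervals whose gap is <= merge_gap,
# carrying a per-interval score combined with `comb`.
merge_intervals <- function(start, end, score, merge_gap, comb = min) {
  if (length(start) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0)))
  ord <- order(start, end)
  start <- start[ord]; end <- end[ord]; score <- score[ord]
  out_s <- start[1]; out_e <- end[1]; out_sc <- score[1]
  res <- list()
  for (i in seq_along(start)[-1]) {
    if (start[i] - out_e <= merge_gap) {
      out_e <- max(out_e, end[i])
      out_sc <- comb(out_sc, score[i])
    } else {
      res[[length(res) + 1L]] <- c(out_s, out_e, out_sc)
      out_s <- start[i]; out_e <- end[i]; out_sc <- score[i]
    }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e, out_sc)
  m <- do.call(rbind, res)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             score = m[, 3])
}

bias_segments <- function(df, kind, dominant) {
  if (nrow(df) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      kind = character(0), dominant_residues = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  data.frame(start = df$start, end = df$end, kind = kind,
             dominant_residues = dominant, score = df$score,
             stringsAsFactors = FALSE)
}

#' Scan a protein for low-complexity regions
#'
#' Two-threshold sliding-window scan: windows whose Shannon entropy is at or
#' below `k_trigger` seed segments; maximal runs of overlapping windows with
#' entropy at or below `k_extend` that contain at least one seed become
#' segments (the union of their window spans); segments separated by at most
#' `merge_gap` residues are merged. The scan is deterministic.
#'
#' @param record a [protein_record()].
#' @param params a [scan_params()].
#' @return A data.frame of segments with columns `start`, `end` (0-based
#'   half-open), `kind` (`"low_complexity"`), `dominant_residues` (most
#'   frequent residue(s) in the segment, `/`-separated), `score` (minimum
#'   window entropy in bits). Sequences shorter than the window yield an
#'   empty result with a warning.
#' @export
scan_low_complexity <- function(record, params = scan_params()) {
  stopifnot(inherits(record, "protein_record"),
            inherits(params, "scan_params"))
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  n <- length(chars); w <- params$window
  if (n < w) {
    warning("sequence '", record$id, "' shorter than window (", n, " < ",
            w, "); no scan performed", call. = FALSE)
    return(bias_segments(data.frame(), "low_complexity", character(0)))
  }
  H <- all_window_entropies(chars, w)
  ext <- H <= params$k_extend
  trig <- H <= params$k_trigger
  # maximal runs of consecutive extendable window starts
  r <- rle(ext)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    idx <- run_start[k]:run_end[k]
    if (!any(trig[idx])) next
    segs[[length(segs) + 1L]] <-
      c(idx[1] - 1L, idx[length(idx)] - 1L + w, min(H[idx]))
  }
  if (length(segs) == 0L)
    return(bias_segments(data.frame(), "low_complexity", character(0)))
  m <- do.call(rbind, segs)
  merged <- merge_intervals(m[, 1], m[, 2], m[, 3], params$merge_gap,
                            comb = min)
  dom <- vapply(seq_len(nrow(merged)), function(i) {
    sub <- chars[(merged$start[i] + 1L):merged$end[i]]
    tab <- table(sub)
    paste(sort(names(tab)[tab == max(tab)]), collapse = "/")
  }, character(1))
  bias_segments(merged, "low_complexity", dom)
}

#' Scan a protein for regions biased toward a residue set
#'
#' For each window the upper binomial tail
#' `P(X >= observed | window, background mass of the residue set)` is
#' computed; windows with tail at or below `p_threshold` are kept, their
#' spans unioned, and segments separated by at most `merge_gap` residues
#' merged. Tails are computed in log space so extreme enrichment does not
#' underflow. The segment score is the maximum `-log10` tail over its
#' windows.
#'
#' @param record a [protein_record()].
#' @param residues non-empty character vector of one-letter codes (or a
#'   single string like `"GS"`).
#' @param params a [scan_params()].
#' @return A data.frame of segments as in [scan_low_complexity()], with
#'   `kind = "residue_bias"` and `dominant_residues` the queried set.
#' @export
scan_residue_bias <- function(record, residues, params = scan_params()) {
  stopifnot(inherits(record, "protein_record"),
            inherits(params, "scan_params"))
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "", fixed = TRUE)[[1]]
  residues <- toupper(residues)
  if (length(residues) == 0L) stop("residue set must be non-empty")
  if (!all(residues %in% AA_ALPHABET))
    stop("unknown residue code(s): ",
         paste(setdiff(residues, AA_ALPHABET), collapse = ", "))
  p0 <- sum(params$background[residues])
  if (p0 <= 0) stop("background mass of the queried residues is 0")
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  n <- length(chars); w <- params$window
  label <- paste(sort(unique(residues)), collapse = "/")
  if (n < w) {
    warning("sequence '", record$id, "' shorter than window (", n, " < ",
            w, "); no scan performed", call. = FALSE)
    return(bias_segments(data.frame(), "residue_bias", character(0)))
  }
  hit <- as.integer(chars %in% residues)
  cs <- c(0L, cumsum(hit))
  obs <- cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]
  logtail <- stats::pbinom(obs - 1L, w, p0, lower.tail = FALSE, log.p = TRUE)
  keep <- which(logtail <= log(params$p_threshold))
  if (length(keep) == 0L)
    return(bias_segments(data.frame(), "residue_bias", character(0)))
  score <- -logtail[keep] / log(10)
  merged <- merge_intervals(keep - 1L, keep - 1L + w, score,
                            params$merge_gap, comb = max)
  bias_segments(merged, "residue_bias", label)
}

#' Fraction of a sequence covered by bias segments
#'
#' @param segments a data.frame of non-overlapping segments (as returned by
#'   the scan functions) with `start`, `end` columns.
#' @param length sequence length.
#' @return Union length divided by sequence length, in `[0, 1]`.
#' @examples
#' coverage(data.frame(start = 0, end = 50), 100)  # 0.5
#' @export
coverage <- function(segments, length) {
  if (length <= 0) stop("length must be positive")
  if (nrow(segments) == 0L) return(0)
  ord <- order(segments$start)
  s <- segments$start[ord]; e <- segments$end[ord]
  if (any(s < 0) || any(e > length) || any(s >= e))
    stop("invalid segment coordinates")
  if (any(s[-1] < e[-length(s)]))
    stop("segments overlap; merge them upstream")
  sum(e - s) / length
}
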