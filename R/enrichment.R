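# Case/control channel enrichment, candidate ranking, profile similarity,
# and two-component mixture-fraction estimation.

#' Per-channel fold change between case and control compositions
#'
#' Computes case/control ratios for every channel and calls the target
#' (enriched) channel(s). The default calling rule is the strictly greatest
#' fold change, provided it exceeds 1 — mirroring the situation where one
#' amino acid rises in the deposit-rich fraction while all others fall. For
#' dipeptide-repeat-like biases a threshold mode calls every channel whose
#' fold change reaches `cutoff`.
#'
#' Control fractions below `epsilon` are replaced by `epsilon` before
#' division (a pseudo-fraction guarding against division by zero); a message
#' is emitted whenever this happens.
#'
#' @param case,control [composition_vector()]s under the same scheme.
#' @param epsilon small positive pseudo-fraction for near-zero controls.
#' @param mode `"max"` (unique maximum > 1) or `"threshold"`.
#' @param cutoff fold-change cutoff for `mode = "threshold"`.
#' @return An object of class `enrichment_result`: list with `fold_change`
#'   (named numeric), `target_channels` (ordered by descending fold change),
#'   `epsilon`, `mode`.
#' @examples
#' sch <- hydrolysis_scheme("msa")
#' case <- composition_vector(c(Ser = 0.38, Gly = 0.62), sch)
#' ctrl <- composition_vector(c(Ser = 0.10, Gly = 0.90), sch)
#' fold_change(case, ctrl)$target_channels  # "Ser"
#' @export
fold_change <- function(case, control, epsilon = 1e-4,
                        mode = c("max", "threshold"), cutoff = 1.5) {
  stopifnot(inherits(case, "composition_vector"),
            inherits(control, "composition_vector"))
  if (case$scheme_name != control$scheme_name)
    stop("scheme mismatch: case is '", case$scheme_name, "', control is '",
         control$scheme_name, "'")
  if (epsilon <= 0) stop("epsilon must be positive")
  mode <- match.arg(mode)
  denom <- control$fractions
  floored <- denom < epsilon
  if (any(floored)) {
    message("fold_change: control fraction below epsilon for ",
            paste(names(denom)[floored], collapse = ", "),
            "; using epsilon = ", epsilon)
    denom[floored] <- epsilon
  }
  fc <- case$fractions / denom
  targets <- if (mode == "max") {
    mx <- max(fc)
    if (mx > 1) names(fc)[fc == mx] else character(0)
  } else {
    names(fc)[fc >= cutoff & fc > 1]
  }
  targets <- targets[order(-fc[targets], targets)]
  structure(list(fold_change = fc, target_channels = targets,
                 epsilon = epsilon, mode = mode),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> target:",
      if (length(x$target_channels)) paste(x$target_channels, collapse = ", ")
      else "(none)", "\n")
  print(round(sort(x$fold_change, decreasing = TRUE), 3))
  invisible(x)
}

#' Rank candidate proteins by their content of one channel
#'
#' Scores every candidate by [protein_composition()] and orders by
#' descending channel fraction. Ties share the smaller rank and are ordered
#' alphabetically by id, so the ranking is deterministic and
#' permutation-invariant. Candidates with no recoverable residues under the
#' scheme are excluded with a warning and listed in the `excluded` field.
#'
#' @param candidates non-empty list of [protein_record()]s.
#' @param channel target channel label.
#' @param scheme a [hydrolysis_scheme()].
#' @return An object of class `candidate_ranking`: list with `channel`,
#'   `scheme_name`, `rows` (data.frame `id`, `fraction`, `rank`), `excluded`.
#' @export
rank_by_channel <- function(candidates, channel, scheme) {
  stopifnot(inherits(scheme, "hydrolysis_scheme"))
  if (length(candidates) == 0L) stop("no candidates to rank")
  if (!channel %in% scheme$channels)
    stop("channel '", channel, "' not in scheme '", scheme$name, "'")
  frac <- vapply(candidates, function(rec) {
    tryCatch(protein_composition(rec, scheme)$fractions[[channel]],
             error = function(e) NA_real_)
  }, numeric(1))
  ids <- vapply(candidates, `[[`, character(1), "id")
  excluded <- ids[is.na(frac)]
  if (length(excluded))
    warning("excluded (no recoverable residues): ",
            paste(excluded, collapse = ", "), call. = FALSE)
  keep <- !is.na(frac)
  ids <- ids[keep]; frac <- frac[keep]
  ord <- order(-frac, ids)
  rows <- data.frame(id = ids[ord], fraction = frac[ord],
                     rank = rank(-frac[ord], ties.method = "min"),
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(channel = channel, scheme_name = scheme$name, rows = rows,
                 excluded = excluded),
            class = "candidate_ranking")
}

#' @export
print.candidate_ranking <- function(x, n = 10, ...) {
  cat("<candidate_ranking> channel:", x$channel, "scheme:", x$scheme_name,
      "\n")
  print(utils::head(x$rows, n))
  invisible(x)
}

# Jensen-Shannon divergence, base 2, in [0, 1]; 0 log 0 := 0.
jsd2 <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Similarity of two composition profiles
#'
#' Reports two complementary metrics: the Pearson correlation of channel
#' fractions (shape agreement) and the base-2 Jensen-Shannon divergence
#' (distributional distance, 0 iff identical, 1 for disjoint support).
#' Neither is privileged; the underlying comparison in the field is visual.
#' If either vector is constant across channels the correlation is undefined
#' and reported as `NA`, with the divergence still computed.
#'
#' @param a,b [composition_vector()]s under the same scheme.
#' @return An object of class `similarity_score`: list with `pearson`, `jsd`.
#' @export
profile_similarity <- function(a, b) {
  stopifnot(inherits(a, "composition_vector"),
            inherits(b, "composition_vector"))
  if (a$scheme_name != b$scheme_name)
    stop("scheme mismatch: '", a$scheme_name, "' vs '", b$scheme_name, "'")
  p <- a$fractions; q <- b$fractions
  pear <- if (stats::sd(p) == 0 || stats::sd(q) == 0) NA_real_ else
    stats::cor(p, q)
  structure(list(pearson = pear, jsd = jsd2(p, q)),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("<similarity_score> pearson = %s, jsd = %.4g\n",
              ifelse(is.na(x$pearson), "NA", sprintf("%.4f", x$pearson)),
              x$jsd))
  invisible(x)
}

#' Estimate the mixture fraction of a candidate in a measured composition
#'
#' Models the measured hydrolysate as a two-component mixture
#' `f * candidate + (1 - f) * background` and returns the `f` in `[0, 1]`
#' minimizing the Euclidean distance to the measurement. The objective is
#' quadratic in `f`, so the minimizer is computed in closed form (the
#' unconstrained projection clamped to `[0, 1]`); the residual distance at
#' the optimum is reported. `f` is a residue-level (recovered-residue molar)
#' fraction, directly comparable to hydrolysate measurements.
#'
#' @param measured,candidate,background [composition_vector()]s under one
#'   scheme.
#' @return List with `fraction`, `residual`, and `degenerate` (`TRUE` with
#'   `fraction = NA` when candidate and background coincide, in which case
#'   `f` is unidentifiable).
#' @export
estimate_mixture_fraction <- function(measured, candidate, background) {
  for (v in list(measured, candidate, background))
    stopifnot(inherits(v, "composition_vector"))
  schemes <- c(measured$scheme_name, candidate$scheme_name,
               background$scheme_name)
  if (length(unique(schemes)) != 1L)
    stop("all three vectors must share a scheme; got ",
         paste(schemes, collapse = ", "))
  m <- measured$fractions; cnd <- candidate$fractions; bg <- background$fractions
  d <- cnd - bg
  dd <- sum(d^2)
  if (dd < 1e-20) {
    warning("candidate equals background; mixture fraction unidentifiable")
    return(list(fraction = NA_real_, residual = NA_real_, degenerate = TRUE))
  }
  f <- min(max(sum((m - bg) * d) / dd, 0), 1)
  residual <- sqrt(sum((m - (bg + f * d))^2))
  list(fraction = f, residual = residual, degenerate = FALSE)
}
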