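# Residue counting and mole-fraction composition under a hydrolysis scheme.
#
# Composition here is always residue-count (mole) based: the fraction of
# counted residues falling into each analyzer channel, after applying the
# scheme's per-residue recovery and renormalizing. Mass enters only through
# the mixture weighting modes.

#' Construct a composition vector
#'
#' @param fractions named non-negative numeric over (a subset of) the
#'   scheme's channels; missing channels are filled with 0; values are
#'   renormalized to sum to 1.
#' @param scheme the [hydrolysis_scheme()] the channels belong to.
#' @param n_residues total residues counted, or `NA` for measured tables.
#' @param raw_sum original (pre-normalization) sum, kept as metadata.
#' @return An object of class `composition_vector` with elements
#'   `scheme_name`, `fractions` (full channel set, scheme order, sums to 1),
#'   `n_residues`, `raw_sum`.
#' @export
composition_vector <- function(fractions, scheme, n_residues = NA_real_,
                               raw_sum = sum(fractions)) {
  stopifnot(inherits(scheme, "hydrolysis_scheme"))
  if (is.null(names(fractions)))
    stop("fractions must be named by channel")
  unknown <- setdiff(names(fractions), scheme$channels)
  if (length(unknown))
    stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  if (any(fractions < 0)) stop("fractions must be non-negative")
  full <- stats::setNames(rep(0, length(scheme$channels)), scheme$channels)
  full[names(fractions)] <- fractions
  tot <- sum(full)
  if (tot <= 0) stop("fractions sum to zero")
  structure(
    list(scheme_name = scheme$name, fractions = full / tot,
         n_residues = n_residues, raw_sum = raw_sum),
    class = "composition_vector"
  )
}

#' @export
print.composition_vector <- function(x, digits = 4, ...) {
  cat("<composition_vector> scheme:", x$scheme_name,
      if (!is.na(x$n_residues)) paste0("(", x$n_residues, " residues)") else
        "(measured)", "\n")
  print(round(x$fractions, digits))
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.composition_vector <- function(x, ...) {
  data.frame(channel = names(x$fractions), fraction = unname(x$fractions),
             stringsAsFactors = FALSE)
}

#' Count residues of a protein record
#'
#' Counts over the 20 canonical residues. Ambiguity handling: `U`
#' (selenocysteine) counts as `C`; `X` is excluded from counts and from the
#' length denominator; `B` and `Z` are tallied separately (they carry channel
#' information only under a pooled hydrolysate scheme) and returned in the
#' `ambiguous` attribute.
#'
#' @param record a [protein_record()].
#' @return Named integer vector over the 20 residues, with attribute
#'   `ambiguous` = counts of `B`, `Z`, `X` seen.
#' @examples
#' residue_counts(protein_record("p", "QEQE"))[c("Q", "E")]
#' @export
residue_counts <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  chars[chars == "U"] <- "C"
  tab <- table(factor(chars, levels = c(AA_ALPHABET, "B", "Z", "X")))
  counts <- stats::setNames(as.integer(tab[AA_ALPHABET]), AA_ALPHABET)
  amb <- stats::setNames(as.integer(tab[c("B", "Z", "X")]), c("B", "Z", "X"))
  attr(counts, "ambiguous") <- amb
  counts
}

# Channel totals (recovery-weighted counts) of one record under a scheme.
# B adds to Asx and Z to Glx under pooled schemes; under intact they are
# dropped with a warning since their residue identity is undetermined.
channel_totals <- function(record, scheme) {
  counts <- residue_counts(record)
  amb <- attr(counts, "ambiguous")
  totals <- stats::setNames(rep(0, length(scheme$channels)), scheme$channels)
  w <- counts * scheme$recovery[names(counts)]
  for (ch in unique(scheme$channel_map))
    totals[ch] <- sum(w[names(scheme$channel_map)[scheme$channel_map == ch]])
  if (scheme$name %in% c("hcl", "msa")) {
    totals["Asx"] <- totals["Asx"] + amb[["B"]]
    totals["Glx"] <- totals["Glx"] + amb[["Z"]]
  } else if (amb[["B"]] + amb[["Z"]] > 0) {
    warning("record '", record$id,
            "': B/Z codes dropped under the intact scheme", call. = FALSE)
  }
  totals
}

#' Composition of one protein under a hydrolysis scheme
#'
#' Channel fraction = (sum over residues mapping to the channel of
#' count x recovery) / (total recovered count). Recovery is applied before
#' normalization, modelling an analyzer that reports relative content of the
#' channels it detects.
#'
#' @param record a [protein_record()].
#' @param scheme a [hydrolysis_scheme()].
#' @return A [composition_vector()].
#' @examples
#' protein_composition(protein_record("p", "QQEE"), hydrolysis_scheme("hcl"))
#' @export
protein_composition <- function(record, scheme) {
  totals <- channel_totals(record, scheme)
  if (sum(totals) <= 0)
    stop("record '", record$id, "': no recoverable residues under scheme '",
         scheme$name, "'")
  counts <- residue_counts(record)
  amb <- attr(counts, "ambiguous")
  n <- sum(counts) + amb[["B"]] + amb[["Z"]]
  composition_vector(totals, scheme, n_residues = n)
}

#' Composition of a weighted mixture of proteins
#'
#' In `molar_chain` mode the weights are chain-molar amounts: each protein's
#' channel totals are scaled by its weight and summed before normalization,
#' so longer chains contribute proportionally more residues. In `mass` mode
#' each weight is a mass amount and is first divided by the chain's molecular
#' weight (polymer convention, [molecular_weight()] `chain` mode) to obtain
#' the chain-molar amount. The two modes agree whenever all components have
#' equal chain mass.
#'
#' @param components list of [protein_record()]s.
#' @param weights non-negative numeric, one per component, not all zero.
#' @param scheme a [hydrolysis_scheme()].
#' @param weight_mode `"molar_chain"` or `"mass"`.
#' @return A [composition_vector()]; `n_residues` is the weighted residue
#'   total (effective, may be non-integer).
#' @export
mixture_composition <- function(components, weights, scheme,
                                weight_mode = c("molar_chain", "mass")) {
  weight_mode <- match.arg(weight_mode)
  if (length(components) == 0L) stop("empty component list")
  if (length(weights) != length(components))
    stop("one weight per component required")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and not all zero")
  if (weight_mode == "mass") {
    chain_mass <- vapply(components, molecular_weight, numeric(1),
                         mode = "chain")
    weights <- weights / chain_mass
  }
  totals <- Reduce(`+`, Map(function(rec, w) w * channel_totals(rec, scheme),
                            components, weights))
  if (sum(totals) <= 0) stop("no recoverable residues in mixture")
  n_eff <- sum(vapply(seq_along(components), function(i) {
    cnt <- residue_counts(components[[i]])
    amb <- attr(cnt, "ambiguous")
    weights[i] * (sum(cnt) + amb[["B"]] + amb[["Z"]])
  }, numeric(1)))
  composition_vector(totals, scheme, n_residues = n_eff)
}

# Polyglutamine-expansion fusion construct: huntingtin exon-1 fragment
# (N-terminal 17-mer, polyQ tract, proline-rich tail) fused to EGFP.
# Reconstructed from the canonical human huntingtin exon-1 and EGFP coding
# sequences; only the tract length varies between variants.
NHTT_HEAD <- "MATLEKLMKAFESLKSF"
NHTT_PRO_TAIL <- "PPPPPPPPPPPQLPQPPPQAQPLLPQPQPPPPPPPPPPGPAVAEEPLHRP"
EGFP_BODY <- paste0(
  "VSKGEELFTGVVPILVELDGDVNGHKFSVSGEGEGDATYGKLTLKFICTTGKLPVPWPTL",
  "VTTLTYGVQCFSRYPDHMKQHDFFKSAMPEGYVQERTIFFKDDGNYKTRAEVKFEGDTLV",
  "NRIELKGIDFKEDGNILGHKLEYNYNSHNVYIMADKQKNGIKVNFKIRHNIEDGSVQLAD",
  "HYQQNTPIGDGPVLLPDNHYLSTQSALSKDPNEKRDHMVLLEFVTAAGITLGMDELYK")

#' Polyglutamine reporter construct (nHTT-EGFP)
#'
#' Builds the positive-control fusion protein used to validate hydrolysate
#' composition analysis: the N-terminal huntingtin exon-1 fragment with a
#' polyglutamine tract of the requested length, fused to EGFP. All non-tract
#' sequence is identical between any two tract lengths, so composition
#' differences are attributable to the tract alone. The expanded disease
#' variant carries a 190-residue tract; the normal-repeat control carries 21.
#'
#' @param polyQ_length tract length in glutamines (positive integer).
#' @return A [protein_record()] with id `nHTT-EGFP_<n>Q`.
#' @examples
#' nchar(construct_nhtt_egfp(190)$sequence) -
#'   nchar(construct_nhtt_egfp(21)$sequence)  # 169
#' @export
construct_nhtt_egfp <- function(polyQ_length) {
  polyQ_length <- as.integer(polyQ_length)
  if (is.na(polyQ_length) || polyQ_length < 1L)
    stop("polyQ_length must be a positive integer")
  protein_record(
    id = sprintf("nHTT-EGFP_%dQ", polyQ_length),
    sequence = paste0(NHTT_HEAD, strrep("Q", polyQ_length), NHTT_PRO_TAIL,
                      EGFP_BODY),
    description = sprintf(
      "huntingtin exon-1 fragment with %dQ tract fused to EGFP", polyQ_length)
  )
}
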