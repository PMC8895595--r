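# Hydrolysis chemistries and residue-level constants.

#' @keywords internal
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @keywords internal
AMBIGUITY_CODES <- c("B", "Z", "X", "U")

# One-letter -> three-letter channel label for intact chains.
#' @keywords internal
AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

# Stable channel orders for tables and plots (analyzer elution-like order).
#' @keywords internal
HYDROLYSATE_CHANNELS <- c("Asx", "Thr", "Ser", "Glx", "Pro", "Gly", "Ala",
                          "Cys", "Val", "Met", "Ile", "Leu", "Tyr", "Phe",
                          "His", "Lys", "Arg", "Trp")

#' @keywords internal
INTACT_CHANNELS <- c("Asp", "Asn", "Thr", "Ser", "Glu", "Gln", "Pro", "Gly",
                     "Ala", "Cys", "Val", "Met", "Ile", "Leu", "Tyr", "Phe",
                     "His", "Lys", "Arg", "Trp")

# Elemental formulas of the free amino acids (counts of C, H, N, O, S, Se).
# Chain (residue) masses are free masses minus one water.
#' @keywords internal
AA_FORMULA <- list(
  A = c(C = 3,  H = 7,  N = 1, O = 2, S = 0, Se = 0),
  R = c(C = 6,  H = 14, N = 4, O = 2, S = 0, Se = 0),
  N = c(C = 4,  H = 8,  N = 2, O = 3, S = 0, Se = 0),
  D = c(C = 4,  H = 7,  N = 1, O = 4, S = 0, Se = 0),
  C = c(C = 3,  H = 7,  N = 1, O = 2, S = 1, Se = 0),
  Q = c(C = 5,  H = 10, N = 2, O = 3, S = 0, Se = 0),
  E = c(C = 5,  H = 9,  N = 1, O = 4, S = 0, Se = 0),
  G = c(C = 2,  H = 5,  N = 1, O = 2, S = 0, Se = 0),
  H = c(C = 6,  H = 9,  N = 3, O = 2, S = 0, Se = 0),
  I = c(C = 6,  H = 13, N = 1, O = 2, S = 0, Se = 0),
  L = c(C = 6,  H = 13, N = 1, O = 2, S = 0, Se = 0),
  K = c(C = 6,  H = 14, N = 2, O = 2, S = 0, Se = 0),
  M = c(C = 5,  H = 11, N = 1, O = 2, S = 1, Se = 0),
  F = c(C = 9,  H = 11, N = 1, O = 2, S = 0, Se = 0),
  P = c(C = 5,  H = 9,  N = 1, O = 2, S = 0, Se = 0),
  S = c(C = 3,  H = 7,  N = 1, O = 3, S = 0, Se = 0),
  T = c(C = 4,  H = 9,  N = 1, O = 3, S = 0, Se = 0),
  W = c(C = 11, H = 12, N = 2, O = 2, S = 0, Se = 0),
  Y = c(C = 9,  H = 11, N = 1, O = 3, S = 0, Se = 0),
  V = c(C = 5,  H = 11, N = 1, O = 2, S = 0, Se = 0),
  U = c(C = 3,  H = 7,  N = 1, O = 2, S = 0, Se = 1)
)

# IUPAC 2021 standard atomic weights.
#' @keywords internal
ATOMIC_WEIGHT <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                   S = 32.06, Se = 78.971)

#' @keywords internal
WATER_MASS <- 2 * ATOMIC_WEIGHT[["H"]] + ATOMIC_WEIGHT[["O"]]

#' Build a hydrolysis scheme
#'
#' A hydrolysis scheme describes how an amino-acid analyzer sees a protein
#' chain after hydrolysis: which residues are pooled into a shared detection
#' channel, and what fraction of each residue survives the chemistry.
#'
#' Three chemistries are supported:
#' \describe{
#'   \item{`intact`}{No hydrolysis model: every residue is its own channel and
#'     all recoveries are 1. Used for in-silico composition of sequences.}
#'   \item{`hcl`}{6 M hydrochloric-acid hydrolysis. Gln and Glu are pooled
#'     into the `Glx` channel and Asn and Asp into `Asx` (deamidation during
#'     hydrolysis); tryptophan is destroyed (recovery 0).}
#'   \item{`msa`}{4 N methanesulfonic-acid hydrolysis. Same Asx/Glx pooling,
#'     but tryptophan is preserved (recovery 1).}
#' }
#'
#' Cysteine recovery defaults to 1 under both hydrolysate chemistries but can
#' be lowered via `recovery`, since acid hydrolysis degrades cysteine in
#' practice.
#'
#' @param name one of `"intact"`, `"hcl"`, `"msa"`.
#' @param recovery optional named numeric vector of per-residue recovery
#'   overrides in `[0, 1]`, e.g. `c(C = 0.5)`. Overrides that contradict the
#'   chemistry itself (`W` under `hcl`) are rejected.
#' @return An object of class `hydrolysis_scheme`: a list with elements
#'   `name`, `channel_map` (named character, residue to channel),
#'   `recovery` (named numeric) and `channels` (ordered channel labels).
#' @examples
#' sch <- hydrolysis_scheme("hcl")
#' sch$channel_map[["Q"]]  # "Glx"
#' sch$recovery[["W"]]     # 0
#' @export
hydrolysis_scheme <- function(name = c("intact", "hcl", "msa"),
                              recovery = NULL) {
  name <- match.arg(name)
  if (name == "intact") {
    channel_map <- AA_THREE
    channels <- INTACT_CHANNELS
    rec <- stats::setNames(rep(1, 20), AA_ALPHABET)
  } else {
    channel_map <- AA_THREE
    channel_map[c("Q", "E")] <- "Glx"
    channel_map[c("N", "D")] <- "Asx"
    channels <- HYDROLYSATE_CHANNELS
    rec <- stats::setNames(rep(1, 20), AA_ALPHABET)
    if (name == "hcl") rec[["W"]] <- 0
  }
  if (!is.null(recovery)) {
    if (is.null(names(recovery)) || !all(names(recovery) %in% AA_ALPHABET))
      stop("recovery overrides must be named by one-letter residue codes")
    if (any(recovery < 0 | recovery > 1))
      stop("recovery values must lie in [0, 1]")
    if (name == "hcl" && "W" %in% names(recovery) && recovery[["W"]] != 0)
      stop("tryptophan recovery under HCl hydrolysis is fixed at 0")
    rec[names(recovery)] <- recovery
  }
  structure(
    list(name = name, channel_map = channel_map, recovery = rec,
         channels = channels),
    class = "hydrolysis_scheme"
  )
}

#' @export
print.hydrolysis_scheme <- function(x, ...) {
  cat("<hydrolysis_scheme>", x$name, "\n")
  cat("  channels:", paste(x$channels, collapse = " "), "\n")
  lost <- names(x$recovery)[x$recovery < 1]
  if (length(lost))
    cat("  reduced recovery:",
        paste(sprintf("%s=%.2g", lost, x$recovery[lost]), collapse = " "), "\n")
  invisible(x)
}

#' Residues feeding a detection channel
#'
#' Inverts a scheme's residue-to-channel map.
#'
#' @param scheme a [hydrolysis_scheme()].
#' @param channel a channel label from `scheme$channels`.
#' @return Character vector of one-letter residue codes pooled into `channel`.
#' @examples
#' channel_residues(hydrolysis_scheme("msa"), "Glx")  # "Q" "E"
#' @export
channel_residues <- function(scheme, channel) {
  stopifnot(inherits(scheme, "hydrolysis_scheme"))
  if (!channel %in% scheme$channels)
    stop("unknown channel '", channel, "'; allowed: ",
         paste(scheme$channels, collapse = ", "))
  names(scheme$channel_map)[scheme$channel_map == channel]
}

#' Molecular weight of a residue or protein chain
#'
#' Masses are computed from elemental composition with standard atomic
#' weights, never stored as literals. `free` mode gives the molecular weight
#' of the free amino acid; `chain` mode gives the polymer mass: the sum of
#' residue masses (free mass minus one water per peptide bond formed) plus
#' one water for the chain termini.
#'
#' @param x a one-letter residue code, a plain sequence string, or a
#'   [protein_record()].
#' @param mode `"free"` (single residue only) or `"chain"`.
#' @return Mass in g/mol.
#' @examples
#' molecular_weight("E", "free")   # 147.13
#' molecular_weight("GG", "chain")
#' @export
molecular_weight <- function(x, mode = c("free", "chain")) {
  mode <- match.arg(mode)
  seq <- if (inherits(x, "protein_record")) x$sequence else as.character(x)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(AA_FORMULA))
  if (length(bad))
    stop("no defined mass for code(s): ", paste(unique(bad), collapse = ", "))
  free <- vapply(chars, function(ch) sum(AA_FORMULA[[ch]] * ATOMIC_WEIGHT),
                 numeric(1))
  if (mode == "free") {
    if (length(chars) != 1L)
      stop("mode 'free' applies to a single residue")
    return(unname(free))
  }
  sum(free - WATER_MASS) + WATER_MASS
}
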