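#' @importFrom data.table data.table as.data.table setorder setnames :=
#' @importFrom data.table copy rbindlist fwrite fread setattr setorderv
#' @importFrom stats quantile rbinom rpois runif setNames pbinom dhyper
#'   fisher.test chisq.test wilcox.test cor.test sd dnorm
#' @importFrom utils head read.delim write.table
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "alt", "alt_n", "avg", "base", "category", "cds_label",
  "clusters", "codon", "codon_pos", "consequence", "cosmic_cases", "count",
  "donor", "family", "frac", "local_index", "maxpf", "missing_piece",
  "mutant_families", "mutation_type", "ns_cases", "piece", "piece_id", "ref",
  "region", "rep_id", "site_label", "size", "slice", "testis",
  "total_families", "uid", "J", "N", "i.alt_n", "keep", "n_alt", "true_frac",
  "activity", "experiment", "score", "frac_sig", "med_avg", "med_maxpf",
  "any_sig", "barcode"
))

DNA_BASES <- c("A", "C", "G", "T")

#' Classify a base substitution into one of the six strand-collapsed types
#'
#' Substitution types are reported jointly with their reverse complement
#' (e.g. a G>A change on the sequenced strand is the same molecular event as a
#' C>T change on the other strand). The two damage-prone classes, `C>T/G>A`
#' (deamination) and `G>T/C>A` (oxidation), carry an elevated assay background.
#'
#' @param ref,alt Character vectors of single bases in `A/C/G/T`.
#' @return Character vector of type labels, one of
#'   `"C>T/G>A"`, `"G>T/C>A"`, `"A>G/T>C"`, `"A>C/T>G"`, `"A>T/T>A"`,
#'   `"C>G/G>C"`.
#' @examples
#' substitution_type("G", "A")  # deamination class
#' substitution_type("A", "G")  # ordinary transition class
#' @export
substitution_type <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  if (!all(ref %in% DNA_BASES) || !all(alt %in% DNA_BASES))
    stop("ref and alt must be single bases in A/C/G/T")
  if (any(ref == alt)) stop("alt must differ from ref")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # collapse onto the pyrimidine-reference representative
  r <- ref; a <- alt
  flip <- r %in% c("A", "G")
  r[flip] <- comp[r[flip]]
  a[flip] <- comp[a[flip]]
  key <- paste0(r, ">", a)
  map <- c("C>T" = "C>T/G>A", "C>A" = "G>T/C>A", "T>C" = "A>G/T>C",
           "T>G" = "A>C/T>G", "T>A" = "A>T/T>A", "C>G" = "C>G/G>C")
  unname(map[key])
}

#' Default per-type assay background rates
#'
#' Background (false-positive) rates of the error-corrected sequencing assay
#' per UID family per site, by substitution type: 3.3e-6 for the four ordinary
#' types and 5.5x that (~1.8e-5) for the two damage-prone types, the midpoint
#' of the reported 5-6x elevation for `C>T/G>A` and `G>T/C>A`.
#'
#' @return Named numeric vector over the six substitution-type labels.
#' @export
default_background_rates <- function() {
  base <- 3.3e-6
  c("C>T/G>A" = 5.5 * base, "G>T/C>A" = 5.5 * base,
    "A>G/T>C" = base, "A>C/T>G" = base, "A>T/T>A" = base, "C>G/G>C" = base)
}

# transition test for Ti/Tv bookkeeping
is_transition <- function(ref, alt) {
  pur <- c("A", "G")
  (ref %in% pur) == (alt %in% pur)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# standard genetic code, indexed by codon string
codon_table <- function() {
  b <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
  setNames(aa, codons)
}
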