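## Residue alphabets and small shared helpers.

.aminoAcids3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                  "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                  "Thr", "Trp", "Tyr", "Val")
.aminoAcids1 <- c("A", "R", "N", "D", "C", "Q", "E", "G",
                  "H", "I", "L", "K", "M", "F", "P", "S",
                  "T", "W", "Y", "V")

.one2three <- stats::setNames(.aminoAcids3, .aminoAcids1)
.three2one <- stats::setNames(.aminoAcids1, .aminoAcids3)

#' Convert between residue letter codes
#'
#' Bijective between the one- and three-letter amino-acid alphabets, with
#' `*` mapping to and from `Ter`; the legacy `X` stop symbol converts to
#' `Ter` one-way.
#'
#' @param code residue code(s).
#' @param to `"three"` or `"one"`.
#' @return converted code(s).
#' @examples
#' residueConvert("G")            # "Gly"
#' residueConvert("*")            # "Ter"
#' residueConvert("Gly", "one")   # "G"
#' @export
residueConvert <- function(code, to = c("three", "one")) {
  to <- match.arg(to)
  vapply(as.character(code), function(x) {
    if (to == "three") {
      if (x %in% c("*", "X")) return("Ter")
      if (x %in% .aminoAcids1) return(unname(.one2three[x]))
      if (x %in% c(.aminoAcids3, "Ter")) return(x)
    } else {
      if (x == "Ter" || x %in% c("*", "X")) return("*")
      if (x %in% .aminoAcids3) return(unname(.three2one[x]))
      if (x %in% .aminoAcids1) return(x)
    }
    stop("unknown residue code: ", x)
  }, character(1L), USE.NAMES = FALSE)
}

## Case-normalize a possibly lower/upper-cased three-letter residue.
.normResidue3 <- function(x) {
  y <- paste0(toupper(substr(x, 1L, 1L)), tolower(substr(x, 2L, 3L)))
  ifelse(toupper(x) == "TER", "Ter", y)
}

.isBases <- function(x) grepl("^[ACGTN]+$", x)

.revComp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

.translateNt <- function(nt) {
  ## character protein string with '*' for stops; tolerates trailing partial
  ## codon (dropped)
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(nt, 1L, n)),
                                     no.init.codon = TRUE))
}

## Deterministic 31-bit sub-seed from a base seed and record index.
.subSeed <- function(seed, i) {
  s <- (as.numeric(seed) * 1103515245 + 12345 * as.numeric(i)) %% 2147483647
  as.integer(s)
}

## Condition used when a position falls outside the modeled transcript locus;
## callers downstream turn it into a "not assessed" verdict.
.outOfTranscript <- function(msg) {
  structure(class = c("outOfTranscript", "error", "condition"),
            list(message = msg, call = NULL))
}
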