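#' @import data.table
#' @importFrom stats runif rgamma dhyper p.adjust pbinom t.test ks.test sd
#' @importFrom utils head tail
NULL

BASES <- c("A", "C", "G", "T")
GENOMES <- c("A", "B", "D")
PAIRS <- c("AB", "AD", "BD")
PATTERNS <- c("tri", "uni_A", "uni_B", "uni_D",
              "bi_AB", "bi_AD", "bi_BD", "intermediate", "unmethylated")
CONTEXTS <- c("CpG", "CHG", "CHH")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(b) chartr("ACGTN", "TGCAN", b)

## split a DNAStringSet / character vector of sequences into a list of
## per-base character vectors
seq_chars <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
}

## deterministic per-stage seed derivation; keeps results < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% .Machine$integer.max
}

## format numbers for TSV output: 4 significant digits, "." for NA
fmt_num <- function(x) {
  out <- ifelse(is.na(x), ".", formatC(signif(x, 4), format = "g", digits = 4))
  sub("^\\s+", "", out)
}

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("polymethyl_input_error", "error")))
}
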