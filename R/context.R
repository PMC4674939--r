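## Cytosine context classification and site-call extraction.
##
## Contexts are always classified from the reference, never from the read:
## bisulfite conversion corrupts read-side context. Internally every
## coordinate is 0-based; SAM/TSV input is converted once on ingest.

CONTEXT_SYMBOL <- c(CpG = "Z", CHG = "X", CHH = "H", unknown = "U")

## Per-contig context maps: character vectors of length L with the context
## at cytosine positions of each strand (NA elsewhere).
context_maps <- function(chars) {
  L <- length(chars)
  n1 <- c(chars[-1], NA)
  n2 <- if (L > 2) c(chars[-(1:2)], NA, NA) else rep(NA_character_, L)
  valid <- function(x) !is.na(x) & x %in% BASES
  plus <- rep(NA_character_, L)
  isC <- chars == "C"
  known <- valid(n1) & valid(n2)
  plus[isC & known & n1 == "G"] <- "CpG"
  plus[isC & known & n1 != "G" & n2 == "G"] <- "CHG"
  plus[isC & known & n1 != "G" & n2 != "G"] <- "CHH"
  plus[isC & !known] <- "unknown"
  m1 <- c(NA, chars[-L])
  m2 <- if (L > 2) c(NA, NA, chars[-((L - 1):L)]) else rep(NA_character_, L)
  minus <- rep(NA_character_, L)
  isG <- chars == "G"
  knownm <- valid(m1) & valid(m2)
  ## on the minus strand the downstream neighbours (5'->3') are the
  ## complements of the plus-strand bases at pos-1 and pos-2
  minus[isG & knownm & m1 == "C"] <- "CpG"
  minus[isG & knownm & m1 != "C" & m2 == "C"] <- "CHG"
  minus[isG & knownm & m1 != "C" & m2 != "C"] <- "CHH"
  minus[isG & !knownm] <- "unknown"
  list(plus = plus, minus = minus)
}

#' Classify the sequence context of a cytosine
#'
#' Determines whether a cytosine lies in CpG, CHG or CHH context (H being
#' adenine, cytosine or thymine), reading the two downstream bases on the
#' cytosine's own strand. For a minus-strand cytosine (a plus-strand G) the
#' downstream neighbours are the reverse-complemented plus-strand bases
#' immediately upstream. Positions with fewer than two defined downstream
#' bases are \code{"unknown"}.
#'
#' @param sequence a single reference sequence (character or
#'   \code{Biostrings::DNAString}).
#' @param pos 0-based position(s) of the queried cytosine on the plus
#'   strand.
#' @param strand \code{"+"} or \code{"-"} (recycled).
#' @return character vector over \code{c("CpG","CHG","CHH","unknown")}.
#' @examples
#' classify_context("ACGA", 1, "+")  # CpG
#' classify_context("ACAG", 1, "+")  # CHG
#' classify_context("ACGA", 2, "-")  # minus-strand C under the G
#' @export
classify_context <- function(sequence, pos, strand = "+") {
  if (methods::is(sequence, "XString")) sequence <- as.character(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- max(length(pos), length(strand))
  pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(strand, n)
  if (any(pos < 0L | pos >= length(chars)))
    stop_input("position out of sequence bounds")
  base <- chars[pos + 1L]
  bad <- (strand == "+" & base != "C") | (strand == "-" & base != "G")
  if (any(bad))
    stop_input("no cytosine on strand '%s' at 0-based position %d",
               strand[which(bad)[1]], pos[which(bad)[1]])
  maps <- context_maps(chars)
  out <- ifelse(strand == "+", maps$plus[pos + 1L], maps$minus[pos + 1L])
  out[is.na(out)] <- "unknown"
  out
}

#' Enumerate cytosine sites of a reference
#'
#' Lists every cytosine on both strands of each contig with its context.
#'
#' @param reference named \code{DNAStringSet} (or named character vector).
#' @param keep_unknown keep sites whose context cannot be determined
#'   (sequence edges, ambiguous bases). Default drops them, as only the
#'   three canonical contexts are analysed.
#' @return \code{data.table} with columns \code{contig}, \code{pos}
#'   (0-based), \code{strand}, \code{context}.
#' @export
cytosine_sites <- function(reference, keep_unknown = FALSE) {
  chars <- seq_chars(reference)
  out <- lapply(names(chars), function(ct) {
    maps <- context_maps(chars[[ct]])
    pp <- which(!is.na(maps$plus)); mp <- which(!is.na(maps$minus))
    data.table(contig = ct,
               pos = c(pp, mp) - 1L,
               strand = rep(c("+", "-"), c(length(pp), length(mp))),
               context = c(maps$plus[pp], maps$minus[mp]))
  })
  out <- rbindlist(out)
  if (!keep_unknown) out <- out[context != "unknown"]
  setkey(out, contig, pos, strand)
  out[]
}

#' Extract per-site methylation observations from aligned reads
#'
#' Walks the methylation call string (XM dialect: \code{Z/z} CpG, \code{X/x}
#' CHG, \code{H/h} CHH, \code{U/u} unknown, \code{.} non-cytosine; uppercase
#' = methylated) of each read and emits one observation per read x cytosine
#' overlap. The strand of an observation follows the read's
#' conversion-strand tag: \code{CT} reads report plus-strand cytosines,
#' \code{GA} reads minus-strand cytosines. Each observation's symbol is
#' validated against the reference context at that position; mismatching
#' observations (typically reads spanning a genome-specific cytosine that
#' the shared reference does not carry) are dropped and counted, as are
#' unknown-context observations.
#'
#' @param reads \code{data.table} of validated reads as returned by
#'   \code{\link{read_bisulfite_sam}} or \code{\link{simulate_reads}}.
#' @param reference named \code{DNAStringSet}.
#' @return \code{data.table} with columns \code{contig}, \code{pos},
#'   \code{strand}, \code{context}, \code{qname}, \code{mapq},
#'   \code{methylated}; attribute \code{"dropped"} counts dropped
#'   observations by reason.
#' @export
extract_site_calls <- function(reads, reference) {
  stopifnot(is.data.frame(reads))
  reads <- as.data.table(reads)
  if (nrow(reads) == 0L) {
    out <- data.table(contig = character(), pos = integer(),
                      strand = character(), context = character(),
                      qname = character(), mapq = integer(),
                      methylated = logical())
    setattr(out, "dropped", c(context_mismatch = 0L, unknown_context = 0L))
    return(out)
  }
  xs <- strsplit(reads$xm, "", fixed = TRUE)
  lens <- lengths(xs)
  sym <- unlist(xs, use.names = FALSE)
  keep <- sym != "."
  idx <- rep(seq_len(nrow(reads)), lens)[keep]
  off <- (sequence(lens) - 1L)[keep]
  sym <- sym[keep]
  obs <- data.table(contig = reads$contig[idx],
                    pos = reads$pos[idx] + off,
                    strand = ifelse(reads$xg[idx] == "CT", "+", "-"),
                    qname = reads$qname[idx],
                    mapq = reads$mapq[idx],
                    sym = sym)
  ## reference context at each observation
  chars <- seq_chars(reference)
  maps <- lapply(chars, context_maps)
  obs[, context := {
    m <- maps[[contig[1]]]
    ifelse(strand == "+", m$plus[pos + 1L], m$minus[pos + 1L])
  }, by = contig]
  expected <- CONTEXT_SYMBOL[obs$context]
  ok <- !is.na(expected) & toupper(obs$sym) == expected
  unknown <- ok & obs$context == "unknown"
  dropped <- c(context_mismatch = sum(!ok),
               unknown_context = sum(unknown))
  obs <- obs[ok & !unknown]
  obs[, methylated := sym == toupper(sym)]
  obs[, sym := NULL]
  setcolorder(obs, c("contig", "pos", "strand", "context", "qname", "mapq",
                     "methylated"))
  setattr(obs, "dropped", dropped)
  obs[]
}

#' Estimate the bisulfite conversion rate from an unmethylated control
#'
#' The control contig carries no methylation, so every cytosine observation
#' on it should read as converted (thymine on the CT strand). The
#' conversion rate is the percentage of converted observations among all
#' reference-cytosine observations on the control.
#'
#' @param reads read table including control-contig alignments.
#' @param reference named \code{DNAStringSet} including the control contig.
#' @param control_contig name of the control contig.
#' @return percentage in \[0, 100\], with attribute \code{"n"} (number of
#'   observations); \code{NA} with a warning when there are none.
#' @export
estimate_conversion_rate <- function(reads, reference,
                                     control_contig = "control") {
  reads <- as.data.table(reads)[contig == control_contig]
  calls <- extract_site_calls(reads, reference)
  if (nrow(calls) == 0L) {
    warning("no cytosine observations on control contig '", control_contig,
            "'; conversion rate undefined")
    return(structure(NA_real_, n = 0L))
  }
  structure(100 * mean(!calls$methylated), n = nrow(calls))
}
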