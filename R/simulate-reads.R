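#' Simulate bisulfite-converted reads with methylation call strings
#'
#' Emits single-end reads of fixed length from each sub-genome's true
#' sequence at uniformly drawn positions, reported in shared-reference
#' coordinates (alignment itself is out of scope, so reads are born
#' aligned; a mapping quality is still attached so quality filters are
#' exercisable). Each read belongs to one of the four bisulfite strand
#' products; products derived from the original top strand (OT, CTOT) carry
#' conversion-strand tag \code{CT} and read out plus-strand cytosines
#' (methylated stays \code{C}, unmethylated converts to \code{T} with
#' probability \code{conversion_rate}), while OB/CTOB carry \code{GA} and
#' read out minus-strand cytosines (\code{G} methylated, \code{A}
#' converted). Sequencing errors are applied after conversion, and the
#' methylation string is derived from the final base, so a conversion
#' failure shows up as a spurious methylated call exactly as it does in
#' real extractor output. Control-contig reads are generated with zero
#' methylation.
#'
#' @param ref a \code{\link{simulate_references}} result.
#' @param truth truth table from \code{\link{simulate_methylation_truth}}.
#' @param config the same \code{\link{sim_config}}.
#' @return \code{data.table} with columns \code{qname}, \code{genome}
#'   (truth label, not used by the pipeline), \code{contig}, \code{pos}
#'   (0-based leftmost), \code{mapq}, \code{strand_origin}, \code{xg},
#'   \code{seq}, \code{xm}.
#' @export
simulate_reads <- function(ref, truth, config) {
  stopifnot(inherits(ref, "sim_reference"), inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 3L))
  rl <- config$read_length
  if (config$depth == 0) {
    warning("depth = 0: no reads simulated")
    return(empty_reads())
  }

  truth <- as.data.table(truth)
  batches <- list()
  sources <- c(GENOMES, "control")
  for (g in sources) {
    seqs <- if (g == "control") {
      ref$reference[ref$control_contig]
    } else ref$genomes[[g]]
    chars_all <- seq_chars(seqs)
    for (ct in names(chars_all)) {
      chars <- chars_all[[ct]]
      L <- length(chars)
      if (L < rl) next
      if (config$paired && L >= config$insert_mean + 3 * config$insert_sd) {
        ## paired-end fragments: both mates carry the same fragment name
        ## and conversion strand, so SNP evidence combines across the
        ## insert during read assignment
        nf <- max(1L, as.integer(round(
          config$depth * (L - config$insert_mean + 1) / (2 * rl))))
        ins <- pmin(L, pmax(2L * rl + 10L, as.integer(round(
          stats::rnorm(nf, config$insert_mean, config$insert_sd)))))
        fs <- floor(runif(nf) * (L - ins + 1))
        starts <- c(fs, fs + ins - rl)
        mate <- rep(1:2, each = nf)
        fid <- rep(seq_len(nf), 2L)
        n <- 2L * nf
      } else {
        n <- max(1L, as.integer(round(config$depth * (L - rl + 1) / rl)))
        starts <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
        mate <- rep(0L, n)
        fid <- seq_len(n)
        nf <- n
      }
      ## per-position methylation probabilities for this genome
      pplus <- pminus <- numeric(L)
      if (g != "control") {
        tt <- truth[contig == ct]
        pp <- tt[strand == "+"]; mm <- tt[strand == "-"]
        pplus[pp$pos + 1L] <- pp[[paste0("p_", g)]]
        pminus[mm$pos + 1L] <- mm[[paste0("p_", g)]]
      }
      gmaps <- context_maps(chars)
      symplus <- unname(CONTEXT_SYMBOL[gmaps$plus])
      symminus <- unname(CONTEXT_SYMBOL[gmaps$minus])

      fCT <- runif(nf) < 0.5
      so_f <- ifelse(fCT, "OT", "OB")
      if (!config$directional) {
        compl <- runif(nf) < 0.5
        so_f[fCT & compl] <- "CTOT"
        so_f[!fCT & compl] <- "CTOB"
      }
      isCT <- fCT[fid]
      strand_origin <- so_f[fid]

      M <- outer(starts, seq_len(rl), "+")      # R (1-based) indices
      B <- matrix(chars[M], n, rl)
      ctm <- matrix(isCT, n, rl)
      ## original cytosine positions of the informative strand
      cmask <- B == "C" & ctm
      gmask <- B == "G" & !ctm
      P <- matrix(0, n, rl)
      P[cmask] <- pplus[M[cmask]]
      P[gmask] <- pminus[M[gmask]]
      meth <- (cmask | gmask) & matrix(runif(n * rl), n, rl) < P
      conv <- (cmask | gmask) & !meth &
        matrix(runif(n * rl), n, rl) < config$conversion_rate
      B[cmask & conv] <- "T"
      B[gmask & conv] <- "A"
      if (config$error_rate > 0) {
        err <- which(matrix(runif(n * rl), n, rl) < config$error_rate)
        if (length(err))
          B[err] <- vapply(B[err],
                           function(b) sample(setdiff(BASES, b), 1L),
                           character(1))
      }
      X <- matrix(".", n, rl)
      symC <- matrix(symplus[M], n, rl)
      symG <- matrix(symminus[M], n, rl)
      up <- cmask & B == "C"; lo <- cmask & B == "T"
      X[up] <- symC[up]; X[lo] <- tolower(symC[lo])
      up <- gmask & B == "G"; lo <- gmask & B == "A"
      X[up] <- symG[up]; X[lo] <- tolower(symG[lo])

      batches[[paste(g, ct)]] <- data.table(
        qname = sprintf("%s_%s_%06d", g, ct, fid),
        genome = g, contig = ct, pos = starts, mate = mate,
        mapq = config$mapq, strand_origin = strand_origin,
        xg = ifelse(isCT, "CT", "GA"),
        seq = do.call(paste0, lapply(seq_len(rl), function(j) B[, j])),
        xm = do.call(paste0, lapply(seq_len(rl), function(j) X[, j])))
    }
  }
  out <- rbindlist(batches)
  if (nrow(out) == 0L) return(empty_reads())
  setkey(out, contig, pos, qname)
  out[]
}

empty_reads <- function() {
  data.table(qname = character(), genome = character(), contig = character(),
             pos = integer(), mate = integer(), mapq = integer(),
             strand_origin = character(), xg = character(),
             seq = character(), xm = character())
}
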