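## Readers and writers for the external formats the pipeline touches.
##
## Conventions: every ingested coordinate is converted exactly once
## (SAM/TSV 1-based -> internal 0-based half-open; BED stays 0-based
## half-open); writers are deterministic (stable ordering, 4 significant
## digits for floats, "." for missing values).

XM_ALPHABET <- c("Z", "z", "X", "x", "H", "h", "U", "u", ".")

#' Read a reference FASTA
#' @param path FASTA file.
#' @return named \code{DNAStringSet}.
#' @export
read_reference_fasta <- function(path) {
  if (!file.exists(path)) stop_input("FASTA file '%s' does not exist", path)
  Biostrings::readDNAStringSet(path)
}

#' Write a reference FASTA
#' @param seqs named \code{DNAStringSet} (or named character vector).
#' @param path output file.
#' @export
write_reference_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet"))
    seqs <- Biostrings::DNAStringSet(unlist(as.list(seqs)))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write bisulfite alignments as SAM
#'
#' Emits a minimal SAM 1.6 file: \code{@SQ} header lines from the
#' reference, one line per read with the methylation string in tag
#' \code{XM}, the conversion strand in tag \code{XG} (\code{CT}/\code{GA}),
#' the bisulfite strand product in tag \code{XO} and, when present, the
#' true genome of origin in tag \code{XT}. Records are written sorted by
#' contig, position and read name so output is deterministic.
#'
#' @param reads read table (\code{\link{simulate_reads}} format).
#' @param path output SAM path.
#' @param reference named \code{DNAStringSet} used for the header.
#' @export
write_bisulfite_sam <- function(reads, path, reference) {
  reads <- as.data.table(reads)
  setorder(reads, contig, pos, qname)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                      Biostrings::width(reference)))
  flag <- ifelse(reads$xg == "GA", 16L, 0L)
  tags <- sprintf("XM:Z:%s\tXG:Z:%s\tXO:Z:%s", reads$xm, reads$xg,
                  reads$strand_origin)
  if ("genome" %in% names(reads))
    tags <- paste0(tags, sprintf("\tXT:Z:%s", reads$genome))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*\t%s",
                   reads$qname, flag, reads$contig, reads$pos + 1L,
                   reads$mapq, nchar(reads$seq), reads$seq, tags)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read bisulfite alignments from SAM
#'
#' Parses a SAM file of bisulfite alignments carrying the extractor's
#' methylation string. Structural validation is per record: records with a
#' missing \code{XM} tag, an \code{XM} length differing from the sequence
#' length, symbols outside \code{Z/z/X/x/H/h/U/u/.}, an invalid or missing
#' \code{XG} tag, an unknown contig or an out-of-bounds span are skipped
#' and counted by reason (attribute \code{"skipped"}); per-position
#' agreement of symbols with the reference context is enforced later, at
#' \code{\link{extract_site_calls}}. A file without \code{@SQ} header lines
#' is rejected outright.
#'
#' @param path SAM file.
#' @param reference named \code{DNAStringSet}; contigs and bounds are
#'   validated against it.
#' @return \code{data.table} with columns \code{qname}, \code{contig},
#'   \code{pos} (converted to 0-based), \code{mapq}, \code{strand_origin},
#'   \code{xg}, \code{seq}, \code{xm} and, if present in the file,
#'   \code{genome}.
#' @export
read_bisulfite_sam <- function(path, reference) {
  if (!file.exists(path)) stop_input("SAM file '%s' does not exist", path)
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  if (!any(grepl("^@SQ\t", lines[hdr])))
    stop_input("malformed SAM header in '%s': no @SQ lines", path)
  body <- lines[!hdr]
  skipped <- c(missing_xm = 0L, xm_length_mismatch = 0L, bad_symbol = 0L,
               bad_xg = 0L, unknown_contig = 0L, out_of_bounds = 0L,
               malformed = 0L)
  if (length(body) == 0L) {
    out <- empty_reads(); out[, c("genome", "mate") := NULL]
    setattr(out, "skipped", skipped)
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf < 11L
  skipped["malformed"] <- sum(bad)
  fields <- fields[!bad]
  get_tag <- function(f, tag) {
    opt <- f[-(1:11)]
    hit <- opt[startsWith(opt, paste0(tag, ":Z:"))]
    if (length(hit)) substring(hit[1], 6L) else NA_character_
  }
  dt <- data.table(
    qname = vapply(fields, `[`, "", 1L),
    contig = vapply(fields, `[`, "", 3L),
    pos = as.integer(vapply(fields, `[`, "", 4L)) - 1L,
    mapq = as.integer(vapply(fields, `[`, "", 5L)),
    seq = vapply(fields, `[`, "", 10L),
    xm = vapply(fields, get_tag, "", "XM"),
    xg = vapply(fields, get_tag, "", "XG"),
    strand_origin = vapply(fields, get_tag, "", "XO"),
    genome = vapply(fields, get_tag, "", "XT"))
  reflen <- stats::setNames(Biostrings::width(reference), names(reference))
  drop <- rep(FALSE, nrow(dt))
  mark <- function(cond, reason) {
    cond <- cond & !drop
    skipped[reason] <<- skipped[reason] + sum(cond)
    drop <<- drop | cond
  }
  mark(is.na(dt$xm), "missing_xm")
  mark(!is.na(dt$xm) & nchar(dt$xm) != nchar(dt$seq), "xm_length_mismatch")
  okset <- !is.na(dt$xm) &
    vapply(strsplit(dt$xm, "", fixed = TRUE),
           function(s) all(s %in% XM_ALPHABET), logical(1))
  mark(!okset, "bad_symbol")
  mark(is.na(dt$xg) | !dt$xg %in% c("CT", "GA"), "bad_xg")
  mark(!dt$contig %in% names(reference), "unknown_contig")
  inb <- !drop & dt$pos >= 0L & dt$pos + nchar(dt$seq) <= reflen[dt$contig]
  mark(!inb, "out_of_bounds")
  out <- dt[!drop]
  out[is.na(strand_origin),
      strand_origin := ifelse(xg == "CT", "OT", "OB")]
  if (all(is.na(out$genome))) out[, genome := NULL]
  setcolorder(out, intersect(c("qname", "genome", "contig", "pos", "mapq",
                               "strand_origin", "xg", "seq", "xm"),
                             names(out)))
  if (sum(skipped) > 0L)
    message(sprintf("read_bisulfite_sam: skipped %d record(s) [%s]",
                    sum(skipped),
                    paste(sprintf("%s=%d", names(skipped), skipped)[skipped > 0],
                          collapse = ", ")))
  setattr(out, "skipped", skipped)
  out[]
}

#' Read a homoeologous SNP catalogue TSV
#'
#' Expected columns: \code{contig}, \code{pos_1based}, \code{allele_A},
#' \code{allele_B}, \code{allele_D}, \code{source}. Alleles outside
#' A/C/G/T and duplicate (contig, position) rows are fatal, with the line
#' number reported.
#'
#' @param path TSV path.
#' @return \code{data.table} with 0-based \code{pos} and recomputed
#'   \code{bisulfite_safe} flag.
#' @export
read_snp_catalog <- function(path) {
  if (!file.exists(path)) stop_input("SNP catalogue '%s' does not exist", path)
  dt <- fread(path, sep = "\t", colClasses = list(character = "contig"))
  need <- c("contig", "pos_1based", "allele_A", "allele_B", "allele_D")
  if (!all(need %in% names(dt)))
    stop_input("SNP catalogue '%s' must have columns %s", path,
               paste(need, collapse = ", "))
  if (!"source" %in% names(dt)) dt[, source := "unknown"]
  for (col in c("allele_A", "allele_B", "allele_D")) {
    bad <- which(!dt[[col]] %in% BASES)
    if (length(bad))
      stop_input("invalid allele '%s' in %s at line %d of '%s'",
                 dt[[col]][bad[1]], col, bad[1] + 1L, path)
  }
  dup <- which(duplicated(dt[, .(contig, pos_1based)]))
  if (length(dup))
    stop_input("duplicate (contig, position) at line %d of '%s'",
               dup[1] + 1L, path)
  dt[, pos := as.integer(pos_1based) - 1L]
  dt[, pos_1based := NULL]
  dt[, bisulfite_safe := is_bisulfite_safe(allele_A, allele_B, allele_D)]
  setcolorder(dt, c("contig", "pos", "allele_A", "allele_B", "allele_D",
                    "source", "bisulfite_safe"))
  setkey(dt, contig, pos)
  dt[]
}

#' Write a homoeologous SNP catalogue TSV
#' @param snps catalogue table with 0-based \code{pos}.
#' @param path output path.
#' @export
write_snp_catalog <- function(snps, path) {
  snps <- as.data.table(snps)
  out <- data.table(contig = snps$contig, pos_1based = snps$pos + 1L,
                    allele_A = snps$allele_A, allele_B = snps$allele_B,
                    allele_D = snps$allele_D,
                    source = if ("source" %in% names(snps)) snps$source
                             else "unknown")
  setorder(out, contig, pos_1based)
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read region annotations from BED
#'
#' BED columns: chrom, start, end (0-based half-open), class in column 4,
#' then optionally score, strand, region id and linked gene id. Promoter
#' regions must carry a linked gene id.
#'
#' @param path BED path.
#' @param reference optional \code{DNAStringSet} for bounds checking.
#' @return \code{data.table} with \code{region_id}, \code{contig},
#'   \code{start}, \code{end}, \code{class}, \code{gene_id}.
#' @export
read_regions_bed <- function(path, reference = NULL) {
  if (!file.exists(path)) stop_input("BED file '%s' does not exist", path)
  dt <- fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 4L)
    stop_input("BED file '%s' needs at least 4 columns (class in column 4)",
               path)
  out <- data.table(contig = as.character(dt[[1]]),
                    start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]),
                    class = as.character(dt[[4]]))
  out[, region_id := if (ncol(dt) >= 7L) as.character(dt[[7]])
      else sprintf("%s:%d-%d", contig, start, end)]
  out[, gene_id := if (ncol(dt) >= 8L) as.character(dt[[8]])
      else NA_character_]
  out[gene_id == ".", gene_id := NA_character_]
  valid <- c("exon", "intron", "promoter", "non_transcribed", "unknown")
  if (any(!out$class %in% valid))
    stop_input("invalid region class '%s' in '%s'",
               setdiff(out$class, valid)[1], path)
  if (any(out$start < 0L | out$end <= out$start))
    stop_input("invalid span in '%s'", path)
  if (!is.null(reference)) {
    reflen <- stats::setNames(Biostrings::width(reference), names(reference))
    if (any(!out$contig %in% names(reference)) ||
        any(out$end > reflen[out$contig]))
      stop_input("region outside reference bounds in '%s'", path)
  }
  if (any(out$class == "promoter" & is.na(out$gene_id)))
    stop_input("promoter region without linked gene id in '%s'", path)
  setcolorder(out, c("region_id", "contig", "start", "end", "class",
                     "gene_id"))
  out[]
}

#' Write region annotations as BED
#' @param regions region table.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  regions <- as.data.table(regions)
  out <- data.table(regions$contig, regions$start, regions$end,
                    regions$class, 0L, ".", regions$region_id,
                    ifelse(is.na(regions$gene_id), ".", regions$gene_id))
  setorder(out, V1, V2)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Derive promoter regions from gene spans
#'
#' Emits a promoter region per gene covering up to \code{promoter_bp}
#' upstream of the transcription start (the gene's lowest coordinate),
#' clipped at the contig start.
#'
#' @param genes table with \code{contig}, \code{start}, \code{end},
#'   \code{gene_id} (one row per gene).
#' @param promoter_bp maximum promoter extent (default 2000).
#' @return region table of class \code{promoter}.
#' @export
derive_promoters <- function(genes, promoter_bp = 2000L) {
  genes <- as.data.table(genes)
  out <- genes[, .(contig, start = pmax(0L, start - as.integer(promoter_bp)),
                   end = start, class = "promoter", gene_id)]
  out <- out[end > start]
  out[, region_id := paste0(gene_id, "_promoter")]
  setcolorder(out, c("region_id", "contig", "start", "end", "class",
                     "gene_id"))
  out[]
}

#' Read an allelic expression TSV
#'
#' Columns: region (or gene) id, \code{raw_A}, \code{raw_B}, \code{raw_D}
#' and optional \code{pplr_A}, \code{pplr_B}, \code{pplr_D} (\code{.} for
#' missing).
#' @param path TSV path.
#' @return \code{data.table} with normalized percentages appended.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop_input("expression table '%s' does not exist",
                                     path)
  dt <- fread(path, sep = "\t", na.strings = ".")
  id_col <- intersect(c("gene_id", "region_id", "region"), names(dt))[1]
  if (is.na(id_col) || !all(c("raw_A", "raw_B", "raw_D") %in% names(dt)))
    stop_input("expression table '%s' needs an id column and raw_A/B/D",
               path)
  setnames(dt, id_col, "gene_id")
  norm <- normalize_allelic_expression(dt$raw_A, dt$raw_B, dt$raw_D)
  cbind(dt, norm)
}

## generic TSV writers with stable column order and "." for missing values

write_tsv_formatted <- function(dt, path) {
  dt <- as.data.table(dt)
  num <- names(dt)[vapply(dt, is.double, logical(1))]
  for (col in num) set(dt, j = col, value = fmt_num(dt[[col]]))
  fwrite(dt, path, sep = "\t", na = ".")
  invisible(path)
}

#' Write the per-site observation/count tables
#'
#' \code{write_site_table} emits per-site per-genome methylation counts
#' (\code{\link{tally_site_counts}} output); \code{write_region_table} and
#' \code{write_dmr_table} emit region summaries and DMR calls. All writers
#' are deterministic: stable ordering, floats at 4 significant digits,
#' \code{.} for missing values.
#'
#' @param x result table.
#' @param path output path.
#' @export
write_site_table <- function(x, path) {
  x <- as.data.table(x)
  if (all(c("contig", "pos") %in% names(x))) {
    x <- copy(x)[, pos_1based := pos + 1L][, pos := NULL]
    setcolorder(x, c("contig", "pos_1based"))
    setorder(x, contig, pos_1based)
  }
  write_tsv_formatted(x, path)
}

#' @rdname write_site_table
#' @export
write_region_table <- function(x, path) {
  x <- as.data.table(x)
  if ("region_id" %in% names(x)) setorder(x, region_id)
  write_tsv_formatted(x, path)
}

#' @rdname write_site_table
#' @export
write_dmr_table <- function(x, path) write_region_table(x, path)

#' Read back a site table written by \code{write_site_table}
#' @param path TSV path.
#' @return \code{data.table} with 0-based \code{pos} restored.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop_input("site table '%s' does not exist", path)
  dt <- fread(path, sep = "\t", na.strings = ".")
  if ("pos_1based" %in% names(dt)) {
    dt[, pos := as.integer(pos_1based) - 1L][, pos_1based := NULL]
    setcolorder(dt, c("contig", "pos"))
  }
  dt[]
}
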