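#' Read peak intervals from a BED6 file
#'
#' Reads a BED file (0-based half-open, as the format requires) into a
#' \link[GenomicRanges]{GRanges} of peaks. The BED name column becomes the
#' peak identifier (stored in \code{names()} and in metadata column
#' \code{peak_id}); the score column is kept but unused. Peak read counts
#' are not set by this reader; see \code{\link{count_reads_in_peaks}}.
#'
#' @param path Path to a BED file with at least 6 columns.
#' @return A \code{GRanges} with metadata column \code{peak_id}.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t160\tpk1\t0\t+", bed)
#' read_peaks_bed(bed)
#' @export
read_peaks_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  bad <- which(n_col < 6L)
  if (length(bad) > 0L)
    stop("malformed BED line ", bad[1L], ": expected >= 6 columns, got ",
         n_col[bad[1L]])
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  name <- vapply(fields, `[[`, "", 4L)
  strand <- vapply(fields, `[[`, "", 6L)
  if (anyNA(start0) || anyNA(end0)) {
    bad <- which(is.na(start0) | is.na(end0))[1L]
    stop("malformed BED line ", bad, ": non-numeric coordinates")
  }
  bad <- which(start0 >= end0)
  if (length(bad) > 0L)
    stop("invalid interval on BED line ", bad[1L], ": start >= end")
  if (!all(strand %in% c("+", "-", ".")))
    stop("invalid strand symbol in BED file: ",
         strand[which(!strand %in% c("+", "-", "."))[1L]])
  if (anyDuplicated(name))
    stop("duplicate peak_id in BED file: ", name[anyDuplicated(name)])
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand
  )
  names(gr) <- name
  gr$peak_id <- name
  gr
}

#' Write peaks to BED6
#'
#' Inverse of \code{\link{read_peaks_bed}}: writes 0-based half-open
#' coordinates so that a read/write round trip is the identity.
#'
#' @param peaks A \code{GRanges} with a \code{peak_id} metadata column (or
#'   names).
#' @param path Output path.
#' @param score Optional numeric score column (default 0).
#' @return Invisibly, \code{path}.
#' @export
write_peaks_bed <- function(peaks, path, score = 0) {
  id <- if (!is.null(peaks$peak_id)) peaks$peak_id else names(peaks)
  strand <- as.character(BiocGenerics::strand(peaks))
  strand[strand == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = BiocGenerics::start(peaks) - 1L,
    end = BiocGenerics::end(peaks),
    name = id,
    score = rep_len(score, length(peaks)),
    strand = strand
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GTF gene model into an annotation object
#'
#' Parses exon and CDS rows of a GTF (1-based inclusive; converted by
#' \pkg{rtracklayer}) and derives, per transcript, the intron ranges (gaps
#' between sorted exons) and the 5'/3' UTR ranges (exonic sequence up/downstream
#' of the CDS in transcript orientation). Transcripts without CDS rows keep all
#' exonic sequence classed as \code{"exon"}.
#'
#' @param path Path to a GTF file with \code{exon} (and optionally \code{CDS})
#'   feature rows carrying \code{gene_id} and \code{transcript_id} attributes.
#' @return A \code{genome_annotation} object: a list with elements
#'   \code{exons}, \code{cds}, \code{five_utr}, \code{three_utr},
#'   \code{introns} (each a \code{GRanges} with \code{gene_id} and
#'   \code{transcript_id}), and \code{transcripts} (a data.frame of per-
#'   transcript gene ids and strands).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  build_annotation(
    exons = gr[gr$type == "exon"],
    cds = gr[gr$type == "CDS"]
  )
}

#' Assemble a genome annotation from exon and CDS ranges
#'
#' @param exons \code{GRanges} of exons with \code{gene_id} and
#'   \code{transcript_id} metadata columns.
#' @param cds \code{GRanges} of CDS pieces with the same columns (may be
#'   empty).
#' @return A \code{genome_annotation} object; see \code{\link{read_gtf}}.
#' @export
build_annotation <- function(exons, cds = GenomicRanges::GRanges()) {
  if (is.null(exons$transcript_id) || is.null(exons$gene_id))
    stop("exon ranges must carry gene_id and transcript_id")
  st <- as.character(BiocGenerics::strand(exons))
  if (any(st == "*"))
    stop("unknown strand for exon of transcript ",
         exons$transcript_id[which(st == "*")[1L]])

  ex_by_tx <- S4Vectors::split(exons, exons$transcript_id)
  tx_ids <- names(ex_by_tx)
  tx_gene <- vapply(ex_by_tx, function(g) as.character(g$gene_id[1L]), "")
  tx_strand <- vapply(ex_by_tx, function(g)
    as.character(BiocGenerics::strand(g)[1L]), "")
  tx_chrom <- vapply(ex_by_tx, function(g)
    as.character(GenomicRanges::seqnames(g)[1L]), "")

  cds_by_tx <- if (length(cds) > 0L)
    S4Vectors::split(cds, cds$transcript_id) else NULL

  introns <- list(); five <- list(); three <- list()
  cds_out <- list()
  for (tx in tx_ids) {
    ex <- BiocGenerics::sort(ex_by_tx[[tx]])
    ir <- IRanges::ranges(ex)
    if (length(IRanges::reduce(ir)) != length(ir))
      stop("overlapping exons in transcript ", tx)
    chrom <- tx_chrom[[tx]]
    strnd <- tx_strand[[tx]]
    gid <- tx_gene[[tx]]
    span <- range(ir)
    gap <- IRanges::setdiff(span, ir)
    if (length(gap) > 0L)
      introns[[tx]] <- ann_ranges(gap, chrom, strnd, gid, tx)
    if (!is.null(cds_by_tx) && tx %in% names(cds_by_tx)) {
      cr <- IRanges::reduce(IRanges::ranges(cds_by_tx[[tx]]))
      if (length(IRanges::setdiff(cr, ir)) > 0L)
        stop("CDS outside exons in transcript ", tx)
      cds_out[[tx]] <- ann_ranges(cr, chrom, strnd, gid, tx)
      utr <- IRanges::setdiff(ir, cr)
      if (length(utr) > 0L) {
        cds_start <- min(IRanges::start(cr))
        cds_end <- max(IRanges::end(cr))
        up <- utr[IRanges::end(utr) < cds_start]     # low-coordinate side
        down <- utr[IRanges::start(utr) > cds_end]   # high-coordinate side
        if (strnd == "+") {
          if (length(up) > 0L) five[[tx]] <- ann_ranges(up, chrom, strnd, gid, tx)
          if (length(down) > 0L) three[[tx]] <- ann_ranges(down, chrom, strnd, gid, tx)
        } else {
          if (length(down) > 0L) five[[tx]] <- ann_ranges(down, chrom, strnd, gid, tx)
          if (length(up) > 0L) three[[tx]] <- ann_ranges(up, chrom, strnd, gid, tx)
        }
      }
    }
  }
  ann <- list(
    exons = exons,
    cds = bind_granges(cds_out),
    five_utr = bind_granges(five),
    three_utr = bind_granges(three),
    introns = bind_granges(introns),
    transcripts = data.frame(
      transcript_id = tx_ids, gene_id = unname(tx_gene),
      chrom = unname(tx_chrom), strand = unname(tx_strand),
      stringsAsFactors = FALSE
    )
  )
  class(ann) <- "genome_annotation"
  ann
}

ann_ranges <- function(ir, chrom, strnd, gid, tx) {
  g <- GenomicRanges::GRanges(chrom, ir, strand = strnd)
  g$gene_id <- gid
  g$transcript_id <- tx
  g
}

bind_granges <- function(lst) {
  lst <- lst[!vapply(lst, is.null, TRUE)]
  if (length(lst) == 0L) {
    g <- GenomicRanges::GRanges()
    g$gene_id <- character(0)
    g$transcript_id <- character(0)
    return(g)
  }
  unname(do.call(c, unname(lst)))
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$transcripts), "transcripts,",
      length(unique(x$transcripts$gene_id)), "genes\n")
  cat("  exons:", length(x$exons), " CDS:", length(x$cds),
      " 5'UTR:", length(x$five_utr), " 3'UTR:", length(x$three_utr),
      " introns:", length(x$introns), "\n")
  invisible(x)
}

#' Write an annotation back to GTF
#'
#' Emits exon and CDS rows only (UTRs and introns are derived on read), so
#' that \code{read_gtf(write_gtf(ann))} reproduces \code{ann}.
#'
#' @param ann A \code{genome_annotation}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gtf <- function(ann, path) {
  rows <- function(gr, type) {
    if (length(gr) == 0L) return(character(0))
    sprintf(
      "%s\tsyncliptic\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
      as.character(GenomicRanges::seqnames(gr)), type,
      BiocGenerics::start(gr), BiocGenerics::end(gr),
      as.character(BiocGenerics::strand(gr)), gr$gene_id, gr$transcript_id)
  }
  writeLines(c(rows(ann$exons, "exon"), rows(ann$cds, "CDS")), path)
  invisible(path)
}

#' Count reads overlapping peaks for two samples
#'
#' A read increments every peak it overlaps by at least \code{min_overlap}
#' bases (no fractional assignment). The per-sample library size is the number
#' of reads overlapping any peak, counted once each; this is the "reads
#' mapping to the peaks" library size used downstream for effective library
#' sizes.
#'
#' @param peaks \code{GRanges} of peaks (see \code{\link{read_peaks_bed}}).
#' @param reads_x,reads_y \code{GRanges} of read fragments for the
#'   compartment (x) and reference (y) sample.
#' @param strand_matched If \code{TRUE}, only same-strand overlaps count;
#'   default counts strand-blind.
#' @param min_overlap Minimum overlap in bases (default 1).
#' @return A list with \code{peaks} (input with metadata columns
#'   \code{count_x}, \code{count_y} added), \code{lib_size_x},
#'   \code{lib_size_y}, and \code{skipped} (reads on chromosomes absent from
#'   the peak set, per sample).
#' @export
count_reads_in_peaks <- function(peaks, reads_x, reads_y,
                                 strand_matched = FALSE, min_overlap = 1L) {
  one <- function(reads) {
    known <- as.character(GenomicRanges::seqnames(reads)) %in%
      unique(as.character(GenomicRanges::seqnames(peaks)))
    n_skip <- sum(!known)
    if (n_skip > 0L) {
      warning(n_skip, " read(s) on chromosomes without peaks skipped")
      reads <- reads[known]
    }
    cnt <- GenomicRanges::countOverlaps(
      peaks, reads, minoverlap = min_overlap,
      ignore.strand = !strand_matched)
    hit <- GenomicRanges::countOverlaps(
      reads, peaks, minoverlap = min_overlap,
      ignore.strand = !strand_matched) > 0L
    list(count = cnt, lib = sum(hit), skipped = n_skip)
  }
  rx <- one(reads_x)
  ry <- one(reads_y)
  peaks$count_x <- rx$count
  peaks$count_y <- ry$count
  list(peaks = peaks, lib_size_x = rx$lib, lib_size_y = ry$lib,
       skipped = c(x = rx$skipped, y = ry$skipped))
}

#' Write a results table as TSV
#'
#' Tab-separated with a header row; columns named \code{p}, \code{q} or
#' ending in \code{_p} are serialized in scientific notation
#' (\code{"1.000000e-12"}) so small p-values survive the round trip.
#'
#' @param results A data.frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_results_tsv <- function(results, path) {
  out <- results
  pcols <- grepl("(^|_)(p|q)$", names(out))
  for (j in which(pcols)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%e", out[[j]])
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write results to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a results table written by \code{write_results_tsv}
#' @param path Path to the TSV.
#' @return A data.frame.
#' @export
read_results_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
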