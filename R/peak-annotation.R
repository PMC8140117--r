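# feature precedence when a position is covered by several transcripts:
# mature-transcript features outrank introns
FEATURE_PRECEDENCE <- c("three_prime_utr", "five_prime_utr", "exon", "intron")

feature_regions <- function(ann, class) {
  switch(class,
         three_prime_utr = ann$three_utr,
         five_prime_utr = ann$five_utr,
         exon = ann$cds,
         intron = ann$introns,
         stop("unknown feature class: ", class))
}

#' Classify peaks into transcript feature classes
#'
#' Each peak is classified by the feature overlapping its center position,
#' with precedence 3'UTR > 5'UTR > exon (CDS) > intron across overlapping
#' transcripts; a center outside every gene is \code{"intergenic"}. Note that
#' exonic sequence of non-coding transcripts is classed \code{"exon"} at
#' annotation build time (their whole exonic extent sits in \code{ann$cds}'s
#' complement; see Details).
#'
#' The assigned gene is the one with the largest peak-interval overlap (ties
#' broken lexicographically by gene id), replacing manual curation of
#' ambiguous assignments with a deterministic rule.
#'
#' @details Non-coding transcripts have no CDS; their exons are classified
#'   through the \code{exons} track, which backs the \code{"exon"} class for
#'   positions not claimed by a UTR of any transcript.
#'
#' @param peaks \code{GRanges} of peaks.
#' @param ann A \code{genome_annotation}.
#' @param centers Optional integer vector of center positions (1-based); peak
#'   interval midpoints (lower median) are used when omitted.
#' @return A data.frame with \code{peak_id}, \code{center}, \code{class},
#'   \code{gene_id} (\code{NA} for intergenic).
#' @export
classify_peaks <- function(peaks, ann, centers = NULL) {
  if (is.null(centers))
    centers <- BiocGenerics::start(peaks) +
      (BiocGenerics::width(peaks) - 1L) %/% 2L
  pts <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                IRanges::IRanges(centers, width = 1L),
                                strand = BiocGenerics::strand(peaks))
  cls <- rep("intergenic", length(peaks))
  tracks <- list(three_prime_utr = ann$three_utr,
                 five_prime_utr = ann$five_utr,
                 exon = combine_exonic(ann),
                 intron = ann$introns)
  for (class in FEATURE_PRECEDENCE) {
    hit <- IRanges::overlapsAny(pts, tracks[[class]], ignore.strand = TRUE)
    cls[cls == "intergenic" & hit] <- class
  }
  # gene assignment: largest peak overlap, ties by lexicographic gene_id
  gene <- rep(NA_character_, length(peaks))
  ov <- GenomicRanges::findOverlaps(peaks, ann$exons, ignore.strand = TRUE)
  ivn <- GenomicRanges::findOverlaps(peaks, ann$introns, ignore.strand = TRUE)
  hits <- data.frame(
    peak = c(S4Vectors::queryHits(ov), S4Vectors::queryHits(ivn)),
    gene = c(ann$exons$gene_id[S4Vectors::subjectHits(ov)],
             ann$introns$gene_id[S4Vectors::subjectHits(ivn)]),
    w = c(overlap_width(peaks, ann$exons, ov),
          overlap_width(peaks, ann$introns, ivn))
  )
  if (nrow(hits) > 0L) {
    agg <- stats::aggregate(w ~ peak + gene, data = hits, FUN = sum)
    agg <- agg[order(agg$peak, -agg$w, agg$gene), ]
    best <- agg[!duplicated(agg$peak), ]
    gene[best$peak] <- best$gene
  }
  data.frame(peak_id = peaks$peak_id, center = centers, class = cls,
             gene_id = gene, stringsAsFactors = FALSE)
}

# CDS plus the exonic extent of non-coding transcripts: the regions backing
# the "exon" class
combine_exonic <- function(ann) {
  coding <- unique(ann$cds$transcript_id)
  nc <- ann$exons[!ann$exons$transcript_id %in% coding]
  if (length(ann$cds) == 0L) return(nc)
  if (length(nc) == 0L) return(ann$cds)
  c(ann$cds, nc)
}

overlap_width <- function(query, subject, hits) {
  if (length(hits) == 0L) return(integer(0))
  BiocGenerics::width(IRanges::pintersect(
    IRanges::ranges(query)[S4Vectors::queryHits(hits)],
    IRanges::ranges(subject)[S4Vectors::subjectHits(hits)]))
}

#' Percentage of peaks per feature class
#'
#' Percentages over the four genic classes sum to 100; intergenic peaks are
#' reported separately as a fraction of all peaks.
#'
#' @param classes Character vector of feature classes (from
#'   \code{\link{classify_peaks}}).
#' @return A list with \code{percent} (named numeric over genic classes) and
#'   \code{intergenic_percent}.
#' @export
feature_distribution <- function(classes) {
  if (length(classes) == 0L) stop("no peaks to summarize")
  genic <- classes[classes != "intergenic"]
  lv <- FEATURE_PRECEDENCE
  tab <- table(factor(genic, levels = lv))
  pct <- if (length(genic) > 0L) 100 * as.numeric(tab) / length(genic)
         else rep(0, length(lv))
  names(pct) <- lv
  list(percent = pct,
       intergenic_percent = 100 * mean(classes == "intergenic"))
}

#' Peak center from per-base coverage
#'
#' The center is the lower median of the positions attaining maximum read
#' coverage inside the peak. All-zero coverage falls back to the interval
#' midpoint, flagged.
#'
#' @param start Peak start (1-based).
#' @param coverage Integer vector of per-base coverage, one entry per peak
#'   base.
#' @return A list with \code{center} (genomic position), \code{max_coverage},
#'   and \code{fallback} (\code{TRUE} when coverage was all zero).
#' @export
peak_center <- function(start, coverage) {
  n <- length(coverage)
  if (n == 0L) stop("empty coverage")
  mx <- max(coverage)
  if (mx == 0) {
    return(list(center = start + (n - 1L) %/% 2L, max_coverage = 0L,
                fallback = TRUE))
  }
  at <- which(coverage == mx)
  med <- at[(length(at) + 1L) %/% 2L]  # lower median
  list(center = start + med - 1L, max_coverage = mx, fallback = FALSE)
}

#' Per-base coverage of a peak from read fragments
#'
#' @param peak A length-1 \code{GRanges}.
#' @param reads \code{GRanges} of read fragments (strand ignored).
#' @return Integer vector of length \code{width(peak)}.
#' @export
peak_coverage <- function(peak, reads) {
  reads <- IRanges::subsetByOverlaps(reads, peak, ignore.strand = TRUE)
  s <- BiocGenerics::start(peak); e <- BiocGenerics::end(peak)
  cov <- integer(e - s + 1L)
  if (length(reads) == 0L) return(cov)
  rs <- pmax(BiocGenerics::start(reads), s)
  re <- pmin(BiocGenerics::end(reads), e)
  # difference array: +1 at each read start, -1 past each read end
  delta <- integer(e - s + 2L)
  for (i in seq_along(rs)) {
    delta[rs[i] - s + 1L] <- delta[rs[i] - s + 1L] + 1L
    delta[re[i] - s + 2L] <- delta[re[i] - s + 2L] - 1L
  }
  cumsum(delta)[seq_len(e - s + 1L)]
}

#' Extract a fixed-width sequence window around a peak center
#'
#' For window size s the window is \code{[center - floor(s/2), center +
#' ceiling(s/2) - 1]} (1-based inclusive), symmetric for odd s; minus-strand
#' peaks are reverse-complemented.
#'
#' @param center Genomic position (1-based).
#' @param chrom Chromosome name.
#' @param strand \code{"+"}, \code{"-"} or \code{"*"}.
#' @param genome A \code{DNAStringSet} keyed by chromosome.
#' @param size Window width (default 41).
#' @return A character string of length \code{size}, or \code{NA} (with a
#'   warning) when the window crosses a chromosome boundary.
#' @export
extract_window <- function(center, chrom, strand, genome, size = 41) {
  half <- size %/% 2L
  from <- center - half
  to <- from + size - 1L
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  if (from < 1L || to > length(genome[[chrom]])) {
    warning("window at ", chrom, ":", center, " crosses chromosome boundary; skipped")
    return(NA_character_)
  }
  s <- Biostrings::subseq(genome[[chrom]], from, to)
  if (identical(strand, "-")) s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Sample annotation-matched zero-coverage background windows
#'
#' Draws \code{n} windows of length \code{size} uniformly over all positions
#' that lie entirely inside a region of the requested feature class and have
#' zero read coverage across their span — background sequences guaranteed not
#' to be bound in the corresponding CLIP sample.
#'
#' @param ann A \code{genome_annotation}.
#' @param genome A \code{DNAStringSet}.
#' @param reads \code{GRanges} of the sample's reads (defines coverage); may
#'   be empty.
#' @param feature_class One of \code{"five_prime_utr"}, \code{"exon"},
#'   \code{"three_prime_utr"}, \code{"intron"}.
#' @param n Number of windows (default 200000).
#' @param size Window length (default 41).
#' @param seed Integer seed for reproducible sampling.
#' @return A list with \code{sequences} (character vector of length \code{n})
#'   and \code{windows} (the sampled \code{GRanges}).
#' @export
sample_background <- function(ann, genome, reads, feature_class,
                              n = 200000, size = 41, seed = 1) {
  regions <- feature_regions(ann, feature_class)
  if (feature_class == "exon") regions <- combine_exonic(ann)
  pool <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  if (length(reads) > 0L) {
    covered <- GenomicRanges::reduce(reads, ignore.strand = TRUE)
    pool <- GenomicRanges::setdiff(pool, covered, ignore.strand = TRUE)
  }
  pool <- pool[BiocGenerics::width(pool) >= size]
  n_starts <- BiocGenerics::width(pool) - size + 1L
  total <- sum(as.numeric(n_starts))
  if (total < 1)
    stop("no eligible positions; achievable maximum is 0 windows")
  set.seed(seed)
  draw <- sample.int(total, n, replace = TRUE)
  cum <- cumsum(as.numeric(n_starts))
  region_idx <- findInterval(draw - 1, cum) + 1L
  within <- draw - c(0, cum)[region_idx] - 1
  starts <- BiocGenerics::start(pool)[region_idx] + within
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(pool)[region_idx],
    IRanges::IRanges(start = starts, width = size))
  seqs <- vapply(seq_along(win), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(win)[i])
    as.character(Biostrings::subseq(genome[[chrom]],
                                    BiocGenerics::start(win)[i],
                                    BiocGenerics::end(win)[i]))
  }, "")
  list(sequences = seqs, windows = win)
}

#' Write sequences as FASTA
#'
#' @param seqs Character vector of sequences (names used as headers; default
#'   seq_1..seq_n).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq_", seq_along(seqs))
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}
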