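# Seeded generators for every stage of the pipeline. Each is a pure function
# of (parameters, seed) and returns ground-truth labels alongside the data.

#' Default nonlinear M-vs-A trend
#'
#' Smooth trend injected into the compartment sample's counts so that the raw
#' MA cloud is off-center and bent, as in real two-sample CLIP comparisons.
#'
#' @param A Average log2 count values.
#' @return Trend values on the log2 scale.
#' @export
default_ma_trend <- function(A) 0.8 * sin(A / 2) - 0.5 * exp(-A)

#' Simulate a toy genome and gene annotation
#'
#' Random non-overlapping genes with 1-3 transcripts of 2-8 exons each; 80\%
#' of genes are coding with a CDS flanked by both UTRs, the rest non-coding.
#' The genome sequence is uniform random over ACGT. The result serializes to
#' GTF/FASTA and passes the annotation invariants (introns tile inter-exon
#' gaps; UTR + CDS lengths sum to the exonic length).
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer seed.
#' @param chrom_name Chromosome name for the single toy chromosome.
#' @return A list with \code{annotation} (a \code{genome_annotation}) and
#'   \code{genome} (a \code{DNAStringSet}).
#' @export
simulate_annotation <- function(n_genes, seed = 1, chrom_name = "chrT") {
  if (n_genes < 1) stop("n_genes must be >= 1")
  set.seed(seed)
  exon_rows <- list(); cds_rows <- list()
  pos <- 1000L
  for (g in seq_len(n_genes)) {
    gid <- sprintf("gene%04d", g)
    strand <- sample(c("+", "-"), 1L)
    n_exons <- sample(2:8, 1L)
    widths <- sample(80:300, n_exons, replace = TRUE)
    gaps <- sample(60:400, n_exons - 1L, replace = TRUE)
    starts <- pos + cumsum(c(0L, widths[-n_exons] + gaps))
    ends <- starts + widths - 1L
    coding <- stats::runif(1) > 0.2
    n_tx <- sample(1:3, 1L)
    for (t in seq_len(n_tx)) {
      tid <- sprintf("%s.t%d", gid, t)
      # transcripts use a contiguous run of the gene's exons
      lo <- if (n_exons > 2L && t > 1L) sample(1:2, 1L) else 1L
      hi <- if (n_exons > 2L && t > 1L) n_exons - sample(0:1, 1L) else n_exons
      idx <- lo:hi
      ex <- GenomicRanges::GRanges(
        chrom_name, IRanges::IRanges(starts[idx], ends[idx]), strand = strand)
      ex$gene_id <- gid; ex$transcript_id <- tid
      exon_rows[[tid]] <- ex
      if (coding) {
        first <- idx[1L]; last <- idx[length(idx)]
        if (first == last) {
          # single-exon transcript: UTRs must leave room for a CDS
          w <- widths[first]
          u_lo <- sample(10:(w - 30L), 1L)
          u_hi <- sample(10:(w - u_lo - 10L), 1L)
        } else {
          u_lo <- sample(20:(widths[first] - 20L), 1L)
          u_hi <- sample(20:(widths[last] - 20L), 1L)
        }
        cds_from <- starts[first] + u_lo
        cds_to <- ends[last] - u_hi
        cr <- IRanges::intersect(
          IRanges::IRanges(starts[idx], ends[idx]),
          IRanges::IRanges(cds_from, cds_to))
        cd <- GenomicRanges::GRanges(chrom_name, cr, strand = strand)
        cd$gene_id <- gid; cd$transcript_id <- tid
        cds_rows[[tid]] <- cd
      }
    }
    pos <- ends[n_exons] + sample(300:1500, 1L)
  }
  glen <- pos + 1000L
  genome <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), glen, replace = TRUE), collapse = ""))
  names(genome) <- chrom_name
  list(annotation = build_annotation(bind_granges(exon_rows),
                                     bind_granges(cds_rows)),
       genome = genome)
}

#' Simulate a two-sample CLIP peak experiment
#'
#' Per-peak baseline abundances are log-normal; the reference sample's count
#' is NB with mean \eqn{\mu_i}, the compartment sample's count NB with mean
#' \eqn{\mu_i \cdot r \cdot 2^{trend(A_i) + e_i}} where \eqn{r} is the
#' library-size ratio, \eqn{trend} a smooth function of the expected average
#' log2 count, and \eqn{e_i} the true log2 effect (nonzero for the labelled
#' enriched minority). Optionally realizes the counts as fixed-length read
#' fragments with a triangular placement density so peak centers are
#' well-defined.
#'
#' @param n_peaks Number of peaks.
#' @param frac_enriched Fraction of truly compartment-enriched peaks.
#' @param effect_log2 True log2 effect of enriched peaks (default 2 = 4-fold).
#' @param phi NB dispersion (0 gives Poisson counts).
#' @param trend Function of A giving the log2 trend.
#' @param lib_ratio Compartment/reference library-scale ratio.
#' @param mean_count Log-normal location of the reference-count distribution
#'   (median extra rate above the floor).
#' @param sdlog Log-normal spread of baseline abundances; the default 1.3
#'   spans the several orders of magnitude seen across real CLIP peaks.
#' @param min_rate Floor on the expected reference count (default 8),
#'   reflecting that a peak caller only reports intervals with substantive
#'   read support.
#' @param seed Integer seed.
#' @param annotation Optional \code{genome_annotation}: peaks are placed in
#'   its genes; otherwise peaks tile a virtual chromosome.
#' @param reads If \code{TRUE}, also generate read fragments realizing the
#'   counts.
#' @param read_length Fragment length for read realization.
#' @return A list with \code{peaks} (\code{GRanges} with \code{peak_id},
#'   \code{count_x}, \code{count_y}), \code{truth} (data.frame with
#'   \code{peak_id}, \code{enriched}, \code{effect_log2}), \code{lib_size_x},
#'   \code{lib_size_y}, and (when \code{reads}) \code{reads_x},
#'   \code{reads_y}.
#' @export
simulate_clip_experiment <- function(n_peaks, frac_enriched = 0.05,
                                     effect_log2 = 2, phi = 0.1,
                                     trend = default_ma_trend,
                                     lib_ratio = 0.6, mean_count = 60,
                                     sdlog = 1.3, min_rate = 8,
                                     seed = 1, annotation = NULL,
                                     reads = FALSE, read_length = 40L) {
  if (frac_enriched < 0 || frac_enriched >= 1)
    stop("frac_enriched must be in [0, 1)")
  if (phi < 0 || mean_count <= 0 || lib_ratio <= 0) stop("invalid parameters")
  set.seed(seed)
  peak_id <- sprintf("peak%06d", seq_len(n_peaks))
  peaks <- place_peaks(n_peaks, annotation)
  names(peaks) <- peak_id
  peaks$peak_id <- peak_id

  mu <- min_rate + stats::rlnorm(n_peaks, meanlog = log(mean_count),
                                 sdlog = sdlog)
  enriched <- stats::runif(n_peaks) < frac_enriched
  e <- ifelse(enriched, effect_log2, 0)
  mean_y <- mu
  a_expect <- (log2(mu * lib_ratio + 1) + log2(mu + 1)) / 2
  tr <- trend(a_expect)
  if (any(!is.finite(tr))) stop("trend function returned non-finite values")
  mean_x <- mu * lib_ratio * 2^(tr + e)
  rnb <- function(m) {
    if (phi == 0) stats::rpois(n_peaks, m)
    else stats::rnbinom(n_peaks, size = 1 / phi, mu = m)
  }
  peaks$count_y <- rnb(mean_y)
  peaks$count_x <- rnb(mean_x)

  out <- list(
    peaks = peaks,
    truth = data.frame(peak_id = peak_id, enriched = enriched,
                       effect_log2 = e, stringsAsFactors = FALSE),
    lib_size_x = sum(peaks$count_x),
    lib_size_y = sum(peaks$count_y))
  if (reads) {
    out$reads_x <- realize_reads(peaks, peaks$count_x, read_length)
    out$reads_y <- realize_reads(peaks, peaks$count_y, read_length)
  }
  out
}

place_peaks <- function(n_peaks, annotation) {
  if (is.null(annotation)) {
    step <- 200L
    return(GenomicRanges::GRanges(
      "chrS",
      IRanges::IRanges(start = step * (seq_len(n_peaks) - 1L) + 1L,
                       width = 60L),
      strand = "+"))
  }
  pool <- GenomicRanges::reduce(annotation$exons, ignore.strand = TRUE)
  pool <- c(pool, GenomicRanges::reduce(annotation$introns,
                                        ignore.strand = TRUE))
  pool <- pool[BiocGenerics::width(pool) >= 60L]
  idx <- sample.int(length(pool), n_peaks, replace = TRUE)
  w <- pmin(sample(30:150, n_peaks, replace = TRUE),
            BiocGenerics::width(pool)[idx])
  off <- floor(stats::runif(n_peaks) *
                 (BiocGenerics::width(pool)[idx] - w + 1))
  GenomicRanges::GRanges(
    GenomicRanges::seqnames(pool)[idx],
    IRanges::IRanges(start = BiocGenerics::start(pool)[idx] + off, width = w),
    strand = "+")
}

# place `count` fragments per peak with a triangular density around a
# peak-specific mode, so the coverage maximum (hence the peak center) is
# well-defined
realize_reads <- function(peaks, counts, read_length) {
  n <- sum(counts)
  if (n == 0L) {
    g <- GenomicRanges::GRanges()
    return(g)
  }
  idx <- rep(seq_along(peaks), counts)
  ps <- BiocGenerics::start(peaks)[idx]
  pw <- BiocGenerics::width(peaks)[idx]
  mode_off <- round(pw * stats::runif(length(peaks))[idx] * 0.6 + pw * 0.2)
  tri <- (stats::runif(n) + stats::runif(n) - 1) * pmax(pw %/% 4L, 2L)
  centers <- ps + mode_off + round(tri)
  starts <- pmax(centers - read_length %/% 2L, 1L)
  GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks)[idx],
    IRanges::IRanges(start = starts, width = read_length),
    strand = BiocGenerics::strand(peaks)[idx])
}

# logFC archetype shapes over (0, 8, 12, 24) h, scaled by log2(halflife_shift):
# a transient early stabilization that fades, a stabilization visible from
# 12 h on, and one visible only at 24 h
STABILITY_ARCHETYPES <- list(
  early_transient = c(0, 1.0, 0.3, 0.00),
  stabilized_12h = c(0, 0.0, 1.0, 0.15),
  stabilized_24h = c(0, 0.0, 0.0, 1.00)
)

#' Simulate a transcription-shutoff stability time course
#'
#' Per-gene exponential decay of expected abundance after transcription
#' inhibition, sampled with NB noise in six replicates per genotype per time
#' point. A labelled fraction of genes is stabilized in genotype B following
#' one of three archetype logFC shapes (early-transient, stabilized by 12 h,
#' stabilized by 24 h), with peak logFC \code{log2(halflife_shift)}.
#' At 0 h the genotypes are exchangeable by construction.
#'
#' @param n_genes Number of genes.
#' @param frac_stabilized Fraction of stabilized (genotype-responsive) genes.
#' @param halflife_shift Half-life multiplier defining the archetype
#'   amplitude (default 2).
#' @param replicates Replicates per genotype per time point (default 6).
#' @param timepoints Chase times in hours (default \code{c(0, 8, 12, 24)}).
#' @param phi NB dispersion across replicates.
#' @param baseline_mean Median expected count at 0 h.
#' @param seed Integer seed.
#' @return A list with \code{counts} (named list of genes x (2 x replicates)
#'   matrices, one per time point), \code{group} (genotype factor over the
#'   columns), \code{truth} (gene_id, stabilized, archetype), and
#'   \code{timepoints}.
#' @export
simulate_stability_timecourse <- function(n_genes, frac_stabilized = 0.1,
                                          halflife_shift = 2,
                                          replicates = 6,
                                          timepoints = c(0, 8, 12, 24),
                                          phi = 0.0225, baseline_mean = 500,
                                          seed = 1) {
  if (halflife_shift <= 0) stop("halflife_shift must be positive")
  set.seed(seed)
  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  n0 <- stats::rlnorm(n_genes, log(baseline_mean), 1)
  hl <- stats::rlnorm(n_genes, log(10), 0.4)  # half-life in hours
  stab <- stats::runif(n_genes) < frac_stabilized
  arch <- rep(NA_character_, n_genes)
  arch[stab] <- sample(names(STABILITY_ARCHETYPES), sum(stab), replace = TRUE)
  amp <- log2(halflife_shift)
  group <- factor(rep(c("A", "B"), each = replicates))
  counts <- list()
  for (ti in seq_along(timepoints)) {
    t <- timepoints[ti]
    base <- n0 * exp(-log(2) * t / hl)
    shift <- rep(0, n_genes)
    shift[stab] <- vapply(arch[stab], function(a)
      STABILITY_ARCHETYPES[[a]][ti], 0) * amp
    libf <- stats::rlnorm(2L * replicates, 0, 0.1)
    m <- cbind(base %o% libf[seq_len(replicates)],
               (base * 2^shift) %o% libf[replicates + seq_len(replicates)])
    cnt <- matrix(stats::rnbinom(length(m), size = 1 / phi, mu = m),
                  nrow = n_genes)
    rownames(cnt) <- gene_id
    colnames(cnt) <- paste0(rep(c("A", "B"), each = replicates),
                            seq_len(replicates), "_t", t)
    counts[[paste0("t", t)]] <- cnt
  }
  list(counts = counts, group = group,
       truth = data.frame(gene_id = gene_id, stabilized = stab,
                          archetype = arch, halflife = hl,
                          stringsAsFactors = FALSE),
       timepoints = timepoints)
}

#' Simulate decay logFC profile archetypes
#'
#' Draws noisy copies of the three archetype shapes directly on the logFC
#' scale — the minimal fixture for clustering-recovery checks.
#'
#' @param n_per_archetype Genes per archetype.
#' @param noise_sd Gaussian noise per time point (default 0.1).
#' @param amplitude Peak logFC (default 1).
#' @param seed Integer seed.
#' @return A list with \code{profiles} (matrix, genes x 4) and \code{truth}
#'   (archetype labels).
#' @export
simulate_decay_profiles <- function(n_per_archetype = 20, noise_sd = 0.1,
                                    amplitude = 1, seed = 1) {
  set.seed(seed)
  shapes <- do.call(rbind, STABILITY_ARCHETYPES)
  lab <- rep(rownames(shapes), each = n_per_archetype)
  prof <- shapes[lab, , drop = FALSE] * amplitude +
    matrix(stats::rnorm(length(lab) * ncol(shapes), 0, noise_sd),
           ncol = ncol(shapes))
  rownames(prof) <- sprintf("g%04d", seq_along(lab))
  colnames(prof) <- paste0("t", c(0, 8, 12, 24))
  list(profiles = prof, truth = lab)
}

#' Simulate a label-free proteomics intensity matrix
#'
#' Log-normal intensities with a group effect for a labelled fraction of
#' proteins and missing-not-at-random holes concentrated in low intensities
#' (dropout probability decreasing in the intensity's overall rank, scaled to
#' the requested overall missing rate). Peptide counts are 1-20.
#'
#' @param n_proteins Number of proteins.
#' @param n_per_group Samples per group (two groups).
#' @param frac_changed Fraction with a true group effect.
#' @param effect_log2 True absolute log2 effect (sign random).
#' @param sd Replicate standard deviation on the log2 scale.
#' @param missing_rate Overall expected fraction of missing cells (< 1).
#' @param seed Integer seed.
#' @return A list with \code{intensities} (linear scale, \code{NA} missing),
#'   \code{peptides}, \code{group}, and \code{truth} (protein, changed,
#'   effect_log2).
#' @export
simulate_proteomics <- function(n_proteins = 1000, n_per_group = 6,
                                frac_changed = 0.1, effect_log2 = 1,
                                sd = 0.25, missing_rate = 0.1, seed = 1) {
  if (missing_rate >= 1 || missing_rate < 0) stop("missing_rate must be in [0, 1)")
  set.seed(seed)
  protein <- sprintf("prot%05d", seq_len(n_proteins))
  base <- stats::rnorm(n_proteins, 20, 2)
  changed <- stats::runif(n_proteins) < frac_changed
  eff <- ifelse(changed, effect_log2 * sample(c(-1, 1), n_proteins,
                                              replace = TRUE), 0)
  n_s <- 2L * n_per_group
  group <- factor(rep(c("A", "B"), each = n_per_group))
  m <- matrix(stats::rnorm(n_proteins * n_s, 0, sd), ncol = n_s) + base
  m[, group == "B"] <- m[, group == "B"] + eff
  if (missing_rate > 0) {
    r <- rank(m) / length(m)              # low rank = low intensity
    p_miss <- pmin(missing_rate * 2 * (1 - r), 1)
    m[stats::runif(length(m)) < p_miss] <- NA
  }
  rownames(m) <- protein
  colnames(m) <- paste0(rep(c("A", "B"), each = n_per_group),
                        seq_len(n_per_group))
  list(intensities = 2^m, peptides = sample(1:20, n_proteins, replace = TRUE),
       group = group,
       truth = data.frame(protein = protein, changed = changed,
                          effect_log2 = eff, stringsAsFactors = FALSE))
}
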