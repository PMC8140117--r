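#' Default pipeline configuration
#'
#' All tunables with their standard defaults: MA offset \code{o = 1}, LOESS
#' span 1/4 with 4 robustness iterations, central-cloud mask (-3, 1),
#' selection cutoff 1e-5, motif window 41 nt, 200,000 background sequences,
#' k = 3 clusters, FDR 0.05, minimum expected frequency 5, proteomics filter
#' (2 peptides, 4 missing).
#'
#' @param ... Overrides of individual fields.
#' @return A named list (class \code{pipeline_config}).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    o = 1, span = 1 / 4, degree = 1, robust_iterations = 4,
    mask_lo = -3, mask_hi = 1, cutoff = 1e-5,
    window_size = 41, n_background = 200000,
    k = 3, fdr = 0.05, min_expected = 5,
    min_peptides = 2, max_missing = 4,
    seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) stop("unknown config fields: ",
                                 paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

write_manifest <- function(cfg, path, extra = list()) {
  vals <- c(unclass(cfg), extra)
  writeLines(sprintf("%s\t%s", names(vals),
                     vapply(vals, function(v) paste(format(v), collapse = ","),
                            "")), path)
  invisible(path)
}

#' Run the CLIP compartment-enrichment pipeline
#'
#' Stages, in order: TMM effective library sizes, M/A computation, robust
#' LOESS fit and adjustment, central-cloud common dispersion, per-peak LRT,
#' forward selection at the p-value cutoff, reverse-contrast selection at the
#' matched-count cutoff, and — when an annotation (and genome/reads) is
#' supplied — peak classification, motif windows, and background sequences.
#'
#' @param peaks \code{GRanges} with \code{peak_id}, \code{count_x},
#'   \code{count_y} metadata columns (see \code{\link{count_reads_in_peaks}}
#'   or \code{\link{simulate_clip_experiment}}).
#' @param lib_size_x,lib_size_y Raw library sizes (reads mapping to peaks).
#' @param config A \code{\link{pipeline_config}}.
#' @param annotation Optional \code{genome_annotation} for classification.
#' @param genome Optional \code{DNAStringSet} for sequence windows.
#' @param reads_x Optional \code{GRanges} of compartment-sample reads (peak
#'   centers, background coverage).
#' @param out_dir Optional directory; when given, result tables, BED, FASTA
#'   and a parameter manifest are written there.
#' @return A list with \code{forward} (ranked enrichment table),
#'   \code{reverse}, \code{selected} (forward \code{p < cutoff}),
#'   \code{reverse_selected} (matched count), \code{dispersion},
#'   \code{reverse_cutoff}, and when annotated: \code{classes},
#'   \code{feature_percent}, \code{windows}, \code{background}.
#' @export
run_clip_pipeline <- function(peaks, lib_size_x, lib_size_y,
                              config = pipeline_config(),
                              annotation = NULL, genome = NULL,
                              reads_x = NULL, out_dir = NULL) {
  x <- peaks$count_x; y <- peaks$count_y
  if (is.null(x) || is.null(y)) stop("peaks must carry count_x / count_y")
  counts <- cbind(x = x, y = y)
  nf <- tmm_factors(counts, lib_sizes = c(lib_size_x, lib_size_y))
  eff <- nf$effective_lib_sizes

  run_dir <- function(direction) {
    prof <- ma_profile(peaks$peak_id, x, y, eff[1L], eff[2L], o = config$o,
                       direction = direction, span = config$span,
                       degree = config$degree,
                       robust_iterations = config$robust_iterations)
    enrichment_test(prof, config$mask_lo, config$mask_hi)
  }
  fwd <- run_dir("x_vs_y")
  fwd_ranked <- select_peaks(fwd, cutoff = config$cutoff)
  n_sel <- sum(fwd_ranked$selected)
  rev <- run_dir("y_vs_x")
  rev_sel <- if (n_sel > 0L) matched_count_cutoff(rev, n_sel) else NULL

  out <- list(forward = fwd_ranked,
              reverse = select_peaks(rev, cutoff = config$cutoff),
              selected = fwd_ranked[fwd_ranked$selected, , drop = FALSE],
              reverse_selected = rev_sel$selected,
              reverse_cutoff = rev_sel$cutoff,
              dispersion = attr(fwd, "dispersion"))

  if (!is.null(annotation)) {
    sel_ids <- out$selected$peak_id
    sel_peaks <- peaks[match(sel_ids, peaks$peak_id)]
    centers <- NULL
    if (!is.null(reads_x) && length(sel_peaks) > 0L) {
      centers <- vapply(seq_along(sel_peaks), function(i)
        peak_center(BiocGenerics::start(sel_peaks)[i],
                    peak_coverage(sel_peaks[i], reads_x))$center, 0L)
    }
    out$classes <- classify_peaks(sel_peaks, annotation, centers = centers)
    out$feature_percent <- if (nrow(out$classes) > 0L)
      feature_distribution(out$classes$class) else NULL
    if (!is.null(genome) && !is.null(centers) && length(sel_peaks) > 0L) {
      seqs <- vapply(seq_along(sel_peaks), function(i) extract_window(
        centers[i],
        as.character(GenomicRanges::seqnames(sel_peaks)[i]),
        as.character(BiocGenerics::strand(sel_peaks)[i]),
        genome, size = config$window_size), "")
      names(seqs) <- sel_ids
      out$windows <- seqs[!is.na(seqs)]
      bg_class <- names(which.max(table(out$classes$class[
        out$classes$class != "intergenic"])))
      if (!is.null(bg_class)) {
        out$background <- sample_background(
          annotation, genome, reads_x, bg_class,
          n = config$n_background, size = config$window_size,
          seed = config$seed)
      }
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_tsv(out$forward, file.path(out_dir, "enrichment.tsv"))
    write_results_tsv(out$reverse, file.path(out_dir, "enrichment_reverse.tsv"))
    sel_peaks <- peaks[match(out$selected$peak_id, peaks$peak_id)]
    if (length(sel_peaks) > 0L)
      write_peaks_bed(sel_peaks, file.path(out_dir, "selected_peaks.bed"))
    if (!is.null(out$classes))
      write_results_tsv(out$classes, file.path(out_dir, "peak_classes.tsv"))
    if (!is.null(out$windows))
      write_fasta(out$windows, file.path(out_dir, "motif_targets.fa"))
    if (!is.null(out$background))
      write_fasta(out$background$sequences,
                  file.path(out_dir, "motif_background.fa"))
    write_manifest(config, file.path(out_dir, "manifest.tsv"),
                   extra = list(lib_size_x = lib_size_x,
                                lib_size_y = lib_size_y,
                                phi = out$dispersion$phi,
                                n_selected = n_sel))
  }
  out
}

#' Run the stability time-course pipeline
#'
#' Per time point: two-group NB differential test at the given FDR. Genes
#' significant at any time point are split by the sign of their logFC at
#' their most significant time point into increased/decreased sets; each set
#' is clustered on its across-time logFC profile with correlation distance
#' \eqn{(1-R)/2} and average linkage, cut into k groups. Optional
#' target-set enrichment (one-sided Fisher) and direction association
#' (Pearson chi-squared with the expected-frequency guard).
#'
#' @param counts Named list of count matrices (genes x samples), one per time
#'   point; equal rownames across time points.
#' @param group Two-level factor over each matrix's columns (genotype).
#' @param config A \code{\link{pipeline_config}}.
#' @param expressed Optional logical vector (gene universe filter).
#' @param targets Optional character vector of target gene ids for the
#'   enrichment/association reports.
#' @param out_dir Optional output directory.
#' @return A list with \code{de} (per-time-point results),
#'   \code{significant}, \code{increased}, \code{decreased} (gene id
#'   vectors), \code{profiles} (logFC matrix), \code{clusters} (per set),
#'   \code{fisher}, \code{chisq}.
#' @export
run_stability_pipeline <- function(counts, group, config = pipeline_config(),
                                   expressed = NULL, targets = NULL,
                                   out_dir = NULL) {
  genes <- rownames(counts[[1L]])
  if (!is.null(expressed)) {
    counts <- lapply(counts, function(m) m[expressed, , drop = FALSE])
    genes <- rownames(counts[[1L]])
  }
  de <- lapply(counts, nb_de_two_group, group = group)
  sig_any <- Reduce(`|`, lapply(de, function(d) d$q < config$fdr))
  lfc <- vapply(de, function(d) d$logFC, numeric(length(genes)))
  qmat <- vapply(de, function(d) d$q, numeric(length(genes)))
  best_tp <- apply(qmat, 1, which.min)
  best_lfc <- lfc[cbind(seq_along(genes), best_tp)]
  significant <- genes[sig_any]
  increased <- genes[sig_any & best_lfc > 0]
  decreased <- genes[sig_any & best_lfc < 0]

  cluster_set <- function(ids) {
    if (length(ids) < config$k) return(NULL)
    prof <- lfc[match(ids, genes), , drop = FALSE]
    rownames(prof) <- ids
    cd <- correlation_distance(prof)
    stats::setNames(average_linkage_cut(cd$d, k = config$k), ids)
  }
  clusters <- list(increased = cluster_set(increased),
                   decreased = cluster_set(decreased))

  fisher <- NULL; chisq <- NULL
  if (!is.null(targets)) {
    targets <- intersect(targets, genes)
    fisher <- list(
      increased = fisher_one_sided(length(intersect(targets, increased)),
                                   K = length(targets),
                                   n = length(increased), N = length(genes)),
      decreased = fisher_one_sided(length(intersect(targets, decreased)),
                                   K = length(targets),
                                   n = length(decreased), N = length(genes)))
    dir3 <- ifelse(genes %in% increased, "up",
                   ifelse(genes %in% decreased, "down", "unchanged"))
    tab <- table(target = genes %in% targets, direction = dir3)
    chisq <- chi_square_association(tab, min_expected = config$min_expected)
  }

  out <- list(de = de, significant = significant, increased = increased,
              decreased = decreased,
              profiles = stats::setNames(as.data.frame(lfc), names(counts)),
              clusters = clusters, fisher = fisher, chisq = chisq)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (tp in names(de))
      write_results_tsv(de[[tp]], file.path(out_dir, paste0("de_", tp, ".tsv")))
    for (s in names(clusters)) {
      if (is.null(clusters[[s]])) next
      write_results_tsv(
        data.frame(gene_id = names(clusters[[s]]),
                   cluster = unname(clusters[[s]])),
        file.path(out_dir, paste0("clusters_", s, ".tsv")))
    }
    write_manifest(config, file.path(out_dir, "manifest.tsv"),
                   extra = list(n_significant = length(significant)))
  }
  out
}
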