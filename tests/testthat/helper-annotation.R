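# Hand-built toy annotation with overlapping genes engineered to exercise
# every feature class and every precedence conflict. Coordinates 1-based
# inclusive on chromosome "chrT".
#
# geneA (+): exons [1001,1200],[1401,1800], CDS 1101..1600
#            -> 5'UTR [1001,1100], CDS ex [1101,1200]+[1401,1600],
#               3'UTR [1601,1800], intron [1201,1400]
# geneB (-): exons [2001,2400],[2601,2900], CDS 2201..2700
#            -> 5'UTR [2701,2900] (high side), 3'UTR [2001,2200],
#               intron [2401,2600]
# geneC (+): non-coding single exon [3001,3300]
# geneE (+): exons [950,1050],[1900,2000], CDS 960..1950
#            -> intron [1051,1899] blankets all of geneA
# geneF (+): single exon [2650,2950], CDS 2700..2850
#            -> 3'UTR [2851,2950] overlaps geneB's 5'UTR
# geneG (+): exons [2980,3000],[3400,3420], CDS 2985..3410
#            -> intron [3001,3399] blankets geneC's exon
toy_annotation <- function() {
  gr <- function(starts, ends, strand, gid, tid) {
    g <- GenomicRanges::GRanges("chrT", IRanges::IRanges(starts, ends),
                                strand = strand)
    g$gene_id <- gid; g$transcript_id <- tid
    g
  }
  exons <- c(
    gr(c(1001, 1401), c(1200, 1800), "+", "geneA", "geneA.t1"),
    gr(c(2001, 2601), c(2400, 2900), "-", "geneB", "geneB.t1"),
    gr(3001, 3300, "+", "geneC", "geneC.t1"),
    gr(c(950, 1900), c(1050, 2000), "+", "geneE", "geneE.t1"),
    gr(2650, 2950, "+", "geneF", "geneF.t1"),
    gr(c(2980, 3400), c(3000, 3420), "+", "geneG", "geneG.t1"))
  cds <- c(
    gr(c(1101, 1401), c(1200, 1600), "+", "geneA", "geneA.t1"),
    gr(c(2201, 2601), c(2400, 2700), "-", "geneB", "geneB.t1"),
    gr(c(960, 1900), c(1050, 1950), "+", "geneE", "geneE.t1"),
    gr(2700, 2850, "+", "geneF", "geneF.t1"),
    gr(c(2985, 3400), c(3000, 3410), "+", "geneG", "geneG.t1"))
  build_annotation(exons, cds)
}

# 12 centers with their expected classes (precedence conflicts noted)
toy_truth_table <- function() {
  data.frame(
    center = c(1020, 1150, 1300, 1700, 2100, 2500,
               2870, 2990, 3100, 3415, 5000, 1000),
    class = c(
      "five_prime_utr",   # geneA 5'UTR vs geneE CDS exon
      "exon",             # geneA CDS vs geneE intron
      "intron",           # intron of both geneA and geneE
      "three_prime_utr",  # geneA 3'UTR vs geneE intron
      "three_prime_utr",  # geneB 3'UTR (minus strand, low side)
      "intron",           # geneB intron
      "three_prime_utr",  # geneF 3'UTR vs geneB 5'UTR
      "exon",             # geneG CDS
      "exon",             # geneC non-coding exon vs geneG intron
      "three_prime_utr",  # geneG 3'UTR
      "intergenic",
      "exon"),            # geneE CDS exon end vs geneA 5'UTR? no: 1000 < 1001, pure geneE CDS
    stringsAsFactors = FALSE)
}

toy_peaks_at <- function(centers) {
  g <- GenomicRanges::GRanges("chrT",
                              IRanges::IRanges(centers - 5L, centers + 5L),
                              strand = "+")
  g$peak_id <- sprintf("tp%02d", seq_along(centers))
  g
}
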