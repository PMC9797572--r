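stopCodons <- c("TAA", "TAG", "TGA")

#' Simulate a toy genome with analytically known dN/dS structure
#'
#' Builds a small annotated genome whose per-site nonsynonymous
#' probabilities under uniform SNP placement are known by codon-table
#' enumeration, for exercising [classifySnp()], [dndsPermutation()] and
#' [multihitSimulation()] against exact oracles. Three compositions:
#'
#' * `"mixed"`: ORFs start with ATG, end with TAA, internal codons drawn
#'   uniformly from the 61 sense codons.
#' * `"allTGG"`: every codon is TGG (Trp) -- all nine single-base changes of
#'   TGG are nonsynonymous, so every possible SNP in every ORF is
#'   nonsynonymous (start codons relaxed).
#' * `"fourfold"`: every codon has a fourfold-degenerate third position
#'   (Ala/Gly/Pro/Thr/Val/Ser4/Arg4/Leu4 families), so all third-position
#'   substitutions are synonymous (start codons relaxed).
#'
#' ORFs are non-overlapping, all on the plus strand unless `minusStrand`
#' marks some, separated by random intergenic spacers.
#'
#' @param nOrfs number of ORFs.
#' @param orfCodons codons per ORF (so ORF length is `3 * orfCodons`).
#' @param composition `"mixed"`, `"allTGG"` or `"fourfold"`.
#' @param intergenic spacer length between ORFs, bp.
#' @param minusStrand indices of ORFs placed on the minus strand.
#' @param seed RNG seed.
#' @return list: `genome` (a [GenomeAnnotation-class]), `qTs`, `qTv` (the
#'   analytic per-placement nonsynonymous probabilities for a transition /
#'   transversion), `composition`.
#' @export
simToyGenome <- function(nOrfs = 5L, orfCodons = 100L,
                         composition = c("mixed", "allTGG", "fourfold"),
                         intergenic = 30L, minusStrand = integer(0), seed = 1L) {
  composition <- match.arg(composition)
  if (nOrfs < 1L || orfCodons < 2L) stop("degenerate genome")
  bases <- c("A", "C", "G", "T")
  allCodons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(allCodons, stopCodons)
  fourfoldPrefix <- c("GC", "GG", "CC", "AC", "GT", "TC", "CG", "CT")

  withSeed(seed, {
    orfSeqs <- lapply(seq_len(nOrfs), function(i) {
      cods <- switch(composition,
        mixed = c("ATG", sample(sense, orfCodons - 2L, replace = TRUE), "TAA"),
        allTGG = rep("TGG", orfCodons),
        fourfold = paste0(sample(fourfoldPrefix, orfCodons, replace = TRUE),
                          sample(bases, orfCodons, replace = TRUE)))
      paste(cods, collapse = "")
    })
    spacers <- vapply(seq_len(nOrfs + 1L), function(i)
      paste(sample(bases, intergenic, replace = TRUE), collapse = ""),
      character(1))

    seq <- spacers[1]
    starts <- integer(nOrfs); ends <- integer(nOrfs)
    for (i in seq_len(nOrfs)) {
      starts[i] <- nchar(seq) + 1L
      seq <- paste0(seq, orfSeqs[[i]])
      ends[i] <- nchar(seq)
      seq <- paste0(seq, spacers[i + 1L])
    }
    strand <- rep("+", nOrfs)
    strand[minusStrand] <- "-"
    # a minus-strand ORF is stored as the reverse complement on the genome
    if (length(minusStrand)) {
      for (i in minusStrand) {
        rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(orfSeqs[[i]])))
        substr(seq, starts[i], ends[i]) <- rc
      }
    }
    genome <- genomeAnnotation(seq,
      data.frame(start = starts, end = ends, strand = strand,
                 gene = sprintf("gene%02d", seq_len(nOrfs))))
    q <- nonsynProbability(genome)
    list(genome = genome, qTs = q$qTs, qTv = q$qTv, composition = composition)
  })
}

#' Write / read a genome annotation as FASTA + GFF3
#'
#' @param genome a [GenomeAnnotation-class].
#' @param fasta,gff file paths.
#' @return `writeGenomeAnnotation` the paths invisibly;
#'   `readGenomeAnnotation` a [GenomeAnnotation-class].
#' @export
writeGenomeAnnotation <- function(genome, fasta, gff) {
  stopifnot(is(genome, "GenomeAnnotation"))
  ss <- Biostrings::DNAStringSet(genome@sequence)
  names(ss) <- "genome"
  Biostrings::writeXStringSet(ss, fasta)
  gr <- genome@orfs
  mc <- S4Vectors::DataFrame(type = "CDS", ID = names(gr), Name = names(gr),
                             phase = 0L)
  S4Vectors::mcols(gr) <- mc
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta = fasta, gff = gff))
}

#' @rdname writeGenomeAnnotation
#' @export
readGenomeAnnotation <- function(fasta, gff) {
  ss <- Biostrings::readDNAStringSet(fasta)
  gr <- rtracklayer::import(gff, format = "gff3")
  if (!is.null(gr$type)) gr <- gr[as.character(gr$type) %in% c("CDS", "gene")]
  nm <- if (!is.null(gr$Name)) as.character(gr$Name)
        else if (!is.null(gr$ID)) as.character(gr$ID)
        else paste0("orf", seq_along(gr))
  gr2 <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::IRanges(GenomicRanges::start(gr),
                                                 GenomicRanges::end(gr)),
                                strand = GenomicRanges::strand(gr))
  names(gr2) <- nm
  genomeAnnotation(ss[[1]], gr2)
}
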