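# VCF output and BAM input. Both go through the Bioconductor stack
# (VariantAnnotation, Rsamtools, GenomicAlignments), loaded on demand.

.need <- function(pkgs) {
  for (p in pkgs) {
    if (!requireNamespace(p, quietly = TRUE)) {
      stop("package '", p, "' is required for this operation")
    }
  }
}

#' Write calls to VCF 4.x
#'
#' One record per call, 1-based positions; `FILTER` is `PASS` for pass
#' calls and `HOLD` for held ones; `INFO` carries `VAF`, `CLUSTER`,
#' `THETA` (the call's cluster frequency) and `NCONF` (classifier-confirmed
#' supporting reads). The header records the tumor fraction, a configuration
#' hash and the seed. An empty call set yields a valid header-only VCF.
#'
#' @param callset An `snv_callset` from [call_variants()], or a call
#'   data.frame (then supply `tumor_fraction`).
#' @param path Output path (`.vcf` or `.vcf.gz` by extension).
#' @param tumor_fraction,seed Metadata overrides.
#' @return The path, invisibly.
#' @export
write_vcf <- function(callset, path, tumor_fraction = NULL, seed = NULL) {
  .need(c("VariantAnnotation", "GenomicRanges", "IRanges", "S4Vectors",
          "Biostrings"))
  DF <- S4Vectors::DataFrame
  if (inherits(callset, "snv_callset")) {
    calls <- callset$calls
    if (is.null(tumor_fraction)) tumor_fraction <- callset$tumor_fraction
    if (is.null(seed)) seed <- callset$config$seed
  } else {
    calls <- callset
  }
  n <- nrow(calls)
  cfg_hash <- sprintf("%08x", sum(utils::head(utf8ToInt(paste(
    collapse = "", names(calls))), 512)))

  if (n) {
    gr <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$pos, width = 1L))
    names(gr) <- sprintf("%s:%d_%s/%s", calls$chrom, calls$pos,
                         calls$ref, calls$alt)
    fixed <- DF(REF = Biostrings::DNAStringSet(calls$ref),
                ALT = Biostrings::DNAStringSetList(as.list(calls$alt)),
                QUAL = rep(NA_real_, n),
                FILTER = ifelse(calls$category == "pass", "PASS", "HOLD"))
    info <- DF(VAF = as.numeric(calls$vaf),
               CLUSTER = as.integer(calls$cluster_index),
               THETA = as.numeric(calls$cluster_theta),
               NCONF = as.integer(calls$n_confirmed))
  } else {
    gr <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo("unplaced"))
    fixed <- DF(REF = Biostrings::DNAStringSet(character()),
                ALT = Biostrings::DNAStringSetList(),
                QUAL = numeric(), FILTER = character())
    info <- DF(VAF = numeric(), CLUSTER = integer(),
               THETA = numeric(), NCONF = integer())
  }

  hdr_info <- DF(
    Number = rep("1", 4L),
    Type = c("Float", "Integer", "Float", "Integer"),
    Description = c("Variant allele frequency",
                    "Mutation cluster index (1 = most frequent)",
                    "Cluster frequency theta of the call's cluster",
                    "Classifier-confirmed variant-supporting reads"),
    row.names = c("VAF", "CLUSTER", "THETA", "NCONF"))
  hdr_filter <- DF(
    Description = c("All filters passed",
                    "Non-essential site filter failed; call retained"),
    row.names = c("PASS", "HOLD"))
  fmt_df <- DF(Value = "VCFv4.2", row.names = "fileformat")
  meta_df <- DF(Value = c("plasmasnv",
                          sprintf("%.6f", ifelse(is.null(tumor_fraction) ||
                                                   is.na(tumor_fraction),
                                                 NA_real_, tumor_fraction)),
                          cfg_hash,
                          as.character(ifelse(is.null(seed), NA, seed))),
                row.names = c("source", "tumor_fraction",
                              "config_hash", "seed"))
  hdr <- VariantAnnotation::VCFHeader(
    samples = character(0),
    header = IRanges::DataFrameList(fileformat = fmt_df, META = meta_df,
                                    INFO = hdr_info, FILTER = hdr_filter))

  vcf <- VariantAnnotation::VCF(rowRanges = gr, fixed = fixed, info = info,
                                colData = DF(row.names = character(0)),
                                collapsed = TRUE)
  VariantAnnotation::header(vcf) <- hdr
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Read a plasmasnv VCF back into a call table
#'
#' @param path VCF path.
#' @return Data frame with chrom, pos, ref, alt, filter and the INFO fields.
#' @export
read_vcf_calls <- function(path) {
  .need(c("VariantAnnotation", "GenomicRanges", "S4Vectors"))
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = if (length(rr)) alt else character(),
    filter = as.character(rr$FILTER),
    vaf = as.numeric(info$VAF),
    cluster_index = as.integer(info$CLUSTER),
    cluster_theta = as.numeric(info$THETA),
    n_confirmed = as.integer(info$NCONF),
    stringsAsFactors = FALSE
  )
}

# flag -> strand
.sam_strand <- function(flag) ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")

#' Import read pairs from a coordinate-sorted, indexed BAM
#'
#' Reads alignments (optionally restricted to a region), lays their
#' sequences and qualities onto reference space (insertions removed,
#' deletions gap-filled with `-`, which contribute no pileup observation),
#' and pairs mates by query name. Paired records become [read_pair()]s
#' ready for [merge_read_pair()]; unpaired records are returned as
#' single-end consensus records.
#'
#' @param bam Path to an indexed BAM file.
#' @param chrom,start,end Optional region restriction.
#' @return List of `read_pair` / `merged_read` objects.
#' @export
bam_read_pairs <- function(bam, chrom = NULL, start = NULL, end = NULL) {
  .need(c("Rsamtools", "GenomicAlignments", "GenomicRanges", "IRanges",
          "S4Vectors", "Biostrings"))
  which <- if (!is.null(chrom)) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  } else NULL
  param <- if (is.null(which)) {
    Rsamtools::ScanBamParam(what = c("qname", "flag", "mapq", "seq", "qual"))
  } else {
    Rsamtools::ScanBamParam(what = c("qname", "flag", "mapq", "seq", "qual"),
                            which = which)
  }
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  if (!length(ga)) return(list())
  mc <- S4Vectors::mcols(ga)
  cig <- GenomicAlignments::cigar(ga)
  seq_ref <- GenomicAlignments::sequenceLayer(mc$seq, cig)
  qual_ref <- GenomicAlignments::sequenceLayer(mc$qual, cig)
  bases <- strsplit(as.character(seq_ref), "")
  quals <- lapply(as(qual_ref, "IntegerList"), as.integer)
  starts <- GenomicAlignments::start(ga)
  chroms <- as.character(GenomicAlignments::seqnames(ga))
  strands <- .sam_strand(mc$flag)
  mapqs <- mc$mapq

  # deletion gap letters carry a bogus quality; mark them unusable
  for (i in seq_along(bases)) {
    gap <- bases[[i]] == "-"
    if (any(gap)) quals[[i]][gap] <- 0L
  }

  idx_by_name <- split(seq_along(ga), mc$qname)
  out <- lapply(idx_by_name, function(ix) {
    if (length(ix) >= 2L) {
      i1 <- ix[1L]
      i2 <- ix[2L]
      read_pair(bases[[i1]], quals[[i1]], bases[[i2]], quals[[i2]],
                mapq1 = mapqs[i1], mapq2 = mapqs[i2],
                start1 = starts[i1], start2 = starts[i2],
                strand1 = strands[i1], strand2 = strands[i2],
                read_id = mc$qname[i1], chrom = chroms[i1])
    } else {
      i1 <- ix[1L]
      structure(list(
        chrom = chroms[i1], bases = bases[[i1]], quals = quals[[i1]],
        mapq = mapqs[i1], strand = strands[i1],
        span = c(starts[i1], starts[i1] + length(bases[[i1]]) - 1L),
        fragment_length = length(bases[[i1]]),
        confirmed = rep(FALSE, length(bases[[i1]])),
        read_id = mc$qname[i1], mapq1 = mapqs[i1], mapq2 = mapqs[i1]
      ), class = "merged_read")
    }
  })
  unname(out)
}
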