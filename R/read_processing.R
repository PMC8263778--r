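# Read-pair merging and pileup construction.
#
# cfDNA fragments peak around 166 bp, so 2x100 (or 2x150) paired-end reads
# usually overlap in the middle of the fragment. The overlap carries two
# sequencing observations of the same template base: concordant calls are
# confirmed (boosted quality), discordant calls resolved toward the
# higher-quality mate. Merging also prevents double-counting a fragment at a
# locus covered by both mates, which would otherwise bias the VAF.

QUAL_CAP <- 60L
TIE_BASE_QUAL <- 2L

#' Construct a raw read pair
#'
#' A pair of mapped mates before merging. Coordinates are 1-based closed
#' reference intervals; qualities are Phred integers, one per base.
#'
#' @param read1_bases,read2_bases Character vectors of base calls (or single
#'   strings, which are split).
#' @param read1_quals,read2_quals Integer Phred base qualities, same lengths.
#' @param mapq1,mapq2 Phred mapping qualities.
#' @param start1,start2 1-based reference start of each mate's aligned span.
#' @param strand1,strand2 `"+"` or `"-"`.
#' @param read_id Opaque fragment identifier.
#' @param chrom Reference sequence name.
#' @return An object of class `read_pair`.
#' @export
read_pair <- function(read1_bases, read1_quals, read2_bases, read2_quals,
                      mapq1, mapq2, start1, start2,
                      strand1 = "+", strand2 = "-",
                      read_id = "frag", chrom = "chr1") {
  split1 <- if (length(read1_bases) == 1L && nchar(read1_bases[1L]) > 1L)
    strsplit(read1_bases, "")[[1L]] else read1_bases
  split2 <- if (length(read2_bases) == 1L && nchar(read2_bases[1L]) > 1L)
    strsplit(read2_bases, "")[[1L]] else read2_bases
  if (length(split1) != length(read1_quals) ||
      length(split2) != length(read2_quals)) {
    stop("base and quality strings must have equal length")
  }
  span1 <- c(start1, start1 + length(split1) - 1L)
  span2 <- c(start2, start2 + length(split2) - 1L)
  structure(list(
    chrom = chrom,
    read1_bases = split1, read1_quals = as.numeric(read1_quals),
    read2_bases = split2, read2_quals = as.numeric(read2_quals),
    mapq1 = mapq1, mapq2 = mapq2,
    strand1 = strand1, strand2 = strand2,
    aligned_span1 = span1, aligned_span2 = span2,
    fragment_length = max(span1[2L], span2[2L]) - min(span1[1L], span2[1L]) + 1L,
    read_id = read_id
  ), class = "read_pair")
}

#' Merge overlapping read mates into a consensus record
#'
#' When the aligned spans of the two mates overlap by at least `min_overlap`
#' bases and the fraction of discordant bases in the overlap is at most
#' `max_mismatch_density`, the pair is collapsed into a single consensus
#' record covering the whole fragment. Within the overlap, concordant bases
#' are kept with a boosted quality `min(q1 + q2, 60)` and marked confirmed;
#' discordant bases are corrected to the call with the higher base quality
#' (keeping the winner's quality); quality ties are unresolvable and emit `N`
#' at quality 2. Outside the overlap, each mate contributes its own calls.
#' Non-overlapping pairs (or pairs on different chromosomes, or pairs failing
#' the thresholds) are returned unchanged. Merging a previously merged record
#' is a no-op.
#'
#' @param pair A [read_pair()] or an already-merged `merged_read`.
#' @param min_overlap Minimum overlap length in bp (default 10).
#' @param max_mismatch_density Maximum discordant fraction in the overlap
#'   (default 0.25).
#' @return A `merged_read` (single-end consensus) or the input `read_pair`.
#' @export
merge_read_pair <- function(pair, min_overlap = 10L, max_mismatch_density = 0.25) {
  if (inherits(pair, "merged_read")) return(pair)
  stopifnot(inherits(pair, "read_pair"))
  s1 <- pair$aligned_span1
  s2 <- pair$aligned_span2
  ov_start <- max(s1[1L], s2[1L])
  ov_end <- min(s1[2L], s2[2L])
  ov_len <- ov_end - ov_start + 1L
  if (ov_len < min_overlap) return(pair)

  pos <- min(s1[1L], s2[1L]):max(s1[2L], s2[2L])
  idx1 <- match(pos, s1[1L]:s1[2L])
  idx2 <- match(pos, s2[1L]:s2[2L])
  b1 <- pair$read1_bases[idx1]
  q1 <- pair$read1_quals[idx1]
  b2 <- pair$read2_bases[idx2]
  q2 <- pair$read2_quals[idx2]

  in_ov <- !is.na(idx1) & !is.na(idx2)
  discord <- in_ov & b1 != b2
  if (sum(discord) / ov_len > max_mismatch_density) return(pair)

  bases <- ifelse(is.na(idx1), b2, b1)
  quals <- ifelse(is.na(idx1), q2, q1)
  confirmed <- rep(FALSE, length(pos))

  agree <- in_ov & b1 == b2
  bases[agree] <- b1[agree]
  quals[agree] <- pmin(q1[agree] + q2[agree], QUAL_CAP)
  confirmed[agree] <- TRUE

  r2_wins <- discord & q2 > q1
  bases[r2_wins] <- b2[r2_wins]
  quals[r2_wins] <- q2[r2_wins]
  r1_wins <- discord & q1 > q2
  bases[r1_wins] <- b1[r1_wins]
  quals[r1_wins] <- q1[r1_wins]
  tie <- discord & q1 == q2
  bases[tie] <- "N"
  quals[tie] <- TIE_BASE_QUAL

  structure(list(
    chrom = pair$chrom,
    bases = bases, quals = quals,
    mapq = max(pair$mapq1, pair$mapq2),
    strand = pair$strand1,
    span = c(pos[1L], pos[length(pos)]),
    fragment_length = length(pos),
    confirmed = confirmed,
    read_id = pair$read_id,
    mapq1 = pair$mapq1, mapq2 = pair$mapq2
  ), class = "merged_read")
}

#' Single-locus pileup container
#'
#' All read observations at one genomic position in one sample. Observations
#' are rows of a data.frame with columns `base`, `bq` (base quality), `mq`
#' (mapping quality), `strand`, `d5p`, `d3p` (offset of the locus from the
#' fragment ends), `flen`, `confirmed` (base seen concordantly in both
#' mates), `merged`, `read_id`, and optionally mate/context feature columns.
#'
#' @param chrom,pos Locus coordinates (1-based).
#' @param ref Reference allele.
#' @param obs Observation data.frame (may have zero rows).
#' @param alt Alternate allele, or `NA` to derive it as the most frequent
#'   non-reference base.
#' @param sample_role `"plasma"`, `"germline"` or `"tumor_biopsy"`.
#' @return An object of class `locus_pileup`.
#' @export
locus_pileup <- function(chrom, pos, ref, obs, alt = NA_character_,
                         sample_role = "plasma") {
  obs <- as.data.frame(obs, stringsAsFactors = FALSE)
  if (is.na(alt) && nrow(obs)) {
    nonref <- obs$base[obs$base != ref & obs$base != "N"]
    if (length(nonref)) {
      tab <- sort(table(nonref), decreasing = TRUE)
      alt <- names(tab)[1L]
    }
  }
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 obs = obs, sample_role = sample_role),
            class = "locus_pileup")
}

#' @export
print.locus_pileup <- function(x, ...) {
  cat(sprintf("<locus_pileup> %s:%d %s>%s depth=%d alt=%d (%s)\n",
              x$chrom, x$pos, x$ref,
              ifelse(is.na(x$alt), "?", x$alt),
              nrow(x$obs), pileup_alt_count(x), x$sample_role))
  invisible(x)
}

pileup_depth <- function(p) nrow(p$obs)

pileup_alt_count <- function(p) {
  if (is.na(p$alt) || !nrow(p$obs)) return(0L)
  sum(p$obs$base == p$alt)
}

pileup_vaf <- function(p) {
  d <- pileup_depth(p)
  if (d == 0L) return(NA_real_)
  pileup_alt_count(p) / d
}

#' Build a locus pileup from merged/unmerged alignment records
#'
#' Collects one observation per fragment covering `pos`: a merged consensus
#' record contributes exactly once, an unmerged pair contributes the mate
#' covering the locus (if both unmerged mates cover it, the higher-quality
#' call is used so that a fragment is never double-counted). Observations
#' below `quality_floor` are retained but flagged `below_floor`.
#'
#' @param alignments List of `merged_read` / `read_pair` records.
#' @param chrom,pos Locus (1-based).
#' @param ref Reference allele at the locus.
#' @param quality_floor Named numeric `c(base, map)` minimum qualities used
#'   only for flagging (default `c(base = 13, map = 20)`).
#' @param sample_role Stored on the result.
#' @return A [locus_pileup()]; depth 0 if no record covers the locus.
#' @export
build_pileup <- function(alignments, chrom, pos, ref,
                         quality_floor = c(base = 13, map = 20),
                         sample_role = "plasma") {
  rows <- lapply(alignments, function(a) {
    if (inherits(a, "merged_read")) {
      if (a$chrom != chrom || pos < a$span[1L] || pos > a$span[2L]) return(NULL)
      i <- pos - a$span[1L] + 1L
      if (a$bases[i] == "-") return(NULL)  # deletion spans the locus
      data.frame(base = a$bases[i], bq = a$quals[i], mq = a$mapq,
                 strand = a$strand, d5p = i - 1L,
                 d3p = a$fragment_length - i,
                 flen = a$fragment_length, confirmed = a$confirmed[i],
                 merged = TRUE, read_id = a$read_id,
                 stringsAsFactors = FALSE)
    } else if (inherits(a, "read_pair")) {
      if (a$chrom != chrom) return(NULL)
      frag_start <- min(a$aligned_span1[1L], a$aligned_span2[1L])
      hit1 <- pos >= a$aligned_span1[1L] && pos <= a$aligned_span1[2L]
      hit2 <- pos >= a$aligned_span2[1L] && pos <= a$aligned_span2[2L]
      if (!hit1 && !hit2) return(NULL)
      b1 <- if (hit1) a$read1_bases[pos - a$aligned_span1[1L] + 1L] else NA
      q1 <- if (hit1) a$read1_quals[pos - a$aligned_span1[1L] + 1L] else -Inf
      b2 <- if (hit2) a$read2_bases[pos - a$aligned_span2[1L] + 1L] else NA
      q2 <- if (hit2) a$read2_quals[pos - a$aligned_span2[1L] + 1L] else -Inf
      use1 <- hit1 && (!hit2 || q1 >= q2)
      if ((if (use1) b1 else b2) == "-") return(NULL)
      data.frame(base = if (use1) b1 else b2,
                 bq = if (use1) q1 else q2,
                 mq = if (use1) a$mapq1 else a$mapq2,
                 strand = if (use1) a$strand1 else a$strand2,
                 d5p = pos - frag_start,
                 d3p = a$fragment_length - (pos - frag_start) - 1L,
                 flen = a$fragment_length, confirmed = FALSE,
                 merged = FALSE, read_id = a$read_id,
                 stringsAsFactors = FALSE)
    } else {
      stop("alignments must be read_pair or merged_read records")
    }
  })
  rows <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(rows)) {
    rows <- data.frame(base = character(), bq = numeric(), mq = numeric(),
                       strand = character(), d5p = integer(), d3p = integer(),
                       flen = integer(), confirmed = logical(),
                       merged = logical(), read_id = character(),
                       stringsAsFactors = FALSE)
  } else {
    rows$below_floor <- rows$bq < quality_floor[["base"]] |
      rows$mq < quality_floor[["map"]]
  }
  locus_pileup(chrom, pos, ref, rows, sample_role = sample_role)
}

#' Write / read the pileup dump TSV
#'
#' Plain-text exchange format for pileup observations, one row per
#' observation: `chrom pos ref base baseq mapq strand frag_len d5p d3p
#' confirmed read_id`.
#'
#' @param pileups A list of [locus_pileup()] objects.
#' @param path Output file.
#' @export
write_pileup_tsv <- function(pileups, path) {
  rows <- do.call(rbind, lapply(pileups, function(p) {
    if (!nrow(p$obs)) return(NULL)
    data.frame(chrom = p$chrom, pos = p$pos, ref = p$ref,
               base = p$obs$base, baseq = p$obs$bq, mapq = p$obs$mq,
               strand = p$obs$strand, frag_len = p$obs$flen,
               d5p = p$obs$d5p, d3p = p$obs$d3p,
               confirmed = p$obs$confirmed, read_id = p$obs$read_id,
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @param sample_role Role stored on each pileup.
#' @return `read_pileup_tsv`: a list of `locus_pileup` objects.
#' @export
read_pileup_tsv <- function(path, sample_role = "plasma") {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  split_idx <- paste(df$chrom, df$pos)
  lapply(split(df, split_idx), function(d) {
    locus_pileup(d$chrom[1L], d$pos[1L], d$ref[1L],
                 data.frame(base = d$base, bq = d$baseq, mq = d$mapq,
                            strand = d$strand, d5p = d$d5p, d3p = d$d3p,
                            flen = d$frag_len, confirmed = d$confirmed,
                            merged = d$confirmed | d$frag_len > 0,
                            read_id = d$read_id, stringsAsFactors = FALSE),
                 sample_role = sample_role)
  })
}

#' Assemble a pileup set from the dump TSV
#'
#' Reads the pileup dump format into the single-table `pileup_set`
#' representation the caller operates on.
#'
#' @inheritParams read_pileup_tsv
#' @param path TSV path (see [write_pileup_tsv()]).
#' @return A [pileup_set()].
#' @export
pileup_set_from_tsv <- function(path, sample_role = "plasma") {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  key <- paste(df$chrom, df$pos)
  ids <- match(key, unique(key))
  obs <- data.table::data.table(
    locus_id = ids, base = df$base, bq = df$baseq, mq = df$mapq,
    strand = df$strand, d5p = df$d5p, d3p = df$d3p, flen = df$frag_len,
    confirmed = df$confirmed, merged = TRUE,
    # the dump format does not carry the mate span; only confirmed bases are
    # known to come from overlapping pairs
    pair_overlap = df$confirmed,
    read_id = df$read_id)
  first <- !duplicated(ids)
  loci <- data.table::data.table(locus_id = ids[first],
                                 chrom = df$chrom[first],
                                 pos = df$pos[first], ref = df$ref[first])
  pileup_set(obs, loci, sample_role)
}
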