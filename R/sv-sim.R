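# Paired-end read simulation across a reciprocal translocation, plus plain
# SAM text I/O.

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random DNA sequence
#'
#' @param n length in bp
#' @return a character scalar over A/C/G/T (uses the session RNG)
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Describe the micro-event anatomy of a reciprocal translocation
#'
#' Junction model: derivative 1 joins `chrom_a[1..bp_a]` to
#' `chrom_b[bp_b + del_len + 1 ..]`, derivative 2 joins `chrom_b[1..bp_b]`
#' to `chrom_a[bp_a - dup_len + 1 ..]`. The `dup_len` bases of chrom_a
#' immediately upstream of `bp_a` are therefore present on both derivative
#' haplotypes, the `del_len` bases of chrom_b immediately downstream of
#' `bp_b` are missing from both, and an `insert_len`-bp motif copied from
#' just downstream of `bp_a` (reverse-complemented when `insert_revcomp`)
#' is templated into the derivative-1 junction only.
#'
#' @param chrom_a,chrom_b reference names of the two partners
#' @param bp_a,bp_b 1-based breakpoint positions (last retained base on the
#'   derivative-1 A side and derivative-2 B side respectively)
#' @param dup_len,del_len,insert_len micro-event lengths in bp (>= 0)
#' @param insert_revcomp logical; insert the motif reverse-complemented
#' @return a `breakpoint_anatomy` list
#' @export
breakpoint_anatomy <- function(chrom_a, bp_a, chrom_b, bp_b, dup_len = 0L,
                               del_len = 0L, insert_len = 0L,
                               insert_revcomp = FALSE) {
  stopifnot(dup_len >= 0, del_len >= 0, insert_len >= 0, bp_a > dup_len,
            bp_b >= 1)
  structure(list(chrom_a = chrom_a, bp_a = as.integer(bp_a),
                 chrom_b = chrom_b, bp_b = as.integer(bp_b),
                 dup_len = as.integer(dup_len), del_len = as.integer(del_len),
                 insert_len = as.integer(insert_len),
                 insert_revcomp = isTRUE(insert_revcomp)),
            class = "breakpoint_anatomy")
}

# map a derivative-coordinate segment [s, e] back to a reference alignment
.map_der1 <- function(s, e, an, ilen) {
  a <- an$bp_a
  len <- e - s + 1L
  m1 <- max(0L, min(e, a) - s + 1L)
  m2 <- max(0L, e - max(s - 1L, a + ilen))
  if (m1 == len) {
    list(chrom = an$chrom_a, pos = s, cigar = sprintf("%dM", len))
  } else if (m2 == len) {
    list(chrom = an$chrom_b, pos = s - (a + ilen) + an$bp_b + an$del_len,
         cigar = sprintf("%dM", len))
  } else if (m1 >= m2 && m1 > 0L) {
    list(chrom = an$chrom_a, pos = s, cigar = sprintf("%dM%dS", m1, len - m1))
  } else if (m2 > 0L) {
    list(chrom = an$chrom_b, pos = an$bp_b + an$del_len + 1L,
         cigar = sprintf("%dS%dM", len - m2, m2))
  } else NULL # entirely within the inserted motif
}

.map_der2 <- function(s, e, an) {
  b <- an$bp_b
  len <- e - s + 1L
  m1 <- max(0L, min(e, b) - s + 1L)
  m2 <- max(0L, e - max(s - 1L, b))
  if (m1 == len) {
    list(chrom = an$chrom_b, pos = s, cigar = sprintf("%dM", len))
  } else if (m2 == len) {
    list(chrom = an$chrom_a, pos = an$bp_a - an$dup_len + (s - b),
         cigar = sprintf("%dM", len))
  } else if (m1 >= m2) {
    list(chrom = an$chrom_b, pos = s, cigar = sprintf("%dM%dS", m1, len - m1))
  } else {
    list(chrom = an$chrom_a, pos = an$bp_a - an$dup_len + 1L,
         cigar = sprintf("%dS%dM", m1, m2))
  }
}

.apply_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate paired-end reads over a reciprocal translocation
#'
#' Emits FR paired-end reads from both derivative chromosomes of the
#' configured translocation plus concordant background pairs from the two
#' unrearranged references (the normal haplotypes of a heterozygous
#' carrier). Reads crossing a junction are soft-clipped in their CIGAR at
#' the junction, with the clipped bases carrying the partner-side (and any
#' inserted-motif) sequence; mate chromosome/position/insert fields are
#' consistent within every pair. A truth record with the exact junction
#' coordinates and micro-event anatomy accompanies the reads.
#'
#' @param ref_a,ref_b reference sequences (character scalars) for the two
#'   partner chromosomes
#' @param anatomy a [breakpoint_anatomy()]
#' @param depth target read depth over each derivative (0 emits only the
#'   truth record); background pairs are emitted at the same depth from the
#'   unrearranged references
#' @param insert_mean,insert_sd fragment-length distribution (bp)
#' @param read_len read length (bp); must not exceed `insert_mean`
#' @param base_error per-base substitution error rate
#' @param seed integer RNG seed; a fixed seed gives byte-identical output
#' @return list with `reads` (tibble of SAM fields), `truth`, and
#'   `ref_lengths`
#' @export
simulate_translocation_reads <- function(ref_a, ref_b, anatomy, depth = 30,
                                         insert_mean = 350, insert_sd = 35,
                                         read_len = 100, base_error = 0,
                                         seed = 1L) {
  stopifnot(inherits(anatomy, "breakpoint_anatomy"))
  if (read_len > insert_mean) {
    stop("configuration error: read_len exceeds the mean fragment length",
         call. = FALSE)
  }
  an <- anatomy
  La <- nchar(ref_a)
  Lb <- nchar(ref_b)
  stopifnot(an$bp_a + an$insert_len <= La, an$bp_b + an$del_len <= Lb)
  set.seed(seed)

  motif <- substr(ref_a, an$bp_a + 1L, an$bp_a + an$insert_len)
  ins <- if (an$insert_len > 0L && an$insert_revcomp) .revcomp(motif) else
    motif
  der1 <- paste0(substr(ref_a, 1L, an$bp_a), ins,
                 substr(ref_b, an$bp_b + an$del_len + 1L, Lb))
  der2 <- paste0(substr(ref_b, 1L, an$bp_b),
                 substr(ref_a, an$bp_a - an$dup_len + 1L, La))

  sources <- list(
    list(tag = "na", seq = ref_a, map = "ref", chrom = an$chrom_a),
    list(tag = "nb", seq = ref_b, map = "ref", chrom = an$chrom_b),
    list(tag = "d1", seq = der1, map = "der1"),
    list(tag = "d2", seq = der2, map = "der2"))

  rows <- list()
  for (src in sources) {
    L <- nchar(src$seq)
    n_pairs <- max(0L, as.integer(round(depth * L / (2 * read_len))))
    if (n_pairs == 0L) next
    frag <- pmax(read_len, as.integer(round(stats::rnorm(n_pairs,
                                                         insert_mean,
                                                         insert_sd))))
    frag <- pmin(frag, L)
    start <- 1L + as.integer(floor(stats::runif(n_pairs) * (L - frag + 1)))
    qual <- strrep("H", read_len)
    qname <- flag <- rname <- cigar <- rnext <- seq_ <- character(2L * n_pairs)
    pos <- pnext <- tlen <- integer(2L * n_pairs)
    used <- logical(2L * n_pairs)
    for (i in seq_len(n_pairs)) {
      s1 <- start[i]
      e1 <- s1 + read_len - 1L
      e2 <- s1 + frag[i] - 1L
      s2 <- e2 - read_len + 1L
      aln1 <- switch(src$map,
                     ref = list(chrom = src$chrom, pos = s1,
                                cigar = sprintf("%dM", read_len)),
                     der1 = .map_der1(s1, e1, an, an$insert_len),
                     der2 = .map_der2(s1, e1, an))
      aln2 <- switch(src$map,
                     ref = list(chrom = src$chrom, pos = s2,
                                cigar = sprintf("%dM", read_len)),
                     der1 = .map_der1(s2, e2, an, an$insert_len),
                     der2 = .map_der2(s2, e2, an))
      if (is.null(aln1) || is.null(aln2)) next # mate lost inside the insert
      seq1 <- .apply_errors(substr(src$seq, s1, e1), base_error)
      seq2 <- .apply_errors(substr(src$seq, s2, e2), base_error)
      same <- aln1$chrom == aln2$chrom
      span2 <- .cigar_ref_span(aln2$cigar)
      tlen1 <- if (same) aln2$pos + span2 - aln1$pos else 0L
      proper <- same && abs(tlen1) <= insert_mean + 4 * insert_sd
      base_flag <- 1L + if (proper) 2L else 0L
      j <- 2L * i - 1L
      used[j + 0:1] <- TRUE
      qname[j + 0:1] <- sprintf("%s_%05d", src$tag, i)
      flag[j] <- base_flag + 64L + 32L
      flag[j + 1L] <- base_flag + 128L + 16L
      rname[j + 0:1] <- c(aln1$chrom, aln2$chrom)
      pos[j + 0:1] <- c(aln1$pos, aln2$pos)
      cigar[j + 0:1] <- c(aln1$cigar, aln2$cigar)
      rnext[j + 0:1] <- c(aln2$chrom, aln1$chrom)
      pnext[j + 0:1] <- c(aln2$pos, aln1$pos)
      tlen[j + 0:1] <- if (same) c(tlen1, -tlen1) else c(0L, 0L)
      seq_[j + 0:1] <- c(seq1, seq2)
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      qname = qname[used], flag = as.integer(flag[used]),
      rname = rname[used], pos = pos[used], mapq = 60L,
      cigar = cigar[used], rnext = rnext[used], pnext = pnext[used],
      tlen = tlen[used], seq = seq_[used], qual = qual)
  }
  reads <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    qname = character(0), flag = integer(0), rname = character(0),
    pos = integer(0), mapq = integer(0), cigar = character(0),
    rnext = character(0), pnext = integer(0), tlen = integer(0),
    seq = character(0), qual = character(0))

  truth <- list(schema_version = 1L, chrom_a = an$chrom_a, bp_a = an$bp_a,
                chrom_b = an$chrom_b, bp_b = an$bp_b, dup_len = an$dup_len,
                del_len = an$del_len, insert_len = an$insert_len,
                insert_seq = ins, insert_revcomp = an$insert_revcomp)
  ref_lengths <- stats::setNames(c(La, Lb), c(an$chrom_a, an$chrom_b))
  list(reads = reads, truth = truth, ref_lengths = ref_lengths)
}

#' Write aligned reads as plain SAM text
#'
#' @param reads tibble of SAM fields as produced by
#'   [simulate_translocation_reads()]
#' @param ref_lengths named vector of reference sequence lengths
#' @param path output file
#' @return the path, invisibly
#' @export
write_sam <- function(reads, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)),
           "@CO\tmmrscreen sam schema_version=1")
  body <- if (nrow(reads)) {
    rnext <- ifelse(reads$rnext == reads$rname, "=", reads$rnext)
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
            reads$qname, reads$flag, reads$rname, reads$pos, reads$mapq,
            reads$cigar, rnext, reads$pnext, reads$tlen, reads$seq,
            reads$qual)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into the read tibble used by the scanner
#'
#' Parsing goes through Rsamtools (SAM -> BAM conversion followed by a full
#' scan), so standard flags, mate fields and CIGARs are handled as any
#' aligner emits them.
#'
#' @param path SAM file
#' @return tibble with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "mrnm", "mpos",
                                        "isize", "seq", "qual"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  tibble::tibble(
    qname = x$qname, flag = as.integer(x$flag),
    rname = as.character(x$rname), pos = x$pos, mapq = x$mapq,
    cigar = x$cigar, rnext = as.character(x$mrnm), pnext = x$mpos,
    tlen = x$isize, seq = as.character(x$seq), qual = as.character(x$qual))
}
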