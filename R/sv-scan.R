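# Discordant read-pair scan and breakpoint-anatomy inference.

# reference span consumed by a CIGAR (M/D/N/=/X)
.cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(1L)
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  }, 1L, USE.NAMES = FALSE)
}

.cigar_clip <- function(cigar, side = c("left", "right")) {
  side <- match.arg(side)
  pat <- if (side == "left") "^([0-9]+)S" else "([0-9]+)S$"
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    m <- regmatches(cg, regexpr(pat, cg))
    if (!length(m)) return(0L)
    as.integer(sub("S", "", m))
  }, 1L, USE.NAMES = FALSE)
}

.mean_qual <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || q == "*") return(Inf)
    mean(utf8ToInt(q) - 33L)
  }, 1, USE.NAMES = FALSE)
}

#' Extract reads overlapping a gene window
#'
#' Returns reads whose alignment footprint overlaps the gene interval
#' extended by `flank` on both sides (clipped at position 1). Positions are
#' 1-based as in SAM.
#'
#' @param reads read tibble (see [read_sam()])
#' @param gene list with `chrom`, `start`, `end`
#' @param flank flanking distance in bp (default 100 kb)
#' @param known_chroms chromosome names considered valid; defaults to those
#'   present in `reads`
#' @return subset of `reads`
#' @export
extract_region <- function(reads, gene, flank = 100000L,
                           known_chroms = unique(reads$rname)) {
  stopifnot(flank >= 0, all(c("chrom", "start", "end") %in% names(gene)))
  if (!gene$chrom %in% known_chroms) {
    stop("unknown chromosome: ", gene$chrom, call. = FALSE)
  }
  lo <- max(1L, gene$start - flank)
  hi <- gene$end + flank
  span <- .cigar_ref_span(reads$cigar)
  keep <- reads$rname == gene$chrom & reads$pos <= hi &
    (reads$pos + span - 1L) >= lo
  reads[keep, , drop = FALSE]
}

#' Base-quality and mapping-quality read filter
#'
#' Drops reads with mapping quality 0 or mean PHRED base quality of 25 or
#' below (both boundaries inclusive on the drop side).
#'
#' @param reads read tibble
#' @return `quality_keep()` returns the logical keep flag per read;
#'   `quality_filter()` the surviving subset.
#' @export
quality_keep <- function(reads) {
  reads$mapq > 0L & .mean_qual(reads$qual) > 25
}

#' @rdname quality_keep
#' @export
quality_filter <- function(reads) {
  reads[quality_keep(reads), , drop = FALSE]
}

#' Estimate the fragment-length distribution
#'
#' Mean and standard deviation of the library insert size, estimated from
#' same-chromosome FR pairs only (one observation per pair, taken from the
#' leftmost mate), with symmetric quantile trimming to resist contamination
#' from mis-paired reads.
#'
#' @param reads read tibble
#' @param max_pairs cap on the number of pairs used
#' @param trim trimming fraction per tail
#' @return list with `mean`, `sd`, `n_pairs`
#' @export
insert_stats <- function(reads, max_pairs = 100000L, trim = 0.01) {
  same <- reads$rnext == reads$rname
  fwd <- bitwAnd(reads$flag, 16L) == 0L
  mate_rev <- bitwAnd(reads$flag, 32L) != 0L
  left <- reads$tlen > 0L
  sel <- same & fwd & mate_rev & left & !is.na(reads$tlen)
  x <- utils::head(reads$tlen[sel], max_pairs)
  if (length(x) < 2L) stop("too few proper pairs to estimate insert size",
                           call. = FALSE)
  q <- stats::quantile(x, c(trim, 1 - trim), names = FALSE, type = 1)
  x <- x[x >= q[1] & x <= q[2]]
  list(mean = mean(x), sd = stats::sd(x), n_pairs = length(x))
}

#' Flag discordant reads
#'
#' A read is discordant when (1) its mate is unaligned or aligned to a
#' different chromosome, (2) the pair orientation is not the expected FR,
#' or (3) the pair span deviates from the library mean insert size by more
#' than three standard deviations. Reasons are evaluated in that order and
#' the first that applies is reported.
#'
#' @param reads read tibble
#' @param stats fragment statistics from [insert_stats()]
#' @param n_sd deviation allowance in standard deviations (default 3)
#' @return tibble with logical `discordant` and character `reason`
#'   (`mate_unaligned_or_interchrom`, `orientation`, `insert_size`, or NA)
#' @export
flag_discordant <- function(reads, stats, n_sd = 3) {
  n <- nrow(reads)
  reason <- rep(NA_character_, n)
  mate_unmapped <- bitwAnd(reads$flag, 8L) != 0L
  interchrom <- is.na(reads$rnext) | (reads$rnext != reads$rname &
                                        reads$rnext != "=")
  r1 <- mate_unmapped | interchrom
  reason[r1] <- "mate_unaligned_or_interchrom"

  self_rev <- bitwAnd(reads$flag, 16L) != 0L
  mate_rev <- bitwAnd(reads$flag, 32L) != 0L
  leftmost <- reads$pos <= reads$pnext
  # FR: leftmost mate forward, rightmost reverse
  fr <- (self_rev != mate_rev) &
    ((leftmost & !self_rev) | (!leftmost & self_rev) |
       (reads$pos == reads$pnext))
  r2 <- !r1 & !fr
  reason[r2] <- "orientation"

  dev <- abs(abs(reads$tlen) - stats$mean) > n_sd * stats$sd
  r3 <- !r1 & !r2 & dev
  reason[r3] <- "insert_size"

  tibble::tibble(discordant = r1 | r2 | r3, reason = reason)
}

#' @rdname flag_discordant
#' @param read one-row read tibble
#' @return `is_discordant()` returns a logical scalar with a `reason`
#'   attribute.
#' @export
is_discordant <- function(read, stats, n_sd = 3) {
  f <- flag_discordant(read, stats, n_sd = n_sd)
  structure(f$discordant[1], reason = f$reason[1])
}

# one row per discordant pair, sides ordered by (chrom, pos)
.discordant_pairs <- function(reads) {
  first <- !duplicated(reads$qname)
  r <- reads[first, , drop = FALSE]
  mate_chrom <- ifelse(r$rnext == "=", r$rname, r$rnext)
  swap <- mate_chrom < r$rname | (mate_chrom == r$rname & r$pnext < r$pos)
  tibble::tibble(
    qname = r$qname,
    chrom1 = ifelse(swap, mate_chrom, r$rname),
    pos1 = ifelse(swap, r$pnext, r$pos),
    chrom2 = ifelse(swap, r$rname, mate_chrom),
    pos2 = ifelse(swap, r$pos, r$pnext))
}

#' Cluster discordant pairs by joint proximity
#'
#' Single-linkage grouping of discordant pairs that share the same
#' chromosome pair and lie within `max_gap` of one another on both sides
#' simultaneously. Input order does not matter; pairs are sorted
#' internally and clusters are returned sorted by their first-side
#' interval.
#'
#' @param reads discordant read tibble (both mates or one mate per pair may
#'   be present; pairs are reconstructed from mate fields)
#' @param max_gap linkage distance in bp
#' @return list of clusters, each a list with `chrom_a`, `start_a`,
#'   `end_a`, `chrom_b`, `start_b`, `end_b`, `qnames`, `n_pairs`
#' @export
cluster_discordant <- function(reads, max_gap = 500L) {
  if (!nrow(reads)) return(list())
  pairs <- .discordant_pairs(reads)
  pairs <- pairs[order(pairs$chrom1, pairs$chrom2, pairs$pos1, pairs$pos2), ,
                 drop = FALSE]
  out <- list()
  for (key in unique(paste(pairs$chrom1, pairs$chrom2))) {
    g <- pairs[paste(pairs$chrom1, pairs$chrom2) == key, , drop = FALSE]
    n <- nrow(g)
    comp <- seq_len(n)
    find <- function(i) {
      while (comp[i] != i) i <- comp[i]
      i
    }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j <= i) next
        if (abs(g$pos1[i] - g$pos1[j]) <= max_gap &&
            abs(g$pos2[i] - g$pos2[j]) <= max_gap) {
          comp[find(j)] <- find(i)
        }
      }
    }
    roots <- vapply(seq_len(n), find, 1L)
    for (root in unique(roots)) {
      m <- g[roots == root, , drop = FALSE]
      out[[length(out) + 1L]] <- list(
        chrom_a = m$chrom1[1], start_a = min(m$pos1), end_a = max(m$pos1),
        chrom_b = m$chrom2[1], start_b = min(m$pos2), end_b = max(m$pos2),
        qnames = m$qname, n_pairs = nrow(m))
    }
  }
  ord <- order(vapply(out, `[[`, "", "chrom_a"),
               vapply(out, `[[`, 1, "start_a"))
  out[ord]
}

.overlaps_mask <- function(chrom, start, end, mask) {
  m <- mask[mask$chrom == chrom, , drop = FALSE]
  if (!nrow(m)) return(FALSE)
  q <- IRanges::IRanges(start, end)
  s <- IRanges::IRanges(m$start, m$end)
  IRanges::countOverlaps(q, s) > 0
}

#' Filter candidate clusters
#'
#' Drops clusters whose either side overlaps the repeat mask, whose
#' discordant-pair support falls below `min_support`, or that are present
#' in more than `max_control_fraction` of the control catalogue (common
#' variants).
#'
#' @param clusters output of [cluster_discordant()]
#' @param mask optional tibble of repetitive intervals (`chrom`, `start`,
#'   `end`, 1-based closed)
#' @param control_counts optional integer vector, per cluster, of controls
#'   carrying the same cluster
#' @param n_controls size of the control panel (required with
#'   `control_counts`)
#' @param min_support minimum discordant pairs (default 3)
#' @param max_control_fraction common-variant cut-off (default 0.01)
#' @return filtered cluster list
#' @export
filter_clusters <- function(clusters, mask = NULL, control_counts = NULL,
                            n_controls = NULL, min_support = 3L,
                            max_control_fraction = 0.01) {
  if (!length(clusters)) return(clusters)
  keep <- vapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    if (cl$n_pairs < min_support) return(FALSE)
    if (!is.null(mask) &&
        (.overlaps_mask(cl$chrom_a, cl$start_a, cl$end_a, mask) ||
         .overlaps_mask(cl$chrom_b, cl$start_b, cl$end_b, mask))) {
      return(FALSE)
    }
    if (!is.null(control_counts)) {
      stopifnot(!is.null(n_controls))
      if (control_counts[i] / n_controls > max_control_fraction) {
        return(FALSE)
      }
    }
    TRUE
  }, TRUE)
  clusters[keep]
}

# soft-clip observations near one side of a cluster
.side_clips <- function(reads, chrom, lo, hi, window) {
  r <- reads[reads$rname == chrom, , drop = FALSE]
  span <- .cigar_ref_span(r$cigar)
  lead <- .cigar_clip(r$cigar, "left")
  trail <- .cigar_clip(r$cigar, "right")
  right_end <- r$pos + span - 1L
  in_win <- function(p) p >= lo - window & p <= hi + window
  ir <- which(trail > 0L & in_win(right_end))
  il <- which(lead > 0L & in_win(r$pos))
  list(
    right = tibble::tibble(
      boundary = right_end[ir],
      tail = substr(r$seq[ir], nchar(r$seq[ir]) - trail[ir] + 1L,
                    nchar(r$seq[ir]))),
    left = tibble::tibble(
      boundary = r$pos[il],
      head = substr(r$seq[il], 1L, lead[il])))
}

# modal value; ties broken toward the smaller coordinate
.mode_min <- function(x) {
  if (!length(x)) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[tab == max(tab)][1])
}

.count_mismatch <- function(x, y) {
  a <- charToRaw(toupper(x))
  b <- charToRaw(toupper(y))
  n <- min(length(a), length(b))
  sum(a[seq_len(n)] != b[seq_len(n)]) + abs(length(a) - length(b))
}

# offset k such that tail[(k+1)..] matches ref from ref_start (right tails)
.offset_right <- function(tail, ref, ref_start, min_match = 8L,
                          max_k = 40L, max_mismatch_frac = 0.25) {
  n <- nchar(tail)
  best <- NA_integer_
  best_frac <- Inf
  for (k in 0:min(max_k, n - min_match)) {
    L <- n - k
    ref_seg <- substr(ref, ref_start, ref_start + L - 1L)
    if (nchar(ref_seg) < L) next
    frac <- .count_mismatch(substr(tail, k + 1L, n), ref_seg) / L
    if (frac < best_frac - 1e-9) {
      best_frac <- frac
      best <- k
    }
    if (frac == 0) break
  }
  if (is.finite(best_frac) && best_frac <= max_mismatch_frac) best else
    NA_integer_
}

# offset k such that head[1..(n-k)] matches ref ending at ref_end (left heads)
.offset_left <- function(head, ref, ref_end, min_match = 8L, max_k = 40L,
                         max_mismatch_frac = 0.25) {
  n <- nchar(head)
  best <- NA_integer_
  best_frac <- Inf
  for (k in 0:min(max_k, n - min_match)) {
    L <- n - k
    if (ref_end - L + 1L < 1L) next
    ref_seg <- substr(ref, ref_end - L + 1L, ref_end)
    frac <- .count_mismatch(substr(head, 1L, L), ref_seg) / L
    if (frac < best_frac - 1e-9) {
      best_frac <- frac
      best <- k
    }
    if (frac == 0) break
  }
  if (is.finite(best_frac) && best_frac <= max_mismatch_frac) best else
    NA_integer_
}

.mode_chr <- function(x) {
  x <- x[!is.na(x) & nchar(x) > 0]
  if (!length(x)) return("")
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1]
}

#' Infer translocation breakpoints and micro-event anatomy
#'
#' Junction positions are the modal soft-clip boundaries on each side
#' (ties toward the smaller coordinate). With the four boundaries — the
#' last retained base (right clip) and first retained base (left clip) on
#' each chromosome — the target-site anatomy falls out: a side whose left
#' boundary lies at or before its right boundary carries a duplication of
#' the overlap, and a side whose left boundary lies beyond `right + 1`
#' carries a deletion of the gap. Clipped tails are then aligned to the
#' partner reference at the opposing junction; any prefix that fails to
#' align is the inserted motif, whose origin is searched on both strands
#' around the breakpoints to set the reverse-complement flag.
#'
#' @param cluster one cluster from [cluster_discordant()]
#' @param reads read tibble supplying soft-clipped reads (typically the
#'   quality-filtered input, both chromosomes)
#' @param refs named character vector of reference sequences
#' @param window distance around the cluster interval within which
#'   soft-clip evidence is collected (bp)
#' @return a `translocation_call` list; when no side has spanning
#'   soft-clips the call is low-resolution: positions degrade to the
#'   cluster intervals and the anatomy is left unset
#' @export
infer_breakpoint <- function(cluster, reads, refs, window = 1000L) {
  sa <- .side_clips(reads, cluster$chrom_a, cluster$start_a, cluster$end_a,
                    window)
  sb <- .side_clips(reads, cluster$chrom_b, cluster$start_b, cluster$end_b,
                    window)
  r_a <- .mode_min(sa$right$boundary)
  l_a <- .mode_min(sa$left$boundary)
  r_b <- .mode_min(sb$right$boundary)
  l_b <- .mode_min(sb$left$boundary)

  low_res <- anyNA(c(r_a, l_a, r_b, l_b))
  if (low_res) {
    return(structure(list(
      chrom_a = cluster$chrom_a, bp_a = NA_integer_,
      chrom_b = cluster$chrom_b, bp_b = NA_integer_,
      interval_a = c(cluster$start_a, cluster$end_a),
      interval_b = c(cluster$start_b, cluster$end_b),
      dup_len = NA_integer_, del_len = NA_integer_,
      insert_seq = NA_character_, insert_revcomp = NA,
      n_softclip_support = 0L,
      n_discordant_support = cluster$n_pairs,
      resolution = "interval"), class = "translocation_call"))
  }

  side_event <- function(r, l) c(dup = max(0L, r - l + 1L),
                                 del = max(0L, l - r - 1L))
  ev_a <- side_event(r_a, l_a)
  ev_b <- side_event(r_b, l_b)
  dup_len <- ev_a[["dup"]] + ev_b[["dup"]]
  del_len <- ev_a[["del"]] + ev_b[["del"]]

  ref_a <- refs[[cluster$chrom_a]]
  ref_b <- refs[[cluster$chrom_b]]
  # junction 1: chrom_a right clips continue into chrom_b at l_b
  k1 <- c(vapply(sa$right$tail[sa$right$boundary == r_a], .offset_right,
                 1L, ref = ref_b, ref_start = l_b),
          vapply(sb$left$head[sb$left$boundary == l_b], .offset_left,
                 1L, ref = ref_a, ref_end = r_a))
  # junction 2: chrom_b right clips continue into chrom_a at l_a
  k2 <- c(vapply(sb$right$tail[sb$right$boundary == r_b], .offset_right,
                 1L, ref = ref_a, ref_start = l_a),
          vapply(sa$left$head[sa$left$boundary == l_a], .offset_left,
                 1L, ref = ref_b, ref_end = r_b))
  k1m <- .mode_min(k1[!is.na(k1)])
  k2m <- .mode_min(k2[!is.na(k2)])
  ins_len <- 0L
  ins_seq <- ""
  if (!is.na(k1m) && k1m > 0L) {
    ins_len <- k1m
    ins_seq <- .mode_chr(substr(sa$right$tail[sa$right$boundary == r_a],
                                1L, k1m))
  } else if (!is.na(k2m) && k2m > 0L) {
    ins_len <- k2m
    ins_seq <- .mode_chr(substr(sb$right$tail[sb$right$boundary == r_b],
                                1L, k2m))
  }
  ins_rc <- NA
  if (nchar(ins_seq) > 0L) {
    w <- 200L
    windows <- c(
      substr(ref_a, max(1L, r_a - w), min(nchar(ref_a), r_a + w + ins_len)),
      substr(ref_b, max(1L, r_b - w), min(nchar(ref_b), r_b + w + ins_len)))
    fwd <- any(vapply(windows, grepl, TRUE, pattern = ins_seq,
                      fixed = TRUE))
    rc <- any(vapply(windows, grepl, TRUE, pattern = .revcomp(ins_seq),
                     fixed = TRUE))
    ins_rc <- if (fwd) FALSE else if (rc) TRUE else NA
  }

  n_support <- sum(sa$right$boundary == r_a) + sum(sa$left$boundary == l_a) +
    sum(sb$right$boundary == r_b) + sum(sb$left$boundary == l_b)
  structure(list(
    chrom_a = cluster$chrom_a, bp_a = r_a,
    chrom_b = cluster$chrom_b, bp_b = r_b,
    interval_a = c(r_a, r_a), interval_b = c(r_b, r_b),
    dup_len = dup_len, del_len = del_len,
    insert_seq = ins_seq, insert_revcomp = ins_rc,
    n_softclip_support = as.integer(n_support),
    n_discordant_support = cluster$n_pairs,
    resolution = "base"), class = "translocation_call")
}

#' Scan a gene window for translocations
#'
#' The full pipeline of the discordant-pair scan: restrict to the gene
#' window with flanks, apply the quality filter, estimate the library
#' fragment distribution, flag and cluster discordant pairs, drop masked /
#' under-supported / common clusters, and infer breakpoint anatomy from
#' soft-clipped reads (drawn from the complete filtered read set so that
#' partner-chromosome evidence is available).
#'
#' @param reads read tibble (e.g. from [read_sam()])
#' @param refs named character vector of reference sequences
#' @param gene list with `chrom`, `start`, `end`
#' @param flank window extension in bp (default 100 kb)
#' @param mask optional repeat-mask tibble (`chrom`, `start`, `end`)
#' @param control_counts,n_controls optional control-catalogue evidence per
#'   candidate cluster, see [filter_clusters()]
#' @param min_support minimum discordant-pair support
#' @param max_gap cluster linkage distance (bp)
#' @param n_sd insert-size deviation allowance
#' @return list of `translocation_call` objects (empty when nothing passes)
#' @export
scan_translocations <- function(reads, refs, gene, flank = 100000L,
                                mask = NULL, control_counts = NULL,
                                n_controls = NULL, min_support = 3L,
                                max_gap = 500L, n_sd = 3) {
  kept <- quality_filter(reads)
  region <- extract_region(kept, gene, flank = flank,
                           known_chroms = names(refs))
  if (!nrow(region)) return(list())
  stats <- insert_stats(kept)
  fl <- flag_discordant(region, stats, n_sd = n_sd)
  disc <- region[fl$discordant, , drop = FALSE]
  clusters <- cluster_discordant(disc, max_gap = max_gap)
  # translocations live on interchromosomal clusters; same-chromosome
  # discordance (orientation / insert-size classes) is not called here
  clusters <- clusters[vapply(clusters, function(cl) {
    cl$chrom_a != cl$chrom_b
  }, TRUE)]
  clusters <- filter_clusters(clusters, mask = mask,
                              control_counts = control_counts,
                              n_controls = n_controls,
                              min_support = min_support)
  lapply(clusters, infer_breakpoint, reads = kept, refs = refs)
}
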