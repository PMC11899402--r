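#' @import GenomicRanges
#' @import IRanges
NULL

#' Build an interval set from vectors
#'
#' Intervals are held as reduced (merged, sorted) unstranded `GRanges`.
#' Input coordinates are 0-based half-open (BED convention); the returned
#' object uses the 1-based closed convention `GRanges` enforces, so
#' `interval_size()` arithmetic is exact.
#'
#' @param chrom character vector of chromosome names
#' @param start,end 0-based half-open coordinates, `start < end`
#' @return a reduced `GRanges`
#' @export
as_intervals <- function(chrom, start, end) {
  if (length(chrom) == 0L) {
    return(GenomicRanges::GRanges())
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop("invalid interval at row ", bad, ": start (", start[bad],
         ") must be < end (", end[bad], ")")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  GenomicRanges::reduce(sort(gr))
}

#' Read a BED file into an interval set
#'
#' @param path path to a BED (0-based half-open) file
#' @return merged, sorted `GRanges`; empty file gives an empty set
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("no such BED file: ", path)
  info <- file.info(path)
  if (info$size == 0) return(GenomicRanges::GRanges())
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, fill = TRUE)
  colnames(tab) <- c("chrom", "start", "end", "name",
                     "score", "strand")[seq_len(ncol(tab))]
  gr <- as_intervals(tab$chrom, tab$start, tab$end)
  if (!is.null(tab$name) && !anyDuplicated(tab$name) &&
      length(tab$name) == length(gr)) {
    # names survive only when merging did not collapse rows
    names(gr) <- tab$name
  }
  gr
}

#' Write an interval set as BED
#'
#' @param gr a `GRanges`
#' @param path output path
#' @export
write_intervals <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Total size of an interval set in bases
#' @param gr a `GRanges`
#' @return integer number of bases covered
#' @export
interval_size <- function(gr) {
  sum(as.numeric(IRanges::width(GenomicRanges::reduce(gr))))
}

#' Union of two interval sets
#' @param a,b `GRanges`
#' @export
interval_union <- function(a, b) {
  suppressWarnings(GenomicRanges::reduce(c(GenomicRanges::granges(a),
                                           GenomicRanges::granges(b))))
}

#' Intersection of two interval sets
#'
#' Bases present in both sets, computed as depth-2 regions of the
#' combined boundary sweep over the two (internally merged) sets.
#' @param a,b `GRanges`
#' @export
interval_intersect <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(GenomicRanges::GRanges())
  coverage_at_least(list(a, b), lower = 2L)
}

#' Pad intervals on both sides
#' @param gr a `GRanges`
#' @param pad bases added to each side; starts are floored at 1
#' @export
pad_intervals <- function(gr, pad = 2L) {
  if (length(gr) == 0L) return(gr)
  st <- pmax(1L, GenomicRanges::start(gr) - pad)
  en <- GenomicRanges::end(gr) + pad
  GenomicRanges::reduce(GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                               IRanges::IRanges(st, en)))
}

# Plain-vector view of a reduced interval set, keyed by chromosome.
# Set operations against a fixed target run orders of magnitude faster on
# these than through repeated S4 set ops in per-sample loops.
target_table <- function(target) {
  target <- GenomicRanges::reduce(sort(GenomicRanges::granges(target)))
  ch <- as.character(GenomicRanges::seqnames(target))
  st <- GenomicRanges::start(target)
  en <- GenomicRanges::end(target)
  idx <- split(seq_along(ch), ch)
  tt <- lapply(idx, function(i) list(start = st[i], end = en[i]))
  attr(tt, "size") <- sum(as.numeric(en - st + 1))
  tt
}

# Merge possibly-overlapping 1-based closed intervals.
merge_closed <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  keep_s <- numeric(0); keep_e <- numeric(0)
  cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ce + 1) ce <- max(ce, end[i])
    else { keep_s <- c(keep_s, cs); keep_e <- c(keep_e, ce)
           cs <- start[i]; ce <- end[i] }
  }
  list(start = c(keep_s, cs), end = c(keep_e, ce))
}

# Overlap in bases between query intervals (1-based closed, one chromosome)
# and one chromosome of a target_table.
overlap_bases_chrom <- function(qs, qe, t) {
  m <- merge_closed(qs, qe)
  tot <- 0
  for (k in seq_along(m$start)) {
    i1 <- findInterval(m$start[k] - 1, t$end) + 1
    i2 <- findInterval(m$end[k], t$start)
    if (i2 >= i1) {
      tot <- tot + sum(pmin(m$end[k], t$end[i1:i2]) -
                         pmax(m$start[k], t$start[i1:i2]) + 1)
    }
  }
  tot
}

# Total overlap of a chrom/start/end (0-based half-open) segment frame
# with the target.
segment_overlap_bases <- function(segments, tt) {
  tot <- 0
  for (ch in unique(segments$chrom)) {
    t <- tt[[ch]]
    if (is.null(t)) next
    sel <- segments$chrom == ch
    tot <- tot + overlap_bases_chrom(segments$start[sel] + 1,
                                     segments$end[sel], t)
  }
  tot
}

# Which 1-based positions fall inside the target.
positions_on_target <- function(chrom, pos, tt) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    t <- tt[[ch]]
    if (is.null(t)) next
    sel <- which(chrom == ch)
    k <- findInterval(pos[sel], t$start)
    out[sel] <- k >= 1 & pos[sel] <= t$end[pmax(k, 1)]
  }
  out
}

# Bases covered by at least `lower` of the given tracks, via a plain
# boundary sweep (each track is merged within itself first so it can
# contribute at most 1 per base).
coverage_at_least <- function(tracks, lower) {
  chs <- sts <- ens <- vector("list", length(tracks))
  for (k in seq_along(tracks)) {
    g <- tracks[[k]]
    if (length(g) == 0L) next
    ch <- as.character(GenomicRanges::seqnames(g))
    st <- GenomicRanges::start(g)
    en <- GenomicRanges::end(g)
    parts <- lapply(unique(ch), function(cc) {
      m <- merge_closed(st[ch == cc], en[ch == cc])
      list(ch = rep(cc, length(m$start)), st = m$start, en = m$end)
    })
    chs[[k]] <- unlist(lapply(parts, `[[`, "ch"))
    sts[[k]] <- unlist(lapply(parts, `[[`, "st"))
    ens[[k]] <- unlist(lapply(parts, `[[`, "en"))
  }
  ch_all <- unlist(chs); st_all <- unlist(sts); en_all <- unlist(ens)
  if (length(ch_all) == 0L) return(GenomicRanges::GRanges())
  out <- list(ch = character(0), st = numeric(0), en = numeric(0))
  for (cc in unique(ch_all)) {
    i <- ch_all == cc
    pos <- c(st_all[i], en_all[i] + 1)
    delta <- rep(c(1, -1), each = sum(i))
    o <- order(pos)
    pos <- pos[o]
    depth <- cumsum(delta[o])
    last <- c(pos[-1] != pos[-length(pos)], TRUE)
    bnd <- pos[last]
    cnt <- depth[last]
    ok <- cnt >= lower
    if (!any(ok)) next
    s_idx <- which(ok & !c(FALSE, ok[-length(ok)]))
    e_idx <- which(ok & !c(ok[-1], FALSE))
    out$ch <- c(out$ch, rep(cc, length(s_idx)))
    out$st <- c(out$st, bnd[s_idx])
    out$en <- c(out$en, bnd[e_idx + 1] - 1)
  }
  if (length(out$ch) == 0L) return(GenomicRanges::GRanges())
  sort(GenomicRanges::GRanges(out$ch, IRanges::IRanges(out$st, out$en)))
}
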