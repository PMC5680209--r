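#' Cluster split reads into breakpoint candidates
#'
#' Split reads whose two aligned segments agree within `window` bp on
#' both sides of the candidate breakpoint (and share the chromosome
#' pair) are grouped into one candidate. Both primary and secondary
#' alignments are counted, which increases sensitivity for reads whose
#' split alignment is reported as a secondary record.
#'
#' @param reads split-read data.frame (see [simulate_split_reads()]).
#' @param window clustering window in bp (default 10).
#' @return list of candidates; each is a list with `reads` (the member
#'   rows), modal `pos_a`/`pos_b` breakpoints (ties broken to the
#'   smaller coordinate), and support counts by side.
#' @export
cluster_split_reads <- function(reads, window = 10L) {
  if (nrow(reads) == 0L) stop("reads must be nonempty")
  pair <- paste(reads$chrom_a, reads$chrom_b, sep = "|")
  cands <- list()
  for (pr in unique(pair)) {
    sub <- reads[pair == pr, , drop = FALSE]
    sub <- sub[order(sub$pos_a, sub$pos_b), , drop = FALSE]
    ga <- cumsum(c(TRUE, diff(sub$pos_a) > window))
    for (g in unique(ga)) {
      sa <- sub[ga == g, , drop = FALSE]
      gb <- cumsum(c(TRUE, diff(sort(sa$pos_b)) > window))
      ob <- order(sa$pos_b)
      for (h in unique(gb)) {
        member <- sa[ob[gb == h], , drop = FALSE]
        modal <- function(x) {
          tb <- table(x)
          as.integer(min(as.integer(names(tb)[tb == max(tb)])))
        }
        cands[[length(cands) + 1L]] <- list(
          reads = member,
          chrom_a = member$chrom_a[1], pos_a = modal(member$pos_a),
          chrom_b = member$chrom_b[1], pos_b = modal(member$pos_b),
          n_support = nrow(member),
          n_left = sum(member$side == "left"),
          n_right = sum(member$side == "right"))
      }
    }
  }
  cands
}

#' Call gene fusions from breakpoint candidates
#'
#' A candidate becomes a fusion call when, after read-level filters
#' (minimum mapping quality and minimum matched segment length), it
#' retains at least `min_support` split reads with at least
#' `min_per_side` mapping to each side of the breakpoint, and the
#' dominant strand orientation accounts for at least
#' `strand_concordance` of the surviving support.
#'
#' @param candidates output of [cluster_split_reads()].
#' @param min_support minimum total split reads (default 4).
#' @param min_per_side minimum reads per breakpoint side (default 2).
#' @param min_mapq minimum mapping quality per counted read.
#' @param strand_concordance required fraction agreeing on strand
#'   orientation.
#' @param min_matched_len minimum matched segment length per counted
#'   read.
#' @return data.frame of fusion calls (possibly 0 rows): breakpoints
#'   (1-based), support totals and per-side counts, strand concordance,
#'   and pass-through gene names.
#' @export
call_fusions <- function(candidates, min_support = 4L, min_per_side = 2L,
                         min_mapq = 20L, strand_concordance = 0.8,
                         min_matched_len = 20L) {
  rows <- lapply(candidates, function(cd) {
    rd <- cd$reads
    keep <- rd$mapq >= min_mapq & rd$matched_len >= min_matched_len
    rd <- rd[keep, , drop = FALSE]
    if (nrow(rd) == 0L) return(NULL)
    orient <- paste(rd$strand_a, rd$strand_b)
    conc <- max(table(orient)) / nrow(rd)
    n_left <- sum(rd$side == "left")
    n_right <- sum(rd$side == "right")
    ok <- nrow(rd) >= min_support && min(n_left, n_right) >= min_per_side &&
      conc >= strand_concordance
    if (!ok) return(NULL)
    data.frame(gene_a = if (!is.null(rd$gene_a)) rd$gene_a[1] else NA,
               chrom_a = cd$chrom_a, pos_a = cd$pos_a,
               gene_b = if (!is.null(rd$gene_b)) rd$gene_b[1] else NA,
               chrom_b = cd$chrom_b, pos_b = cd$pos_b,
               n_support = nrow(rd), n_left = n_left, n_right = n_right,
               strand_concordance = conc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_a = character(0), chrom_a = character(0),
                      pos_a = integer(0), gene_b = character(0),
                      chrom_b = character(0), pos_b = integer(0),
                      n_support = integer(0), n_left = integer(0),
                      n_right = integer(0),
                      strand_concordance = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
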