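#' Per-exon normal reference from a cohort of normal samples
#'
#' Normalizes each normal sample by its mean target coverage and takes
#' the per-exon median of the normalized depths as the expected diploid
#' coverage.
#'
#' @param normal_depths exon-by-sample depth matrix (rownames = exon
#'   ids) from at least 3 normal samples.
#' @return data.frame with `exon` and `ref_norm_depth`.
#' @export
normal_reference <- function(normal_depths) {
  normal_depths <- as.matrix(normal_depths)
  if (ncol(normal_depths) < 3L)
    stop("the normal reference requires at least 3 samples")
  norm <- sweep(normal_depths, 2, colMeans(normal_depths), "/")
  data.frame(exon = rownames(normal_depths),
             ref_norm_depth = apply(norm, 1, stats::median),
             stringsAsFactors = FALSE)
}

#' Normalize and standardize exon depths
#'
#' Each exon's mean depth is normalized by the sample's overall target
#' coverage, then standardized by the expected normalized coverage of a
#' normal individual (the per-exon median across the normal reference).
#' Diploid exons in a normal sample therefore give a ratio near 1.
#' Exons with a zero reference median are masked.
#'
#' @param sample_depths named numeric vector of exon depths, or a
#'   data.frame with `exon` and `depth`.
#' @param reference output of [normal_reference()]; must cover all
#'   exons.
#' @param exons optional data.frame mapping `exon` to `gene`.
#' @return data.frame of exon depth records: `exon`, `gene` (if
#'   supplied), `depth`, `norm_depth`, standardized ratio `R`, and a
#'   `masked` flag.
#' @export
normalize_and_standardize <- function(sample_depths, reference,
                                      exons = NULL) {
  if (is.data.frame(sample_depths)) {
    depth <- sample_depths$depth
    names(depth) <- sample_depths$exon
    sample_depths <- depth
  }
  missing <- setdiff(names(sample_depths), reference$exon)
  if (length(missing) > 0L)
    stop("reference does not cover exons: ",
         paste(utils::head(missing, 5), collapse = ", "))
  ref <- reference$ref_norm_depth[match(names(sample_depths),
                                        reference$exon)]
  norm_depth <- sample_depths / mean(sample_depths)
  masked <- !is.finite(ref) | ref <= 0
  R <- ifelse(masked, NA_real_, norm_depth / ref)
  out <- data.frame(exon = names(sample_depths),
                    depth = as.numeric(sample_depths),
                    norm_depth = as.numeric(norm_depth),
                    R = as.numeric(R), masked = masked,
                    stringsAsFactors = FALSE)
  if (!is.null(exons))
    out$gene <- exons$gene[match(out$exon, exons$exon)]
  rownames(out) <- NULL
  out
}

#' Purity-adjusted copy number amplitude
#'
#' Inverts the mixture relation `R = (P*C + 2*(1-P)) / 2` for the tumor
#' copy number `C`, floored at zero, and reports the amplitude
#' `log2(C / 2)`. At purity 1 this reduces to `log2(R)`.
#'
#' @param R standardized depth ratio (>= 0).
#' @param P tumor purity in (0, 1].
#' @return log2 copy amplitude (`-Inf` for a fully deleted region).
#' @export
purity_adjusted_amplitude <- function(R, P) {
  stopifnot(all(R >= 0, na.rm = TRUE))
  if (any(P <= 0) || any(P > 1)) stop("purity must lie in (0, 1]")
  C <- pmax(0, (2 * R - 2 * (1 - P)) / P)
  log2(C / 2)
}

#' Call copy number variants from exon depth records
#'
#' Aggregates the purity-adjusted amplitude to the gene level by the
#' median over unmasked exons and calls amplification when the
#' amplitude is strictly greater than `amp_threshold` and deletion when
#' strictly less than `del_threshold` (log2 units; amplitude exactly at
#' a boundary stays neutral).
#'
#' @param records output of [normalize_and_standardize()] with a `gene`
#'   column.
#' @param purity estimated tumor purity used for the adjustment.
#' @param amp_threshold,del_threshold log2 boundaries (defaults +1/-1).
#' @return data.frame with `gene`, `n_exons`, `amplitude`, `call`.
#' @export
call_cnv <- function(records, purity = 1, amp_threshold = 1,
                     del_threshold = -1) {
  if (is.null(records$gene))
    stop("records must carry a gene column (pass exons= to ",
         "normalize_and_standardize)")
  use <- records[!records$masked, , drop = FALSE]
  if (nrow(use) == 0L) stop("all exons are masked")
  use$amplitude <- purity_adjusted_amplitude(use$R, purity)
  out <- do.call(rbind, lapply(split(use, use$gene), function(g) {
    amp <- stats::median(g$amplitude)
    data.frame(gene = g$gene[1], n_exons = nrow(g), amplitude = amp,
               call = if (is.finite(amp) && amp > amp_threshold)
                 "amplification"
               else if (amp < del_threshold) "deletion" else "neutral",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
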