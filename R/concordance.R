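#' Mean target copies per droplet from digital PCR counts
#'
#' Poisson quantification of droplet digital PCR: with `n_positive` of
#' `n_total` droplets fluorescing, the mean number of target copies per
#' droplet is `lambda = -ln(1 - n_positive/n_total)` (the Poisson zero
#' term). Fully saturated wells carry no upper information and raise an
#' error.
#'
#' @param n_positive positive droplet count.
#' @param n_total total droplets (~20,000 per well).
#' @return lambda, copies per droplet.
#' @export
dpcr_lambda <- function(n_positive, n_total) {
  stopifnot(all(n_positive >= 0), all(n_total > 0),
            all(n_positive <= n_total))
  if (any(n_positive == n_total))
    stop("saturated well (all droplets positive): lambda is unbounded")
  -log(1 - n_positive / n_total)
}

#' Absolute target concentration from droplet counts
#'
#' @param n_positive positive droplet count.
#' @param n_total total droplets.
#' @param droplet_volume_nl droplet volume in nanoliters (default 0.85,
#'   the nominal droplet volume of common ddPCR instruments).
#' @return copies per nanoliter.
#' @export
dpcr_concentration <- function(n_positive, n_total,
                               droplet_volume_nl = 0.85) {
  stopifnot(droplet_volume_nl > 0)
  dpcr_lambda(n_positive, n_total) / droplet_volume_nl
}

#' Variant allele fraction from mutant/wild-type dPCR channels
#'
#' `VAF = lambda_mut / (lambda_mut + lambda_wt)`.
#'
#' @param lambda_mut mean mutant copies per droplet.
#' @param lambda_wt mean wild-type copies per droplet.
#' @return VAF in [0, 1].
#' @export
dpcr_vaf <- function(lambda_mut, lambda_wt) {
  stopifnot(all(lambda_mut >= 0), all(lambda_wt >= 0))
  tot <- lambda_mut + lambda_wt
  if (any(tot == 0)) stop("both channels are empty: VAF undefined")
  lambda_mut / tot
}

#' Panel vs dPCR VAF concordance
#'
#' Pearson correlation between panel-estimated and dPCR-estimated VAFs,
#' with an optional stratification by sequencing depth (variants with
#' higher coverage tend to agree better).
#'
#' @param pairs data.frame with `panel_vaf`, `dpcr_vaf` and optionally
#'   `depth`.
#' @param depth_breaks optional depth cut points for stratified
#'   correlations; defaults to terciles when `depth` is present.
#' @return object of class `vaf_concordance`: `r`, `n`, and a
#'   `by_depth` stratum table when depth is available.
#' @export
vaf_concordance <- function(pairs, depth_breaks = NULL) {
  stopifnot(all(c("panel_vaf", "dpcr_vaf") %in% names(pairs)))
  if (nrow(pairs) < 3L) stop("at least 3 pairs are required")
  if (stats::sd(pairs$panel_vaf) == 0 || stats::sd(pairs$dpcr_vaf) == 0)
    stop("zero variance in one coordinate: correlation undefined")
  r <- stats::cor(pairs$panel_vaf, pairs$dpcr_vaf)
  by_depth <- NULL
  if (!is.null(pairs$depth)) {
    if (is.null(depth_breaks))
      depth_breaks <- stats::quantile(pairs$depth, c(0, 1/3, 2/3, 1))
    grp <- cut(pairs$depth, unique(depth_breaks), include.lowest = TRUE)
    by_depth <- do.call(rbind, lapply(split(pairs, grp), function(g) {
      data.frame(n = nrow(g),
                 r = if (nrow(g) >= 3 && stats::sd(g$panel_vaf) > 0 &&
                         stats::sd(g$dpcr_vaf) > 0)
                   stats::cor(g$panel_vaf, g$dpcr_vaf) else NA_real_)
    }))
  }
  structure(list(r = r, n = nrow(pairs), by_depth = by_depth),
            class = "vaf_concordance")
}

#' @method print vaf_concordance
#' @export
print.vaf_concordance <- function(x, ...) {
  cat(sprintf("Panel vs dPCR VAF concordance: Pearson r = %.3f (n = %d)\n",
              x$r, x$n))
  if (!is.null(x$by_depth)) {
    cat("  by depth stratum:\n")
    print(round(x$by_depth, 3))
  }
  invisible(x)
}

#' Fractions of calls below VAF thresholds, per hotspot group
#'
#' For each group (e.g. a hotspot such as EGFR T790M) and each
#' threshold, reports the fraction of calls with VAF *strictly* below
#' the threshold; ties at the threshold count as not-below. Empty
#' groups are omitted with a message.
#'
#' @param calls data.frame with `group` and `vaf`.
#' @param thresholds VAF thresholds (defaults 5, 10, 20%).
#' @return data.frame with `group`, `threshold`, `n`, `n_below`,
#'   `fraction_below`.
#' @export
vaf_distribution_summary <- function(calls,
                                     thresholds = c(0.05, 0.10, 0.20)) {
  stopifnot(all(c("group", "vaf") %in% names(calls)))
  groups <- unique(calls$group)
  rows <- lapply(groups, function(g) {
    v <- calls$vaf[calls$group == g]
    if (length(v) == 0L) {
      message("group '", g, "' is empty; omitted")
      return(NULL)
    }
    data.frame(group = g, threshold = thresholds,
               n = length(v),
               n_below = vapply(thresholds, function(t) sum(v < t),
                                integer(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fraction_below <- out$n_below / out$n
  rownames(out) <- NULL
  out
}
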