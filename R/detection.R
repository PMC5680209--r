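#' Reference SNV detection model
#'
#' A declared reference model standing in for a production two-caller
#' union: a site is called when it has at least `min_alt_reads` variant
#' reads, the upper-tail binomial probability of seeing that many reads
#' from sequencing error alone (rate \eqn{\epsilon/3} for the specific
#' alternative base) is below `alpha`, and the VAF clears `min_vaf` if
#' one is set. With ~1000x coverage and a well-controlled error rate,
#' variants supported by as few as 3-4 reads (0.3-0.4% VAF) are in
#' principle identifiable, which motivates the default of 4.
#'
#' @param min_alt_reads minimum variant-supporting reads (default 4).
#' @param error_rate per-base sequencing error rate \eqn{\epsilon}.
#' @param alpha significance threshold of the binomial error test;
#'   `NULL` disables the test (pure "alt >= k" rule, used by the exact
#'   binomial LOD oracle).
#' @param min_vaf optional VAF floor.
#' @return an object of class `detection_model`.
#' @export
detection_model <- function(min_alt_reads = 4L, error_rate = 0.001,
                            alpha = 1e-6, min_vaf = NULL) {
  min_alt_reads <- as.integer(min_alt_reads)
  stopifnot(min_alt_reads >= 1L, error_rate > 0, error_rate < 1)
  if (!is.null(alpha) && (alpha <= 0 || alpha >= 1))
    stop("alpha must lie in (0, 1), or be NULL to disable the error test")
  structure(list(min_alt_reads = min_alt_reads, error_rate = error_rate,
                 alpha = alpha, min_vaf = min_vaf),
            class = "detection_model")
}

#' @method print detection_model
#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf(
    "Reference detection model: alt >= %d, error rate %g, alpha %s%s\n",
    x$min_alt_reads, x$error_rate,
    if (is.null(x$alpha)) "disabled" else format(x$alpha),
    if (is.null(x$min_vaf)) "" else sprintf(", min VAF %g", x$min_vaf)))
  invisible(x)
}

## Vectorized detection over parallel count vectors; the workhorse for
## the dilution grids where millions of (depth, alt) trials are scored.
.detect_counts <- function(depth, alt, model) {
  ok <- alt >= model$min_alt_reads & depth > 0L
  if (!is.null(model$alpha)) {
    p <- stats::pbinom(alt - 1L, pmax(depth, 1L), model$error_rate / 3,
                       lower.tail = FALSE)
    ok <- ok & p < model$alpha
  }
  if (!is.null(model$min_vaf))
    ok <- ok & (alt / pmax(depth, 1L)) >= model$min_vaf
  ok
}

#' Run the reference detection model over pileup sites
#'
#' @param sites pileup data.frame.
#' @param model a [detection_model()].
#' @return `sites` with appended columns `vaf`, `error_p` (upper-tail
#'   binomial probability under the error model, `NA` when the test is
#'   disabled) and logical `detected`.
#' @export
detect_pileups <- function(sites, model = detection_model()) {
  stopifnot(inherits(model, "detection_model"))
  out <- sites
  out$vaf <- ifelse(sites$depth > 0, sites$alt_count / sites$depth, 0)
  out$error_p <- if (is.null(model$alpha)) NA_real_ else
    stats::pbinom(sites$alt_count - 1L, pmax(sites$depth, 1L),
                  model$error_rate / 3, lower.tail = FALSE)
  out$detected <- .detect_counts(sites$depth, sites$alt_count, model)
  out
}

#' Detect a single site, returning a variant call or NULL
#'
#' @param site single-row pileup data.frame.
#' @param model a [detection_model()].
#' @return a single-row variant call data.frame (see
#'   [as_variant_calls()]) or `NULL` when the site is not called.
#' @export
detect_site <- function(site, model = detection_model()) {
  stopifnot(nrow(site) == 1L)
  d <- detect_pileups(site, model)
  if (!d$detected) return(NULL)
  as_variant_calls(d)
}

#' Build a variant call table from detected pileups
#'
#' @param detected output of [detect_pileups()]; only rows with
#'   `detected == TRUE` are kept.
#' @return data.frame of calls with identity columns, `depth`,
#'   `alt_count`, `vaf`, filter flags (all clear), `tier` (`NA` until
#'   classified) and `is_hotspot`.
#' @export
as_variant_calls <- function(detected) {
  keep <- if (is.null(detected$detected)) rep(TRUE, nrow(detected))
          else detected$detected
  d <- detected[keep, , drop = FALSE]
  out <- data.frame(
    chrom = d$chrom, pos = d$pos, ref = d$ref_base, alt = d$alt_base,
    depth = d$depth, alt_count = d$alt_count,
    vaf = ifelse(d$depth > 0, d$alt_count / d$depth, 0),
    flag_germline_vaf = FALSE, flag_pon = FALSE,
    flag_blacklist = FALSE, flag_lr_artifact = FALSE,
    is_hotspot = FALSE, tier = NA_integer_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
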