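#' Germline/artifact filter thresholds
#'
#' @param germline_vaf_cutoff VAF at or above which a non-hotspot call
#'   is treated as germline (default 0.97; ties removed).
#' @param pon_af_cutoff panel-of-normals population allele frequency
#'   strictly above which a call is removed (default 0.03).
#' @param lr_score_cutoff decision threshold of the regression artifact
#'   filter; `NULL` defers to the trained model's ROC-selected value.
#' @return an object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(germline_vaf_cutoff = 0.97,
                              pon_af_cutoff = 0.03,
                              lr_score_cutoff = NULL) {
  stopifnot(germline_vaf_cutoff > 0, germline_vaf_cutoff <= 1,
            pon_af_cutoff > 0, pon_af_cutoff <= 1)
  if (!is.null(lr_score_cutoff))
    stopifnot(lr_score_cutoff > 0, lr_score_cutoff < 1)
  structure(list(germline_vaf_cutoff = germline_vaf_cutoff,
                 pon_af_cutoff = pon_af_cutoff,
                 lr_score_cutoff = lr_score_cutoff),
            class = "filter_thresholds")
}

.pos_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

#' Apply germline, panel-of-normals, blacklist and artifact filters
#'
#' Sets four independent filter flags on a call set: (i) very high VAF
#' (>= 97% by default) at non-hotspot positions, treated as putative
#' germline; (ii) population allele frequency above 3% in the
#' panel-of-normals cohort; (iii) membership in a curated blacklist of
#' recurrent alignment artifacts; (iv) the regression artifact filter.
#' Flags are set independently, so applying them in any order yields
#' the same surviving set.
#'
#' @param calls variant call data.frame (see [as_variant_calls()]).
#' @param cohort optional `normal_cohort`; positions absent from the
#'   cohort are treated as population AF 0.
#' @param hotspots optional data.frame (`chrom`, `pos`) of hotspot
#'   positions exempt from the high-VAF rule.
#' @param blacklist optional data.frame (`chrom`, `pos`).
#' @param lr optional trained [train_fp_filter()] model.
#' @param lr_features feature data.frame aligned with `calls`
#'   (required when `lr` is given).
#' @param thresholds a [filter_thresholds()].
#' @return `calls` with flags and `is_hotspot` filled in and a logical
#'   `pass` column; attribute `removal_counts` tallies removals per
#'   filter.
#' @export
apply_filters <- function(calls, cohort = NULL, hotspots = NULL,
                          blacklist = NULL, lr = NULL, lr_features = NULL,
                          thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  out <- calls
  key <- .pos_key(calls$chrom, calls$pos)
  out$is_hotspot <- if (!is.null(hotspots) && nrow(hotspots) > 0)
    key %in% .pos_key(hotspots$chrom, hotspots$pos) else FALSE
  out$flag_germline_vaf <- out$vaf >= thresholds$germline_vaf_cutoff &
    !out$is_hotspot
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "normal_cohort"))
    af <- cohort$sites$cohort_af[
      match(key, .pos_key(cohort$sites$chrom, cohort$sites$pos))]
    af[is.na(af)] <- 0
    out$flag_pon <- af > thresholds$pon_af_cutoff
    out$pon_af <- af
  } else {
    out$flag_pon <- FALSE
    out$pon_af <- 0
  }
  out$flag_blacklist <- if (!is.null(blacklist) && nrow(blacklist) > 0)
    key %in% .pos_key(blacklist$chrom, blacklist$pos) else FALSE
  if (!is.null(lr)) {
    if (is.null(lr_features))
      stop("lr_features must be supplied along with a trained lr model")
    cutoff <- if (!is.null(thresholds$lr_score_cutoff))
      thresholds$lr_score_cutoff else lr$threshold
    out$lr_score <- predict(lr, lr_features)
    out$flag_lr_artifact <- out$lr_score > cutoff
  } else {
    out$flag_lr_artifact <- FALSE
  }
  out$pass <- !(out$flag_germline_vaf | out$flag_pon |
                  out$flag_blacklist | out$flag_lr_artifact)
  attr(out, "removal_counts") <- c(
    germline_vaf = sum(out$flag_germline_vaf),
    pon = sum(out$flag_pon),
    blacklist = sum(out$flag_blacklist),
    lr_artifact = sum(out$flag_lr_artifact))
  out
}

#' Classify variant calls into clinical tiers
#'
#' Tier 1: positions on the actionable (therapy-linked) list.
#' Tier 2: any other mutation reported in COSMIC.
#' Tier 3: everything else.
#'
#' @param calls variant call data.frame.
#' @param tier1_positions data.frame (`chrom`, `pos`) of actionable
#'   positions.
#' @param cosmic_positions data.frame (`chrom`, `pos`) of COSMIC
#'   positions.
#' @return `calls` with the `tier` column filled in.
#' @export
classify_tier <- function(calls, tier1_positions = NULL,
                          cosmic_positions = NULL) {
  key <- .pos_key(calls$chrom, calls$pos)
  in_t1 <- if (!is.null(tier1_positions) && nrow(tier1_positions) > 0)
    key %in% .pos_key(tier1_positions$chrom, tier1_positions$pos) else FALSE
  in_cos <- if (!is.null(cosmic_positions) && nrow(cosmic_positions) > 0)
    key %in% .pos_key(cosmic_positions$chrom, cosmic_positions$pos) else FALSE
  calls$tier <- ifelse(in_t1, 1L, ifelse(in_cos, 2L, 3L))
  calls
}

#' Classify fusion calls into clinical tiers
#'
#' A fusion of a target gene with a known partner is Tier 1; a novel
#' partner is Tier 2.
#'
#' @param fusions fusion call data.frame with `gene_a`, `gene_b`.
#' @param known_partners character vector of known partner genes.
#' @return `fusions` with a `tier` column.
#' @export
classify_fusion_tier <- function(fusions, known_partners = character(0)) {
  fusions$tier <- ifelse(fusions$gene_a %in% known_partners |
                           fusions$gene_b %in% known_partners, 1L, 2L)
  fusions
}
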