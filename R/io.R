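#' Write a pileup table as TSV
#'
#' The variant read offset list-column is serialized as a
#' comma-separated string; all other columns are written as-is with a
#' documented header.
#'
#' @param sites pileup data.frame.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_pileup_tsv <- function(sites, path) {
  out <- sites
  if (!is.null(out$alt_read_offsets)) {
    out$alt_read_offsets <- vapply(out$alt_read_offsets,
                                   function(o) paste(o, collapse = ","),
                                   character(1))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pileup table written by [write_pileup_tsv()]
#'
#' @param path TSV path.
#' @return pileup data.frame with the offset list-column restored.
#' @export
read_pileup_tsv <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "depth", "alt_count")
  missing <- setdiff(need, names(out))
  if (length(missing) > 0L)
    stop("pileup TSV is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!is.null(out$alt_read_offsets)) {
    out$alt_read_offsets <- I(lapply(as.character(out$alt_read_offsets),
                                     function(s) {
      if (is.na(s) || s == "") integer(0)
      else as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
    }))
  }
  out
}

#' Read panel regions from a BED file
#'
#' BED intervals are 0-based half-open on disk; they are returned
#' 1-based inclusive, the package's internal convention.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive)
#'   and `name` when present.
#' @export
read_panel_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Read a position list (hotspots, blacklist, COSMIC) from TSV
#'
#' @param path TSV with header columns `chrom`, `pos` and optionally
#'   `ref`, `alt`.
#' @return data.frame of positions.
#' @export
read_positions_tsv <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  missing <- setdiff(c("chrom", "pos"), names(out))
  if (length(missing) > 0L)
    stop("position TSV is missing required column(s): ",
         paste(missing, collapse = ", "))
  out
}

#' Export variant calls as VCF 4.2
#'
#' FILTER entries GERMLINE_VAF, PON, BLACKLIST and LR_ARTIFACT mirror
#' the filter flags; INFO carries VAF, TIER, DP and AC.
#'
#' @param calls filtered variant call data.frame.
#' @param path output path.
#' @param sample_name sample column name.
#' @return `path` invisibly.
#' @export
write_vcf <- function(calls, path, sample_name = "SAMPLE") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=panelvaf",
    "##FILTER=<ID=GERMLINE_VAF,Description=\"VAF >= 97% at a non-hotspot position (putative germline)\">",
    "##FILTER=<ID=PON,Description=\"Population allele frequency > 3% in the panel of normals\">",
    "##FILTER=<ID=BLACKLIST,Description=\"Curated recurrent artifact position\">",
    "##FILTER=<ID=LR_ARTIFACT,Description=\"Regression artifact filter\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=TIER,Number=1,Type=Integer,Description=\"Clinical tier (1 actionable, 2 COSMIC, 3 other)\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Deduplicated depth\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Variant-supporting reads\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  filt <- vapply(seq_len(nrow(calls)), function(i) {
    f <- c(if (isTRUE(calls$flag_germline_vaf[i])) "GERMLINE_VAF",
           if (isTRUE(calls$flag_pon[i])) "PON",
           if (isTRUE(calls$flag_blacklist[i])) "BLACKLIST",
           if (isTRUE(calls$flag_lr_artifact[i])) "LR_ARTIFACT")
    if (length(f) == 0L) "PASS" else paste(f, collapse = ";")
  }, character(1))
  info <- sprintf("VAF=%.6g;TIER=%s;DP=%d;AC=%d", calls$vaf,
                  ifelse(is.na(calls$tier), ".", calls$tier),
                  calls$depth, calls$alt_count)
  body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                filt, info, "GT", "0/1", sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Every pipeline run records its configuration, seed and package
#' version so outputs can be reproduced bit for bit.
#'
#' @param path JSON output path.
#' @param config named list of parameters.
#' @param seed the seed used.
#' @return `path` invisibly.
#' @export
write_run_manifest <- function(path, config, seed) {
  manifest <- list(
    package = "panelvaf",
    version = as.character(utils::packageVersion("panelvaf")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
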