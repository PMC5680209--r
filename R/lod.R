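#' Run an in silico dilution grid
#'
#' For every target VAF, every replicate dilutes each heterozygous
#' substrate site down to that VAF ([dilute_in_silico()]) and then
#' thins the pool to each target depth by binomial downsampling
#' ([pool_downsample()]), scoring detection with the reference model.
#' Trials are binned by *realized* VAF: only trials whose diluted VAF
#' lies within `vaf_bin_tol` relative of the nominal target contribute
#' to that target's bin, mirroring the concern that the true
#' concentration of a dilution differs from the intended one.
#'
#' @param het_sites substrate pileup data.frame (heterozygous SNPs at
#'   high depth; every site must have observed VAF above the largest
#'   target).
#' @param vafs target VAFs.
#' @param depths target depths.
#' @param model a [detection_model()].
#' @param reps dilution replicates per site per cell (default 10).
#' @param seed optional integer seed.
#' @param vaf_bin_tol relative half-width of the realized-VAF bin
#'   (default 0.2).
#' @param thinning `"pool"` (default) thins every read independently so
#'   realized depths vary binomially around the target, emulating
#'   down-sampling a pool at a fraction; `"fixed"` draws exactly the
#'   target depth without replacement (hypergeometric), which pins the
#'   realized depth and is the design matched by the exact fixed-depth
#'   binomial oracle.
#' @return data.frame of sensitivity records: `vaf_bin`, `depth_bin`,
#'   `n_trials`, `n_detected`.
#' @export
run_dilution_grid <- function(het_sites, vafs, depths,
                              model = detection_model(), reps = 10L,
                              seed = NULL, vaf_bin_tol = 0.2,
                              thinning = c("pool", "fixed")) {
  thinning <- match.arg(thinning)
  if (!is.null(seed)) set.seed(seed)
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be at least 1")
  if (nrow(het_sites) == 0L || length(vafs) == 0L || length(depths) == 0L)
    stop("het_sites, vafs and depths must all be nonempty")
  obs <- het_sites$alt_count / pmax(het_sites$depth, 1L)
  if (any(obs < max(vafs)))
    stop("some substrate sites have observed VAF below the largest target")
  n <- nrow(het_sites)
  depth0 <- het_sites$depth
  alt0 <- het_sites$alt_count
  grid <- expand.grid(vaf_bin = vafs, depth_bin = depths)
  n_trials <- n_detected <- numeric(nrow(grid))
  for (vi in seq_along(vafs)) {
    v <- vafs[vi]
    for (r in seq_len(reps)) {
      # dilution: each variant read kept with probability v / observed
      alt_d <- stats::rbinom(n, alt0, v / obs)
      realized <- alt_d / pmax(depth0, 1L)
      in_bin <- abs(realized - v) <= vaf_bin_tol * v
      for (di in seq_along(depths)) {
        d <- depths[di]
        usable <- in_bin & depth0 >= d
        if (!any(usable)) next
        if (thinning == "pool") {
          frac <- pmin(d / depth0, 1)
          alt_s <- stats::rbinom(n, alt_d, frac)
          dep_s <- alt_s + stats::rbinom(n, depth0 - alt_d, frac)
        } else {
          alt_s <- stats::rhyper(n, alt_d, depth0 - alt_d,
                                 pmin(d, depth0))
          dep_s <- rep.int(as.integer(d), n)
        }
        det <- .detect_counts(dep_s, alt_s, model)
        k <- which(grid$vaf_bin == v & grid$depth_bin == d)
        n_trials[k] <- n_trials[k] + sum(usable)
        n_detected[k] <- n_detected[k] + sum(det[usable])
      }
    }
  }
  grid$n_trials <- as.integer(n_trials)
  grid$n_detected <- as.integer(n_detected)
  grid[order(grid$vaf_bin, grid$depth_bin), ]
}

#' Fit a probit sensitivity model on log10 depth
#'
#' Maximum-likelihood probit regression of detection outcome on
#' log10(depth): sensitivity(d) = Phi(a + b log10 d). Complete (or
#' quasi-complete) separation -- every depth bin fully detected or
#' fully missed -- is handled by a bias-reduced refit with Jeffreys-type
#' pseudo-counts (half a success and half a failure per bin) and
#' flagged.
#'
#' @param records sensitivity records for a single VAF bin
#'   (`depth_bin`, `n_trials`, `n_detected`).
#' @return object of class `probit_model` with intercept `a`, slope
#'   `b`, the `glm` fit, `vaf_bin`, deviance diagnostics and a
#'   `separation` flag.
#' @export
fit_probit <- function(records) {
  records <- records[records$n_trials > 0, , drop = FALSE]
  if (length(unique(records$vaf_bin)) > 1L)
    stop("fit_probit expects records for a single VAF bin")
  if (length(unique(records$depth_bin)) < 2L)
    stop("need at least 2 distinct depth bins")
  rate <- records$n_detected / records$n_trials
  degenerate <- all(rate %in% c(0, 1))
  fml <- cbind(n_detected, n_trials - n_detected) ~ log10(depth_bin)
  quiet_glm <- function(dat) {
    warned <- FALSE
    fit <- withCallingHandlers(
      stats::glm(fml, data = dat, family = stats::binomial(link = "probit")),
      warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") })
    list(fit = fit, warned = warned)
  }
  g <- quiet_glm(records)
  co <- stats::coef(g$fit)
  separation <- degenerate || g$warned || !g$fit$converged ||
    any(!is.finite(co)) || abs(co[2]) > 50
  if (separation) {
    aug <- records
    aug$n_detected <- records$n_detected + 0.5
    aug$n_trials <- records$n_trials + 1
    g <- quiet_glm(aug)
    co <- stats::coef(g$fit)
  }
  structure(list(a = unname(co[1]), b = unname(co[2]),
                 vaf_bin = if (!is.null(records$vaf_bin))
                   records$vaf_bin[1] else NA_real_,
                 fit = g$fit, deviance = stats::deviance(g$fit),
                 df_residual = stats::df.residual(g$fit),
                 vcov = stats::vcov(g$fit),
                 separation = separation),
            class = "probit_model")
}

#' Construct a probit sensitivity model from known coefficients
#'
#' Mainly for interpolation or testing against analytic curves;
#' sensitivity(d) = Phi(a + b log10 d).
#'
#' @param a intercept.
#' @param b slope per log10 read (must be positive to be invertible).
#' @param vaf_bin the VAF the model is calibrated for.
#' @return a `probit_model`.
#' @export
probit_model <- function(a, b, vaf_bin = NA_real_) {
  structure(list(a = a, b = b, vaf_bin = vaf_bin, fit = NULL,
                 deviance = NA_real_, df_residual = NA_integer_,
                 vcov = NULL, separation = FALSE),
            class = "probit_model")
}

#' @method print probit_model
#' @export
print.probit_model <- function(x, ...) {
  cat(sprintf(
    "Probit sensitivity model%s: Phi(%.3f + %.3f log10 d)%s\n",
    if (is.na(x$vaf_bin)) "" else sprintf(" (VAF %g)", x$vaf_bin),
    x$a, x$b, if (x$separation) " [bias-reduced: separation]" else ""))
  invisible(x)
}

#' Predicted sensitivity of a probit model at given depths
#'
#' @param object a `probit_model`.
#' @param depth depths (reads).
#' @param ... unused.
#' @return vector of sensitivities.
#' @export
predict.probit_model <- function(object, depth, ...) {
  stats::pnorm(object$a + object$b * log10(depth))
}

#' Depth achieving a target sensitivity
#'
#' Inverts the probit curve: `depth = 10^((qnorm(s) - a) / b)`.
#'
#' @param model a `probit_model` with positive slope.
#' @param s target sensitivity (default 0.95, the conventional LOD
#'   definition).
#' @return depth in reads.
#' @export
depth_for_sensitivity <- function(model, s = 0.95) {
  stopifnot(inherits(model, "probit_model"), s > 0, s < 1)
  if (!is.finite(model$b) || model$b <= 0)
    stop("probit slope must be positive to invert the sensitivity curve")
  10^((stats::qnorm(s) - model$a) / model$b)
}

#' Limit of detection at a given depth
#'
#' The LOD at depth d is the smallest calibrated VAF whose
#' 95%-sensitivity depth is at most d. Queries outside the calibrated
#' range are flagged: above every 95% depth the smallest calibrated VAF
#' is returned with flag `"above_range"`; below the 95% depth of even
#' the largest calibrated VAF no LOD exists and flag `"below_range"`
#' is returned with `lod = NA`.
#'
#' @param models list of `probit_model`s, one per calibrated VAF.
#' @param depth query depth.
#' @param s target sensitivity.
#' @return list with `lod`, `flag` (`"ok"`, `"above_range"`,
#'   `"below_range"`) and the `depth_at_s` table used.
#' @export
lod_at_depth <- function(models, depth, s = 0.95) {
  stopifnot(length(models) >= 2L)
  vaf <- vapply(models, function(m) m$vaf_bin, numeric(1))
  d95 <- vapply(models, depth_for_sensitivity, numeric(1), s = s)
  o <- order(vaf)
  vaf <- vaf[o]; d95 <- d95[o]
  tab <- data.frame(vaf = vaf, depth_at_s = d95)
  ok <- which(d95 <= depth)
  if (length(ok) == 0L)
    return(list(lod = NA_real_, flag = "below_range", depth_at_s = tab))
  lod <- vaf[min(ok)]
  # depth strictly above every calibrated 95% depth: the true LOD may be
  # below the smallest calibrated VAF, so flag the extrapolation
  flag <- if (depth > max(d95)) "above_range" else "ok"
  list(lod = lod, flag = flag, depth_at_s = tab)
}

#' Detection rate under read downsampling of patient sites
#'
#' Downsamples each site (hypergeometric, [downsample_site()]) to each
#' target depth over `n_iter` iterations and reports the mean detection
#' rate under the reference model, with its standard error. Sites
#' shallower than a target depth are skipped with a warning. Sites are
#' assumed detected at full depth.
#'
#' @param sites patient pileup data.frame.
#' @param depths target depths.
#' @param model a [detection_model()].
#' @param n_iter iterations per site per depth (default 10).
#' @param seed optional integer seed.
#' @return data.frame with `depth`, `n_sites`, `rate`, `se`.
#' @export
detection_rate_by_downsampling <- function(sites, depths,
                                           model = detection_model(),
                                           n_iter = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_iter <- as.integer(n_iter)
  stopifnot(n_iter >= 1L)
  out <- lapply(depths, function(d) {
    use <- sites$depth >= d
    if (any(!use))
      warning(sum(!use), " site(s) shallower than ", d, "x skipped")
    if (!any(use))
      return(data.frame(depth = d, n_sites = 0L, rate = NA_real_,
                        se = NA_real_))
    sub <- sites[use, , drop = FALSE]
    n <- nrow(sub)
    det <- matrix(FALSE, n, n_iter)
    for (it in seq_len(n_iter)) {
      alt2 <- stats::rhyper(n, sub$alt_count, sub$depth - sub$alt_count, d)
      det[, it] <- .detect_counts(rep.int(as.integer(d), n), alt2, model)
    }
    site_rate <- rowMeans(det)
    data.frame(depth = d, n_sites = n, rate = mean(site_rate),
               se = stats::sd(site_rate) / sqrt(n))
  })
  do.call(rbind, out)
}

#' Per-position limit-of-detection report
#'
#' Annotates each panel position with the LOD achievable at its
#' observed depth. Positions whose LOD exceeds `lod_ceiling` (or where
#' no calibrated VAF reaches the target sensitivity) are marked
#' `"insufficient power"`; zero-depth positions are marked
#' `"no power"`.
#'
#' @param positions data.frame with `chrom`, `pos`, `depth`.
#' @param models list of `probit_model`s per calibrated VAF.
#' @param lod_ceiling VAF above which a position is reported as
#'   underpowered (default 0.5).
#' @param s target sensitivity.
#' @param path optional TSV output path.
#' @return data.frame with `chrom`, `pos`, `depth`, `lod`, `status`.
#' @export
lod_report <- function(positions, models, lod_ceiling = 0.5, s = 0.95,
                       path = NULL) {
  res <- lapply(seq_len(nrow(positions)), function(i) {
    d <- positions$depth[i]
    if (is.na(d) || d <= 0)
      return(data.frame(lod = NA_real_, status = "no power"))
    r <- lod_at_depth(models, d, s = s)
    if (is.na(r$lod) || r$lod > lod_ceiling)
      data.frame(lod = r$lod, status = "insufficient power")
    else
      data.frame(lod = r$lod, status = "ok")
  })
  out <- cbind(positions[, c("chrom", "pos", "depth")], do.call(rbind, res))
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

#' Fit probit sensitivity models for every VAF bin of a dilution grid
#'
#' @param records output of [run_dilution_grid()].
#' @return named list of `probit_model`s keyed by VAF bin.
#' @export
fit_probit_grid <- function(records) {
  vafs <- sort(unique(records$vaf_bin))
  models <- lapply(vafs, function(v)
    fit_probit(records[records$vaf_bin == v, , drop = FALSE]))
  names(models) <- as.character(vafs)
  models
}
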