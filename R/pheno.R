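#' Multi-environment line BLUPs
#'
#' Fits `value = mu + location + year + line + error` with location and year
#' as fixed effects and line as a random effect (REML via lme4), and returns
#' the shrunken line effect plus the grand fixed-effect mean as each line's
#' BLUP. Fixed terms with a single observed level are dropped automatically so
#' that small fixtures remain identifiable. In balanced data the BLUP ranking
#' equals the line-mean ranking, and as residual variance vanishes BLUPs
#' converge to per-line means.
#'
#' @param tt Trait table: data frame with columns `sample`, `trait`,
#'   `location`, `year`, `value`.
#' @param trait Trait name to fit.
#' @return Data frame with columns `sample`, `trait`, `blup`.
#' @export
fit_line_blup <- function(tt, trait) {
  dat <- tt[tt$trait == trait, , drop = FALSE]
  if (nrow(dat) == 0L) hf_stop("no records for trait '", trait, "'")
  if (anyDuplicated(dat[, c("sample", "trait", "location", "year")])) {
    hf_stop("duplicate (sample, trait, location, year) records")
  }
  if (!all(is.finite(dat$value))) hf_stop("phenotype values must be finite")
  if (length(unique(dat$sample)) < 2L) hf_stop("need >= 2 lines")
  dat$sample <- factor(dat$sample)
  dat$location <- factor(dat$location)
  dat$year <- factor(dat$year)
  fixed <- c(if (nlevels(dat$location) > 1L) "location",
             if (nlevels(dat$year) > 1L) "year")
  rhs <- paste(c(fixed, "(1 | sample)"), collapse = " + ")
  n_fixed <- 1L + sum(c(nlevels(dat$location) - 1L, nlevels(dat$year) - 1L) *
                        c(nlevels(dat$location) > 1L, nlevels(dat$year) > 1L))
  if (nrow(dat) <= n_fixed + 1L) hf_stop("zero residual degrees of freedom")
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(stats::as.formula(paste("value ~", rhs)), data = dat,
               REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  mu <- mean(stats::model.matrix(fit) %*% lme4::fixef(fit))
  re <- lme4::ranef(fit)$sample
  data.frame(sample = rownames(re), trait = trait,
             blup = mu + re[, 1], stringsAsFactors = FALSE, row.names = NULL)
}

#' Check-row spatial adjustment
#'
#' Removes local field heterogeneity using repeated check entries: within each
#' (trait, location, year) stratum, every plot value is shifted by minus
#' (mean of check values within `window` rows of the plot - global check
#' mean). Spatially flat checks leave values unchanged; a single check yields
#' the identity (global correction only). Requires a `row` column giving field
#' row order.
#'
#' @param tt Trait table with columns `sample`, `trait`, `location`, `year`,
#'   `value`, `row`.
#' @param check_id Sample ID of the repeated check entry.
#' @param window Half-width, in rows, of the local check neighbourhood.
#' @return The trait table with adjusted `value`s.
#' @export
check_row_adjust <- function(tt, check_id, window = 25L) {
  if (!"row" %in% names(tt)) hf_stop("trait table needs a 'row' column")
  strata <- interaction(tt$trait, tt$location, tt$year, drop = TRUE)
  out <- tt
  for (s in levels(strata)) {
    i <- which(strata == s)
    chk <- i[tt$sample[i] == check_id]
    if (!length(chk)) {
      warning("no check rows in stratum ", s, ": values unchanged")
      next
    }
    g <- mean(tt$value[chk])
    crow <- tt$row[chk]; cval <- tt$value[chk]
    for (k in i) {
      near <- abs(crow - tt$row[k]) <= window
      local <- if (any(near)) mean(cval[near]) else g
      out$value[k] <- tt$value[k] - (local - g)
    }
  }
  out
}

#' z-score normalisation and its exact inverse
#'
#' `zscore(x)` maps values to `(x - mean) / sd` and attaches the transform so
#' predictions can be mapped back to absolute trait units with
#' `inverse_zscore(z, transform)`, i.e. `z * sd + mean`. Transforms are
#' estimated within one population (one tester's hybrids constitute one
#' population).
#'
#' @param x Numeric vector (>= 2 distinct values when `transform` is NULL).
#' @param transform A transform as returned in the `transform` attribute (list
#'   with `mean` and `sd`), to apply instead of estimating one.
#' @return For `zscore`: the z values with attribute `transform`. For
#'   `inverse_zscore`: values in original units.
#' @export
#' @examples
#' z <- zscore(c(1, 2, 3))
#' inverse_zscore(z, attr(z, "transform"))
zscore <- function(x, transform = NULL) {
  if (is.null(transform)) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) hf_stop("cannot z-score a constant vector")
    transform <- list(mean = mean(x), sd = s)
  }
  if (transform$sd <= 0) hf_stop("transform sd must be positive")
  structure((x - transform$mean) / transform$sd, transform = transform)
}

#' @rdname zscore
#' @param z Numeric vector of z values.
#' @export
inverse_zscore <- function(z, transform) {
  if (is.null(transform$sd) || transform$sd <= 0) {
    hf_stop("invalid z-score transform")
  }
  as.numeric(z) * transform$sd + transform$mean
}

#' Mid-parent heterosis
#'
#' `MPH = (y_h - (y_m + y_p) / 2) / ((y_m + y_p) / 2)`: the hybrid's relative
#' deviation from its parents' mean. Dimensionless, symmetric in the two
#' parents and invariant to a common positive rescaling of all three inputs.
#' A zero mid-parent value leaves MPH undefined (`NA`, with a warning).
#'
#' @param y_h,y_m,y_p Hybrid, maternal and paternal trait values (vectors
#'   recycle as usual).
#' @return Numeric vector of MPH scores.
#' @export
#' @examples
#' compute_mph(10, 4, 6)  # 1: the hybrid doubles the mid-parent value
compute_mph <- function(y_h, y_m, y_p) {
  mid <- (y_m + y_p) / 2
  mph <- (y_h - mid) / mid
  bad <- !is.na(mid) & mid == 0
  if (any(bad)) {
    warning(sum(bad), " cross(es) with zero mid-parent value: MPH undefined")
    mph[bad] <- NA_real_
  }
  mph
}
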