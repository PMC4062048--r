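#' Mean target molecules per droplet from negative-droplet counts
#'
#' Digital PCR quantification rests on the Poisson occupancy model: when
#' molecules are confined independently and uniformly into droplets, the
#' number per droplet is Poisson with mean lambda, so the fraction of
#' negative droplets estimates `exp(-lambda)` and
#' `lambda = -log(n_negative / n_total)`.
#'
#' @param n_negative Number of droplets negative for the target (vectorised).
#' @param n_total Total accepted droplets (vectorised).
#' @return Numeric vector of lambda estimates (molecules per droplet).
#'   An all-negative well returns exactly 0.
#' @details A well with no negative droplets is *saturated*: lambda is
#'   unbounded and a classed error (`ddpcrlink_error_saturation`) is raised.
#'   Pipeline wrappers such as [quantify_channels()] catch this state and
#'   report it as a `saturated` flag instead.
#' @examples
#' lambda_from_counts(3679, 10000)
#' @export
lambda_from_counts <- function(n_negative, n_total) {
  check_counts(n_negative, n_total)
  if (any(n_negative == 0)) {
    stop_ddpcr("no negative droplets: lambda is unbounded (saturated well)",
               class = "ddpcrlink_error_saturation")
  }
  -log(n_negative / n_total)
}

check_counts <- function(n_negative, n_total) {
  if (length(n_negative) == 0 || length(n_total) == 0 ||
      any(is.na(n_negative)) || any(is.na(n_total))) {
    stop_ddpcr("counts must be non-missing", class = "ddpcrlink_error_counts")
  }
  if (any(n_total <= 0)) {
    stop_ddpcr("n_total must be positive", class = "ddpcrlink_error_counts")
  }
  if (any(n_negative < 0) || any(n_negative > n_total)) {
    stop_ddpcr("n_negative must lie in [0, n_total]",
               class = "ddpcrlink_error_counts")
  }
  invisible(TRUE)
}

#' Delta-method confidence interval for lambda
#'
#' The negative fraction `p = n_negative / n_total` is binomial; propagating
#' its variance through `lambda = -log(p)` gives
#' `se(lambda) = sqrt((1 - p) / (n_total * p))`. The interval is the
#' symmetric normal interval `lambda +/- z * se`, with the lower bound
#' clamped at zero. This is standard digital-PCR practice.
#'
#' @inheritParams lambda_from_counts
#' @param level Confidence level (default 0.95).
#' @return A tibble with columns `lambda`, `se`, `ci_low`, `ci_high`.
#' @examples
#' lambda_ci(3679, 10000)
#' @export
lambda_ci <- function(n_negative, n_total, level = 0.95) {
  lambda <- lambda_from_counts(n_negative, n_total)
  p <- n_negative / n_total
  se <- sqrt((1 - p) / (n_total * p))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    lambda = lambda,
    se = se,
    ci_low = pmax(0, lambda - z * se),
    ci_high = lambda + z * se
  )
}

#' Concentration estimate for one channel of a well
#'
#' Converts the per-droplet mean into copies per microliter by dividing by
#' the droplet volume: 1 molecule per 1-nL droplet is 1000 copies/uL. The
#' droplet nano-reactor volume defaults to 1 nL (1e-9 L); 0.85 nL is a
#' common instrument calibration and can be passed instead. All ratio
#' statistics downstream (%L, copy number) are volume-independent.
#'
#' @inheritParams lambda_ci
#' @param droplet_volume_nl Droplet volume in nanoliters (default 1).
#' @return A one-row-per-input tibble: `lambda_hat`, `concentration`
#'   (copies/uL), `ci_low`, `ci_high` (copies/uL), `n_droplets`,
#'   `droplet_volume_nl`, `saturated`.
#' @examples
#' concentration_estimate(3679, 10000)           # lambda 1 -> 1000 copies/uL
#' concentration_estimate(3679, 10000, droplet_volume_nl = 0.85)
#' @export
concentration_estimate <- function(n_negative, n_total,
                                   droplet_volume_nl = 1, level = 0.95) {
  if (any(droplet_volume_nl <= 0)) {
    stop_ddpcr("droplet_volume_nl must be positive",
               class = "ddpcrlink_error_input")
  }
  check_counts(n_negative, n_total)
  saturated <- n_negative == 0
  lambda <- se <- lo <- hi <- rep(NA_real_, length(saturated))
  if (any(!saturated)) {
    ci <- lambda_ci(n_negative[!saturated], n_total[!saturated], level)
    lambda[!saturated] <- ci$lambda
    se[!saturated] <- ci$se
    lo[!saturated] <- ci$ci_low
    hi[!saturated] <- ci$ci_high
  }
  # molecules per nL-droplet -> copies per uL (1000 nL per uL)
  scale <- 1000 / droplet_volume_nl
  tibble::tibble(
    lambda_hat = lambda,
    concentration = lambda * scale,
    ci_low = lo * scale,
    ci_high = hi * scale,
    n_droplets = as.integer(n_total),
    droplet_volume_nl = droplet_volume_nl,
    saturated = saturated
  )
}

#' Quantify both channels of every well in a droplet table
#'
#' The data-frame entry point for Poisson quantification: takes a droplet
#' quadrant-count table (one row per well, as read by
#' [read_droplet_table()] or emitted by the simulator) and returns one row
#' per well x channel with the concentration estimate and QC flags.
#' Saturated channels (no negative droplets) are flagged rather than
#' raising an error; wells with fewer accepted droplets than `min_droplets`
#' are flagged `qc_pass = FALSE`.
#'
#' @param df Droplet table with quadrant-count columns; identifying columns
#'   (`well`, `sample_id`, `assay`, `digested`, target names) are carried
#'   through when present.
#' @param droplet_volume_nl Droplet volume in nanoliters (default 1 nL).
#' @param level Confidence level for the interval on the concentration.
#' @param min_droplets Minimum accepted droplets for QC (default 8000).
#' @return A tibble, two rows (channels A and B) per input well, with
#'   columns `channel`, `target`, `n_negative`, `n_total`, `lambda_hat`,
#'   `concentration`, `ci_low`, `ci_high`, `saturated`, `qc_pass`.
#' @examples
#' sim <- simulate_cnv_well(2, n_genomes = 2000, n_droplets = 20000, seed = 1)
#' quantify_channels(sim)
#' @export
quantify_channels <- function(df, droplet_volume_nl = 1, level = 0.95,
                              min_droplets = 8000) {
  df <- validate_quadrants(df)
  id_cols <- intersect(c("well", "sample_id", "assay", "digested"), names(df))
  per_channel <- function(channel) {
    m <- channel_marginals(df, channel)
    target_col <- if (channel == "A") "channel_a_target" else "channel_b_target"
    est <- concentration_estimate(
      # saturation handled per-row: estimate the non-saturated rows only
      pmax(m$n_negative, 1L), m$n_total, droplet_volume_nl, level
    )
    est$saturated <- m$n_negative == 0
    est[est$saturated, c("lambda_hat", "concentration", "ci_low", "ci_high")] <- NA_real_
    dplyr::bind_cols(
      df[id_cols],
      tibble::tibble(
        channel = channel,
        target = if (target_col %in% names(df)) df[[target_col]] else channel,
        n_negative = m$n_negative
      ),
      est
    )
  }
  out <- dplyr::bind_rows(per_channel("A"), per_channel("B"))
  out$qc_pass <- out$n_droplets >= min_droplets
  dplyr::arrange(out, dplyr::across(dplyr::any_of(c("well", "sample_id", "channel"))))
}
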