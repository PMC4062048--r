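#' Linked-molecule concentration from duplex quadrant counts
#'
#' When two targets are carried on one DNA fragment they enter the same
#' droplet together, so double-positive droplets are more frequent than the
#' independence expectation. Writing `p_nn` for the double-negative
#' fraction and `p_a_neg`, `p_b_neg` for the per-channel negative
#' fractions, the mean number of *linked* molecules per droplet is the
#' chance-corrected excess
#'
#' \deqn{\gamma = \lambda_A + \lambda_B - \lambda_\cup
#'   = \log\!\big(p_{nn} / (p_{A-} \, p_{B-})\big)}
#'
#' where \eqn{\lambda_\cup = -\log p_{nn}} is the mean count of molecules
#' carrying *either* target. Under independent confinement of unlinked
#' targets the expectation of gamma is zero; fully linked targets give
#' gamma equal to both channel means. gamma is also the maximum-likelihood
#' estimate of the linked-species rate in the three-species Poisson model
#' (A-only, B-only, linked AB molecules).
#'
#' @param df Droplet table of quadrant counts (see [quadrant_tbl()]).
#' @param droplet_volume_nl Droplet volume in nanoliters (default 1).
#' @return A tibble, one row per well: identifying columns plus
#'   `lambda_a`, `lambda_b`, `lambda_union`, `gamma`,
#'   `linked_concentration` (copies/uL of molecules carrying both targets).
#'   Point estimates of `gamma` can be slightly negative by sampling noise;
#'   they are reported as-is.
#' @examples
#' # fully linked molecules: single-positives impossible
#' linked_concentration(quadrant_tbl(n_nn = 9048, n_pn = 0, n_np = 0, n_pp = 952))
#' @export
linked_concentration <- function(df, droplet_volume_nl = 1) {
  df <- validate_quadrants(df)
  if (any(df$n_nn == 0)) {
    stop_ddpcr("no double-negative droplets: assay saturated, gamma unbounded",
               class = "ddpcrlink_error_saturation")
  }
  ma <- channel_marginals(df, "A")
  mb <- channel_marginals(df, "B")
  if (any(ma$n_negative == 0) || any(mb$n_negative == 0)) {
    stop_ddpcr("a channel is saturated (no negative droplets)",
               class = "ddpcrlink_error_saturation")
  }
  lambda_a <- lambda_from_counts(ma$n_negative, ma$n_total)
  lambda_b <- lambda_from_counts(mb$n_negative, mb$n_total)
  lambda_union <- lambda_from_counts(df$n_nn, df$n_total)
  gamma <- lambda_a + lambda_b - lambda_union
  id_cols <- intersect(
    c("well", "sample_id", "assay", "channel_a_target", "channel_b_target",
      "digested"),
    names(df)
  )
  dplyr::bind_cols(
    df[id_cols],
    tibble::tibble(
      n_droplets = df$n_total,
      lambda_a = lambda_a,
      lambda_b = lambda_b,
      lambda_union = lambda_union,
      gamma = gamma,
      linked_concentration = gamma * 1000 / droplet_volume_nl
    )
  )
}

norm_lambda <- function(lambda_a, lambda_b,
                        normalization = c("max_channel", "channel_a", "channel_b")) {
  normalization <- rlang::arg_match(normalization)
  switch(normalization,
    max_channel = pmax(lambda_a, lambda_b),
    channel_a = lambda_a,
    channel_b = lambda_b
  )
}

#' Normalized linkage score (%L)
#'
#' Expresses the linked-molecule concentration as a percentage of a
#' channel's total target concentration:
#' `%L = 100 * gamma / denominator`. The default denominator is the larger
#' of the two channel means (`max_channel`), which makes the expected score
#' respect copy-number ceilings: a diploid genome with two copies of one
#' target but a single linked copy of the other can reach at most %L = 50.
#' `channel_a` / `channel_b` normalize by a named channel instead, e.g. by
#' the partner gene of an anchor target.
#'
#' @param result A tibble from [linked_concentration()] (columns `gamma`,
#'   `lambda_a`, `lambda_b`), or a raw quadrant-count table, in which case
#'   [linked_concentration()] is applied first.
#' @param normalization One of `"max_channel"` (default), `"channel_a"`,
#'   `"channel_b"`.
#' @return The input tibble with columns `percent_linked` (raw; may be
#'   slightly negative by noise), `percent_linked_floor` (zero-floored
#'   convenience value) and `normalization` appended.
#' @examples
#' quadrant_tbl(9048, 0, 0, 952) |> percent_linked()
#' @export
percent_linked <- function(result,
                           normalization = c("max_channel", "channel_a", "channel_b")) {
  normalization <- rlang::arg_match(normalization)
  if (!all(c("gamma", "lambda_a", "lambda_b") %in% names(result))) {
    result <- linked_concentration(result)
  }
  denom <- norm_lambda(result$lambda_a, result$lambda_b, normalization)
  if (any(denom <= 0)) {
    stop_ddpcr("%L undefined: normalizing channel concentration is zero",
               class = "ddpcrlink_error_input")
  }
  result$percent_linked <- 100 * result$gamma / denom
  result$percent_linked_floor <- pmax(0, result$percent_linked)
  result$normalization <- normalization
  result
}

#' Bootstrap confidence interval for %L
#'
#' Percentile bootstrap over multinomial resamples of the four quadrant
#' counts of each well: each resample redraws `n_total` droplets from the
#' observed class proportions and recomputes %L. Resamples in which a
#' required class count hits zero (saturation) are dropped.
#'
#' @param df Droplet table of quadrant counts.
#' @inheritParams percent_linked
#' @param level Confidence level (default 0.95).
#' @param n_boot Number of multinomial resamples (default 2000).
#' @param seed Integer seed for reproducibility (default 1).
#' @return The [percent_linked()] tibble with `ci_low`, `ci_high` and
#'   `n_boot_used` columns appended.
#' @export
percent_linked_ci <- function(df,
                              normalization = c("max_channel", "channel_a", "channel_b"),
                              level = 0.95, n_boot = 2000, seed = 1) {
  normalization <- rlang::arg_match(normalization)
  df <- validate_quadrants(df)
  point <- percent_linked(df, normalization)
  alpha <- (1 - level) / 2
  boot_one <- function(i) {
    probs <- c(df$n_nn[i], df$n_pn[i], df$n_np[i], df$n_pp[i]) / df$n_total[i]
    draws <- stats::rmultinom(n_boot, df$n_total[i], probs)
    # saturation in a resample: drop it rather than propagate an error
    ok <- draws[1, ] > 0 &
      (draws[1, ] + draws[3, ]) > 0 & (draws[1, ] + draws[2, ]) > 0
    d <- draws[, ok, drop = FALSE]
    la <- -log((d[1, ] + d[3, ]) / df$n_total[i])
    lb <- -log((d[1, ] + d[2, ]) / df$n_total[i])
    lu <- -log(d[1, ] / df$n_total[i])
    pl <- 100 * (la + lb - lu) / norm_lambda(la, lb, normalization)
    qs <- stats::quantile(pl, c(alpha, 1 - alpha), names = FALSE)
    tibble::tibble(ci_low = qs[1], ci_high = qs[2], n_boot_used = sum(ok))
  }
  boots <- withr::with_seed(seed, purrr::map_dfr(seq_len(nrow(df)), boot_one))
  dplyr::bind_cols(point, boots)
}

#' Contrast undigested against restriction-digested aliquots
#'
#' Restriction digestion at a site between two linked targets physically
#' severs them, so a genuine linkage signal must collapse after digestion.
#' Given %L scores measured on paired undigested/digested aliquots of the
#' same sample and assay, this reports the drop and whether linkage was
#' *abrogated* (digested %L at or below `abrogation_fraction` times the
#' undigested score).
#'
#' @param df A tibble with columns `sample_id`, `assay`, `digested`
#'   (logical) and `percent_linked` — e.g. rows from [percent_linked()] on
#'   both aliquots. Alternatively a raw quadrant table carrying a
#'   `digested` column; %L is then computed with default normalization.
#' @param abrogation_fraction Relative threshold (default 0.5): digestion
#'   must at least halve the score.
#' @return One row per sample x assay: `percent_linked_undigested`,
#'   `percent_linked_digested`, `delta_percent_linked`, `abrogated`,
#'   `no_linkage` (flag: nothing measurable to abrogate).
#' @examples
#' wells <- dplyr::bind_rows(
#'   quadrant_tbl(9000, 100, 100, 800, sample_id = "s1", digested = FALSE),
#'   quadrant_tbl(8100, 900, 900, 100, sample_id = "s1", digested = TRUE))
#' digestion_contrast(wells)
#' @export
digestion_contrast <- function(df, abrogation_fraction = 0.5) {
  if (!"percent_linked" %in% names(df)) df <- percent_linked(df)
  if (!"digested" %in% names(df)) {
    stop_ddpcr("need a logical `digested` column to contrast aliquots",
               class = "ddpcrlink_error_columns")
  }
  group_cols <- intersect(c("sample_id", "assay"), names(df))
  wide <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols)), .data$digested) |>
    dplyr::summarise(percent_linked = mean(.data$percent_linked), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "digested", values_from = "percent_linked",
                       names_prefix = "dig_")
  if (!all(c("dig_FALSE", "dig_TRUE") %in% names(wide))) {
    stop_ddpcr("each sample/assay needs both an undigested and a digested aliquot",
               class = "ddpcrlink_error_input")
  }
  wide |>
    dplyr::transmute(
      dplyr::across(dplyr::all_of(group_cols)),
      percent_linked_undigested = .data$dig_FALSE,
      percent_linked_digested = .data$dig_TRUE,
      delta_percent_linked = .data$dig_FALSE - .data$dig_TRUE,
      no_linkage = .data$dig_FALSE <= 0,
      abrogated = !.data$no_linkage &
        .data$dig_TRUE <= abrogation_fraction * .data$dig_FALSE
    )
}

#' Call presence of a haplotype motif from a digestion contrast
#'
#' A two-gene haplotype motif (e.g. an anchor gene adjacent to its partner)
#' is called *present* when the undigested aliquot shows a linkage score
#' above `presence_threshold` **and** digestion abrogates it. Scores above
#' threshold but below `weak_threshold` are flagged as weak evidence — the
#' signature of linkage over an unusually long range or from a minority of
#' intact fragments.
#'
#' @param df Output of [digestion_contrast()], or anything it accepts.
#' @param presence_threshold Minimum undigested %L to call presence
#'   (default 1.0).
#' @param abrogation_fraction Passed to [digestion_contrast()] when `df` is
#'   not already contrasted (default 0.5).
#' @param weak_threshold %L below which a presence call is flagged weak
#'   (default 5).
#' @return The contrast tibble with `present` and `weak_evidence` columns.
#' @export
call_motif <- function(df, presence_threshold = 1.0, abrogation_fraction = 0.5,
                       weak_threshold = 5) {
  if (!"abrogated" %in% names(df)) {
    df <- digestion_contrast(df, abrogation_fraction)
  }
  df |>
    dplyr::mutate(
      present = .data$percent_linked_undigested > presence_threshold &
        .data$abrogated,
      weak_evidence = .data$present &
        .data$percent_linked_undigested < weak_threshold
    )
}
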