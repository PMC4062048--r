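#' Build a tibble of droplet quadrant counts
#'
#' The atomic observation of a duplex droplet digital PCR well is the split of
#' its droplets into four end-point classes: double-negative (`n_nn`),
#' positive on channel A only (`n_pn`), positive on channel B only (`n_np`)
#' and double-positive (`n_pp`). Channel A is conventionally the FAM dye and
#' channel B the HEX dye.
#'
#' @param n_nn Double-negative droplet count.
#' @param n_pn Channel-A-only positive count (FAM+HEX-).
#' @param n_np Channel-B-only positive count (FAM-HEX+).
#' @param n_pp Double-positive count (FAM+HEX+).
#' @param channel_a_target,channel_b_target Assay target labels for the two
#'   channels.
#' @param well,sample_id,assay Optional identifying labels, recycled.
#' @param digested Logical flag: was the aliquot restriction-digested?
#'
#' @return A tibble with one row per well, columns `well`, `sample_id`,
#'   `assay`, `channel_a_target`, `channel_b_target`, `digested`, `n_total`,
#'   `n_pp`, `n_pn`, `n_np`, `n_nn`.
#' @examples
#' quadrant_tbl(n_nn = 9048, n_pn = 0, n_np = 0, n_pp = 952)
#' @export
quadrant_tbl <- function(n_nn, n_pn, n_np, n_pp,
                         channel_a_target = "A", channel_b_target = "B",
                         well = "A01", sample_id = "sample", assay = "duplex",
                         digested = FALSE) {
  out <- tibble::tibble(
    well = well, sample_id = sample_id, assay = assay,
    channel_a_target = channel_a_target, channel_b_target = channel_b_target,
    digested = digested,
    n_total = as.integer(n_nn + n_pn + n_np + n_pp),
    n_pp = as.integer(n_pp), n_pn = as.integer(n_pn),
    n_np = as.integer(n_np), n_nn = as.integer(n_nn)
  )
  validate_quadrants(out)
}

#' Validate quadrant-count columns of a droplet table
#'
#' Checks the invariants every downstream operation relies on: counts are
#' non-negative integers, the four classes sum to `n_total`, and `n_total`
#' is positive. Called internally by every analysis entry point.
#'
#' @param df A data frame with columns `n_total`, `n_pp`, `n_pn`, `n_np`,
#'   `n_nn`.
#' @return The input as a tibble, invisibly validated.
#' @export
validate_quadrants <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("n_total", "n_pp", "n_pn", "n_np", "n_nn")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop_ddpcr("missing quadrant count column(s): ",
               paste(missing_cols, collapse = ", "),
               class = "ddpcrlink_error_columns")
  }
  counts <- as.matrix(df[need])
  if (any(is.na(counts))) {
    stop_ddpcr("quadrant counts contain missing values",
               class = "ddpcrlink_error_counts")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_ddpcr("quadrant counts must be non-negative integers",
               class = "ddpcrlink_error_counts")
  }
  if (any(df$n_total <= 0)) {
    stop_ddpcr("n_total must be positive", class = "ddpcrlink_error_counts")
  }
  bad <- which(df$n_pp + df$n_pn + df$n_np + df$n_nn != df$n_total)
  if (length(bad) > 0) {
    stop_ddpcr("quadrant counts do not sum to n_total in row(s) ",
               paste(bad, collapse = ", "),
               class = "ddpcrlink_error_counts")
  }
  df
}

# classed conditions so callers can distinguish saturation from bad input
stop_ddpcr <- function(..., class) {
  rlang::abort(paste0(...), class = c(class, "ddpcrlink_error"))
}

#' Per-channel negative/total marginals of a duplex well
#'
#' Collapses the four quadrant classes to the single-channel counts that feed
#' Poisson quantification: a droplet is negative on channel A when it falls in
#' the FAM- classes (`n_nn + n_np`) and negative on channel B when it falls in
#' the HEX- classes (`n_nn + n_pn`).
#'
#' @param df A data frame of quadrant counts (see [quadrant_tbl()]).
#' @param channel `"A"` or `"B"`.
#' @return A tibble with columns `n_negative` and `n_total`, one row per
#'   input row.
#' @examples
#' channel_marginals(quadrant_tbl(4000, 4000, 4000, 4000), "A")
#' @export
channel_marginals <- function(df, channel = c("A", "B")) {
  df <- validate_quadrants(df)
  channel <- rlang::arg_match(channel)
  n_negative <- if (channel == "A") df$n_nn + df$n_np else df$n_nn + df$n_pn
  tibble::tibble(n_negative = as.integer(n_negative),
                 n_total = as.integer(df$n_total))
}
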