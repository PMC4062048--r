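#' Diploidy-corrected copy number from a target/reference duplex well
#'
#' With the target gene on channel A and an invariant reference gene
#' (single copy per haplotype, i.e. two per genome) on channel B, the
#' copy number of the target per diploid genome is
#' `raw_cn = 2 * lambda_target / lambda_ref`. The confidence interval is a
#' delta-method interval on `log(lambda_target / lambda_ref)` treating the
#' two channel estimates as independent (they share droplets, so this is
#' approximate); a multinomial bootstrap is available as an alternative.
#'
#' @param df Droplet table of quadrant counts; channel A carries the
#'   target, channel B the reference.
#' @param level Confidence level (default 0.95).
#' @param method `"delta"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples when `method = "bootstrap"`.
#' @param seed Seed for the bootstrap (default 1).
#' @return A tibble, one row per well: identifying columns plus `gene`,
#'   `raw_cn`, `ci_low`, `ci_high`, `lambda_target`, `lambda_ref`,
#'   `n_droplets`.
#' @examples
#' sim <- simulate_cnv_well(1, n_genomes = 2000, n_droplets = 20000, seed = 7)
#' cnv_from_quadrants(sim)
#' @export
cnv_from_quadrants <- function(df, level = 0.95,
                               method = c("delta", "bootstrap"),
                               n_boot = 2000, seed = 1) {
  method <- rlang::arg_match(method)
  df <- validate_quadrants(df)
  ma <- channel_marginals(df, "A")
  mb <- channel_marginals(df, "B")
  if (any(ma$n_negative == 0) || any(mb$n_negative == 0)) {
    stop_ddpcr("a channel is saturated (no negative droplets)",
               class = "ddpcrlink_error_saturation")
  }
  lambda_ref <- lambda_from_counts(mb$n_negative, mb$n_total)
  if (any(lambda_ref <= 0)) {
    stop_ddpcr("reference channel concentration is zero: copy number undefined",
               class = "ddpcrlink_error_no_reference")
  }
  lambda_target <- lambda_from_counts(ma$n_negative, ma$n_total)
  raw_cn <- 2 * lambda_target / lambda_ref
  z <- stats::qnorm(1 - (1 - level) / 2)

  if (method == "delta") {
    # var(log lambda) = var(lambda) / lambda^2, binomial negative fraction
    var_log <- function(m, lambda) {
      p <- m$n_negative / m$n_total
      ifelse(lambda > 0, (1 - p) / (m$n_total * p) / lambda^2, NA_real_)
    }
    se_log <- sqrt(var_log(ma, lambda_target) + var_log(mb, lambda_ref))
    ci_low <- raw_cn * exp(-z * se_log)
    ci_high <- raw_cn * exp(z * se_log)
    # a well with zero target molecules has raw_cn 0 and a degenerate lower bound
    ci_low[lambda_target == 0] <- 0
    ci_high[lambda_target == 0] <- 0
  } else {
    alpha <- (1 - level) / 2
    boot <- withr::with_seed(seed, purrr::map_dfr(seq_len(nrow(df)), function(i) {
      probs <- c(df$n_nn[i], df$n_pn[i], df$n_np[i], df$n_pp[i]) / df$n_total[i]
      d <- stats::rmultinom(n_boot, df$n_total[i], probs)
      neg_a <- d[1, ] + d[3, ]
      neg_b <- d[1, ] + d[2, ]
      ok <- neg_a > 0 & neg_b > 0 & neg_b < df$n_total[i]
      cn <- 2 * log(neg_a[ok] / df$n_total[i]) / log(neg_b[ok] / df$n_total[i])
      qs <- stats::quantile(cn, c(alpha, 1 - alpha), names = FALSE)
      tibble::tibble(ci_low = qs[1], ci_high = qs[2])
    }))
    ci_low <- boot$ci_low
    ci_high <- boot$ci_high
  }

  id_cols <- intersect(c("well", "sample_id", "assay", "digested"), names(df))
  dplyr::bind_cols(
    df[id_cols],
    tibble::tibble(
      gene = if ("channel_a_target" %in% names(df)) df$channel_a_target else "target",
      reference = if ("channel_b_target" %in% names(df)) df$channel_b_target else "reference",
      raw_cn = raw_cn,
      ci_low = pmin(ci_low, raw_cn),
      ci_high = pmax(ci_high, raw_cn),
      lambda_target = lambda_target,
      lambda_ref = lambda_ref,
      n_droplets = df$n_total
    )
  )
}

# ---- Gaussian mixture fitting -------------------------------------------

# one EM run for a k-component univariate Gaussian mixture.
# Deterministic quantile initialization; optional shared variance.
# Returns NULL when the fit degenerates (empty/collapsing component).
em_gmm <- function(x, k, equal_var = FALSE, tol = 1e-8, max_iter = 1000L) {
  n <- length(x)
  mu <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  sd0 <- max(stats::sd(x), 1e-3)
  if (k > 1) sd0 <- max(min(diff(sort(mu))) / 2, 1e-3, sd0 / k)
  sigma <- rep(sd0, k)
  w <- rep(1 / k, k)
  loglik_trace <- numeric(0)
  # floor on component sd, in copy-number units: clusters narrower than
  # 0.05 copies are below ddPCR measurement error and would create likelihood
  # singularities at duplicated values (e.g. many exact-zero estimates)
  min_sd <- 0.05
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) {
      w[j] * stats::dnorm(x, mu[j], sigma[j])
    }, numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_d <- rowSums(dens)
    if (any(rowsum_d <= 0) || any(!is.finite(rowsum_d))) return(NULL)
    ll <- sum(log(rowsum_d))
    loglik_trace <- c(loglik_trace, ll)
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    if (equal_var) {
      s2 <- sum(resp * (matrix(x, n, k) - matrix(mu, n, k, byrow = TRUE))^2) / n
      sigma <- rep(max(sqrt(s2), min_sd), k)
    } else {
      s2 <- colSums(resp * (matrix(x, n, k) - matrix(mu, n, k, byrow = TRUE))^2) / nk
      sigma <- pmax(sqrt(s2), min_sd)
    }
    if (iter > 1 && abs(ll - loglik_trace[iter - 1]) < tol) break
  }
  n_par <- if (equal_var) 2 * k else 3 * k - 1
  list(k = k, means = mu, sds = sigma, weights = w,
       loglik = loglik_trace[length(loglik_trace)],
       loglik_trace = loglik_trace,
       bic = -2 * loglik_trace[length(loglik_trace)] + n_par * log(n),
       equal_var = equal_var, n_par = n_par)
}

# map sorted component means to integer copy numbers: nearest integer,
# bumped to keep the mapping strictly increasing (tolerates a shared
# downward bias in cluster locations).
components_to_integers <- function(means) {
  ints <- pmax(0L, as.integer(round(means)))
  for (j in seq_along(ints)[-1]) {
    if (ints[j] <= ints[j - 1]) ints[j] <- ints[j - 1] + 1L
  }
  ints
}

#' Fit a Gaussian mixture model to raw copy-number estimates
#'
#' Clusters raw diploidy-corrected copy-number values into integer bins via
#' finite Gaussian mixture modelling fitted by expectation-maximization.
#' For each candidate number of components both an equal-variance and a
#' free-variance parameterization are fitted (deterministic quantile
#' initialization, convergence tolerance 1e-8, at most 1000 iterations) and
#' the model with the lowest BIC is retained. Sorted component means are
#' mapped to integer copy numbers by rounding, bumped where needed to keep
#' the mapping strictly increasing — so a shared downward bias in cluster
#' locations (degraded DNA) does not collapse neighbouring bins.
#'
#' @param values Numeric vector of raw copy-number estimates, or a data
#'   frame with a `raw_cn` column (e.g. from [cnv_from_quadrants()]).
#' @param k_candidates Candidate component counts (default `1:5`,
#'   truncated so every component can hold at least two observations).
#' @param tol,max_iter EM convergence tolerance and iteration cap.
#' @param seed Retained for interface stability; the quantile
#'   initialization is deterministic so the fit does not depend on it.
#' @return An object of class `copy_number_model`: a list with `k`,
#'   `means`, `sds`, `weights` (sorted by mean), `component_to_integer`,
#'   `bic`, `loglik`, `loglik_trace`, `equal_var`, `bic_table`, `data`.
#'   Supports [tidy()][generics::tidy], [glance()][generics::glance],
#'   `autoplot()` and `predict()`.
#' @examples
#' x <- c(rnorm(30, 0, 0.05), rnorm(30, 1, 0.05), rnorm(30, 2, 0.05))
#' fit <- fit_copy_number_mixture(x)
#' glance(fit)
#' @export
fit_copy_number_mixture <- function(values, k_candidates = 1:5,
                                    tol = 1e-8, max_iter = 1000L, seed = 1) {
  if (is.data.frame(values)) {
    if (!"raw_cn" %in% names(values)) {
      stop_ddpcr("data-frame input needs a `raw_cn` column",
                 class = "ddpcrlink_error_columns")
    }
    values <- values$raw_cn
  }
  x <- as.numeric(values)
  if (any(!is.finite(x))) {
    stop_ddpcr("raw copy-number values must be finite",
               class = "ddpcrlink_error_input")
  }
  k_candidates <- sort(unique(as.integer(k_candidates)))
  k_feasible <- k_candidates[k_candidates >= 1 & 2 * k_candidates <= length(x)]
  # degenerate data: a single distinct value supports only one component
  if (length(unique(x)) == 1) k_feasible <- 1L
  if (length(k_feasible) == 0) {
    stop_ddpcr("too few values for the requested number of components",
               class = "ddpcrlink_error_degenerate_fit")
  }

  fits <- list()
  for (k in k_feasible) {
    for (ev in c(TRUE, FALSE)) {
      f <- withr::with_seed(seed, em_gmm(x, k, equal_var = ev,
                                         tol = tol, max_iter = max_iter))
      if (!is.null(f)) fits[[length(fits) + 1]] <- f
    }
  }
  if (length(fits) == 0) {
    stop_ddpcr("all mixture fits degenerated", class = "ddpcrlink_error_degenerate_fit")
  }
  bic_table <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(k = f$k, equal_var = f$equal_var,
                   loglik = f$loglik, bic = f$bic)
  })
  best <- fits[[which.min(bic_table$bic)]]
  ord <- order(best$means)
  model <- list(
    k = best$k,
    means = best$means[ord],
    sds = best$sds[ord],
    weights = best$weights[ord],
    component_to_integer = components_to_integers(best$means[ord]),
    bic = best$bic,
    loglik = best$loglik,
    loglik_trace = best$loglik_trace,
    equal_var = best$equal_var,
    bic_table = bic_table,
    data = x
  )
  class(model) <- "copy_number_model"
  model
}

#' @export
print.copy_number_model <- function(x, ...) {
  cat("Gaussian copy-number mixture (", x$k, " component",
      if (x$k > 1) "s", ", ",
      if (x$equal_var) "equal" else "free", " variance)\n", sep = "")
  cat("  BIC:", format(x$bic, digits = 6),
      " log-likelihood:", format(x$loglik, digits = 6), "\n")
  comp <- tidy(x)
  cat(paste0("  copies=", comp$integer_cn,
             " mean=", format(comp$mean, digits = 3),
             " sd=", format(comp$sd, digits = 3),
             " weight=", format(comp$weight, digits = 3)),
      sep = "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-component summary of a fitted copy-number mixture
#'
#' @param x A `copy_number_model`.
#' @param ... Unused.
#' @return A tibble with one row per component: `component`, `integer_cn`,
#'   `mean`, `sd`, `weight`.
#' @export
tidy.copy_number_model <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$k),
    integer_cn = x$component_to_integer,
    mean = x$means,
    sd = x$sds,
    weight = x$weights
  )
}

#' One-row summary of a fitted copy-number mixture
#'
#' @param x A `copy_number_model`.
#' @param ... Unused.
#' @return A tibble with `k`, `equal_var`, `loglik`, `bic`, `n`, `n_iter`.
#' @export
glance.copy_number_model <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    equal_var = x$equal_var,
    loglik = x$loglik,
    bic = x$bic,
    n = length(x$data),
    n_iter = length(x$loglik_trace)
  )
}

# posterior responsibility matrix for new values under a fitted model
posterior_matrix <- function(model, values) {
  dens <- vapply(seq_len(model$k), function(j) {
    model$weights[j] * stats::dnorm(values, model$means[j], model$sds[j])
  }, numeric(length(values)))
  dens <- matrix(dens, nrow = length(values))
  denom <- rowSums(dens)
  # values far in the tails of every component: fall back to nearest mean
  far <- denom <= 0 | !is.finite(denom)
  if (any(far)) {
    nearest <- vapply(values[far], function(v) which.min(abs(model$means - v)),
                      integer(1))
    dens[far, ] <- 0
    dens[cbind(which(far), nearest)] <- 1
    denom[far] <- 1
  }
  dens / denom
}

#' Assign integer copy numbers to raw estimates
#'
#' Each estimate is assigned the integer of its maximum-posterior mixture
#' component. Ties are broken toward the lower integer. A call is flagged
#' for review when its posterior falls below `posterior_floor`, or when a
#' confidence interval accompanies the estimate and excludes the assigned
#' integer's neighbourhood `[integer - integer_band, integer + integer_band]`
#' — the machine assignment then contradicts the well's own Poisson
#' interval and a human should look.
#'
#' @param df A data frame with a `raw_cn` column, optionally `ci_low` /
#'   `ci_high` (e.g. from [cnv_from_quadrants()]); or a bare numeric vector.
#' @param model A fitted [copy_number_model][fit_copy_number_mixture].
#' @param posterior_floor Minimum max-posterior before flagging
#'   (default 0.95).
#' @param integer_band Half-width of the integer neighbourhood used in the
#'   CI check (default 0: the CI must contain the integer itself).
#' @return The input tibble with `integer_cn`, `posterior` and
#'   `review_flag` columns appended.
#' @examples
#' x <- c(rnorm(30, 1, 0.05), rnorm(30, 2, 0.05))
#' fit <- fit_copy_number_mixture(x)
#' assign_copy_numbers(tibble::tibble(raw_cn = c(0.97, 2.04)), fit)
#' @export
assign_copy_numbers <- function(df, model, posterior_floor = 0.95,
                                integer_band = 0) {
  if (!inherits(model, "copy_number_model")) {
    stop_ddpcr("`model` must be a fitted copy_number_model",
               class = "ddpcrlink_error_input")
  }
  if (!is.data.frame(df)) df <- tibble::tibble(raw_cn = as.numeric(df))
  df <- tibble::as_tibble(df)
  if (!"raw_cn" %in% names(df)) {
    stop_ddpcr("need a `raw_cn` column", class = "ddpcrlink_error_columns")
  }
  post <- posterior_matrix(model, df$raw_cn)
  # which.max breaks ties toward the first (lowest-integer) component
  best <- apply(post, 1L, which.max)
  df$integer_cn <- model$component_to_integer[best]
  df$posterior <- post[cbind(seq_len(nrow(df)), best)]
  ci_excludes <- rep(FALSE, nrow(df))
  if (all(c("ci_low", "ci_high") %in% names(df))) {
    ci_excludes <- !is.na(df$ci_low) & !is.na(df$ci_high) &
      (df$ci_low > df$integer_cn + integer_band |
         df$ci_high < df$integer_cn - integer_band)
  }
  tie <- rowSums(abs(post - df$posterior) < 1e-12) > 1
  df$review_flag <- df$posterior < posterior_floor | ci_excludes | tie
  df
}

#' Density plot of a fitted copy-number mixture
#'
#' Shows the raw copy-number estimates as a rug, the fitted mixture
#' density, and each component's mean labelled with its integer bin.
#'
#' @param object A `copy_number_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export autoplot
#' @export
autoplot.copy_number_model <- function(object, ...) {
  grid <- seq(min(object$data) - 0.5, max(object$data) + 0.5, length.out = 512)
  dens <- purrr::map_dfr(seq_len(object$k), function(j) {
    tibble::tibble(
      raw_cn = grid,
      density = object$weights[j] * stats::dnorm(grid, object$means[j], object$sds[j]),
      component = factor(object$component_to_integer[j])
    )
  })
  total <- dplyr::summarise(dplyr::group_by(dens, .data$raw_cn),
                            density = sum(.data$density), .groups = "drop")
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$raw_cn, y = .data$density)) +
    ggplot2::geom_line(data = total, colour = "grey40") +
    ggplot2::geom_area(ggplot2::aes(fill = .data$component),
                       alpha = 0.4, position = "identity") +
    ggplot2::geom_rug(data = tibble::tibble(raw_cn = object$data),
                      ggplot2::aes(x = .data$raw_cn), inherit.aes = FALSE,
                      sides = "b", alpha = 0.5) +
    ggplot2::geom_vline(xintercept = object$means, linetype = 3) +
    ggplot2::labs(x = "raw copy-number estimate", y = "mixture density",
                  fill = "copies") +
    ggplot2::theme_minimal()
}

# ---- Cohen's kappa -------------------------------------------------------

#' Chance-corrected agreement between two sets of categorical calls
#'
#' Cohen's kappa for paired categorical calls (e.g. integer copy numbers
#' from two genotyping methods): `kappa = (p_o - p_e) / (1 - p_e)` where
#' `p_o` is the observed agreement fraction and `p_e` the agreement
#' expected by chance from the marginal call frequencies, over the union
#' of categories observed in either method. Categories are unordered and
#' unweighted. The confidence interval uses the large-sample standard
#' error `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`, clamped to [-1, 1].
#'
#' @param data Either a data frame holding both call columns, or the first
#'   call vector.
#' @param ... When `data` is a data frame: exactly two tidy-selected call
#'   columns, e.g. `cohen_kappa(df, ddpcr_cn, qpcr_cn)`. Otherwise: the
#'   second call vector.
#' @param level Confidence level (default 0.95).
#' @return An object of class `kappa_result`: list with `kappa`, `se`,
#'   `ci_low`, `ci_high`, `p_observed`, `p_expected`, `n_pairs`,
#'   `contingency` (category x category table). Supports `tidy()` and
#'   `glance()`.
#' @details Perfect agreement on a single shared category leaves
#'   `p_e = 1` and kappa undefined; this *degenerate agreement* is
#'   reported with `kappa = NA` and a `degenerate = TRUE` field rather
#'   than an error.
#' @examples
#' cohen_kappa(c(1, 1, 2, 2), c(1, 1, 2, 2))
#' @export
cohen_kappa <- function(data, ..., level = 0.95) {
  if (is.data.frame(data)) {
    sel <- dplyr::select(tibble::as_tibble(data), ...)
    if (ncol(sel) != 2) {
      stop_ddpcr("select exactly two call columns from the data frame",
                 class = "ddpcrlink_error_input")
    }
    calls1 <- sel[[1]]
    calls2 <- sel[[2]]
  } else {
    dots <- list(...)
    if (length(dots) != 1) {
      stop_ddpcr("supply exactly two call vectors", class = "ddpcrlink_error_input")
    }
    calls1 <- data
    calls2 <- dots[[1]]
  }
  x <- as.character(calls1)
  y <- as.character(calls2)
  if (length(x) != length(y)) {
    stop_ddpcr("call vectors must have equal length", class = "ddpcrlink_error_input")
  }
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) {
    stop_ddpcr("need at least two complete call pairs", class = "ddpcrlink_error_input")
  }
  cats <- sort(unique(c(x, y)))
  tab <- table(factor(x, levels = cats), factor(y, levels = cats))
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  degenerate <- abs(1 - p_e) < .Machine$double.eps^0.5
  if (degenerate) {
    kappa <- se <- ci_low <- ci_high <- NA_real_
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
    se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci_low <- max(-1, kappa - z * se)
    ci_high <- min(1, kappa + z * se)
  }
  out <- list(kappa = kappa, se = se, ci_low = ci_low, ci_high = ci_high,
              p_observed = p_o, p_expected = p_e, n_pairs = n,
              degenerate = degenerate, contingency = tab)
  class(out) <- "kappa_result"
  out
}

#' @export
print.kappa_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Cohen's kappa: undefined (all", x$n_pairs,
        "pairs share one category; chance agreement is 1)\n")
  } else {
    cat(sprintf("Cohen's kappa: %.3f (95%% CI %.3f to %.3f), n = %d pairs\n",
                x$kappa, x$ci_low, x$ci_high, x$n_pairs))
  }
  invisible(x)
}

#' @export
tidy.kappa_result <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, se = x$se,
                 ci_low = x$ci_low, ci_high = x$ci_high)
}

#' @export
glance.kappa_result <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, se = x$se, ci_low = x$ci_low,
                 ci_high = x$ci_high, p_observed = x$p_observed,
                 p_expected = x$p_expected, n_pairs = x$n_pairs,
                 degenerate = x$degenerate)
}
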