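test_that("raw copy number is twice the target/reference ratio", {
  # equal channel means: diploid
  q_eq <- quadrant_tbl(8100, 900, 900, 100)
  est <- cnv_from_quadrants(q_eq)
  expect_equal(est$raw_cn, 2, tolerance = 1e-12)
  expect_equal(est$raw_cn, 2 * est$lambda_target / est$lambda_ref,
               tolerance = 1e-15)
  expect_true(est$ci_low <= est$raw_cn && est$raw_cn <= est$ci_high)

  # half the reference concentration: one copy. Build counts with exact
  # marginals lambda_t = 0.05, lambda_r = 0.10 under independence.
  n <- 100000
  neg_a <- round(n * exp(-0.05)); neg_b <- round(n * exp(-0.10))
  nn <- round(neg_a * neg_b / n)
  q_half <- quadrant_tbl(nn, neg_b - nn, neg_a - nn, n - neg_a - neg_b + nn)
  expect_equal(cnv_from_quadrants(q_half)$raw_cn, 1, tolerance = 1e-3)

  # errors: no reference molecules / saturation
  expect_error(cnv_from_quadrants(quadrant_tbl(9000, 1000, 0, 0)),
               class = "ddpcrlink_error_no_reference")
  expect_error(cnv_from_quadrants(quadrant_tbl(0, 0, 0, 9000)),
               class = "ddpcrlink_error_saturation")
})

test_that("copy-number ratio is invariant to volume and count rescaling", {
  q <- quadrant_tbl(8100, 900, 900, 100)
  base <- cnv_from_quadrants(q)$raw_cn
  # droplet volume never enters the ratio
  # (cnv_from_quadrants takes no volume argument by construction: lambdas only)
  # proportional rescaling of all four counts changes nothing
  q10 <- quadrant_tbl(81000, 9000, 9000, 1000)
  expect_equal(cnv_from_quadrants(q10)$raw_cn, base, tolerance = 1e-12)
})

test_that("delta and bootstrap intervals agree on a well-behaved well", {
  q <- simulate_cnv_well(2, n_genomes = 2000, n_droplets = 20000, seed = 3)
  d <- cnv_from_quadrants(q, method = "delta")
  b <- cnv_from_quadrants(q, method = "bootstrap", n_boot = 4000, seed = 5)
  expect_equal(d$raw_cn, b$raw_cn, tolerance = 1e-12)
  expect_equal(d$ci_low, b$ci_low, tolerance = 0.05)
  expect_equal(d$ci_high, b$ci_high, tolerance = 0.05)
})

test_that("synthetic zero-copy-cluster well reproduces the published worked values", {
  # synthetic stand-in constructed to emulate the published low-copy sample:
  # a faint target signal against the reference, raw_cn 0.268, CI ~[0.18, 0.35]
  path <- system.file("extdata", "synthetic_f1268_well.csv",
                      package = "ddpcrlink")
  est <- cnv_from_quadrants(read_droplet_table(path))
  expect_equal(est$raw_cn, 0.268, tolerance = 0.005)
  expect_lt(abs(est$ci_low - 0.182), 0.05)
  expect_lt(abs(est$ci_high - 0.353), 0.05)
  # the interval excludes zero: the sample cannot be a true zero-copy
  expect_gt(est$ci_low, 0)
})

test_that("EM selects the true component count and bins every value", {
  x <- withr::with_seed(11, c(rnorm(30, 0, 0.05), rnorm(30, 1, 0.05),
                              rnorm(30, 2, 0.05)))
  fit <- fit_copy_number_mixture(x)
  expect_s3_class(fit, "copy_number_model")
  expect_identical(fit$k, 3L)
  expect_identical(fit$component_to_integer, c(0L, 1L, 2L))
  calls <- assign_copy_numbers(tibble::tibble(raw_cn = x), fit)
  expect_identical(calls$integer_cn, rep(0:2, each = 30))
  # weights sum to one, sds positive, means sorted
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(fit$sds > 0))
  expect_true(!is.unsorted(fit$means, strictly = TRUE))
})

test_that("EM handles degenerate inputs", {
  # identical values: one component at that value
  fit1 <- fit_copy_number_mixture(rep(2, 12))
  expect_identical(fit1$k, 1L)
  expect_equal(fit1$means, 2, tolerance = 1e-9)
  expect_identical(fit1$component_to_integer, 2L)
  # too few values for the requested components
  expect_error(fit_copy_number_mixture(c(1, 2), k_candidates = 3),
               class = "ddpcrlink_error_degenerate_fit")
})

test_that("EM log-likelihood is non-decreasing on every fit", {
  sets <- withr::with_seed(21, list(
    c(rnorm(40, 1, 0.1), rnorm(40, 2, 0.1)),
    c(pmax(0, rnorm(20, 0, 0.05)), rnorm(25, 0.9, 0.1), rnorm(25, 1.8, 0.1)),
    runif(60, 0, 3),
    c(rnorm(50, 2, 0.3))
  ))
  for (x in sets) {
    for (k in 1:4) {
      fit <- tryCatch(fit_copy_number_mixture(x, k_candidates = k),
                      ddpcrlink_error = function(e) NULL)
      if (is.null(fit)) next
      expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    }
  }
})

test_that("mixture recovers k and means on separated clusters", {
  # separation >= 6 sds; parameter recovery across seeded replicates
  hits <- 0
  for (rep in 1:40) {
    x <- withr::with_seed(3000 + rep, {
      k_true <- sample(2:4, 1)
      sizes <- sample(15:25, k_true, replace = TRUE)
      unlist(purrr::map(seq_len(k_true) - 1, function(m) {
        rnorm(sizes[m + 1], mean = m, sd = 0.12)
      }))
    })
    k_true <- length(unique(round(tapply(x, cut(x, breaks = seq(-0.5, 4.5, 1)),
                                         length) > 0)))
    fit <- fit_copy_number_mixture(x)
    means_ref <- sort(unique(round(fit$means)))
    # recovered means within 2 standard errors of the integer centres
    ok <- all(abs(fit$means - round(fit$means)) <
                2 * fit$sds / sqrt(length(x) * fit$weights) + 0.05)
    hits <- hits + ok
  }
  expect_gte(hits, 38)
})

test_that("a shared downward bias leaves integer assignments unchanged", {
  x <- withr::with_seed(31, c(rnorm(20, 1, 0.08), rnorm(20, 2, 0.08),
                              rnorm(10, 3, 0.08)))
  truth <- rep(c(1L, 2L, 3L), c(20, 20, 10))
  plain <- assign_copy_numbers(tibble::tibble(raw_cn = x),
                               fit_copy_number_mixture(x))
  shifted <- assign_copy_numbers(tibble::tibble(raw_cn = 0.85 * x),
                                 fit_copy_number_mixture(0.85 * x))
  expect_identical(plain$integer_cn, truth)
  expect_identical(shifted$integer_cn, truth)
})

test_that("posterior assignment flags ties, low posteriors and CI conflicts", {
  x <- withr::with_seed(41, c(rnorm(30, 0, 0.05), rnorm(30, 1, 0.05),
                              rnorm(30, 2, 0.05)))
  fit <- fit_copy_number_mixture(x)
  # a clean value: no flag
  clean <- assign_copy_numbers(tibble::tibble(raw_cn = 2.01), fit)
  expect_identical(clean$integer_cn, 2L)
  expect_false(clean$review_flag)
  expect_gt(clean$posterior, 0.95)
  # midpoint between components: flagged, tie broken toward lower integer
  mid <- assign_copy_numbers(
    tibble::tibble(raw_cn = mean(fit$means[1:2])), fit
  )
  expect_identical(mid$integer_cn, 0L)
  expect_true(mid$review_flag)
  # assigned integer excluded by the estimate's own CI: review
  f1268 <- assign_copy_numbers(
    tibble::tibble(raw_cn = 0.268, ci_low = 0.202, ci_high = 0.355), fit
  )
  expect_identical(f1268$integer_cn, 0L)
  expect_true(f1268$review_flag)
})

test_that("27-sample cohort with shifted clusters yields the published bin sizes", {
  # synthetic stand-in for the family cohort: clusters sit ~15% below the
  # integers and have sizes 3 / 10 / 12 / 2 for 0-3 copies
  vals <- withr::with_seed(7, c(
    pmax(0, rnorm(3, 0, 0.03)), rnorm(10, 0.85, 0.08),
    rnorm(12, 1.70, 0.08), rnorm(2, 2.55, 0.08)
  ))
  fit <- fit_copy_number_mixture(vals)
  calls <- assign_copy_numbers(tibble::tibble(raw_cn = vals), fit)
  expect_identical(fit$k, 4L)
  expect_identical(fit$component_to_integer, 0:3)
  expect_identical(as.integer(table(calls$integer_cn)), c(3L, 10L, 12L, 2L))
})

test_that("independent EM implementation agrees with the reference fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")  # Mclust() needs its namespace attached
  x <- withr::with_seed(51, c(rnorm(40, 1, 0.1), rnorm(40, 2, 0.12),
                              rnorm(20, 3, 0.1)))
  fit <- fit_copy_number_mixture(x)
  ref <- mclust::Mclust(x, G = 1:5, verbose = FALSE)
  expect_identical(fit$k, as.integer(ref$G))
  expect_equal(sort(fit$means), as.numeric(sort(ref$parameters$mean)),
               tolerance = 0.02)
  # identical partitions of the data
  expect_identical(
    as.integer(factor(assign_copy_numbers(x, fit)$integer_cn)),
    as.integer(factor(ref$classification))
  )
})

test_that("kappa matches hand computations and the published summaries", {
  # hand-computed 10-pair example: p_o = 0.9, p_e = 0.5, kappa = 0.8
  k <- cohen_kappa(c(rep(1, 4), rep(2, 5), 1), c(rep(1, 4), rep(2, 5), 2))
  expect_equal(k$p_observed, 0.9, tolerance = 1e-12)
  expect_equal(k$p_expected, 0.5, tolerance = 1e-12)
  expect_equal(k$kappa, 0.8, tolerance = 1e-12)

  # identical vectors over >= 2 categories: perfect agreement
  expect_equal(cohen_kappa(c(0, 1, 2, 1), c(0, 1, 2, 1))$kappa, 1)

  # degenerate: a single shared category leaves kappa undefined
  deg <- cohen_kappa(rep(1, 5), rep(1, 5))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$kappa))

  # synthetic stand-in call table reproduces the published per-assay kappas
  calls <- readr::read_csv(
    system.file("extdata", "synthetic_qpcr_ddpcr_calls.csv",
                package = "ddpcrlink"),
    show_col_types = FALSE
  )
  by_assay <- calls |>
    dplyr::group_by(assay) |>
    dplyr::summarise(tidy(cohen_kappa(ddpcr_cn, qpcr_cn)), .groups = "drop")
  perfect <- c("KIR2DL1", "KIR2DS1", "KIR2DS2", "KIR2DS3", "KIR2DS5", "KIR3DS1")
  expect_equal(by_assay$kappa[by_assay$assay %in% perfect], rep(1, 6))
  expect_equal(by_assay$kappa[by_assay$assay == "KIR3DL1"], 0.9,
               tolerance = 0.005)
  expect_equal(by_assay$kappa[by_assay$assay == "KIR3DP1"], 0.74,
               tolerance = 0.005)
})

test_that("kappa equals a brute-force expected-agreement enumeration", {
  # oracle: count agreement over all ordered observation pairs (i, j) to
  # get chance agreement, never through the contingency-table shortcut
  kappa_oracle <- function(x, y) {
    n <- length(x)
    p_o <- mean(x == y)
    agree <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      agree <- agree + (x[i] == y[j])
    }
    p_e <- agree / n^2
    (p_o - p_e) / (1 - p_e)
  }
  cases <- withr::with_seed(61, purrr::map(1:50, function(i) {
    n <- sample(2:6, 1)
    list(x = sample(0:2, n, replace = TRUE), y = sample(0:2, n, replace = TRUE))
  }))
  for (cs in cases) {
    k <- cohen_kappa(cs$x, cs$y)
    if (k$degenerate) next
    expect_equal(k$kappa, kappa_oracle(cs$x, cs$y), tolerance = 1e-12)
  }
})

test_that("tidy, glance and autoplot work on fitted objects", {
  x <- withr::with_seed(71, c(rnorm(25, 1, 0.06), rnorm(25, 2, 0.06)))
  fit <- fit_copy_number_mixture(x)
  td <- tidy(fit)
  expect_identical(nrow(td), 2L)
  expect_named(td, c("component", "integer_cn", "mean", "sd", "weight"))
  gl <- glance(fit)
  expect_identical(gl$k, 2L)
  expect_identical(gl$n, 50L)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  k <- cohen_kappa(c(1, 2, 1), c(1, 2, 2))
  expect_named(tidy(k), c("kappa", "se", "ci_low", "ci_high"))
  expect_identical(glance(k)$n_pairs, 3L)
})
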