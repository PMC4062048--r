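test_that("motif pairs compose genotypes with the expected gene content", {
  # the all-A genotype carries no KIR2DL5 at all
  g0 <- build_genotype("cA01~tA01", "cA01~tA01")
  expect_identical(gene_copy_number(g0, "KIR2DL5"), 0L)
  # double cB01~tB01 carries the diploid maximum of four copies
  g4 <- build_genotype("cB01~tB01", "cB01~tB01")
  expect_identical(gene_copy_number(g4, "KIR2DL5"), 4L)
  # the mixed genotype: two KIR2DL5, one KIR2DL2, one KIR3DS1
  g2 <- genotype_two_dl5()
  expect_identical(gene_copy_number(g2, "KIR2DL5"), 2L)
  expect_identical(gene_copy_number(g2, "KIR2DL2"), 1L)
  expect_identical(gene_copy_number(g2, "KIR3DS1"), 1L)
  expect_error(build_genotype("cZ99~tA01", "cA01~tA01"),
               class = "ddpcrlink_error_input")
  expect_error(build_genotype("tA01~cA01", "cA01~tA01"),
               class = "ddpcrlink_error_input")
})

test_that("default library encodes the published inter-locus distances", {
  lib <- kir_motif_library()
  d_cen <- diff(lib$position_kb[lib$motif == "cB01" &
                                  lib$gene %in% c("KIR2DL2", "KIR2DL5")])
  expect_equal(d_cen, 21.8, tolerance = 1e-12)
  d_tel <- diff(lib$position_kb[lib$motif == "tB01" &
                                  lib$gene %in% c("KIR3DS1", "KIR2DL5")])
  expect_equal(d_tel, 19.9, tolerance = 1e-12)
})

test_that("diploid KIR2DL5 totals across the motif library stay within 0..4", {
  cen <- c("cA01", "cB01", "cB02")
  tel <- c("tA01", "tB01")
  haps <- expand.grid(c = cen, t = tel, stringsAsFactors = FALSE)
  hap_names <- paste0(haps$c, "~", haps$t)
  per_hap <- purrr::map_int(seq_len(nrow(haps)), function(i) {
    g <- build_genotype(hap_names[i], "cA01~tA01")
    gene_copy_number(g, "KIR2DL5")
  })
  # single-haplotype counts are 0, 1 or 2
  expect_true(all(per_hap %in% 0:2))
  expect_identical(max(per_hap), 2L)
  # every diploid combination stays within 0..4 and the maximum is reached
  totals <- outer(per_hap, per_hap, `+`)
  expect_true(all(totals %in% 0:4))
  expect_identical(max(totals), 4L)
})

test_that("fragmentation severs linked pairs at the closed-form rate", {
  g <- genotype_two_dl5()
  # no fragmentation: every pair stays linked, conservation is exact
  sp_inf <- molecules_for_assay(g, "KIR2DL2", "KIR2DL5", n_genomes = 5000,
                                seed = 1)
  expect_identical(sp_inf$linked_ab, 5000L)
  expect_identical(sp_inf$a_only, 0L)
  expect_identical(sp_inf$b_only, 5000L)  # the lone telomeric KIR2DL5

  # complete digestion between the loci: linkage impossible
  frag_cut <- fragmentation_model(Inf, cut_between(g, "KIR2DL2", "KIR2DL5"))
  sp_cut <- molecules_for_assay(g, "KIR2DL2", "KIR2DL5", n_genomes = 5000,
                                frag = frag_cut, seed = 2)
  expect_identical(sp_cut$linked_ab, 0L)
  expect_identical(sp_cut$a_only, 5000L)
  expect_identical(sp_cut$b_only, 10000L)

  # random breakage at 50 kb over 21.8 kb: intact fraction exp(-21.8/50),
  # observed within 3 binomial standard deviations at 10000 genomes
  p_int <- exp(-21.8 / 50)
  sp50 <- molecules_for_assay(g, "KIR2DL2", "KIR2DL5", n_genomes = 10000,
                              frag = fragmentation_model(50), seed = 3)
  tol <- 3 * sqrt(10000 * p_int * (1 - p_int))
  expect_lt(abs(sp50$linked_ab - 10000 * p_int), tol)
})

test_that("species conservation holds for every seed and cut setting", {
  g <- genotype_two_dl5()
  frags <- list(
    fragmentation_model(Inf),
    fragmentation_model(30),
    fragmentation_model(50, cut_between(g, "KIR2DL2", "KIR2DL5", prob = 0.5))
  )
  for (i in 1:20) {
    frag <- frags[[1 + (i %% 3)]]
    sp <- molecules_for_assay(g, "KIR2DL2", "KIR2DL5", n_genomes = 1000,
                              frag = frag, seed = 100 + i)
    # totals per channel: 1 KIR2DL2 and 2 KIR2DL5 per genome
    expect_identical(sp$a_only + sp$linked_ab, 1000L)
    expect_identical(sp$b_only + sp$linked_ab, 2000L)
  }
})

test_that("assay targets absent from the genotype give zero counts, not errors", {
  g0 <- build_genotype("cA01~tA01", "cA01~tA01")
  sp <- molecules_for_assay(g0, "KIR2DL2", "KIR2DL5", n_genomes = 100, seed = 4)
  expect_identical(sp$a_only + sp$b_only + sp$linked_ab, 0L)
  q <- partition_into_droplets(sp, n_droplets = 1000, seed = 5)
  expect_identical(q$n_nn, 1000L)
})

test_that("droplet confinement reproduces Poisson marginals", {
  # only linked molecules: single positives are impossible
  q_link <- partition_into_droplets(
    list(a_only = 0, b_only = 0, linked_ab = 800),
    n_droplets = 8000, seed = 6
  )
  expect_identical(q_link$n_pn, 0L)
  expect_identical(q_link$n_np, 0L)

  # unlinked loading at lambda 0.1 each: negative fractions near exp(-0.1)
  # and gamma near zero on averaging
  stats <- purrr::map_dfr(1:200, function(i) {
    q <- partition_into_droplets(
      list(a_only = 2000, b_only = 2000, linked_ab = 0),
      n_droplets = 20000, seed = 2000 + i
    )
    percent_linked(q)[, c("lambda_a", "lambda_b", "gamma")]
  })
  expect_equal(mean(stats$lambda_a), 0.1, tolerance = 0.01)
  expect_equal(mean(stats$lambda_b), 0.1, tolerance = 0.01)
  expect_lt(abs(mean(stats$gamma)), 5e-4)
})

test_that("identical seeds reproduce identical wells, different seeds differ", {
  g <- genotype_two_dl5()
  w1 <- simulate_linkage_well(g, "KIR2DL2", "KIR2DL5", seed = 42)
  w2 <- simulate_linkage_well(g, "KIR2DL2", "KIR2DL5", seed = 42)
  w3 <- simulate_linkage_well(g, "KIR2DL2", "KIR2DL5", seed = 43)
  expect_identical(w1, w2)
  expect_false(identical(w1, w3))
  c1 <- simulate_cnv_well(2, seed = 42)
  c2 <- simulate_cnv_well(2, seed = 42)
  expect_identical(c1, c2)
  # seeded simulation leaves the global RNG stream untouched
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(simulate_cnv_well(1, seed = 9))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("expected %L decays with distance over fragment length", {
  # same physical distance, shrinking fragment lengths
  g <- genotype_two_dl5()
  mean_pl <- purrr::map_dbl(c(Inf, 100, 50, 20, 8), function(mfl) {
    mean(purrr::map_dbl(1:8, function(i) {
      w <- simulate_linkage_well(g, "KIR2DL2", "KIR2DL5", n_genomes = 3000,
                                 frag = fragmentation_model(mfl),
                                 seed = round(min(mfl, 1e6)) * 10 + i)
      percent_linked(w)$percent_linked
    }))
  })
  expect_true(all(diff(mean_pl) < 0))
})

test_that("cnv wells round-trip their target copy number", {
  for (copies in 0:4) {
    est <- purrr::map_dbl(1:8, function(i) {
      q <- simulate_cnv_well(copies, n_genomes = 1500, n_droplets = 20000,
                             seed = copies * 100 + i)
      cnv_from_quadrants(q)$raw_cn
    })
    expect_equal(mean(est), copies, tolerance = 0.05 + 0.02 * copies)
  }
})

test_that("grid of simulated cnv wells clusters back to the true integers", {
  wells <- purrr::map_dfr(0:4, function(copies) {
    purrr::map_dfr(1:20, function(i) {
      q <- simulate_cnv_well(copies, n_genomes = 1500, n_droplets = 20000,
                             seed = 10000 + copies * 100 + i,
                             sample_id = sprintf("cn%d_%02d", copies, i))
      est <- cnv_from_quadrants(q)
      est$true_cn <- copies
      est
    })
  })
  fit <- fit_copy_number_mixture(wells$raw_cn)
  calls <- assign_copy_numbers(wells, fit)
  expect_identical(fit$k, 5L)
  expect_identical(calls$integer_cn, calls$true_cn)
})

test_that("families inherit one haplotype from each parent", {
  m <- build_genotype("cB01~tB01", "cA01~tA01")  # 2 or 0 KIR2DL5 transmitted
  f <- build_genotype("cA01~tA01", "cA01~tA01")  # always 0
  fam <- simulate_family(m, f, n_children = 30, seed = 12)
  kids <- fam$ped[fam$ped$father_id != "0", ]
  expect_true(all(kids$kir2dl5_cn %in% c(0L, 2L)))
  # both maternal haplotypes appear among 30 children
  expect_identical(sort(unique(kids$kir2dl5_cn)), c(0L, 2L))
  # homozygous-null parents only produce null children
  null_fam <- simulate_family(f, f, n_children = 5, seed = 13)
  expect_true(all(null_fam$ped$kir2dl5_cn == 0L))
})

test_that("optional droplet misclassification noise perturbs calls", {
  q_clean <- partition_into_droplets(
    list(a_only = 0, b_only = 0, linked_ab = 1000),
    n_droplets = 10000, seed = 14
  )
  q_noisy <- partition_into_droplets(
    list(a_only = 0, b_only = 0, linked_ab = 1000),
    n_droplets = 10000, seed = 14, noise_rate = 0.01
  )
  expect_identical(q_clean$n_pn + q_clean$n_np, 0L)
  expect_gt(q_noisy$n_pn + q_noisy$n_np, 0L)
})
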