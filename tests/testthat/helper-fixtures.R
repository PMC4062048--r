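# shared fixtures and independent oracles used across test files

# the reference two-haplotype genotype used throughout: one haplotype with
# the centromeric KIR2DL2~KIR2DL5 pair, the other with the telomeric
# KIR3DS1~KIR2DL5 pair -> two KIR2DL5 copies, one KIR2DL2, one KIR3DS1
genotype_two_dl5 <- function() build_genotype("cB01~tA01", "cA01~tB01")

# quadrant table for exact independence of the two channels
independence_quadrants <- function() {
  quadrant_tbl(n_nn = 4000, n_pn = 4000, n_np = 4000, n_pp = 4000)
}

# quadrant table for fully linked molecules (single-positives impossible)
fully_linked_quadrants <- function() {
  quadrant_tbl(n_nn = 9048, n_pn = 0, n_np = 0, n_pp = 952)
}

# brute-force Mendelian oracle: enumerate every parental split and every
# per-child transmission choice independently (no shortcuts shared with
# the implementation's search order)
mendelian_oracle <- function(mother_cn, father_cn, children_cn, phm = 2) {
  totals <- function(cn) if (is.na(cn)) 0:(2 * phm) else cn
  splits <- function(total) {
    out <- list()
    for (h1 in 0:phm) {
      h2 <- total - h1
      if (h2 >= 0 && h2 <= phm) out[[length(out) + 1]] <- c(h1, h2)
    }
    out
  }
  for (mt in totals(mother_cn)) for (ft in totals(father_cn)) {
    for (ms in splits(mt)) for (fs in splits(ft)) {
      # children choose transmissions independently: expand the full grid
      grids <- rep(list(1:4), length(children_cn))
      combos <- do.call(expand.grid, grids)
      for (r in seq_len(nrow(combos))) {
        ok <- TRUE
        for (i in seq_along(children_cn)) {
          choice <- combos[r, i]
          m_h <- ms[ifelse(choice <= 2, 1, 2)]
          f_h <- fs[ifelse(choice %% 2 == 1, 1, 2)]
          if (m_h + f_h != children_cn[i]) {
            ok <- FALSE
            break
          }
        }
        if (ok) return(TRUE)
      }
    }
  }
  FALSE
}

# multinomial class probabilities of the three-species droplet model:
# rates a (A-only), b (B-only), g (linked AB) molecules per droplet
quadrant_probs <- function(a, b, g) {
  p_nn <- exp(-(a + b + g))
  p_pn <- exp(-(b + g)) * (1 - exp(-a))
  p_np <- exp(-(a + g)) * (1 - exp(-b))
  c(nn = p_nn, pn = p_pn, np = p_np, pp = 1 - p_nn - p_pn - p_np)
}
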