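#' Default KIR haplotype-motif library
#'
#' A KIR haplotype is one centromeric motif (cA01, cB01, cB02) joined to
#' one telomeric motif (tA01, tB01) through the central recombination
#' hotspot. The library records, per motif, the genes this toolkit tracks
#' and their positions in kb from the motif start. Only the genes relevant
#' to linkage and copy-number analysis are positioned: KIR2DL5 sits
#' adjacent to KIR2DL2 in the centromeric B01 motif (21.8 kb apart) and
#' adjacent to KIR3DS1 in the telomeric B01 motif (19.9 kb apart); KIR2DS3
#' and KIR2DS5 travel with the centromeric and telomeric KIR2DL5 copies
#' respectively. The A-type motifs and cB02 carry no KIR2DL5. Positions of
#' genes other than these two printed inter-locus distances are schematic
#' and editable: the library is plain data, so rows can be added or moved
#' to encode other arrangements (see [read_motif_library()]).
#'
#' @return A tibble with columns `motif`, `motif_type` (`"cen"`/`"tel"`),
#'   `length_kb`, `gene`, `position_kb`.
#' @examples
#' kir_motif_library()
#' @export
kir_motif_library <- function() {
  tibble::tribble(
    ~motif, ~motif_type, ~length_kb, ~gene,       ~position_kb,
    "cA01", "cen", 70, "KIR2DL3",  25.0,
    "cB01", "cen", 70, "KIR2DL2",  25.0,
    "cB01", "cen", 70, "KIR2DL5",  46.8,   # 21.8 kb from KIR2DL2
    "cB01", "cen", 70, "KIR2DS3",  55.0,
    "cB02", "cen", 70, "KIR2DL2",  25.0,
    "tA01", "tel", 55, "KIR3DL1",  10.0,
    "tB01", "tel", 55, "KIR3DS1",  10.0,
    "tB01", "tel", 55, "KIR2DL5",  29.9,   # 19.9 kb from KIR3DS1
    "tB01", "tel", 55, "KIR2DS5",  38.0
  )
}

#' Read / write a motif library configuration
#'
#' The motif library is stored as a plain CSV with columns `motif`,
#' `motif_type`, `length_kb`, `gene`, `position_kb`, so alternative gene
#' arrangements (e.g. extended haplotypes) can be described without
#' touching code.
#'
#' @param path File path.
#' @return `read_motif_library()` returns the library tibble;
#'   `write_motif_library()` returns `path` invisibly.
#' @export
read_motif_library <- function(path) {
  lib <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("motif", "motif_type", "length_kb", "gene", "position_kb")
  if (!all(need %in% names(lib))) {
    stop_ddpcr("motif library must have columns: ", paste(need, collapse = ", "),
               class = "ddpcrlink_error_columns")
  }
  validate_motif_library(lib)
}

#' @rdname read_motif_library
#' @param library A motif library tibble.
#' @export
write_motif_library <- function(library, path) {
  readr::write_csv(validate_motif_library(library), path)
  invisible(path)
}

validate_motif_library <- function(lib) {
  lib <- tibble::as_tibble(lib)
  by_motif <- split(lib, lib$motif)
  for (m in by_motif) {
    if (anyDuplicated(m$gene)) {
      stop_ddpcr("gene names must be unique within motif ", m$motif[1],
                 class = "ddpcrlink_error_input")
    }
    if (is.unsorted(m$position_kb, strictly = TRUE)) {
      stop_ddpcr("positions must be strictly increasing within motif ", m$motif[1],
                 class = "ddpcrlink_error_input")
    }
  }
  lib
}

#' Build a diploid genotype from haplotype motif pairs
#'
#' Concatenates a centromeric and a telomeric motif into each haplotype,
#' separating them by `gap_kb`, and lays the tracked genes out on a common
#' kb coordinate per haplotype. Motif pairs are given as `"cB01~tA01"`
#' strings or as two-element character vectors.
#'
#' @param h1,h2 The two haplotypes, e.g. `"cB01~tA01"`.
#' @param library Motif library tibble (default [kir_motif_library()]).
#' @param gap_kb Distance between the end of the centromeric motif and the
#'   start of the telomeric motif (default 40 kb). Only affects linkage
#'   across the motif boundary.
#' @return An object of class `kir_genotype`: a tibble with columns
#'   `haplotype` (1 or 2), `motif`, `gene`, `position_kb`, plus the
#'   haplotype names as attributes.
#' @examples
#' g <- build_genotype("cB01~tA01", "cA01~tB01")
#' gene_copy_number(g, "KIR2DL5")
#' @export
build_genotype <- function(h1, h2, library = kir_motif_library(), gap_kb = 40) {
  library <- validate_motif_library(library)
  lay_out <- function(pair, hap) {
    if (length(pair) == 1) pair <- strsplit(pair, "~", fixed = TRUE)[[1]]
    if (length(pair) != 2) {
      stop_ddpcr("a haplotype is one centromeric and one telomeric motif",
                 class = "ddpcrlink_error_input")
    }
    cen <- library[library$motif == pair[1], ]
    tel <- library[library$motif == pair[2], ]
    if (nrow(cen) == 0 && !pair[1] %in% library$motif) {
      stop_ddpcr("unknown motif: ", pair[1], class = "ddpcrlink_error_input")
    }
    if (nrow(tel) == 0 && !pair[2] %in% library$motif) {
      stop_ddpcr("unknown motif: ", pair[2], class = "ddpcrlink_error_input")
    }
    if (nrow(cen) > 0 && any(cen$motif_type != "cen") ||
        nrow(tel) > 0 && any(tel$motif_type != "tel")) {
      stop_ddpcr("haplotype must pair a centromeric with a telomeric motif",
                 class = "ddpcrlink_error_input")
    }
    offset <- max(library$length_kb[library$motif == pair[1]]) + gap_kb
    dplyr::bind_rows(
      tibble::tibble(haplotype = hap, motif = cen$motif, gene = cen$gene,
                     position_kb = cen$position_kb),
      tibble::tibble(haplotype = hap, motif = tel$motif, gene = tel$gene,
                     position_kb = tel$position_kb + offset)
    )
  }
  g <- dplyr::bind_rows(lay_out(h1, 1L), lay_out(h2, 2L))
  structure(g, class = c("kir_genotype", class(g)),
            h1 = paste(if (length(h1) == 1) h1 else paste(h1, collapse = "~")),
            h2 = paste(if (length(h2) == 1) h2 else paste(h2, collapse = "~")))
}

#' Diploid copy number of a gene in a genotype
#'
#' @param genotype A [build_genotype()] object.
#' @param gene Gene name.
#' @return Integer count of occurrences over both haplotypes.
#' @export
gene_copy_number <- function(genotype, gene) {
  sum(genotype$gene == gene)
}

#' Random-breakage fragmentation model with optional restriction sites
#'
#' Extraction and handling shear genomic DNA; the toolkit models breakage
#' as a Poisson process along the molecule, so two loci `d` kb apart stay
#' on one fragment with probability `exp(-d / mean_fragment_kb)`.
#' Restriction digestion adds deterministic-position cut sites, each
#' severing the molecule with its own probability (1 for complete
#' digestion). The default 50 kb scale matches column-extraction kits that
#' prepare fragments up to ~50 kb.
#'
#' @param mean_fragment_kb Mean fragment length in kb (default 50).
#'   `Inf` disables random breakage.
#' @param cut_sites A tibble with columns `position_kb` and `prob`
#'   (haplotype coordinates), or NULL for none.
#' @return A list of class `fragmentation_model`.
#' @examples
#' fragmentation_model(50)
#' @export
fragmentation_model <- function(mean_fragment_kb = 50, cut_sites = NULL) {
  if (!(is.numeric(mean_fragment_kb) && mean_fragment_kb > 0)) {
    stop_ddpcr("mean_fragment_kb must be positive (Inf allowed)",
               class = "ddpcrlink_error_input")
  }
  if (!is.null(cut_sites)) {
    cut_sites <- tibble::as_tibble(cut_sites)
    if (!all(c("position_kb", "prob") %in% names(cut_sites))) {
      stop_ddpcr("cut_sites needs columns position_kb and prob",
                 class = "ddpcrlink_error_columns")
    }
    if (any(cut_sites$prob < 0 | cut_sites$prob > 1)) {
      stop_ddpcr("cut probabilities must lie in [0, 1]",
                 class = "ddpcrlink_error_input")
    }
  }
  structure(list(mean_fragment_kb = mean_fragment_kb, cut_sites = cut_sites),
            class = "fragmentation_model")
}

#' Place a restriction cut site between two genes of a genotype
#'
#' Convenience for digestion experiments: returns a one-row `cut_sites`
#' table at the midpoint between the two named genes on the first
#' haplotype that carries both.
#'
#' @param genotype A [build_genotype()] object.
#' @param gene_a,gene_b Gene names flanking the cut.
#' @param prob Cut probability (default 1: complete digestion).
#' @return A tibble usable as `cut_sites` in [fragmentation_model()].
#' @export
cut_between <- function(genotype, gene_a, gene_b, prob = 1) {
  for (hap in unique(genotype$haplotype)) {
    h <- genotype[genotype$haplotype == hap, ]
    if (gene_a %in% h$gene && gene_b %in% h$gene) {
      pa <- h$position_kb[h$gene == gene_a][1]
      pb <- h$position_kb[h$gene == gene_b][1]
      return(tibble::tibble(position_kb = (pa + pb) / 2, prob = prob))
    }
  }
  stop_ddpcr("no haplotype carries both ", gene_a, " and ", gene_b,
             class = "ddpcrlink_error_input")
}

# probability that two positions on one haplotype stay on one fragment
intact_probability <- function(pos_a, pos_b, frag) {
  d <- abs(pos_b - pos_a)
  p <- exp(-d / frag$mean_fragment_kb)
  if (!is.null(frag$cut_sites)) {
    lo <- min(pos_a, pos_b); hi <- max(pos_a, pos_b)
    between <- frag$cut_sites$position_kb > lo & frag$cut_sites$position_kb < hi
    p <- p * prod(1 - frag$cut_sites$prob[between])
  }
  p
}

#' Molecule species delivered to a duplex assay
#'
#' Fragments each genome copy of each haplotype and counts the molecule
#' species that matter to a duplex assay probing `target_a` and
#' `target_b`: molecules carrying only A, only B, or both in physical
#' linkage. On a haplotype carrying both targets, each A occurrence is
#' paired with its nearest unpaired B occurrence; a pair survives as one
#' linked molecule with probability
#' `exp(-d / mean_fragment_kb) * prod(1 - cut_prob)` over intervening cut
#' sites, and otherwise contributes one A-only and one B-only molecule.
#' Unpaired occurrences always contribute single-target molecules.
#'
#' @param genotype A [build_genotype()] object.
#' @param target_a,target_b Gene names probed on channels A and B.
#' @param n_genomes Number of diploid genome copies in the reaction.
#' @param frag A [fragmentation_model()] (default: intact DNA, no cuts).
#' @param seed Optional integer seed (isolated from the global RNG).
#' @return A tibble with one row: `a_only`, `b_only`, `linked_ab`
#'   molecule counts.
#' @examples
#' g <- build_genotype("cB01~tA01", "cA01~tB01")
#' molecules_for_assay(g, "KIR2DL2", "KIR2DL5", n_genomes = 1000, seed = 1)
#' @export
molecules_for_assay <- function(genotype, target_a, target_b, n_genomes,
                                frag = fragmentation_model(Inf), seed = NULL) {
  if (identical(target_a, target_b)) {
    stop_ddpcr("duplex targets must be distinct", class = "ddpcrlink_error_input")
  }
  if (n_genomes <= 0) {
    stop_ddpcr("n_genomes must be positive", class = "ddpcrlink_error_input")
  }
  draw <- function() {
    a_only <- 0L; b_only <- 0L; linked <- 0L
    for (hap in unique(genotype$haplotype)) {
      h <- genotype[genotype$haplotype == hap, ]
      pos_a <- h$position_kb[h$gene == target_a]
      pos_b <- h$position_kb[h$gene == target_b]
      # greedy nearest pairing of A and B occurrences on this haplotype
      free_b <- pos_b
      for (pa in pos_a) {
        if (length(free_b) == 0) {
          a_only <- a_only + n_genomes
          next
        }
        j <- which.min(abs(free_b - pa))
        p_int <- intact_probability(pa, free_b[j], frag)
        kept <- stats::rbinom(1L, n_genomes, p_int)
        linked <- linked + kept
        a_only <- a_only + (n_genomes - kept)
        b_only <- b_only + (n_genomes - kept)
        free_b <- free_b[-j]
      }
      b_only <- b_only + length(free_b) * n_genomes
    }
    tibble::tibble(a_only = as.integer(a_only), b_only = as.integer(b_only),
                   linked_ab = as.integer(linked))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Stochastically confine molecules into droplets
#'
#' Each molecule lands in a uniformly chosen droplet, independently of all
#' others; droplet occupancy is therefore multinomial and, in the dilute
#' limit, Poisson per droplet. A droplet reads positive on a channel when
#' it holds at least one molecule bearing that channel's target; a linked
#' molecule lights both channels at once. Optionally, each droplet's
#' per-channel call is flipped with probability `noise_rate`
#' (misclassification "rain"; default 0).
#'
#' @param species A tibble or list with `a_only`, `b_only`, `linked_ab`
#'   molecule counts (see [molecules_for_assay()]).
#' @param n_droplets Number of droplets (default 20000).
#' @param seed Optional integer seed (isolated from the global RNG).
#' @param noise_rate Per-channel misclassification probability (default 0).
#' @param ... Labels passed to [quadrant_tbl()] (`well`, `sample_id`,
#'   `assay`, `channel_a_target`, `channel_b_target`, `digested`).
#' @return A one-row quadrant-count tibble (see [quadrant_tbl()]).
#' @examples
#' partition_into_droplets(list(a_only = 0, b_only = 0, linked_ab = 1000),
#'                         n_droplets = 10000, seed = 1)
#' @export
partition_into_droplets <- function(species, n_droplets = 20000, seed = NULL,
                                    noise_rate = 0, ...) {
  if (n_droplets <= 0) {
    stop_ddpcr("n_droplets must be positive", class = "ddpcrlink_error_input")
  }
  draw <- function() {
    occupy <- function(n) {
      if (n == 0) return(logical(n_droplets))
      tabulate(sample.int(n_droplets, n, replace = TRUE), n_droplets) > 0
    }
    occ_a <- occupy(species$a_only)
    occ_b <- occupy(species$b_only)
    occ_ab <- occupy(species$linked_ab)
    pos_a <- occ_a | occ_ab
    pos_b <- occ_b | occ_ab
    if (noise_rate > 0) {
      pos_a <- xor(pos_a, stats::runif(n_droplets) < noise_rate)
      pos_b <- xor(pos_b, stats::runif(n_droplets) < noise_rate)
    }
    quadrant_tbl(
      n_nn = sum(!pos_a & !pos_b), n_pn = sum(pos_a & !pos_b),
      n_np = sum(!pos_a & pos_b), n_pp = sum(pos_a & pos_b), ...
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate one duplex linkage well from a genotype
#'
#' End-to-end wrapper: fragment `n_genomes` copies of the genotype, keep
#' the species relevant to the duplex, and confine them into droplets.
#'
#' @inheritParams molecules_for_assay
#' @inheritParams partition_into_droplets
#' @param sample_id,well,digested Labels for the emitted record.
#' @return A one-row quadrant-count tibble.
#' @examples
#' g <- build_genotype("cB01~tA01", "cA01~tB01")
#' simulate_linkage_well(g, "KIR2DL2", "KIR2DL5", seed = 1)
#' @export
simulate_linkage_well <- function(genotype, target_a, target_b,
                                  n_genomes = 3000, n_droplets = 20000,
                                  frag = fragmentation_model(Inf), seed = NULL,
                                  noise_rate = 0, sample_id = "sim",
                                  well = "A01", digested = FALSE) {
  run <- function() {
    species <- molecules_for_assay(genotype, target_a, target_b, n_genomes, frag)
    partition_into_droplets(
      species, n_droplets, noise_rate = noise_rate,
      channel_a_target = target_a, channel_b_target = target_b,
      assay = paste0(target_a, "~", target_b),
      sample_id = sample_id, well = well, digested = digested
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate one copy-number well (target vs invariant reference)
#'
#' The target gene (channel A) is present at `target_copies_per_genome`
#' unlinked copies per genome; the reference gene (channel B) at two
#' copies per genome, one per haplotype. All molecules are unlinked, as
#' for targets on different chromosomes or far apart.
#'
#' @param target_copies_per_genome Integer 0-4.
#' @param n_genomes Genome copies in the reaction (default 1500).
#' @inheritParams partition_into_droplets
#' @param gene,reference Channel target labels.
#' @param sample_id,well Labels for the emitted record.
#' @return A one-row quadrant-count tibble.
#' @examples
#' simulate_cnv_well(2, seed = 1)
#' @export
simulate_cnv_well <- function(target_copies_per_genome, n_genomes = 1500,
                              n_droplets = 20000, seed = NULL,
                              gene = "KIR2DL5", reference = "RPP30",
                              sample_id = "sim", well = "A01") {
  if (!target_copies_per_genome %in% 0:4) {
    stop_ddpcr("target_copies_per_genome must be an integer in 0..4",
               class = "ddpcrlink_error_input")
  }
  run <- function() {
    # two independent species: no physical linkage between target and reference
    occupy <- function(n) {
      if (n == 0) return(logical(n_droplets))
      tabulate(sample.int(n_droplets, n, replace = TRUE), n_droplets) > 0
    }
    pos_a <- occupy(target_copies_per_genome * n_genomes)
    pos_b <- occupy(2L * n_genomes)
    quadrant_tbl(
      n_nn = sum(!pos_a & !pos_b), n_pn = sum(pos_a & !pos_b),
      n_np = sum(!pos_a & pos_b), n_pp = sum(pos_a & pos_b),
      channel_a_target = gene, channel_b_target = reference,
      assay = paste0(gene, "/", reference), sample_id = sample_id, well = well
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a nuclear family's genotypes and copy-number table
#'
#' Each child inherits one uniformly chosen haplotype from each parent.
#' Emits a PED-like per-individual table with the diploid copy number of
#' `gene` and presence/absence of the co-segregating `presence_genes`
#' (by default KIR2DS3 and KIR2DS5, the genes in tight linkage
#' disequilibrium with the centromeric and telomeric KIR2DL5 copies).
#'
#' @param mother,father [build_genotype()] objects.
#' @param n_children Number of children (>= 1).
#' @param seed Optional integer seed.
#' @param family_id Family label.
#' @param gene Gene whose copy number is tabulated (default KIR2DL5).
#' @param presence_genes Genes reported as presence/absence columns.
#' @return A list with `ped`: tibble (`family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`, `<gene>_cn`, one logical column per
#'   presence gene) and `genotypes`: the per-child `kir_genotype` objects.
#' @examples
#' m <- build_genotype("cB01~tB01", "cA01~tA01")
#' f <- build_genotype("cA01~tA01", "cA01~tA01")
#' simulate_family(m, f, n_children = 3, seed = 1)$ped
#' @export
simulate_family <- function(mother, father, n_children, seed = NULL,
                            family_id = "F1", gene = "KIR2DL5",
                            presence_genes = c("KIR2DS3", "KIR2DS5")) {
  if (n_children < 1) {
    stop_ddpcr("need at least one child", class = "ddpcrlink_error_input")
  }
  run <- function() {
    hap <- function(g, i) g[g$haplotype == i, ]
    row_for <- function(id, father_id, mother_id, sex, g) {
      out <- tibble::tibble(
        family_id = family_id, individual_id = id,
        father_id = father_id, mother_id = mother_id, sex = sex
      )
      out[[paste0(tolower(gene), "_cn")]] <- sum(g$gene == gene)
      for (p in presence_genes) out[[tolower(p)]] <- p %in% g$gene
      out
    }
    kids <- purrr::map(seq_len(n_children), function(i) {
      hm <- sample.int(2L, 1L)
      hf <- sample.int(2L, 1L)
      g <- dplyr::bind_rows(
        dplyr::mutate(hap(mother, hm), haplotype = 1L),
        dplyr::mutate(hap(father, hf), haplotype = 2L)
      )
      structure(g, class = c("kir_genotype", class(g)))
    })
    ped <- dplyr::bind_rows(
      row_for("MOTHER", "0", "0", 2L, mother),
      row_for("FATHER", "0", "0", 1L, father),
      purrr::imap_dfr(kids, function(g, i) {
        row_for(paste0("CHILD", i), "FATHER", "MOTHER", 1L, g)
      })
    )
    list(ped = ped, genotypes = kids)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
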