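#' Enumerate haplotype splits of a diploid copy-number total
#'
#' A diploid total `total_cn` can be carried as any ordered pair of
#' per-haplotype counts `(h1, h2)` with `h1 + h2 = total_cn` and each
#' count at most `per_haplotype_max` (2 for a gene that can occur twice
#' on one haplotype, giving diploid totals up to 4).
#'
#' @param total_cn Diploid copy-number total.
#' @param per_haplotype_max Maximum copies on a single haplotype
#'   (default 2).
#' @return A tibble with columns `h1`, `h2`, one row per ordered split.
#' @examples
#' enumerate_haplotype_splits(3)
#' @export
enumerate_haplotype_splits <- function(total_cn, per_haplotype_max = 2) {
  if (is.na(total_cn) || total_cn < 0 || total_cn > 2 * per_haplotype_max ||
      total_cn != round(total_cn)) {
    stop_ddpcr("infeasible genotype: total copy number must be an integer in [0, ",
               2 * per_haplotype_max, "]",
               class = "ddpcrlink_error_infeasible_genotype")
  }
  h1 <- max(0L, total_cn - per_haplotype_max):min(per_haplotype_max, total_cn)
  tibble::tibble(h1 = as.integer(h1), h2 = as.integer(total_cn - h1))
}

# feasible totals for an unknown parent
feasible_totals <- function(cn, per_haplotype_max) {
  if (is.na(cn)) 0:(2 * per_haplotype_max) else as.integer(cn)
}

#' Mendelian consistency of copy-number calls in one nuclear family
#'
#' A family's integer copy numbers are Mendelian-consistent when there is
#' one split of each parent's total into two per-haplotype counts such
#' that *every* child's total is the sum of one maternal and one paternal
#' haplotype count — the same parental splits must explain all siblings
#' jointly, since parental haplotypes are fixed. Unknown parental totals
#' (`NA`) are unconstrained: all feasible totals are tried. De novo
#' copy-number events are not modelled; an inconsistency is reported, not
#' explained away.
#'
#' @param mother_cn,father_cn Parental diploid totals (integer or `NA`).
#' @param children_cn Integer vector of child totals (>= 1 child).
#' @param per_haplotype_max Maximum copies on one haplotype (default 2).
#' @return A one-row tibble: `consistent` (logical), `witness` (list
#'   column: when consistent, a list with `mother_split`, `father_split`
#'   and per-child `transmitted` tibble), `violating_child` (index of the
#'   first child no parental split can accommodate, or `NA`).
#' @examples
#' mendelian_consistent(3, 1, c(1, 2, 3))
#' @export
mendelian_consistent <- function(mother_cn, father_cn, children_cn,
                                 per_haplotype_max = 2) {
  if (length(children_cn) < 1) {
    stop_ddpcr("family must have at least one child",
               class = "ddpcrlink_error_input")
  }
  kids <- as.integer(children_cn)
  if (any(is.na(kids))) {
    # unknown children impose no constraint
    kids <- kids[!is.na(kids)]
    if (length(kids) == 0) {
      return(tibble::tibble(consistent = TRUE, witness = list(NULL),
                            violating_child = NA_integer_))
    }
  }
  if (any(kids < 0 | kids > 2 * per_haplotype_max)) {
    stop_ddpcr("infeasible child copy number",
               class = "ddpcrlink_error_infeasible_genotype")
  }
  for (m_total in feasible_totals(mother_cn, per_haplotype_max)) {
    m_splits <- enumerate_haplotype_splits(m_total, per_haplotype_max)
    for (f_total in feasible_totals(father_cn, per_haplotype_max)) {
      f_splits <- enumerate_haplotype_splits(f_total, per_haplotype_max)
      for (i in seq_len(nrow(m_splits))) {
        mh <- c(m_splits$h1[i], m_splits$h2[i])
        for (j in seq_len(nrow(f_splits))) {
          fh <- c(f_splits$h1[j], f_splits$h2[j])
          # each child needs one maternal + one paternal haplotype count
          trans <- purrr::map(kids, function(k) {
            hit <- which(outer(mh, fh, `+`) == k, arr.ind = TRUE)
            if (nrow(hit) == 0) NULL else
              tibble::tibble(maternal = mh[hit[1, 1]], paternal = fh[hit[1, 2]])
          })
          if (!any(purrr::map_lgl(trans, is.null))) {
            witness <- list(
              mother_split = mh, father_split = fh,
              transmitted = dplyr::bind_rows(trans)
            )
            return(tibble::tibble(consistent = TRUE, witness = list(witness),
                                  violating_child = NA_integer_))
          }
        }
      }
    }
  }
  # first child that no split pair can produce, for reporting
  viol <- first_violating_child(mother_cn, father_cn, kids, per_haplotype_max)
  tibble::tibble(consistent = FALSE, witness = list(NULL),
                 violating_child = viol)
}

first_violating_child <- function(mother_cn, father_cn, kids, per_haplotype_max) {
  possible <- function(k) {
    for (m_total in feasible_totals(mother_cn, per_haplotype_max)) {
      ms <- enumerate_haplotype_splits(m_total, per_haplotype_max)
      for (f_total in feasible_totals(father_cn, per_haplotype_max)) {
        fs <- enumerate_haplotype_splits(f_total, per_haplotype_max)
        if (any(outer(c(ms$h1, ms$h2), c(fs$h1, fs$h2), `+`) == k)) return(TRUE)
      }
    }
    FALSE
  }
  solo <- which(!purrr::map_lgl(kids, possible))
  if (length(solo) > 0) return(solo[1])
  # every child is individually explainable; the joint constraint fails.
  # report the child whose removal restores consistency, else the last one.
  for (i in seq_along(kids)) {
    rest <- kids[-i]
    if (length(rest) == 0 ||
        mendelian_consistent_quiet(mother_cn, father_cn, rest, per_haplotype_max)) {
      return(i)
    }
  }
  length(kids)
}

mendelian_consistent_quiet <- function(mother_cn, father_cn, kids, phm) {
  mendelian_consistent(mother_cn, father_cn, kids, phm)$consistent
}

#' Check Mendelian consistency across a pedigree table
#'
#' Data-frame entry point: takes a PED-like table (one row per individual,
#' as read by [read_pedigree_table()] or emitted by [simulate_family()])
#' and runs [mendelian_consistent()] on every family. Individuals whose
#' parent ids are `"0"` are founders; all non-founders in a family are
#' treated as one sibship of the named parents.
#'
#' @param ped A tibble with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id` and the copy-number column `cn_col`.
#' @param cn_col Name of the integer copy-number column
#'   (default `"kir2dl5_cn"`).
#' @param per_haplotype_max Maximum copies on one haplotype (default 2).
#' @return A tibble with one row per family: `family_id`, `n_children`,
#'   `consistent`, `violating_child` (individual id or `NA`), `witness`
#'   (list column).
#' @export
check_mendelian <- function(ped, cn_col = "kir2dl5_cn", per_haplotype_max = 2) {
  need <- c("family_id", "individual_id", "father_id", "mother_id", cn_col)
  if (!all(need %in% names(ped))) {
    stop_ddpcr("pedigree table needs columns: ", paste(need, collapse = ", "),
               class = "ddpcrlink_error_columns")
  }
  ped |>
    dplyr::group_split(.data$family_id) |>
    purrr::map_dfr(function(fam) {
      founders <- fam$father_id %in% c("0", NA) & fam$mother_id %in% c("0", NA)
      kids <- fam[!founders, ]
      if (nrow(kids) == 0) {
        stop_ddpcr("family ", fam$family_id[1], " has no children",
                   class = "ddpcrlink_error_input")
      }
      mother_id <- unique(kids$mother_id)
      father_id <- unique(kids$father_id)
      if (length(mother_id) != 1 || length(father_id) != 1) {
        stop_ddpcr("family ", fam$family_id[1],
                   " is not a single nuclear sibship",
                   class = "ddpcrlink_error_input")
      }
      cn_of <- function(id) {
        v <- fam[[cn_col]][fam$individual_id == id]
        if (length(v) == 0) NA_integer_ else as.integer(v[1])
      }
      res <- mendelian_consistent(cn_of(mother_id), cn_of(father_id),
                                  kids[[cn_col]], per_haplotype_max)
      tibble::tibble(
        family_id = fam$family_id[1],
        n_children = nrow(kids),
        consistent = res$consistent,
        violating_child = if (is.na(res$violating_child)) NA_character_
                          else kids$individual_id[res$violating_child],
        witness = res$witness
      )
    })
}

#' Co-segregation consistency of KIR2DL5 with KIR2DS3/KIR2DS5
#'
#' In most populations KIR2DS3 travels with the centromeric KIR2DL5 copy
#' and KIR2DS5 with the telomeric copy, in tight linkage disequilibrium.
#' Two population-level expectations follow: absence of both KIR2DS3 and
#' KIR2DS5 implies absence of KIR2DL5, and presence of both implies at
#' least two KIR2DL5 copies. Violations are *warnings* for review, not
#' errors — the disequilibrium is not perfect in every population.
#'
#' @param df A data frame with the copy-number and presence columns, or
#'   nothing (use the vector arguments instead).
#' @param cn_col,ds3_col,ds5_col Column names (defaults `kir2dl5_cn`,
#'   `kir2ds3`, `kir2ds5`).
#' @return The input tibble with a logical `cosegregation_violation`
#'   column appended.
#' @examples
#' cosegregation_check(tibble::tibble(
#'   kir2dl5_cn = c(0, 1, 2), kir2ds3 = c(FALSE, FALSE, TRUE),
#'   kir2ds5 = c(FALSE, FALSE, TRUE)))
#' @export
cosegregation_check <- function(df, cn_col = "kir2dl5_cn",
                                ds3_col = "kir2ds3", ds5_col = "kir2ds5") {
  need <- c(cn_col, ds3_col, ds5_col)
  if (!all(need %in% names(df))) {
    stop_ddpcr("need columns: ", paste(need, collapse = ", "),
               class = "ddpcrlink_error_columns")
  }
  cn <- df[[cn_col]]
  ds3 <- df[[ds3_col]]
  ds5 <- df[[ds5_col]]
  df <- tibble::as_tibble(df)
  df$cosegregation_violation <-
    (!ds3 & !ds5 & cn > 0) | (ds3 & ds5 & cn < 2)
  df
}
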