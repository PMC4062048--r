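#' Read a droplet quadrant-count table
#'
#' Reads the toolkit's droplet-count CSV: one row per well with the four
#' quadrant counts and identifying labels. Common vendor-export header
#' spellings are accepted via an alias map (e.g. `Well`, `Sample`,
#' `Ch1+Ch2+`, `AccptedDroplets`). Every row is validated (non-negative
#' integer counts summing to `n_total`); offending rows are reported by
#' line number.
#'
#' @param path CSV file path.
#' @return A validated tibble with columns `well`, `sample_id`, `assay`,
#'   `channel_a_target`, `channel_b_target`, `digested`, `n_total`,
#'   `n_pp`, `n_pn`, `n_np`, `n_nn`.
#' @export
read_droplet_table <- function(path) {
  if (!file.exists(path)) {
    stop_ddpcr("file not found: ", path, class = "ddpcrlink_error_io")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_guess()))
  aliases <- c(
    well = "well", Well = "well",
    sample = "sample_id", Sample = "sample_id", sample_id = "sample_id",
    assay = "assay", Assay = "assay", Target = "assay",
    channel_a_target = "channel_a_target", channel_b_target = "channel_b_target",
    TargetCh1 = "channel_a_target", TargetCh2 = "channel_b_target",
    digested = "digested", Digested = "digested",
    n_total = "n_total", AcceptedDroplets = "n_total", AccptedDroplets = "n_total",
    n_pp = "n_pp", `Ch1+Ch2+` = "n_pp",
    n_pn = "n_pn", `Ch1+Ch2-` = "n_pn",
    n_np = "n_np", `Ch1-Ch2+` = "n_np",
    n_nn = "n_nn", `Ch1-Ch2-` = "n_nn"
  )
  hit <- names(raw) %in% names(aliases)
  names(raw)[hit] <- aliases[names(raw)[hit]]
  required <- c("well", "sample_id", "n_total", "n_pp", "n_pn", "n_np", "n_nn")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_ddpcr("missing required column(s): ",
               paste(missing_cols, collapse = ", "),
               class = "ddpcrlink_error_columns")
  }
  if (!"assay" %in% names(raw)) raw$assay <- "duplex"
  if (!"digested" %in% names(raw)) raw$digested <- FALSE
  raw$digested <- as.logical(raw$digested)
  bad_id <- which(is.na(raw$well) | raw$well == "" |
                    is.na(raw$sample_id) | raw$sample_id == "")
  if (length(bad_id) > 0) {
    stop_ddpcr("empty well/sample label in data row(s) ",
               paste(bad_id, collapse = ", "),
               class = "ddpcrlink_error_io")
  }
  for (col in c("n_total", "n_pp", "n_pn", "n_np", "n_nn")) {
    raw[[col]] <- as.integer(raw[[col]])
  }
  counts <- raw[c("n_total", "n_pp", "n_pn", "n_np", "n_nn")]
  sums <- rowSums(counts[-1])
  bad <- which(is.na(raw$n_total) | sums != raw$n_total)
  if (length(bad) > 0) {
    stop_ddpcr("quadrant counts do not sum to n_total in data row(s) ",
               paste(bad, collapse = ", "),
               class = "ddpcrlink_error_io")
  }
  validate_quadrants(raw)
}

#' Write a droplet quadrant-count table
#'
#' @param df A validated droplet table (see [quadrant_tbl()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_droplet_table <- function(df, path) {
  df <- validate_quadrants(df)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a PED-like pedigree table
#'
#' Tab-separated, one row per individual, with header:
#' `family_id`, `individual_id`, `father_id`, `mother_id`, `sex`, then
#' per-gene copy-number (`*_cn`) and presence/absence columns. Founders
#' use `"0"` as parent id; unknown values may be `NA`.
#'
#' @param path TSV file path.
#' @return A tibble grouped implicitly by `family_id`.
#' @export
read_pedigree_table <- function(path) {
  if (!file.exists(path)) {
    stop_ddpcr("file not found: ", path, class = "ddpcrlink_error_io")
  }
  ped <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  need <- c("family_id", "individual_id", "father_id", "mother_id")
  missing_cols <- setdiff(need, names(ped))
  if (length(missing_cols) > 0) {
    stop_ddpcr("missing required column(s): ",
               paste(missing_cols, collapse = ", "),
               class = "ddpcrlink_error_columns")
  }
  ped$individual_id <- as.character(ped$individual_id)
  ped$father_id <- as.character(ped$father_id)
  ped$mother_id <- as.character(ped$mother_id)
  if (anyDuplicated(paste(ped$family_id, ped$individual_id))) {
    stop_ddpcr("duplicated individual id within a family",
               class = "ddpcrlink_error_io")
  }
  # structural check: every named parent must exist in the family
  for (fam in split(ped, ped$family_id)) {
    parents <- setdiff(unique(c(fam$father_id, fam$mother_id)), c("0", NA))
    absent <- setdiff(parents, fam$individual_id)
    if (length(absent) > 0) {
      stop_ddpcr("family ", fam$family_id[1],
                 ": child references absent parent ",
                 paste(absent, collapse = ", "),
                 class = "ddpcrlink_error_io")
    }
  }
  ped
}

#' Write a PED-like pedigree table
#'
#' @param ped Pedigree tibble (see [read_pedigree_table()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pedigree_table <- function(ped, path) {
  readr::write_tsv(ped, path)
  invisible(path)
}

#' Default analysis configuration
#'
#' All operational thresholds live in one nested list that can be saved
#' to / read from a YAML file and passed to the command-line interface.
#' Defaults: droplet volume 1 nL; QC minimum 8000 accepted droplets;
#' max-channel %L normalization; motif presence above %L = 1 with
#' digestion at or below half the undigested score; mixture posterior
#' floor 0.95.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    quant = list(droplet_volume_nl = 1, min_droplets = 8000, level = 0.95),
    linkage = list(normalization = "max_channel", presence_threshold = 1.0,
                   abrogation_fraction = 0.5, weak_threshold = 5,
                   n_boot = 2000),
    cnv = list(k_candidates = 1:5, posterior_floor = 0.95, integer_band = 0),
    pedigree = list(per_haplotype_max = 2),
    simulate = list(mean_fragment_kb = 50, gap_kb = 40, n_droplets = 20000,
                    n_genomes = 3000, noise_rate = 0)
  )
}

#' @rdname default_config
#' @param path YAML file path.
#' @return `read_config()` returns the defaults with any values in the
#'   file overriding them.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) {
    stop_ddpcr("config file not found: ", path, class = "ddpcrlink_error_io")
  }
  user <- yaml::read_yaml(path)
  for (section in names(user)) {
    for (key in names(user[[section]])) {
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  cfg
}
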