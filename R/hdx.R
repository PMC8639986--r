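#' Maximum number of exchange-competent amides of a peptide
#'
#' Standard fast-exchange convention: the peptide's N-terminal residue has no
#' retained amide and the second residue back-exchanges too fast to measure,
#' so the maximum exchangeable amides are `length - 2 - interior prolines`
#' (prolines beyond the first two residues, which lack an amide proton).
#' The `"minus1"` convention (`length - 1 - prolines`) is also available.
#'
#' @param sequence Peptide amino-acid string.
#' @param convention `"minus2"` (default) or `"minus1"`.
#' @return Integer count.
#' @examples
#' max_exchangeable("GSSGKLMNPQ") # 10 - 2 - 1 interior proline = 7
#' @export
max_exchangeable <- function(sequence, convention = c("minus2", "minus1")) {
  convention <- match.arg(convention)
  vapply(sequence, function(s) {
    aa <- strsplit(s, "")[[1]]
    skip <- if (convention == "minus2") 2L else 1L
    interior <- aa[-seq_len(min(skip, length(aa)))]
    as.integer(length(aa) - skip - sum(interior == "P"))
  }, integer(1), USE.NAMES = FALSE)
}

#' Raw deuterium uptake from centroid masses
#'
#' Collapses a per-replicate centroid table to per-peptide, per-time-point
#' uptake: the replicate mean of (deuterated centroid - undeuterated
#' centroid), with the replicate SD. The undeuterated control is taken from
#' the `undeuterated_centroid` column, or, when absent, from the mean
#' centroid of the `time == 0` rows of each peptide.
#'
#' @param data Long tibble with columns `peptide_id`, `sequence`, `start`,
#'   `end`, `time`, `replicate`, `centroid_mass` and (optionally)
#'   `undeuterated_centroid` — the "state table" layout written by
#'   [sim_hdx_peptides()] and common HDX exports after column mapping.
#' @return Tibble with one row per peptide and time point: `peptide_id`,
#'   `sequence`, `start`, `end`, `time`, `n_replicates`, `uptake_raw` (Da),
#'   `uptake_sd` (Da).
#' @export
uptake_from_centroids <- function(data) {
  check_columns(data, c("peptide_id", "sequence", "start", "end", "time",
                        "replicate", "centroid_mass"), "data")
  if (!"undeuterated_centroid" %in% names(data)) {
    und <- data |>
      dplyr::filter(.data$time == 0) |>
      dplyr::summarise(undeuterated_centroid = mean(.data$centroid_mass),
                       .by = "peptide_id")
    if (nrow(und) == 0 || !all(unique(data$peptide_id) %in% und$peptide_id)) {
      abort("Missing undeuterated control: supply `undeuterated_centroid` or time-0 rows for every peptide.")
    }
    data <- dplyr::left_join(data, und, by = "peptide_id")
  }
  data |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      uptake_raw = mean(.data$centroid_mass - .data$undeuterated_centroid),
      uptake_sd = if (dplyr::n() > 1) {
        sd(.data$centroid_mass - .data$undeuterated_centroid)
      } else {
        0
      },
      .by = c("peptide_id", "sequence", "start", "end", "time")
    ) |>
    dplyr::arrange(.data$start, .data$peptide_id, .data$time)
}

#' Correct deuterium uptake for back-exchange
#'
#' Applies the global back-exchange correction
#' `uptake_corrected = uptake_raw / (1 - factor)`; a factor of 0.25 (the
#' typical value determined from disordered-termini standards) maps a raw
#' uptake of 1.5 Da to 2.0 Da.
#'
#' @param records Uptake table from [uptake_from_centroids()].
#' @param factor Back-exchange fraction lost, in \[0, 1).
#' @return The table with columns `uptake_corrected` and `uptake_corrected_sd`.
#' @export
correct_back_exchange <- function(records, factor = 0.25) {
  check_number(factor, "factor", lower = 0, upper = 1, strict_upper = TRUE)
  check_columns(records, c("uptake_raw", "uptake_sd"), "records")
  dplyr::mutate(records,
                uptake_corrected = .data$uptake_raw / (1 - factor),
                uptake_corrected_sd = .data$uptake_sd / (1 - factor))
}

#' Relative fractional uptake
#'
#' Divides back-exchange-corrected uptake by the peptide's maximum number of
#' exchange-competent amides.
#'
#' @param records Table from [correct_back_exchange()] (columns `sequence`,
#'   `uptake_corrected`, `uptake_corrected_sd`).
#' @param convention Passed to [max_exchangeable()].
#' @return The table with columns `max_uptake`, `rfu` and `rfu_sd`.
#' @export
relative_fractional_uptake <- function(records,
                                       convention = c("minus2", "minus1")) {
  convention <- match.arg(convention)
  check_columns(records, c("sequence", "uptake_corrected"), "records")
  mx <- max_exchangeable(records$sequence, convention)
  if (any(mx <= 0)) {
    abort("Peptide with no exchange-competent amides (all-proline interior).")
  }
  dplyr::mutate(records,
                max_uptake = mx,
                rfu = .data$uptake_corrected / mx,
                rfu_sd = .data$uptake_corrected_sd / mx)
}

#' Full uptake pipeline: centroids to relative fractional uptake
#'
#' Convenience wrapper chaining [uptake_from_centroids()],
#' [correct_back_exchange()] and [relative_fractional_uptake()].
#'
#' @inheritParams uptake_from_centroids
#' @param back_exchange Global back-exchange factor (default 0.25).
#' @param convention Amide-counting convention (see [max_exchangeable()]).
#' @return Uptake tibble with `uptake_raw`, `uptake_corrected`, `rfu` and
#'   their SDs per peptide and time point.
#' @examples
#' peps <- data.frame(start = 1, end = 10)
#' d <- sim_hdx_peptides("GSSGKLMNQA", rates = rep(0.8, 10), peptides = peps,
#'                       replicate_sd = 0, seed = 1)
#' hdx_uptake(d)
#' @export
hdx_uptake <- function(data, back_exchange = 0.25,
                       convention = c("minus2", "minus1")) {
  data |>
    uptake_from_centroids() |>
    correct_back_exchange(factor = back_exchange) |>
    relative_fractional_uptake(convention = convention)
}

#' Difference in relative fractional uptake between two conditions
#'
#' Joins two uptake tables (e.g. a phosphomimetic mutant and the wild type)
#' on the intersection of peptide and time coverage and reports
#' `delta_rfu = rfu_a - rfu_b` with a pooled replicate SD
#' (`sqrt(sd_a^2 + sd_b^2)`). A difference is flagged significant when
#' `|delta_rfu| > sd_multiplier * pooled_sd`. Positive values indicate more
#' exchange in condition `a`.
#'
#' @param a,b Uptake tables from [hdx_uptake()] (columns `peptide_id`,
#'   `time`, `rfu`, `rfu_sd`).
#' @param sd_multiplier Significance multiplier (default 2).
#' @return Tibble: `peptide_id`, `start`, `end`, `time`, `rfu_a`, `rfu_b`,
#'   `delta_rfu`, `pooled_sd`, `significant`.
#' @export
uptake_difference <- function(a, b, sd_multiplier = 2) {
  for (df in list(a, b)) {
    check_columns(df, c("peptide_id", "time", "rfu", "rfu_sd"), "uptake table")
  }
  keys <- intersect(paste(a$peptide_id, a$time), paste(b$peptide_id, b$time))
  if (length(keys) == 0) abort("No shared peptide/time coverage between conditions.")
  joined <- dplyr::inner_join(
    dplyr::select(a, "peptide_id", dplyr::any_of(c("start", "end")), "time",
                  rfu_a = "rfu", sd_a = "rfu_sd"),
    dplyr::select(b, "peptide_id", "time", rfu_b = "rfu", sd_b = "rfu_sd"),
    by = c("peptide_id", "time")
  )
  joined |>
    dplyr::mutate(
      delta_rfu = .data$rfu_a - .data$rfu_b,
      pooled_sd = sqrt(.data$sd_a^2 + .data$sd_b^2),
      significant = abs(.data$delta_rfu) > sd_multiplier * .data$pooled_sd
    ) |>
    dplyr::select(-"sd_a", -"sd_b")
}

#' Map peptide-level uptake onto residues
#'
#' Projects per-peptide relative fractional uptake at a single time point
#' onto residues: each covered residue gets the unweighted mean RFU of the
#' peptides whose span contains it; residues inside the construct but
#' outside every peptide span are marked as having no coverage.
#'
#' @param records Uptake table with columns `peptide_id`, `start`, `end`,
#'   `time`, `rfu`, restricted or restrictable to one time point.
#' @param time Time point to map (required when `records` holds several).
#' @param residues Optional integer vector of residues to report; default
#'   spans the full range covered by any peptide.
#' @return Tibble: `residue`, `rfu` (`NA` when uncovered), `n_peptides`,
#'   `covered`.
#' @export
map_to_residues <- function(records, time = NULL, residues = NULL) {
  check_columns(records, c("peptide_id", "start", "end", "rfu"), "records")
  if (!is.null(time)) {
    records <- records[records$time == time, , drop = FALSE]
  } else if ("time" %in% names(records) &&
             length(unique(records$time)) > 1) {
    abort("Records span several time points; pass `time`.")
  }
  if (nrow(records) == 0) abort("No records at the requested time point.")
  if (is.null(residues)) {
    residues <- seq(min(records$start), max(records$end))
  }
  per_res <- purrr::map(seq_len(nrow(records)), function(i) {
    tibble::tibble(residue = records$start[i]:records$end[i],
                   rfu = records$rfu[i])
  }) |>
    dplyr::bind_rows() |>
    dplyr::summarise(rfu = mean(.data$rfu), n_peptides = dplyr::n(),
                     .by = "residue")
  tibble::tibble(residue = residues) |>
    dplyr::left_join(per_res, by = "residue") |>
    dplyr::mutate(n_peptides = dplyr::coalesce(.data$n_peptides, 0L),
                  covered = .data$n_peptides > 0)
}

#' Read an HDX state table from CSV
#'
#' Expects the documented long layout: `peptide_id`, `sequence`, `start`,
#' `end`, `time`, `replicate`, `centroid_mass` and optionally
#' `undeuterated_centroid`.
#'
#' @param path CSV file path.
#' @return Tibble.
#' @export
read_hdx_table <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  check_columns(df, c("peptide_id", "sequence", "start", "end", "time",
                      "replicate", "centroid_mass"), "HDX csv")
  df
}
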