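#' Rank kinases by signal with cumulative-share curve
#'
#' Sorts a single-substrate kinase table by descending signal (ties broken
#' alphabetically by kinase name) and adds cumulative signal and cumulative
#' fraction columns, the backbone of "top k kinases account for X% of the
#' total signal" statements.
#'
#' @param records Tibble with columns `kinase`, `signal` and optionally
#'   `family`, `substrate_peptide`, `assay`. Signals must be a single assay
#'   type and a single substrate.
#' @return Tibble ordered by rank with columns `rank`, `kinase`, `signal`,
#'   `cumulative_signal`, `cumulative_fraction` (plus any metadata columns).
#' @examples
#' rank_kinases(data.frame(kinase = c("a", "b", "c"),
#'                         signal = c(10, 30, 60)))
#' @export
rank_kinases <- function(records) {
  check_columns(records, c("kinase", "signal"), "records")
  if (any(records$signal < 0)) abort("Signals must be >= 0.")
  if ("assay" %in% names(records) && length(unique(records$assay)) > 1) {
    abort("Mixed assay types (CPM and RLU) cannot be ranked together.")
  }
  if ("substrate_peptide" %in% names(records) &&
      length(unique(records$substrate_peptide)) > 1) {
    abort("Rank one substrate peptide at a time.")
  }
  total <- sum(records$signal)
  if (total == 0) abort("Total signal is zero; nothing to rank.")
  records |>
    dplyr::arrange(dplyr::desc(.data$signal), .data$kinase) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      cumulative_signal = cumsum(.data$signal),
      cumulative_fraction = cumsum(.data$signal) / total,
      .before = 1
    )
}

#' Cumulative signal share of the top k kinases
#'
#' @param records Kinase table (see [rank_kinases()]) or an already ranked
#'   table.
#' @param k Number of top kinases.
#' @return Fraction of total signal carried by the `k` highest-signal
#'   kinases.
#' @examples
#' top_k_share(data.frame(kinase = c("a", "b", "c"),
#'                        signal = c(10, 30, 60)), k = 2) # 0.9
#' @export
top_k_share <- function(records, k) {
  k <- check_count(k, "k")
  ranked <- if ("cumulative_fraction" %in% names(records)) records else
    rank_kinases(records)
  if (k > nrow(ranked)) abort("`k` exceeds the number of kinases.")
  ranked$cumulative_fraction[k]
}

#' Count kinases with signal above a cutoff
#'
#' Strict inequality, matching ">50,000 CPM"-style statements.
#'
#' @param records Kinase table with a `signal` column.
#' @param cutoff Signal cutoff (>= 0).
#' @return Integer count of records with `signal > cutoff`.
#' @export
threshold_count <- function(records, cutoff) {
  check_columns(records, "signal", "records")
  check_number(cutoff, "cutoff", lower = 0)
  sum(records$signal > cutoff)
}

#' Site-preference analysis across substrate-peptide variants
#'
#' Attributes kinase activity to individual phosphosites by comparing signal
#' between substrate peptides that differ in the availability or priming
#' state of exactly one site. Substrate variants that differ only in their
#' last residue (marked by a shared `variant_group`) are arithmetically
#' averaged before comparison. For an available-vs-blocked (Ala) contrast,
#' a signal ratio of at least `require_ratio` yields
#' "mainly phosphorylates X" and at least `prefer_ratio` yields
#' "prefers X"; for a primed-vs-blocked contrast the labels are
#' "requires priming at X" / "prefers priming at X"; anything below
#' `prefer_ratio` is "indifferent".
#'
#' @param records Tibble with `kinase`, `substrate`, `signal` (single assay).
#' @param substrates Tibble describing peptide variants: `substrate`, `site`
#'   (e.g. `"S892"`), `status` in `{"available", "blocked", "primed"}`,
#'   and optionally `variant_group` (variants differing only in the last
#'   residue share a group and are averaged).
#' @param kinases Optional subset of kinases to analyse.
#' @param prefer_ratio,require_ratio Classification ratio thresholds
#'   (defaults 3 and 10; reported in the output).
#' @return Tibble with one row per kinase x informative substrate pair:
#'   `kinase`, `site`, `contrast` (`"availability"` or `"priming"`),
#'   `substrate_hi`, `substrate_lo`, `signal_hi`, `signal_lo`, `ratio`,
#'   `label`. Kinases whose substrates offer no informative pair are
#'   returned with `label = "no inference"`.
#' @export
site_preference <- function(records, substrates, kinases = NULL,
                            prefer_ratio = 3, require_ratio = 10) {
  check_columns(records, c("kinase", "substrate", "signal"), "records")
  check_columns(substrates, c("substrate", "site", "status"), "substrates")
  if (!all(substrates$status %in% c("available", "blocked", "primed"))) {
    abort("`substrates$status` must be 'available', 'blocked' or 'primed'.")
  }
  if ("assay" %in% names(records) && length(unique(records$assay)) > 1) {
    abort("Mixed assay types cannot be compared.")
  }
  if (!is.null(kinases)) records <- records[records$kinase %in% kinases, ]
  if (nrow(records) == 0) abort("No records for the requested kinases.")

  # collapse last-residue variants first
  if ("variant_group" %in% names(substrates)) {
    grp <- unique(substrates[, c("substrate", "variant_group")])
    records <- records |>
      dplyr::left_join(grp, by = "substrate") |>
      dplyr::mutate(variant_group = dplyr::coalesce(.data$variant_group,
                                                    .data$substrate)) |>
      dplyr::summarise(signal = mean(.data$signal),
                       .by = c("kinase", "variant_group")) |>
      dplyr::rename(substrate = "variant_group")
    substrates <- substrates |>
      dplyr::mutate(substrate = dplyr::coalesce(.data$variant_group,
                                                .data$substrate)) |>
      dplyr::distinct(.data$substrate, .data$site, .data$status)
  }

  status_tab <- substrates |>
    tidyr::pivot_wider(names_from = "site", values_from = "status",
                       values_fill = "blocked")
  sites <- setdiff(names(status_tab), "substrate")
  subs <- status_tab$substrate
  smat <- as.matrix(status_tab[, sites, drop = FALSE])
  rownames(smat) <- subs

  # informative pairs: substrate status vectors differing at exactly one site
  pairs <- list()
  if (length(subs) >= 2) {
    cmb <- utils::combn(seq_along(subs), 2)
    for (j in seq_len(ncol(cmb))) {
      i1 <- cmb[1, j]; i2 <- cmb[2, j]
      diffs <- which(smat[i1, ] != smat[i2, ])
      if (length(diffs) != 1) next
      site <- sites[diffs]
      st <- c(smat[i1, diffs], smat[i2, diffs])
      if ("blocked" %in% st) {
        hi <- if (st[1] == "blocked") i2 else i1
        lo <- if (st[1] == "blocked") i1 else i2
        contrast <- if (smat[hi, diffs] == "primed") "priming" else "availability"
        pairs[[length(pairs) + 1]] <- list(site = site, hi = subs[hi],
                                           lo = subs[lo], contrast = contrast)
      }
    }
  }

  per_kinase <- split(records, records$kinase)
  out <- purrr::imap(per_kinase, function(rec, kin) {
    sig <- setNames(rec$signal, rec$substrate)
    rows <- purrr::map(pairs, function(p) {
      if (!all(c(p$hi, p$lo) %in% names(sig))) return(NULL)
      ratio <- sig[[p$hi]] / max(sig[[p$lo]], .Machine$double.eps)
      label <- if (ratio >= require_ratio) {
        if (p$contrast == "priming") {
          sprintf("requires priming at %s", p$site)
        } else {
          sprintf("mainly phosphorylates %s", p$site)
        }
      } else if (ratio >= prefer_ratio) {
        if (p$contrast == "priming") {
          sprintf("prefers priming at %s", p$site)
        } else {
          sprintf("prefers %s", p$site)
        }
      } else {
        "indifferent"
      }
      tibble::tibble(kinase = kin, site = p$site, contrast = p$contrast,
                     substrate_hi = p$hi, substrate_lo = p$lo,
                     signal_hi = sig[[p$hi]], signal_lo = sig[[p$lo]],
                     ratio = ratio, label = label)
    })
    rows <- dplyr::bind_rows(rows)
    if (nrow(rows) == 0) {
      tibble::tibble(kinase = kin, site = NA_character_,
                     contrast = NA_character_, substrate_hi = NA_character_,
                     substrate_lo = NA_character_, signal_hi = NA_real_,
                     signal_lo = NA_real_, ratio = NA_real_,
                     label = "no inference")
    } else {
      rows
    }
  })
  dplyr::bind_rows(out)
}

parse_sites <- function(x) {
  if (is.list(x)) return(purrr::map(x, as.character))
  strsplit(as.character(x), "[;+,/|[:space:]]+")
}

#' Fraction of phosphopeptides carrying multiple sites
#'
#' Summarizes phosphopeptide observations over a site cluster: the fraction
#' of observations (weighted by `count` when present) with two or more
#' modified sites simultaneously, the frequency table of site combinations,
#' and the maximum number of sites seen on one peptide.
#'
#' @param observations Tibble with a `sites` column — either a list-column
#'   of site vectors or strings like `"897+901"` (separators `+ ; , /`
#'   or whitespace) — and an optional `count` column.
#' @return List with `fraction_multisite`, `max_sites`, `n_observations`,
#'   and `combinations` (tibble: `combination`, `n_sites`, `count`,
#'   `frequency`).
#' @examples
#' obs <- data.frame(sites = c("897", "897+901", "892+897+898+899"))
#' multisite_fraction(obs)$fraction_multisite # 2/3
#' @export
multisite_fraction <- function(observations) {
  check_columns(observations, "sites", "observations")
  sites <- parse_sites(observations$sites)
  if (any(purrr::map_int(sites, length) == 0) ||
      any(purrr::map_lgl(sites, function(s) all(!nzchar(s))))) {
    abort("Each phosphopeptide observation must carry at least one site.")
  }
  count <- if ("count" %in% names(observations)) observations$count else
    rep(1, length(sites))
  if (any(count < 0)) abort("`count` must be >= 0.")
  n_sites <- purrr::map_int(sites, ~ length(unique(.x)))
  combos <- purrr::map_chr(sites, ~ paste(sort(unique(.x)), collapse = "+"))
  total <- sum(count)
  comb_tab <- tibble::tibble(combination = combos, n_sites = n_sites,
                             count = count) |>
    dplyr::summarise(n_sites = .data$n_sites[1], count = sum(.data$count),
                     .by = "combination") |>
    dplyr::mutate(frequency = .data$count / total) |>
    dplyr::arrange(dplyr::desc(.data$count))
  list(
    fraction_multisite = sum(count[n_sites >= 2]) / total,
    max_sites = max(n_sites),
    n_observations = total,
    combinations = comb_tab
  )
}

#' Pairwise correlations of phosphorylation levels across sites
#'
#' Pearson correlation for every pair of phosphosites over a panel of cell
#' lines (rows). Constant columns have undefined correlation; they are
#' flagged with a warning and returned as `NA`.
#'
#' @param levels Data frame or matrix with one row per cell line and one
#'   column per site (>= 3 rows required).
#' @return Symmetric correlation matrix with unit diagonal (site names on
#'   both dimensions).
#' @examples
#' m <- cbind(S897 = c(1, 2, 3, 4), S901 = c(1.1, 2.2, 2.9, 4.1))
#' site_correlation(m)
#' @export
site_correlation <- function(levels) {
  m <- as.matrix(levels)
  if (!is.numeric(m)) abort("`levels` must be numeric.")
  if (nrow(m) < 3) abort("Need at least 3 cell lines (rows).")
  if (any(!is.finite(m))) abort("`levels` must be finite.")
  const <- apply(m, 2, function(col) var(col) == 0)
  if (any(const)) {
    warn(sprintf("Constant column(s) with undefined correlation: %s.",
                 paste(colnames(m)[const], collapse = ", ")))
  }
  suppressWarnings(stats::cor(m))
}

#' Read a kinase-screen table from CSV
#'
#' Expects columns `kinase`, `family`, `substrate_peptide` (or `substrate`),
#' `signal`, `assay`.
#'
#' @param path CSV file path.
#' @return Tibble.
#' @export
read_kinase_table <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  check_columns(df, c("kinase", "signal"), "kinase csv")
  df
}
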