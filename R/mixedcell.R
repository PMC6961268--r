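# Single-cell heterogeneity: observed vs expected proportion of "mixed"
# cells (cells carrying both edited and unedited reads of one transcript)
# under the null of random, independent assignment of editing to reads.

#' Observed mixed-cell statistics for one site
#'
#' Among cells with at least two reads of the site's transcript (both
#' variants combined), the observed mixed proportion is the fraction
#' carrying at least one edited and at least one unedited read. The
#' pooled editing level over all reads of the site and the per-cell
#' read-count histogram are returned for the expectation.
#'
#' @param ct a `cell_table`
#' @param site_id editing site
#' @return list of class `mixed_cell_stats`: `site_id`, `n_cells_ge2`,
#'   `histogram` (named vector: reads-per-cell n -> number of cells),
#'   `observed_mixed`, `editing_level` (pooled over all reads of the
#'   site), `expected_mixed`, `deviation`.
#' @export
observed_mixed <- function(ct, site_id) {
  cs <- .cell_site_counts(ct, site_id)
  tot <- cs$n_edited + cs$n_unedited
  ge2 <- tot >= 2
  hist <- table(tot[ge2])
  observed <- if (any(ge2))
    mean(cs$n_edited[ge2] >= 1 & cs$n_unedited[ge2] >= 1) else NA_real_
  p <- editing_level(sum(cs$n_edited), sum(cs$n_unedited))
  expected <- expected_mixed(p, hist)
  structure(list(site_id = site_id,
                 n_cells_ge2 = sum(ge2),
                 histogram = hist,
                 observed_mixed = observed,
                 editing_level = p,
                 expected_mixed = expected,
                 deviation = observed - expected),
            class = "mixed_cell_stats")
}

#' @export
print.mixed_cell_stats <- function(x, ...) {
  cat(sprintf("mixed cells at %s: observed %.3f, expected %.3f (n=%d, level %.3f)\n",
              x$site_id, x$observed_mixed, x$expected_mixed,
              x$n_cells_ge2, x$editing_level))
  invisible(x)
}

#' Expected mixed-cell proportion under random read assignment
#'
#' Conditional on the observed per-cell read counts, with each read
#' independently edited with probability `p`, a cell with `n` reads is
#' mixed unless all reads are edited or all unedited:
#' `P(mixed | n) = 1 - p^n - (1-p)^n`. The expectation averages this over
#' the read-count histogram of cells with `n >= 2`.
#'
#' @param p editing level in `[0, 1]`
#' @param histogram named vector/table: reads-per-cell -> number of cells
#' @return Expected proportion (NA for an empty histogram or `NA` level).
#' @export
expected_mixed <- function(p, histogram) {
  if (length(histogram) == 0 || sum(histogram) == 0 || is.na(p)) return(NA_real_)
  if (p < 0 || p > 1) stop("editing level must lie in [0, 1]")
  n <- as.numeric(names(histogram))
  if (any(is.na(n)) || any(n < 2)) stop("histogram must be keyed by read counts >= 2")
  f <- as.numeric(histogram)
  sum(f * (1 - p^n - (1 - p)^n)) / sum(f)
}

#' Compare observed and expected mixed-cell proportions across sites
#'
#' @param stats list of `mixed_cell_stats` (one per site), or a data frame
#'   with columns `site_id`, `observed_mixed`, `expected_mixed`
#' @return list of class `mixed_cell_comparison`: `pearson_r`, and `table`
#'   with per-site deviations and an `under_represented` flag (observed
#'   below expected — the signature of cell-to-cell editing
#'   heterogeneity / bimodal editing).
#' @export
compare_mixed <- function(stats) {
  if (is.data.frame(stats)) {
    tab <- stats
  } else {
    tab <- do.call(rbind, lapply(stats, function(s)
      data.frame(site_id = s$site_id, n_cells_ge2 = s$n_cells_ge2,
                 observed_mixed = s$observed_mixed,
                 expected_mixed = s$expected_mixed,
                 stringsAsFactors = FALSE)))
  }
  tab <- tab[!is.na(tab$observed_mixed) & !is.na(tab$expected_mixed), , drop = FALSE]
  if (nrow(tab) < 3) stop("need at least 3 sites with defined mixed-cell stats")
  tab$deviation <- tab$observed_mixed - tab$expected_mixed
  tab$under_represented <- tab$observed_mixed < tab$expected_mixed
  r <- if (stats::sd(tab$observed_mixed) == 0 || stats::sd(tab$expected_mixed) == 0)
    NA_real_ else stats::cor(tab$observed_mixed, tab$expected_mixed)
  structure(list(pearson_r = r, table = tab), class = "mixed_cell_comparison")
}

#' @export
print.mixed_cell_comparison <- function(x, ...) {
  cat(sprintf("mixed-cell comparison over %d sites: Pearson r = %.3f, %d under-represented\n",
              nrow(x$table), x$pearson_r, sum(x$table$under_represented)))
  invisible(x)
}

#' Mixed-cell analysis over all sites of a cell table
#'
#' @param ct a `cell_table`
#' @param min_cells minimum number of cells with >= 2 reads for a site to
#'   be reported (sites below it get `NA` proportions)
#' @return data frame, one row per site: `site_id`, `n_cells_ge2`,
#'   `observed_mixed`, `expected_mixed`, `deviation`.
#' @export
mixed_cell_table <- function(ct, min_cells = 1) {
  sites <- site_pairs(ct$codebook)$site_id
  rows <- lapply(sites, function(s) {
    st <- observed_mixed(ct, s)
    if (st$n_cells_ge2 < min_cells) {
      st$observed_mixed <- NA_real_; st$expected_mixed <- NA_real_
      st$deviation <- NA_real_
    }
    data.frame(site_id = s, n_cells_ge2 = st$n_cells_ge2,
               observed_mixed = st$observed_mixed,
               expected_mixed = st$expected_mixed,
               deviation = st$deviation, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
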