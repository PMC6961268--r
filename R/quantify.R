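# Editing-level quantification: per-site edited/unedited read counts by
# stratum, coverage filters, editing ratios versus the stratum complement,
# Adar2 active/inactive decomposition, and replicate aggregation.

#' Editing level from variant read counts
#'
#' @param n_edited,n_unedited nonnegative integer vectors
#' @return `n_edited / (n_edited + n_unedited)`, `NA` where the denominator
#'   is zero (no data is reported as `NA`, never imputed as zero).
#' @export
editing_level <- function(n_edited, n_unedited) {
  if (any(n_edited < 0, na.rm = TRUE) || any(n_unedited < 0, na.rm = TRUE))
    stop("read counts must be nonnegative")
  tot <- n_edited + n_unedited
  ifelse(tot > 0, n_edited / tot, NA_real_)
}

#' Editing ratio between a stratum and its complement
#'
#' The regional (or marker) editing level divided by the level of the same
#' site outside the stratum (whole tissue minus the region; marker-negative
#' cells). `NA` when either level is `NA` or the outside level is zero.
#'
#' @param level_in,level_out editing levels in `[0, 1]` (or `NA`)
#' @return Ratio vector with `NA` propagation.
#' @export
editing_ratio <- function(level_in, level_out) {
  ifelse(is.na(level_in) | is.na(level_out) | level_out == 0,
         NA_real_, level_in / level_out)
}

#' Annotate reads with editing-site identity
#'
#' @param reads read table with a `target` column
#' @param cb a [codebook]
#' @return `reads` with `site_id` (NA for non-variant reads) and `edited`
#'   (logical) columns; only QC-passing reads should be fed to the count
#'   functions.
#' @keywords internal
annotate_sites <- function(reads, cb) {
  idx <- match(reads$target, cb$target_name)
  reads$site_id <- cb$site_id[idx]
  reads$edited <- cb$probe_class[idx] == "edited_variant"
  reads$edited[is.na(reads$site_id)] <- NA
  reads
}

# count edited/unedited reads of every site within groups defined by the
# given read-table columns (character vector `by`, possibly empty)
.site_counts <- function(reads, cb, by = character(0)) {
  reads <- annotate_sites(reads, cb)
  v <- reads[!is.na(reads$site_id), , drop = FALSE]
  if (nrow(v) == 0) {
    out <- data.frame(site_id = character(0))
    for (b in by) out[[b]] <- character(0)
    out$n_edited <- integer(0); out$n_unedited <- integer(0)
    return(out)
  }
  key <- do.call(paste, c(v[c("site_id", by)], sep = "\r"))
  ed <- tapply(v$edited, key, sum)
  tot <- tapply(v$edited, key, length)
  parts <- do.call(rbind, strsplit(names(ed), "\r", fixed = TRUE))
  out <- data.frame(site_id = parts[, 1], stringsAsFactors = FALSE)
  for (j in seq_along(by)) out[[by[j]]] <- parts[, j + 1]
  out$n_edited <- as.integer(ed)
  out$n_unedited <- as.integer(tot - ed)
  rownames(out) <- NULL
  out[order(out$site_id), , drop = FALSE]
}

#' Whole-tissue editing-site counts
#'
#' Per-site edited/unedited counts pooled over the whole scene, one row
#' per site (and per any grouping columns present, e.g. `replicate`,
#' `stage`).
#'
#' @param reads QC-passing, annotated read table
#' @param cb a [codebook]
#' @param by extra grouping columns present in `reads` (e.g.
#'   `c("replicate","stage")`)
#' @return data frame with `site_id`, grouping columns, `n_edited`,
#'   `n_unedited`, `level`.
#' @export
whole_counts <- function(reads, cb, by = character(0)) {
  out <- .site_counts(reads, cb, by)
  out$level <- editing_level(out$n_edited, out$n_unedited)
  out
}

#' Whole-tissue coverage filter for editing sites
#'
#' A site is retained iff at some stage the replicate-mean count of its
#' least prevalent variant (min of edited, unedited) reaches
#' `min_reads`; all other sites are flagged `below_500_whole`.
#'
#' @param counts data frame with `site_id`, `replicate`, `stage`,
#'   `n_edited`, `n_unedited` (whole-tissue counts per replicate)
#' @param min_reads threshold on the mean minor-variant count (default 500)
#' @return data frame `site_id`, `retained`, `qc`.
#' @export
whole_brain_site_filter <- function(counts, min_reads = 500) {
  if (!"stage" %in% names(counts)) counts$stage <- "all"
  minor <- pmin(counts$n_edited, counts$n_unedited)
  key <- paste(counts$site_id, counts$stage, sep = "\r")
  means <- tapply(minor, key, mean)
  site_of <- sub("\r.*$", "", names(means))
  best <- tapply(means, site_of, max)
  sites <- sort(unique(counts$site_id))
  retained <- best[sites] >= min_reads
  data.frame(site_id = sites,
             retained = as.vector(retained),
             qc = ifelse(retained, "", "below_500_whole"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Regional editing counts with complement strata
#'
#' For every (site, region, replicate): edited/unedited counts inside the
#' region and in its complement (`whole_minus_region`), with editing
#' levels. Replicates whose combined count inside a region falls below
#' `min_reads` are flagged `below_100_region` and must be excluded from
#' aggregation (the flag is carried, not silently dropped).
#'
#' @param reads QC-passing read table with a `region` column (see
#'   [assign_reads()]); reads with region `"NONE"` count only toward the
#'   complement strata
#' @param cb a [codebook]
#' @param min_reads per-replicate combined-count threshold (default 100)
#' @param replicate optional name of a replicate column in `reads`
#' @return data frame with `site_id`, `region`, `stratum`
#'   (`"region"`/`"whole_minus_region"`), `replicate`, counts, `level`,
#'   `qc`.
#' @export
regional_counts <- function(reads, cb, min_reads = 100, replicate = NULL) {
  regions <- sort(setdiff(unique(reads$region), REGION_NONE))
  if ("region" %in% names(reads) == FALSE)
    stop("reads must carry a region column; run assign_reads() first")
  rep_col <- if (is.null(replicate)) rep("1", nrow(reads)) else as.character(reads[[replicate]])
  reads$..rep <- rep_col
  whole <- .site_counts(reads, cb, by = "..rep")
  per_reg <- .site_counts(reads, cb, by = c("region", "..rep"))
  out <- NULL
  reps <- sort(unique(rep_col))
  sites <- site_pairs(cb)$site_id
  grid <- expand.grid(site_id = sites, region = regions, replicate = reps,
                      stringsAsFactors = FALSE)
  m_in <- match(paste(grid$site_id, grid$region, grid$replicate),
                paste(per_reg$site_id, per_reg$region, per_reg$..rep))
  n_ed_in <- ifelse(is.na(m_in), 0L, per_reg$n_edited[m_in])
  n_un_in <- ifelse(is.na(m_in), 0L, per_reg$n_unedited[m_in])
  m_wh <- match(paste(grid$site_id, grid$replicate),
                paste(whole$site_id, whole$..rep))
  n_ed_wh <- ifelse(is.na(m_wh), 0L, whole$n_edited[m_wh])
  n_un_wh <- ifelse(is.na(m_wh), 0L, whole$n_unedited[m_wh])
  inside <- data.frame(grid, stratum = "region",
                       n_edited = n_ed_in, n_unedited = n_un_in,
                       stringsAsFactors = FALSE)
  outside <- data.frame(grid, stratum = "whole_minus_region",
                        n_edited = n_ed_wh - n_ed_in,
                        n_unedited = n_un_wh - n_un_in,
                        stringsAsFactors = FALSE)
  out <- rbind(inside, outside)
  out$level <- editing_level(out$n_edited, out$n_unedited)
  combined <- out$n_edited + out$n_unedited
  out$qc <- ifelse(out$stratum == "region" & combined < min_reads,
                   "below_100_region",
                   ifelse(combined == 0, "NA_zero_denominator", ""))
  out[order(out$site_id, out$region, out$stratum, out$replicate), ]
}

#' Regional editing ratios
#'
#' Ratio of each region's editing level over the level of the rest of the
#' tissue, per site and replicate, from [regional_counts()] output.
#' Region strata flagged below the coverage filter yield `NA`.
#'
#' @param rc output of [regional_counts()]
#' @return data frame `site_id`, `region`, `replicate`, `level_in`,
#'   `level_out`, `ratio`.
#' @export
regional_ratios <- function(rc) {
  inside <- rc[rc$stratum == "region", ]
  outside <- rc[rc$stratum == "whole_minus_region", ]
  m <- match(paste(inside$site_id, inside$region, inside$replicate),
             paste(outside$site_id, outside$region, outside$replicate))
  level_in <- ifelse(inside$qc == "", inside$level, NA_real_)
  level_out <- outside$level[m]
  data.frame(site_id = inside$site_id, region = inside$region,
             replicate = inside$replicate,
             level_in = level_in, level_out = level_out,
             ratio = editing_ratio(level_in, level_out),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Decompose Adar2 reads into active and inactive isoforms
#'
#' ADAR2 auto-editing at the intronic -1 site creates an alternative
#' splice acceptor yielding a frameshifted, catalytically inactive
#' isoform; the observed auto-editing level therefore splits total Adar2
#' reads into inactive (edited at the auto-site) and active parts.
#' Rounding is half-up on the inactive count.
#'
#' @param auto_editing_level auto-editing level in `[0, 1]` (or `NA`)
#' @param total_adar2_reads total Adar2 read count
#' @return list with `active` and `inactive` integer counts (`NA` when the
#'   level is `NA`).
#' @export
adar2_decompose <- function(auto_editing_level, total_adar2_reads) {
  if (any(total_adar2_reads < 0, na.rm = TRUE)) stop("negative read count")
  if (any(!is.na(auto_editing_level) &
          (auto_editing_level < 0 | auto_editing_level > 1)))
    stop("auto-editing level must lie in [0, 1]")
  inactive <- ifelse(is.na(auto_editing_level), NA_integer_,
                     as.integer(floor(auto_editing_level * total_adar2_reads + 0.5)))
  active <- ifelse(is.na(inactive), NA_integer_,
                   as.integer(total_adar2_reads) - inactive)
  list(active = active, inactive = inactive)
}

#' Aggregate per-replicate editing levels
#'
#' Unweighted mean of per-replicate levels with the sample standard
#' deviation (`NA` at n = 1), per site and stratum. Replicates flagged by
#' a coverage filter or with `NA` levels do not contribute; strata with
#' zero contributing replicates are reported `NA` with a qc reason.
#'
#' @param est data frame with `site_id`, `level`, `qc`, optional `stratum`
#'   and further grouping columns
#' @param by grouping columns in addition to `site_id` (default: `stratum`
#'   and `region` when present)
#' @param pool_counts if `TRUE`, pool `n_edited`/`n_unedited` across
#'   replicates instead of averaging levels (alternative aggregation kept
#'   behind this flag)
#' @return data frame with grouping columns, `mean_level`, `sd_level`,
#'   `n_replicates`, `qc`.
#' @export
aggregate_replicates <- function(est, by = intersect(c("stratum", "region", "stage",
                                                       "marker", "cell_class"),
                                                     names(est)),
                                 pool_counts = FALSE) {
  keycols <- c("site_id", by)
  key <- do.call(paste, c(est[keycols], sep = "\r"))
  ok <- est$qc == "" & !is.na(est$level)
  ukey <- unique(key)
  rows <- lapply(ukey, function(k) {
    sel <- key == k & ok
    n <- sum(sel)
    if (pool_counts) {
      ne <- sum(est$n_edited[sel]); nu <- sum(est$n_unedited[sel])
      mean_level <- editing_level(ne, nu)
      sd_level <- NA_real_
    } else {
      lv <- est$level[sel]
      mean_level <- if (n > 0) mean(lv) else NA_real_
      sd_level <- if (n > 1) stats::sd(lv) else NA_real_
    }
    first <- which(key == k)[1]
    cbind(est[first, keycols, drop = FALSE],
          data.frame(mean_level = mean_level, sd_level = sd_level,
                     n_replicates = n,
                     qc = if (n == 0) "no_contributing_replicates" else ""))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
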