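# Cell typing by marker reads (non-strict, multi-label) and
# marker-stratified editing levels, ratios and the temporal three-class
# comparison.

#' Build a cell table from cell-assigned reads
#'
#' @param reads QC-passing read table with `cell_id` and `target` columns
#'   (see [assign_reads()]); reads with `NA` cell_id are dropped here
#' @param cb a [codebook]
#' @param replicate,stage optional column names in `reads` carried through
#'   per cell
#' @return Object of class `cell_table`: list with `counts` (long data
#'   frame `cell_id`, `target`, `n`), `cells` (per-cell metadata incl.
#'   `region` if present), and `classes` (filled by [classify_cells()]).
#' @export
build_cell_table <- function(reads, cb, replicate = NULL, stage = NULL) {
  r <- reads[!is.na(reads$cell_id) & reads$target != UNMATCHED, , drop = FALSE]
  key <- paste(r$cell_id, r$target, sep = "\r")
  n <- tapply(rep(1L, nrow(r)), key, sum)
  parts <- do.call(rbind, strsplit(names(n), "\r", fixed = TRUE))
  counts <- data.frame(cell_id = as.integer(parts[, 1]), target = parts[, 2],
                       n = as.integer(n), row.names = NULL,
                       stringsAsFactors = FALSE)
  ids <- sort(unique(r$cell_id))
  cells <- data.frame(cell_id = ids)
  for (col in c("region", replicate, stage)) {
    if (!is.null(col) && col %in% names(r))
      cells[[col]] <- r[[col]][match(ids, r$cell_id)]
  }
  structure(list(counts = counts, cells = cells, classes = NULL,
                 codebook = cb),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("cell_table: %d cells, %d targets%s\n",
              nrow(x$cells), length(unique(x$counts$target)),
              if (is.null(x$classes)) "" else
                sprintf(", %d class assignments", nrow(x$classes))))
  invisible(x)
}

#' Classify cells by marker expression (non-strict, multi-label)
#'
#' A cell positive for a marker (at least `min_count` reads) belongs to
#' that marker's class; a cell with several markers belongs to several
#' classes — classes are not mutually exclusive. Cells without any marker
#' read stay unclassified.
#'
#' @param ct a `cell_table`
#' @param min_count minimum marker read count for positivity (default 1)
#' @return The `cell_table` with `classes` filled: long data frame
#'   `cell_id`, `marker`, `cell_class`.
#' @export
classify_cells <- function(ct, min_count = 1) {
  cb <- ct$codebook
  markers <- cb[cb$probe_class == "marker", , drop = FALSE]
  mc <- ct$counts[ct$counts$target %in% markers$target_name &
                    ct$counts$n >= min_count, , drop = FALSE]
  ct$classes <- data.frame(
    cell_id = mc$cell_id,
    marker = mc$target,
    cell_class = markers$cell_class[match(mc$target, markers$target_name)],
    row.names = NULL, stringsAsFactors = FALSE)
  ct
}

# per-cell edited/unedited counts of one site
.cell_site_counts <- function(ct, site_id) {
  pr <- site_pairs(ct$codebook)
  pr <- pr[pr$site_id == site_id, ]
  if (nrow(pr) != 1) stop("unknown site_id: ", site_id)
  cb <- ct$codebook
  ed_t <- cb$target_name[cb$barcode == pr$edited_barcode]
  un_t <- cb$target_name[cb$barcode == pr$unedited_barcode]
  ids <- ct$cells$cell_id
  ed <- ct$counts$n[match(paste(ids, ed_t), paste(ct$counts$cell_id, ct$counts$target))]
  un <- ct$counts$n[match(paste(ids, un_t), paste(ct$counts$cell_id, ct$counts$target))]
  data.frame(cell_id = ids,
             n_edited = ifelse(is.na(ed), 0L, ed),
             n_unedited = ifelse(is.na(un), 0L, un))
}

#' Marker-stratified editing level for one site
#'
#' Pools edited/unedited reads of `site_id` over marker-positive cells
#' (and, for the ratio's complement, over marker-negative cells: cells
#' without a single read of that marker, whatever other markers they
#' carry). A replicate contributes only if, on average across replicates,
#' at least `min_cells` cells express both the marker and the site's
#' transcript (>= 1 read of either variant).
#'
#' @param ct a classified `cell_table`
#' @param site_id editing site
#' @param marker marker target name
#' @param min_cells replicate-mean qualifying-cell threshold (default 100)
#' @param replicate optional per-cell replicate column name in `ct$cells`
#' @return data frame with strata `marker:<name>` and
#'   `marker_negative:<name>`: counts, `level`, `n_cells`, `qc`.
#' @export
marker_editing <- function(ct, site_id, marker, min_cells = 100,
                           replicate = NULL) {
  if (is.null(ct$classes)) stop("run classify_cells() first")
  cb <- ct$codebook
  if (!marker %in% cb$target_name[cb$probe_class == "marker"])
    stop("unknown marker: ", marker)
  cs <- .cell_site_counts(ct, site_id)
  pos_ids <- unique(ct$classes$cell_id[ct$classes$marker == marker])
  pos <- cs$cell_id %in% pos_ids
  has_site <- cs$n_edited + cs$n_unedited >= 1
  rep_of <- if (!is.null(replicate) && replicate %in% names(ct$cells))
    as.character(ct$cells[[replicate]][match(cs$cell_id, ct$cells$cell_id)])
  else rep("1", nrow(cs))
  reps <- sort(unique(rep_of))
  qualifying <- tapply(pos & has_site, rep_of, sum)
  mean_qual <- mean(qualifying[reps])
  qc <- if (mean_qual < min_cells) "below_100_cells" else ""
  one <- function(sel, stratum) {
    ne <- sum(cs$n_edited[sel]); nu <- sum(cs$n_unedited[sel])
    data.frame(site_id = site_id, stratum = stratum, marker = marker,
               n_edited = ne, n_unedited = nu,
               level = editing_level(ne, nu),
               n_cells = sum(sel & has_site),
               qc = qc, stringsAsFactors = FALSE)
  }
  rbind(one(pos, paste0("marker:", marker)),
        one(!pos, paste0("marker_negative:", marker)))
}

#' Marker editing ratio
#'
#' Level in marker-positive cells over the level in marker-negative
#' cells; same contract as [editing_ratio()].
#'
#' @param level_positive,level_negative editing levels
#' @return Ratio or `NA`.
#' @export
marker_editing_ratio <- function(level_positive, level_negative) {
  editing_ratio(level_positive, level_negative)
}

#' Temporal editing levels per cell class
#'
#' Per (site, class, stage, replicate) pooled editing level over cells of
#' the class, with the per-replicate minimum-cell filter used for the
#' interneuron / pyramidal / oligodendrocyte temporal comparison; the
#' output feeds [kruskal_wallis()] / [dunn_sidak()] across classes per
#' stage.
#'
#' @param ct a classified `cell_table`
#' @param site_id editing site
#' @param classes cell class names to include
#' @param min_cells_per_replicate minimum qualifying cells per replicate
#'   (default 20); qualifying means in the class with >= 1 read of the
#'   site's transcript
#' @param replicate,stage optional per-cell column names in `ct$cells`
#' @return data frame `site_id`, `cell_class`, `stage`, `replicate`,
#'   counts, `level`, `n_cells`, `qc`.
#' @export
class_temporal_editing <- function(ct, site_id,
                                   classes = c("interneuron", "pyramidal",
                                               "oligodendrocyte"),
                                   min_cells_per_replicate = 20,
                                   replicate = NULL, stage = NULL) {
  if (is.null(ct$classes)) stop("run classify_cells() first")
  cs <- .cell_site_counts(ct, site_id)
  has_site <- cs$n_edited + cs$n_unedited >= 1
  meta <- ct$cells
  rep_of <- if (!is.null(replicate) && replicate %in% names(meta))
    as.character(meta[[replicate]][match(cs$cell_id, meta$cell_id)]) else rep("1", nrow(cs))
  stage_of <- if (!is.null(stage) && stage %in% names(meta))
    as.character(meta[[stage]][match(cs$cell_id, meta$cell_id)]) else rep("all", nrow(cs))
  out <- NULL
  for (cl in classes) {
    in_cl <- cs$cell_id %in% ct$classes$cell_id[ct$classes$cell_class == cl]
    for (st in sort(unique(stage_of))) for (rp in sort(unique(rep_of))) {
      sel <- in_cl & stage_of == st & rep_of == rp
      nq <- sum(sel & has_site)
      ne <- sum(cs$n_edited[sel]); nu <- sum(cs$n_unedited[sel])
      out <- rbind(out, data.frame(
        site_id = site_id, cell_class = cl, stage = st, replicate = rp,
        n_edited = ne, n_unedited = nu,
        level = editing_level(ne, nu), n_cells = nq,
        qc = if (nq < min_cells_per_replicate) "below_20_cells" else "",
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
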