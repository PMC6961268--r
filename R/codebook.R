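# Barcode codebook: maps 4-nt probe barcodes to targets, pairing the
# edited/unedited padlock-probe variant of every interrogated editing site.

#' Sequencing channel order
#'
#' The fixed mapping between barcode letters and fluorescence channels used
#' consistently by the decoder and the scene simulator: channel 1 = A,
#' 2 = C, 3 = G, 4 = T.
#'
#' @return Character vector `c("A","C","G","T")`.
#' @export
iss_channels <- function() c("A", "C", "G", "T")

#' Sentinel for reads whose barcode is absent from the codebook
#' @export
UNMATCHED <- "UNMATCHED"

.probe_classes <- c("edited_variant", "unedited_variant", "marker", "adar", "other")

#' Construct and validate a codebook
#'
#' A codebook is a data frame with one row per probe barcode. Editing sites
#' are represented by a *pair* of entries sharing a `site_id`: the
#' edited-variant probe (3' G, reading the inosine) and the unedited-variant
#' probe (3' A). Marker probes carry the `cell_class` they report; probe sets
#' sharing one transcript (e.g. several Adar2 probes) share a
#' `transcript_group` but each entry keeps its own `target_name`.
#'
#' @param entries data frame with columns `target_name`, `barcode`,
#'   `probe_class` (one of `"edited_variant"`, `"unedited_variant"`,
#'   `"marker"`, `"adar"`, `"other"`), and optionally `site_id`,
#'   `cell_class`, `transcript_group`.
#' @return An object of class `codebook` (a validated data frame with a
#'   `barcode_length` attribute).
#' @details Validation enforces: one constant barcode length (the number of
#'   sequencing cycles), barcodes unique and over the alphabet A/C/G/T, and
#'   every `site_id` occurring exactly twice, once per variant class.
#' @export
codebook <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  needed <- c("target_name", "barcode", "probe_class")
  miss <- setdiff(needed, names(entries))
  if (length(miss) > 0)
    stop("codebook is missing required columns: ", paste(miss, collapse = ", "))
  for (col in c("site_id", "cell_class", "transcript_group"))
    if (!col %in% names(entries)) entries[[col]] <- rep(NA_character_, nrow(entries))
  entries <- entries[c(needed, "site_id", "cell_class", "transcript_group")]
  for (col in names(entries)) {
    entries[[col]] <- as.character(entries[[col]])
    entries[[col]][!is.na(entries[[col]]) & entries[[col]] == ""] <- NA_character_
  }

  bad_class <- setdiff(unique(entries$probe_class), .probe_classes)
  if (length(bad_class) > 0)
    stop("unknown probe_class: ", paste(bad_class, collapse = ", "))

  bc <- entries$barcode
  if (nrow(entries) > 0) {
    lens <- nchar(bc)
    if (length(unique(lens)) != 1)
      stop("barcodes must share one length; found lengths ",
           paste(sort(unique(lens)), collapse = ", "))
    if (any(grepl("[^ACGT]", bc)))
      stop("barcode with non-ACGT character: ",
           paste(bc[grepl("[^ACGT]", bc)], collapse = ", "))
    dup <- unique(bc[duplicated(bc)])
    if (length(dup) > 0)
      stop("duplicate barcode ", paste(dup, collapse = ", "))
  }

  variants <- entries[entries$probe_class %in% c("edited_variant", "unedited_variant"), ]
  if (any(is.na(variants$site_id)))
    stop("edited/unedited variant entries require a site_id")
  if (nrow(variants) > 0) {
    for (sid in unique(variants$site_id)) {
      cls <- sort(variants$probe_class[variants$site_id == sid])
      if (!identical(cls, c("edited_variant", "unedited_variant")))
        stop("site_id '", sid, "' must have exactly one edited_variant and ",
             "one unedited_variant entry; found ", paste(cls, collapse = "+"))
    }
  }

  rownames(entries) <- NULL
  structure(entries,
            barcode_length = if (nrow(entries) > 0) nchar(bc[1]) else NA_integer_,
            class = c("codebook", "data.frame"))
}

#' Read a codebook from CSV or JSON
#'
#' @param path file path. CSV must have the header
#'   `target_name,barcode,probe_class,site_id,cell_class,transcript_group`;
#'   JSON is a list of objects with the same keys.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return A validated [codebook].
#' @export
read_codebook <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("codebook file not found: ", path)
  entries <- switch(format,
    csv  = utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    json = {
      x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
      as.data.frame(x, stringsAsFactors = FALSE)
    })
  codebook(entries)
}

#' Write a codebook to CSV or JSON
#'
#' `read_codebook(write_codebook(cb, path))` round-trips to an identical
#' codebook in both formats.
#'
#' @param cb a [codebook]
#' @param path output file
#' @param format `"auto"`, `"csv"` or `"json"`
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  df <- as.data.frame(cb)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(df, path, na = "null", auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("codebook: %d entries, barcode length %s\n",
              nrow(x), attr(x, "barcode_length")))
  tab <- table(x$probe_class)
  cat("  ", paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  cat(sprintf("  %d paired editing sites\n", nrow(site_pairs(x))))
  invisible(x)
}

#' Paired edited/unedited barcodes per editing site
#'
#' @param cb a [codebook]
#' @return data frame with columns `site_id`, `edited_barcode`,
#'   `unedited_barcode`, ordered lexicographically by `site_id`.
#' @export
site_pairs <- function(cb) {
  v <- cb[cb$probe_class %in% c("edited_variant", "unedited_variant"), ]
  sids <- sort(unique(v$site_id))
  data.frame(
    site_id = sids,
    edited_barcode = vapply(sids, function(s)
      v$barcode[v$site_id == s & v$probe_class == "edited_variant"], ""),
    unedited_barcode = vapply(sids, function(s)
      v$barcode[v$site_id == s & v$probe_class == "unedited_variant"], ""),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Look up targets for called barcodes
#'
#' Total over all L-mers: any barcode absent from the codebook maps to the
#' [UNMATCHED] sentinel.
#'
#' @param barcodes character vector of called barcodes
#' @param cb a [codebook]
#' @return character vector of `target_name` or `"UNMATCHED"`.
#' @export
match_barcodes <- function(barcodes, cb) {
  idx <- match(barcodes, cb$barcode)
  out <- cb$target_name[idx]
  out[is.na(idx)] <- UNMATCHED
  out
}

#' Generate an example codebook
#'
#' Builds a codebook with the structure of a typical ISS editing panel:
#' `n_sites` paired editing sites, marker probes for a set of cell classes,
#' and one probe per Adar transcript (`Adar1`, `Adar2`, `Adar3`), with
#' distinct random 4-nt barcodes.
#'
#' @param n_sites number of paired editing sites
#' @param markers named character vector mapping marker target names to cell
#'   class names, e.g. `c(Sst = "interneuron")`
#' @param adar character vector of Adar transcript group names
#' @param cycles barcode length / number of sequencing cycles
#' @param seed integer seed for barcode assignment
#' @return A validated [codebook].
#' @export
example_codebook <- function(n_sites = 22,
                             markers = c(Sst = "interneuron",
                                         Pcp4 = "pyramidal",
                                         Plp1 = "oligodendrocyte",
                                         Gfap = "astrocyte"),
                             adar = c("Adar1", "Adar2", "Adar3"),
                             cycles = 4L,
                             seed = 1L) {
  n_needed <- 2L * n_sites + length(markers) + length(adar)
  all_bc <- apply(expand.grid(rep(list(iss_channels()), cycles)), 1, paste0, collapse = "")
  if (n_needed > length(all_bc))
    stop("panel needs ", n_needed, " barcodes but only ", length(all_bc), " exist")
  bc <- with_seed(seed, sample(all_bc, n_needed))
  sites <- if (n_sites > 0) sprintf("site%02d", seq_len(n_sites)) else character(0)
  rows <- list()
  k <- 0L
  for (s in sites) {
    rows[[length(rows) + 1L]] <- data.frame(
      target_name = paste0(s, c("_ed", "_un")),
      barcode = bc[k + 1:2],
      probe_class = c("edited_variant", "unedited_variant"),
      site_id = s, cell_class = NA_character_, transcript_group = NA_character_,
      stringsAsFactors = FALSE)
    k <- k + 2L
  }
  if (length(markers) > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      target_name = names(markers),
      barcode = bc[k + seq_along(markers)],
      probe_class = "marker",
      site_id = NA_character_, cell_class = unname(markers),
      transcript_group = NA_character_, stringsAsFactors = FALSE)
    k <- k + length(markers)
  }
  if (length(adar) > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      target_name = adar,
      barcode = bc[k + seq_along(adar)],
      probe_class = "adar",
      site_id = NA_character_, cell_class = NA_character_,
      transcript_group = adar, stringsAsFactors = FALSE)
  }
  codebook(do.call(rbind, rows))
}

# run expr under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
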