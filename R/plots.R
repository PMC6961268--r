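# Simple base-graphics bubble chart of editing levels per site and stratum.

#' Bubble chart of editing levels
#'
#' One bubble per (site, stratum): the area scales with the read count the
#' level is based on, the fill encodes the editing level (blue = 0,
#' red = 1) — the standard display for ISS editing panels.
#'
#' @param est data frame with `site_id`, a stratum column, `level` (or
#'   `mean_level`) and counts `n_edited`/`n_unedited`
#' @param stratum_col name of the stratum column (default `"region"`)
#' @param max_cex largest bubble size
#' @param ... passed to [graphics::plot()]
#' @return Invisibly, the plotted data frame.
#' @export
plot_editing_bubbles <- function(est, stratum_col = "region", max_cex = 4, ...) {
  lv <- if ("level" %in% names(est)) est$level else est$mean_level
  n <- if (all(c("n_edited", "n_unedited") %in% names(est)))
    est$n_edited + est$n_unedited else rep(1, nrow(est))
  keep <- !is.na(lv)
  est <- est[keep, , drop = FALSE]; lv <- lv[keep]; n <- n[keep]
  sites <- sort(unique(est$site_id))
  strata <- sort(unique(est[[stratum_col]]))
  xi <- match(est[[stratum_col]], strata)
  yi <- match(est$site_id, sites)
  pal <- grDevices::colorRamp(c("#2166ac", "#f7f7f7", "#b2182b"))
  cols <- grDevices::rgb(pal(lv), maxColorValue = 255)
  cex <- max_cex * sqrt(n / max(n))
  graphics::plot(xi, yi, pch = 21, bg = cols, cex = cex,
                 xaxt = "n", yaxt = "n", xlab = stratum_col, ylab = "site",
                 xlim = c(0.5, length(strata) + 0.5),
                 ylim = c(0.5, length(sites) + 0.5), ...)
  graphics::axis(1, at = seq_along(strata), labels = strata, las = 2)
  graphics::axis(2, at = seq_along(sites), labels = sites, las = 1, cex.axis = 0.6)
  invisible(est)
}
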