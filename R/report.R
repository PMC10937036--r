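#' Hybrid linear/ordinal heatmap colour scale
#'
#' To stop rare extreme values from driving a heatmap's colour scale, values
#' inside a central quantile interval (by default between the 1st and 99th
#' percentiles, linearly interpolated order statistics) map linearly onto the
#' colour range, while values outside it map ordinally — by rank within their
#' tail — onto the few colour slots reserved for each tail. The composite
#' mapping is monotone.
#'
#' @param values Numeric values to be plotted (at least two distinct).
#' @param central_fraction Width of the central interval, in (0, 1].
#' @param n_colors Total number of colour slots.
#' @return An `nrx_heatmap_scale` list: `lower_break`, `upper_break`,
#'   `central_fraction`, `n_colors`, and `map(x)` returning colour positions
#'   in `[0, 1]`.
#' @export
heatmap_scale <- function(values, central_fraction = 0.98, n_colors = 256) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2) abort("Constant input: the colour scale is degenerate.")
  if (central_fraction <= 0 || central_fraction > 1) {
    abort("`central_fraction` must lie in (0, 1].")
  }
  tail_q <- (1 - central_fraction) / 2
  lower <- quantile(values, tail_q, names = FALSE, type = 7)
  upper <- quantile(values, 1 - tail_q, names = FALSE, type = 7)

  lows <- sort(unique(values[values < lower]))
  highs <- sort(unique(values[values > upper]))
  # tail slots proportional to tail counts, at least one per non-empty tail
  n_low <- if (length(lows) > 0) max(1, round(n_colors * tail_q)) else 0
  n_high <- if (length(highs) > 0) max(1, round(n_colors * tail_q)) else 0
  n_mid <- n_colors - n_low - n_high
  # slot centres on [0, 1]
  pos <- (seq_len(n_colors) - 0.5) / n_colors
  mid_lo <- pos[n_low + 1]
  mid_hi <- pos[n_low + n_mid]

  map <- function(x) {
    out <- numeric(length(x))
    inside <- x >= lower & x <= upper
    if (upper > lower) {
      out[inside] <- mid_lo + (x[inside] - lower) / (upper - lower) * (mid_hi - mid_lo)
    } else {
      out[inside] <- (mid_lo + mid_hi) / 2
    }
    below <- x < lower
    if (any(below)) {
      r <- findInterval(x[below], lows) # ordinal within-tail position
      out[below] <- pos[pmin(pmax(ceiling(r / length(lows) * n_low), 1), n_low)]
    }
    above <- x > upper
    if (any(above)) {
      r <- findInterval(x[above], highs)
      out[above] <- pos[n_low + n_mid +
                          pmin(pmax(ceiling(r / length(highs) * n_high), 1), n_high)]
    }
    out
  }
  structure(list(lower_break = lower, upper_break = upper,
                 central_fraction = central_fraction, n_colors = n_colors,
                 map = map),
            class = "nrx_heatmap_scale")
}

#' Order heatmap rows by their angle on a two-dimensional projection
#'
#' Rows (genes) are treated as points in condition space, centred, and
#' projected onto their first two principal axes; rows are then ordered by
#' ascending `atan2(PC2, PC1)`. Each axis is oriented so that its loading of
#' largest magnitude is positive, making the ordering deterministic. Similar
#' response profiles end up adjacent, producing the familiar "wheel"
#' ordering of expression heatmaps. A rank-1 matrix falls back to ordering
#' by the single component.
#'
#' @param x Numeric matrix (genes x conditions) or a tibble whose first
#'   column is `gene_id`.
#' @return Integer row ordering with an `angles` attribute; for tibble input
#'   the vector is named by gene id.
#' @export
sort_rows_by_angle <- function(x) {
  ids <- NULL
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    x <- as.matrix(x[, -1, drop = FALSE])
  }
  if (nrow(x) < 3) abort("Need at least three rows to order by angle.")
  ctr <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(ctr)
  orient <- function(u, v) { # positive largest-magnitude loading
    s <- sign(v[which.max(abs(v))])
    if (s == 0) s <- 1
    u * s
  }
  pc1 <- orient(ctr %*% sv$v[, 1], sv$v[, 1])
  if (length(sv$d) < 2 || sv$d[2] < 1e-10 * sv$d[1]) {
    ord <- order(pc1)
    angles <- rep(NA_real_, nrow(x))
  } else {
    pc2 <- orient(ctr %*% sv$v[, 2], sv$v[, 2])
    angles <- atan2(pc2, pc1)
    ord <- order(angles)
  }
  if (!is.null(ids)) names(ord) <- ids[ord]
  attr(ord, "angles") <- angles
  ord
}

#' Volcano-plot data table
#'
#' @param result An `nrx_dge` tibble.
#' @param fdr_threshold Significance threshold on the FDR.
#' @return Tibble: `gene_id`, `log2fc`, `neg_log10_p`, `significant`,
#'   `direction` (`"up"`, `"down"`, or `"neither"` at log2FC = 0).
#' @export
volcano_table <- function(result, fdr_threshold = 0.05) {
  tibble::tibble(
    gene_id = result$gene_id,
    log2fc = result$log2fc,
    neg_log10_p = -log10(result$p_value),
    significant = result$fdr < fdr_threshold,
    direction = dplyr::case_when(
      result$log2fc > 0 ~ "up",
      result$log2fc < 0 ~ "down",
      .default = "neither"
    )
  )
}

#' Radial-plot data: per-condition fold changes for selected genes
#'
#' One row per condition and gene: the log2 fold-change magnitude plus an
#' up/down flag from its sign, for radial displays of the most responsive
#' genes across manipulations. Genes absent from a result are recorded as
#' absent, not as zero change.
#'
#' @param results Named list of `nrx_dge` tibbles (one per condition).
#' @param genes Character vector of gene ids, in display order.
#' @return Tibble: `condition`, `gene_id`, `log2fc`, `magnitude`,
#'   `direction`, `present`.
#' @export
radial_logfc_table <- function(results, genes) {
  nm <- names(results) %||% paste0("condition", seq_along(results))
  purrr::map2_dfr(results, nm, function(res, n) {
    idx <- match(genes, res$gene_id)
    lfc <- res$log2fc[idx]
    tibble::tibble(
      condition = n, gene_id = genes,
      log2fc = lfc,
      magnitude = abs(lfc),
      direction = dplyr::case_when(
        is.na(lfc) ~ NA_character_,
        lfc > 0 ~ "up", lfc < 0 ~ "down", .default = "neither"
      ),
      present = !is.na(idx)
    )
  })
}

#' @exportS3Method base::print
print.nrx_heatmap_scale <- function(x, ...) {
  cat(sprintf("Heatmap scale: linear on [%.4g, %.4g] (central %.0f%%), %d colours\n",
              x$lower_break, x$upper_break, 100 * x$central_fraction, x$n_colors))
  invisible(x)
}
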