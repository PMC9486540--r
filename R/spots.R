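## Scale-normalized Laplacian-of-Gaussian kernel (sign-flipped so bright
## blobs give positive response), zero-mean so flat regions respond 0.
log_kernel <- function(sigma) {
  half <- ceiling(4 * sigma)
  ax <- -half:half
  d2 <- outer(ax^2, ax^2, "+")
  g <- exp(-d2 / (2 * sigma^2))
  lap <- (d2 / sigma^2 - 2) * g
  k <- -sigma^2 * lap / (2 * pi * sigma^2)  # scale-normalized, inverted
  k - mean(k)
}

#' Detect fluorescence spots within segmented cells
#'
#' Laplacian-of-Gaussian blob detection at the configured spot scale.
#' Pixels whose (sign-corrected, scale-normalized) LoG response exceeds
#' `min_response` are grouped into connected components; each component is
#' one candidate spot. The integrated spot fluorescence is the sum of the
#' channel intensity over the component after subtracting a local
#' background, estimated as the median intensity in an annulus surrounding
#' the spot. Spots are assigned to the cell containing their response-
#' weighted centroid; candidates whose centroid falls on background are
#' discarded, as are candidates with non-positive integrated fluorescence.
#'
#' `min_response` defaults to an automatic rule: `6 x MAD` of the response
#' map (robust noise floor), floored at 8 intensity units, which rejects
#' both pixel noise and the shallow edge response of spatially diffuse
#' (unclustered) signal.
#'
#' @param field An `image_field` or numeric matrix (the channel itself).
#' @param cells A `cell_label_map` from [segment_cells()].
#' @param channel Channel role: `"achr"` or `"marker"` (ignored when
#'   `field` is a matrix).
#' @param spot_sigma Expected spot sigma in pixels.
#' @param min_response Detection threshold on the LoG response; `NULL`
#'   for the automatic rule.
#' @param annulus Inner/outer radii (pixels) of the local-background
#'   annulus, as a length-2 vector.
#' @return A `spot_table` tibble: `spot_id`, `cell_id`, `channel`,
#'   `centroid_row`, `centroid_col`, `area`, `intensity` (integrated
#'   background-subtracted fluorescence, > 0).
#' @export
detect_spots <- function(field, cells, channel = c("achr", "marker"),
                         spot_sigma = 1.6, min_response = NULL,
                         annulus = c(4, 7)) {
  channel <- match.arg(channel)
  x <- get_channel(field, channel)
  stopifnot(inherits(cells, "cell_label_map"))
  if (!all(dim(x) == dim(cells$cell_labels))) {
    abort("channel and cell label image shape mismatch")
  }
  empty <- tibble(spot_id = integer(), cell_id = integer(),
                  channel = character(), centroid_row = numeric(),
                  centroid_col = numeric(), area = integer(),
                  intensity = numeric())
  if (max(x) <= 0 || cells$n_cells == 0L) return(empty)

  resp <- EBImage::imageData(EBImage::filter2(EBImage::Image(x),
                                              log_kernel(spot_sigma)))
  if (is.null(min_response)) {
    min_response <- max(6 * stats::mad(resp, center = 0), 8)
  }
  mask <- resp > min_response
  if (!any(mask)) return(empty)
  comp <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  storage.mode(comp) <- "integer"

  idx <- which(comp > 0L)
  ids <- comp[idx]
  rows <- (idx - 1L) %% nrow(comp) + 1L
  colsv <- (idx - 1L) %/% nrow(comp) + 1L
  w <- resp[idx]
  cen_r <- tapply(rows * w, ids, sum) / tapply(w, ids, sum)
  cen_c <- tapply(colsv * w, ids, sum) / tapply(w, ids, sum)
  area <- tabulate(ids, nbins = max(ids))
  uid <- sort(unique(ids))

  lab <- cells$cell_labels
  nr <- nrow(lab); nc <- ncol(lab)
  ri <- pmin(pmax(round(cen_r), 1L), nr)
  ci <- pmin(pmax(round(cen_c), 1L), nc)
  cell_of <- lab[cbind(ri, ci)]

  pix_by_spot <- split(idx, ids)
  intensity <- vapply(seq_along(uid), function(k) {
    id <- uid[k]
    if (cell_of[k] == 0L) return(NA_real_)
    cy <- cen_r[k]; cx <- cen_c[k]
    r0 <- max(1L, floor(cy - annulus[2])); r1 <- min(nr, ceiling(cy + annulus[2]))
    c0 <- max(1L, floor(cx - annulus[2])); c1 <- min(nc, ceiling(cx + annulus[2]))
    yy <- r0:r1; xx <- c0:c1
    d2 <- outer((yy - cy)^2, (xx - cx)^2, "+")
    ring <- d2 > annulus[1]^2 & d2 <= annulus[2]^2
    patch <- x[yy, xx]
    in_spot <- comp[yy, xx] > 0L
    ring <- ring & !in_spot
    bg <- if (any(ring)) median(patch[ring]) else 0
    sum(x[pix_by_spot[[as.character(id)]]] - bg)
  }, numeric(1))

  out <- tibble(
    spot_id = seq_along(uid),
    cell_id = as.integer(cell_of),
    channel = channel,
    centroid_row = as.numeric(cen_r),
    centroid_col = as.numeric(cen_c),
    area = area[uid],
    intensity = intensity
  )
  out <- out[!is.na(out$intensity) & out$intensity > 0 & out$cell_id > 0L, ]
  out$spot_id <- seq_len(nrow(out))
  out
}

#' Per-cell summed spot fluorescence
#'
#' Sums the integrated spot fluorescence over each cell's spots; cells
#' with no spots get 0. The total over all cells equals the total of the
#' spot table (spots partition exactly one cell each).
#'
#' @param spots A spot table from [detect_spots()].
#' @param cells A `cell_label_map` (supplies the full cell roster, so
#'   spotless cells appear with sum 0).
#' @return Tibble with `cell_id` and `spot_sum`.
#' @export
per_cell_spot_sum <- function(spots, cells) {
  stopifnot(inherits(cells, "cell_label_map"))
  ids <- sort(setdiff(unique(as.vector(cells$cell_labels)), 0L))
  sums <- setNames(numeric(length(ids)), ids)
  if (nrow(spots)) {
    agg <- tapply(spots$intensity, spots$cell_id, sum)
    sums[names(agg)] <- agg
  }
  tibble(cell_id = as.integer(ids), spot_sum = unname(sums))
}

#' Call positive cells by thresholding summed spot fluorescence
#'
#' A cell is positive when its summed spot fluorescence strictly exceeds
#' the threshold. The threshold is either a fixed configured value or the
#' automatic rule: an Otsu two-class split on `log1p(spot_sum)` computed
#' over `reference` (typically the plate's negative-control wells),
#' mapped back to the intensity scale.
#'
#' @param spot_sums Numeric vector of per-cell summed spot fluorescence.
#' @param threshold Numeric threshold, or `"otsu"` for the automatic rule.
#' @param reference Values the automatic threshold is computed from;
#'   defaults to `spot_sums` itself.
#' @return Logical vector, one entry per cell.
#' @export
#' @examples
#' call_positive(c(0, 10, 100), threshold = 50)
call_positive <- function(spot_sums, threshold = "otsu",
                          reference = spot_sums) {
  if (identical(threshold, "otsu")) {
    threshold <- otsu_log1p_threshold(reference)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold)) {
    abort("threshold must be a finite number or \"otsu\"")
  }
  spot_sums > threshold
}

## One-dimensional Otsu split of log1p-transformed sums, returned on the
## original intensity scale. Degenerate (constant) input yields the
## constant itself, so no cell exceeds it.
otsu_log1p_threshold <- function(values, n_bins = 256L) {
  v <- log1p(values[is.finite(values)])
  if (!length(v) || diff(range(v)) < 1e-12) return(expm1(max(v, 0)))
  breaks <- seq(min(v), max(v), length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                nbins = n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  expm1(mids[which.max(between)])
}

#' Percent positive cells
#'
#' Number of positive cells divided by the total number of cells, times
#' 100. Zero cells is undefined and reported as `NA` with a warning.
#'
#' @param calls Logical vector of per-cell positivity.
#' @return Percentage in \[0, 100\], or `NA` for an empty input.
#' @export
percent_positive <- function(calls) {
  if (length(calls) == 0L) {
    warn("no cells: percent positive undefined")
    return(NA_real_)
  }
  100 * sum(calls) / length(calls)
}

#' Percent MAC-positive cells within the AChR-positive population
#'
#' AChR/MAC double-positive cells divided by the total AChR-positive
#' cells, times 100. With zero AChR-positive cells the value is undefined
#' and reported as `NA` with a warning.
#'
#' @param records Data frame with logical columns `achr_pos` and
#'   `mac_pos` (one row per cell).
#' @return Percentage in \[0, 100\], or `NA`.
#' @export
mac_within_achr_pos <- function(records) {
  stopifnot(all(c("achr_pos", "mac_pos") %in% names(records)))
  n_achr <- sum(records$achr_pos)
  if (n_achr == 0L) {
    warn("no AChR-positive cells: MAC readout undefined")
    return(NA_real_)
  }
  100 * sum(records$achr_pos & records$mac_pos) / n_achr
}
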