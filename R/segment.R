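#' Detect nuclei in the nuclear (DAPI) channel
#'
#' Standard high-content-screening recipe: Gaussian smoothing, Otsu
#' thresholding, distance-transform watershed to split touching nuclei,
#' and a minimum-area filter. Labels are renumbered 1..K; 0 is background.
#'
#' @param field An `image_field` (see [generate_field()]) or a plain
#'   numeric matrix taken as the nuclear channel.
#' @param sigma Smoothing sigma in pixels.
#' @param min_area Minimum nucleus area in px^2; smaller regions dropped.
#' @param split Split touching nuclei by watershed? Default `TRUE`.
#' @return Integer label matrix (an all-zero channel yields zero labels,
#'   not an error).
#' @export
detect_nuclei <- function(field, sigma = 2, min_area = 30, split = TRUE) {
  x <- get_channel(field, "nuclear")
  mx <- max(x)
  if (mx <= 0) return(matrix(0L, nrow(x), ncol(x)))
  img <- EBImage::Image(x / mx)
  sm <- EBImage::gblur(img, sigma = sigma)
  thr <- EBImage::otsu(sm, range = c(0, 1))
  mask <- sm > thr
  labels <- if (split) {
    EBImage::watershed(EBImage::distmap(mask), tolerance = 1, ext = 1)
  } else {
    EBImage::bwlabel(mask)
  }
  lab <- EBImage::imageData(labels)
  storage.mode(lab) <- "integer"
  drop_small_and_renumber(lab, min_area)
}

drop_small_and_renumber <- function(lab, min_area) {
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab, nbins = max(lab))
  keep <- which(sizes >= min_area)
  map <- integer(max(lab))
  map[keep] <- seq_along(keep)
  out <- lab
  nz <- lab > 0L
  out[nz] <- map[lab[nz]]
  out
}

#' Segment cells around detected nuclei
#'
#' Draws the cell perimeter by seeded region growing (Voronoi-style
#' propagation) on the smoothed actin channel, constrained to a
#' foreground mask (Otsu on the smoothed actin, united with the dilated
#' nuclei so every nucleus owns a region). Exactly one cell region per
#' nucleus; background pixels stay unlabeled.
#'
#' @param field An `image_field` or a numeric matrix taken as the actin
#'   channel.
#' @param nuclei Integer nucleus label matrix from [detect_nuclei()].
#' @param sigma Actin smoothing sigma in pixels.
#' @param lambda Propagation regularization (EBImage `propagate`);
#'   balances intensity gradients against geometric distance.
#' @param exclude_border Drop cells touching the field border?
#'   Default `FALSE` (kept).
#' @return A `cell_label_map`: list with `nuclei_labels`, `cell_labels`
#'   (integer matrices sharing the nucleus numbering) and `n_cells`.
#' @export
segment_cells <- function(field, nuclei, sigma = 2, lambda = 1e-4,
                          exclude_border = FALSE) {
  x <- get_channel(field, "actin")
  if (!all(dim(x) == dim(nuclei))) {
    abort("nuclei label image and field shape mismatch")
  }
  n_seed <- max(nuclei)
  if (n_seed == 0L) {
    z <- matrix(0L, nrow(x), ncol(x))
    return(structure(list(nuclei_labels = nuclei, cell_labels = z,
                          n_cells = 0L), class = "cell_label_map"))
  }
  mx <- max(x)
  img <- EBImage::Image(x / max(mx, 1e-12))
  sm <- EBImage::gblur(img, sigma = sigma)
  thr <- EBImage::otsu(sm, range = c(0, 1))
  fg <- sm > thr
  seeds <- EBImage::Image(nuclei)
  fg <- fg | EBImage::dilate(seeds > 0, EBImage::makeBrush(7, "disc"))
  cells <- EBImage::propagate(sm, seeds = seeds, mask = fg, lambda = lambda)
  lab <- EBImage::imageData(cells)
  storage.mode(lab) <- "integer"
  if (exclude_border) {
    border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                              lab[, ncol(lab)]))
    border_labels <- setdiff(border_labels, 0L)
    if (length(border_labels)) {
      lab[lab %in% border_labels] <- 0L
      nuclei[nuclei %in% border_labels] <- 0L
      ## renumber both maps consistently
      keep <- sort(setdiff(unique(as.vector(lab)), 0L))
      map <- integer(max(keep, 0L))
      map[keep] <- seq_along(keep)
      lab[lab > 0L] <- map[lab[lab > 0L]]
      nuclei[nuclei > 0L] <- map[nuclei[nuclei > 0L]]
    }
  }
  structure(
    list(nuclei_labels = nuclei, cell_labels = lab,
         n_cells = length(setdiff(unique(as.vector(lab)), 0L))),
    class = "cell_label_map"
  )
}

#' @export
print.cell_label_map <- function(x, ...) {
  cat(sprintf("<cell_label_map> %d cells, %dx%d px\n", x$n_cells,
              nrow(x$cell_labels), ncol(x$cell_labels)))
  invisible(x)
}

#' Per-cell geometry table
#'
#' @param cells A `cell_label_map` from [segment_cells()].
#' @return Tibble with `cell_id`, nucleus centroid (`nucleus_row`,
#'   `nucleus_col`) and cell `area` in px^2.
#' @export
cell_table <- function(cells) {
  stopifnot(inherits(cells, "cell_label_map"))
  lab <- cells$nuclei_labels
  if (cells$n_cells == 0L) {
    return(tibble(cell_id = integer(), nucleus_row = numeric(),
                  nucleus_col = numeric(), area = integer()))
  }
  idx <- which(lab > 0L)
  ids <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  colsv <- (idx - 1L) %/% nrow(lab) + 1L
  area_cell <- tabulate(cells$cell_labels[cells$cell_labels > 0L],
                        nbins = max(cells$cell_labels))
  tibble(
    cell_id = sort(unique(ids)),
    nucleus_row = as.numeric(tapply(rows, ids, mean)),
    nucleus_col = as.numeric(tapply(colsv, ids, mean)),
    area = area_cell[sort(unique(ids))]
  )
}

get_channel <- function(field, role) {
  if (is.matrix(field)) return(field)
  if (inherits(field, "image_field")) {
    ch <- field$channels[[role]]
    if (is.null(ch)) abort(paste0("field has no ", role, " channel"))
    return(ch)
  }
  abort("field must be an image_field or a numeric matrix")
}
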