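# Segmentation of two-channel live-cell images (Hoechst nuclear + calcein AM
# viability) into viable cells, dead cells and neurites, and the nine
# per-well injury metrics.

as_img_matrix <- function(img) {
  if (inherits(img, "Image")) img <- EBImage::imageData(img)
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a 2D grayscale image")
  img
}

#' Preprocess a live-cell fluorescence image
#'
#' A 3 x 3 median filter removes shot noise, then uneven background
#' illumination is corrected: the background surface is estimated by a
#' large-scale morphological opening (structuring disk wider than any cell
#' body) and its non-uniform part is subtracted, so a flat background is left
#' unchanged and a tilted one is levelled.
#'
#' @param img 2D grayscale matrix (or EBImage Image), values in [0, 1].
#' @param correct_illumination logical.
#' @param opening_radius radius (px) of the background-estimation disk; must
#'   exceed the radius of the largest foreground object.
#' @return matrix in [0, 1].
#' @export
preprocess_live <- function(img, correct_illumination = TRUE,
                            opening_radius = 15) {
  img <- as_img_matrix(img)
  med <- ebi_mat(EBImage::medianFilter(EBImage::Image(clip01(img)),
                                         size = 1))
  if (correct_illumination) {
    # replicate-pad before the opening so the background estimate is not
    # biased at the image border
    r <- opening_radius
    px <- c(rep(1, r), seq_len(nrow(med)), rep(nrow(med), r))
    py <- c(rep(1, r), seq_len(ncol(med)), rep(ncol(med), r))
    padded <- med[px, py]
    brush <- EBImage::makeBrush(2 * opening_radius + 1, shape = "disc")
    bg <- ebi_mat(EBImage::opening(EBImage::Image(padded), brush))
    bg <- bg[r + seq_len(nrow(med)), r + seq_len(ncol(med))]
    med <- med - (bg - min(bg))
  }
  clip01(med)
}

#' Segment nuclei from the nuclear channel
#'
#' Global threshold (background method: twice the histogram mode), hole
#' filling, optional watershed declumping on the distance map, and removal of
#' objects below a minimum area.
#'
#' @param img preprocessed nuclear channel.
#' @param min_area_um2 minimum nucleus area (default 20 um^2).
#' @param pixel_size microns per pixel.
#' @param threshold optional fixed threshold; default Otsu's method, which
#'   tracks the half-maximum contour of blurred objects and so recovers
#'   object geometry more faithfully than a background-level cut.
#' @param declump watershed-declump touching nuclei (default TRUE).
#' @return integer label matrix (0 = background).
#' @export
segment_nuclei <- function(img, min_area_um2 = 20, pixel_size = 0.33,
                           threshold = NULL, declump = TRUE) {
  img <- as_img_matrix(img)
  if (diff(range(img)) == 0) return(matrix(0L, nrow(img), ncol(img)))
  if (is.null(threshold))
    threshold <- EBImage::otsu(EBImage::Image(clip01(img)))
  mask <- img > threshold
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  mask_img <- EBImage::fillHull(EBImage::Image(mask * 1))
  labels <- if (declump) {
    EBImage::watershed(EBImage::distmap(mask_img), tolerance = 1, ext = 1)
  } else EBImage::bwlabel(mask_img)
  labels <- ebi_mat(labels)
  min_px <- min_area_um2 / pixel_size^2
  tab <- tabulate(labels[labels > 0])
  keep <- which(tab >= min_px)
  labels[!(labels %in% keep)] <- 0L
  matrix(match(labels, c(0L, keep)) - 1L, nrow(labels), ncol(labels))
}

#' Segment viable cell bodies, dead nuclei and rejected candidates
#'
#' Candidate cell bodies are extracted from the viability channel by global
#' thresholding (Otsu by default) followed by a morphological opening that
#' strips neurites.
#' A candidate is accepted as a viable cell iff it overlaps at least one
#' nucleus and its area reaches the minimum soma area; candidates failing
#' either rule are recorded as rejected (beads on neurites lack nuclei and
#' are small). Nuclei with essentially no calcein signal over them are dead
#' cells (this also rejects extracellular nuclei as cell bodies).
#'
#' @param viability preprocessed viability (calcein) channel.
#' @param nuclei nucleus label matrix from \code{\link{segment_nuclei}}.
#' @param min_soma_area_um2 minimum soma area (default 60 um^2).
#' @param pixel_size microns per pixel.
#' @param candidate_opening_radius disk radius (px) of the neurite-stripping
#'   opening; must exceed the neurite half-width and stay below the soma
#'   radius.
#' @param overlap_frac a nucleus is live when at least this fraction of its
#'   pixels carries viability signal.
#' @param soma_threshold threshold for the bright cell-body mask from which
#'   candidates are derived (default Otsu).
#' @param mask_threshold lower threshold for the full cell mask so that dim,
#'   thin (injured) neurites are retained (default half the soma threshold).
#' @return list: \code{somata} (label matrix of viable cell bodies),
#'   \code{cell_mask} (binary viability mask), \code{n_viable},
#'   \code{n_dead}, \code{dead_nuclei} (nucleus label ids), \code{rejected}
#'   (data.frame id, area_px, reason).
#' @export
segment_cells <- function(viability, nuclei, min_soma_area_um2 = 60,
                          pixel_size = 0.33, candidate_opening_radius = 3,
                          overlap_frac = 0.1, soma_threshold = NULL,
                          mask_threshold = NULL) {
  viability <- as_img_matrix(viability)
  if (!all(dim(viability) == dim(nuclei))) stop("channel shape mismatch")
  if (is.null(soma_threshold))
    soma_threshold <- EBImage::otsu(EBImage::Image(clip01(viability)))
  if (is.null(mask_threshold)) mask_threshold <- soma_threshold / 2
  vmask <- viability > mask_threshold
  hi_mask <- viability > soma_threshold
  brush <- EBImage::makeBrush(2 * candidate_opening_radius + 1, shape = "disc")
  cand <- EBImage::bwlabel(EBImage::opening(EBImage::Image(hi_mask * 1), brush))
  cand <- ebi_mat(cand)
  min_px <- min_soma_area_um2 / pixel_size^2
  ids <- setdiff(unique(as.vector(cand)), 0L)
  keep <- integer(0)
  rejected <- list()
  for (id in ids) {
    sel <- cand == id
    area <- sum(sel)
    has_nuc <- any(nuclei[sel] > 0)
    if (has_nuc && area >= min_px) keep <- c(keep, id)
    else rejected[[length(rejected) + 1]] <- data.frame(
      id = id, area_px = area,
      reason = if (!has_nuc) "no_nucleus" else "too_small",
      stringsAsFactors = FALSE)
  }
  somata <- matrix(match(cand, c(0L, keep)) - 1L, nrow(cand), ncol(cand))
  somata[is.na(somata)] <- 0L
  nuc_ids <- setdiff(unique(as.vector(nuclei)), 0L)
  dead <- integer(0)
  for (id in nuc_ids) {
    sel <- nuclei == id
    if (mean(vmask[sel]) < overlap_frac) dead <- c(dead, id)
  }
  list(somata = somata, cell_mask = vmask,
       n_viable = length(keep), n_dead = length(dead),
       dead_nuclei = dead,
       rejected = if (length(rejected)) do.call(rbind, rejected) else
         data.frame(id = integer(0), area_px = integer(0),
                    reason = character(0), stringsAsFactors = FALSE))
}

#' Trace neurites as a skeleton graph and measure their length
#'
#' The viability mask minus the (slightly dilated) cell bodies is
#' skeletonized (Golay-mask thinning). Component arc length is the orthogonal-first
#' spanning tree over 8-adjacency (orthogonal steps 1 px, diagonal sqrt(2)),
#' with free endpoints compensated by the local half-width (distance-map
#' value) lost to end-cap thinning. Short terminal spurs are pruned before
#' counting; junctions and endpoints are identified by the crossing number.
#' Each skeleton component is attached to the soma it contacts; unattached
#' fragments still contribute to totals but are flagged.
#'
#' @param cell_mask binary viability mask (from \code{\link{segment_cells}}).
#' @param somata viable soma label matrix.
#' @param pixel_size microns per pixel (required for lengths).
#' @param min_fragment_px discard mask fragments smaller than this (noise).
#' @param prune_len maximum spur length (px) removed before counting.
#' @param soma_margin_px extra soma dilation subtracted from the neurite
#'   mask (eats the halo the soma's point-spread leaves around the
#'   segmented cell body).
#' @param band_px width of the proximity band used for soma attachment and
#'   process counting.
#' @return list: \code{skeleton} (0/1 matrix), \code{total_length_um},
#'   \code{n_processes}, \code{n_branches}, \code{components} (data.frame
#'   id, length_um, soma, attached), \code{n_unattached}.
#' @export
trace_neurites <- function(cell_mask, somata, pixel_size = 0.33,
                           min_fragment_px = 10, prune_len = 4,
                           soma_margin_px = 2, band_px = 5) {
  if (is.null(pixel_size) || !is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size metadata is required")
  soma_bin <- somata > 0
  soma_grown <- if (any(soma_bin) && soma_margin_px > 0)
    ebi_mat(EBImage::dilate(EBImage::Image(soma_bin * 1),
      EBImage::makeBrush(2 * soma_margin_px + 1, shape = "disc"))) > 0
    else soma_bin
  nmask <- cell_mask & !soma_grown
  empty <- list(skeleton = matrix(0L, nrow(somata), ncol(somata)),
                total_length_um = 0, n_processes = 0L, n_branches = 0L,
                components = data.frame(id = integer(0), length_um = numeric(0),
                                        soma = integer(0), attached = logical(0)),
                n_unattached = 0L)
  if (!any(nmask)) return(empty)
  frag <- ebi_mat(EBImage::bwlabel(EBImage::Image(nmask * 1)))
  tab <- tabulate(frag[frag > 0])
  nmask <- matrix(frag > 0 & tab[pmax(frag, 1)] >= min_fragment_px,
                  nrow(frag), ncol(frag))
  if (!any(nmask)) return(empty)
  skel <- skeletonize(nmask)
  if (!any(skel == 1L)) return(empty)
  dm <- ebi_mat(EBImage::distmap(EBImage::Image(nmask * 1)))

  # proximity map of soma labels (grayscale dilation of the label image)
  soma_dil <- ebi_mat(EBImage::dilate(EBImage::Image(somata),
    EBImage::makeBrush(2 * (soma_margin_px + band_px) + 1, shape = "disc")))

  # spur pruning removes both thinning end-artifacts and the short side
  # spurs that swellings (beads) induce; lengths and counts both use the
  # pruned skeleton
  pruned <- prune_spurs(skel, prune_len)
  if (!any(pruned == 1L)) pruned <- skel
  gp <- skeleton_graph(pruned)

  # 8-connected skeleton components via dilation labeling
  comp_lab <- ebi_mat(EBImage::bwlabel(EBImage::dilate(
    EBImage::Image(pruned), EBImage::makeBrush(3, shape = "box"))))
  comp_lab[pruned == 0L] <- 0L

  endpoints <- gp$cn <= 1L
  near_soma <- soma_dil[gp$idx] > 0

  comp_ids <- setdiff(unique(as.vector(comp_lab)), 0L)
  comp_of_pixel <- comp_lab[gp$idx]
  rows <- lapply(comp_ids, function(cid) {
    sel <- which(comp_of_pixel == cid)
    # end-cap compensation: the local half-width, capped at the component's
    # median half-width so a terminal swelling cannot inflate the length
    halfw <- stats::median(dm[gp$idx[sel]])
    free_ends <- gp$idx[sel[endpoints[sel] & !near_soma[sel]]]
    len <- component_length_px(gp, sel) +
      sum(pmin(dm[free_ends], halfw)) +
      soma_margin_px * sum(endpoints[sel] & near_soma[sel])
    touching <- soma_dil[gp$idx[sel]]
    touching <- touching[touching > 0]
    soma_id <- if (length(touching))
      as.integer(names(sort(table(touching), decreasing = TRUE))[1]) else NA_integer_
    data.frame(id = cid, length_um = len * pixel_size,
               soma = soma_id, attached = length(touching) > 0)
  })
  components <- do.call(rbind, rows)

  soma_near_p <- near_soma
  # processes: clusters of skeleton pixels inside the soma proximity band
  entry <- matrix(0L, nrow(skel), ncol(skel))
  entry[gp$idx[soma_near_p]] <- 1L
  n_processes <- if (any(entry == 1L))
    max(ebi_mat(EBImage::bwlabel(EBImage::dilate(
      EBImage::Image(entry), EBImage::makeBrush(3, shape = "box"))))) else 0L
  # branches: clusters of junction pixels outside the proximity band
  junc <- matrix(0L, nrow(skel), ncol(skel))
  junc[gp$idx[gp$cn >= 3L & !soma_near_p]] <- 1L
  n_branches <- if (any(junc == 1L))
    max(ebi_mat(EBImage::bwlabel(EBImage::dilate(
      EBImage::Image(junc), EBImage::makeBrush(3, shape = "box"))))) else 0L

  list(skeleton = skel, total_length_um = sum(components$length_um),
       n_processes = as.integer(n_processes), n_branches = as.integer(n_branches),
       components = components,
       n_unattached = sum(!components$attached))
}

#' Nine per-well injury metrics from a segmentation
#'
#' @param segmentation result of \code{\link{segment_cells}}.
#' @param neurites result of \code{\link{trace_neurites}}.
#' @param reference_count reference cell count for the viability percentage
#'   (e.g. the seeded, thawed-viable count); NULL or non-positive reports
#'   viability as NA.
#' @return one-row data.frame with the nine metrics: viable_cells_per_image,
#'   dead_cells_per_image, neurite_length_per_cell, processes_per_cell,
#'   branches_per_cell, total_neurite_length, total_processes,
#'   total_branches, cell_viability.
#' @export
well_injury_metrics <- function(segmentation, neurites, reference_count = NULL) {
  v <- segmentation$n_viable
  per_cell <- function(total) if (v > 0) total / v else 0
  viability <- if (is.null(reference_count) || !is.finite(reference_count) ||
                   reference_count <= 0) NA_real_ else 100 * v / reference_count
  data.frame(
    viable_cells_per_image = v,
    dead_cells_per_image = segmentation$n_dead,
    neurite_length_per_cell = per_cell(neurites$total_length_um),
    processes_per_cell = per_cell(neurites$n_processes),
    branches_per_cell = per_cell(neurites$n_branches),
    total_neurite_length = neurites$total_length_um,
    total_processes = neurites$n_processes,
    total_branches = neurites$n_branches,
    cell_viability = viability)
}

#' Full live-cell analysis of one nuclear/viability image pair
#'
#' Convenience wrapper: preprocess both channels, segment nuclei and cells,
#' trace neurites, and compute the nine injury metrics.
#'
#' @param nuclear,viability raw grayscale channels in [0, 1].
#' @param pixel_size microns per pixel.
#' @param reference_count see \code{\link{well_injury_metrics}}.
#' @param ... passed through to \code{\link{segment_cells}}.
#' @return list with \code{segmentation}, \code{neurites} and \code{metrics}.
#' @export
analyze_live_image <- function(nuclear, viability, pixel_size = 0.33,
                               reference_count = NULL, ...) {
  nuc_p <- preprocess_live(nuclear)
  via_p <- preprocess_live(viability)
  nuclei <- segment_nuclei(nuc_p, pixel_size = pixel_size)
  seg <- segment_cells(via_p, nuclei, pixel_size = pixel_size, ...)
  neur <- trace_neurites(seg$cell_mask, seg$somata, pixel_size = pixel_size)
  list(segmentation = seg, neurites = neur,
       metrics = well_injury_metrics(seg, neur, reference_count))
}
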