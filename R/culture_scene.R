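# Parametric culture scenes and their rendering into fluorescence channels.
# A scene fixes all random structure (positions, neurite geometry, bead
# slots, puncta, per-cell death order); the injury level then deterministically
# shortens and thins neurites, activates bead slots and kills cells, so
# ground truth is monotone in injury for a fixed scene.

#' Generate a parametric neuronal culture scene
#'
#' Somata with concentric nuclei are placed on a jittered grid whose pitch
#' guarantees that neurites of neighbouring cells cannot touch. Each soma
#' grows 1-3 straight neurites at well-separated angles; a neurite may carry
#' one side branch and a set of latent bead slots that become visible beads
#' under injury. Synaptophysin puncta are laid down inside somata and along
#' neurites. Optional extracellular nuclei (nuclei with no cell body) can be
#' injected to exercise the rejection rules of the segmentation.
#'
#' @param n_cells number of somata (must fit the placement grid).
#' @param width,height image size in pixels.
#' @param pixel_size microns per pixel (default 1.0 for these scenes).
#' @param soma_radius range of soma radii (px).
#' @param neurites_per_cell integer range of neurites per soma.
#' @param neurite_length range of neurite lengths beyond the soma boundary (px).
#' @param neurite_thickness uninjured neurite thickness (px).
#' @param branch_prob probability a neurite carries one side branch.
#' @param bead_radius range of bead radii (px).
#' @param beads_per_100px expected latent bead slots per 100 px of neurite.
#' @param n_extra_nuclei number of extracellular (calcein-negative) nuclei.
#' @param noise_sd additive Gaussian noise sd of the rendered channels.
#' @param background background intensity level.
#' @param background_gradient peak-to-peak amplitude of a left-to-right
#'   linear illumination gradient added to every channel (0 = flat).
#' @param seed integer seed.
#' @return list of class \code{culture_scene}.
#' @export
culture_scene <- function(n_cells = 9, width = 480, height = 480,
                          pixel_size = 1.0, soma_radius = c(7, 9),
                          neurites_per_cell = c(1, 3),
                          neurite_length = c(30, 50),
                          neurite_thickness = 2, branch_prob = 0.5,
                          bead_radius = c(2.5, 3.5), beads_per_100px = 4,
                          n_extra_nuclei = 0, noise_sd = 0.02,
                          background = 0.05, background_gradient = 0,
                          seed = 1L) {
  set.seed(as.integer(seed))
  reach <- max(soma_radius) + max(neurite_length) + 2 * neurite_thickness
  pitch <- 2 * reach + 12
  cx <- seq(reach + 6, width - reach - 6, by = pitch)
  cy <- seq(reach + 6, height - reach - 6, by = pitch)
  if (n_cells > length(cx) * length(cy))
    stop("n_cells exceeds grid capacity (", length(cx) * length(cy),
         ") for this image size")
  grid <- expand.grid(x = cx, y = cy)
  grid <- grid[sample(nrow(grid), n_cells), , drop = FALSE]
  somata <- if (n_cells > 0) data.frame(
    id = seq_len(n_cells),
    x = grid$x + stats::runif(n_cells, -5, 5),
    y = grid$y + stats::runif(n_cells, -5, 5),
    r = stats::runif(n_cells, soma_radius[1], soma_radius[2]),
    death_u = stats::runif(n_cells)
  ) else data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    r = numeric(0), death_u = numeric(0))
  somata$nucleus_r <- 0.55 * somata$r
  somata$has_nucleus <- rep(TRUE, n_cells)

  neurites <- list()
  puncta_soma <- list()
  puncta_neurite <- list()
  for (i in seq_len(n_cells)) {
    nn <- sample(seq(neurites_per_cell[1], neurites_per_cell[2]), 1)
    rot <- stats::runif(1, 0, 2 * pi)
    for (j in seq_len(nn)) {
      ang <- rot + (j - 1) * 2 * pi / nn + stats::runif(1, -0.25, 0.25)
      len <- stats::runif(1, neurite_length[1], neurite_length[2])
      has_branch <- stats::runif(1) < branch_prob
      n_slots <- stats::rpois(1, len * beads_per_100px / 100)
      bead_fracs <- sort(stats::runif(n_slots, 0.2, 0.85))
      nrec <- list(
        soma = i, angle = ang, length = len,
        thickness = neurite_thickness,
        branch = has_branch,
        branch_frac = stats::runif(1, 0.4, 0.7),
        branch_angle = sample(c(-1, 1), 1) * stats::runif(1, 0.5, 0.9),
        branch_len = stats::runif(1, 0.3, 0.5) * len,
        bead_fracs = bead_fracs,
        bead_r = stats::runif(length(bead_fracs), bead_radius[1], bead_radius[2]))
      neurites[[length(neurites) + 1]] <- nrec
      np <- max(1, round(len / 10))
      puncta_neurite[[length(puncta_neurite) + 1]] <- data.frame(
        neurite = length(neurites),
        frac = stats::runif(np, 0.05, 0.95),
        r = stats::runif(np, 1.5, 2))
    }
    ns <- sample(5:9, 1)
    rr <- somata$r[i] * sqrt(stats::runif(ns)) * 0.75
    aa <- stats::runif(ns, 0, 2 * pi)
    puncta_soma[[i]] <- data.frame(
      soma = i, x = somata$x[i] + rr * cos(aa), y = somata$y[i] + rr * sin(aa),
      r = stats::runif(ns, 1.5, 2))
  }
  extra <- if (n_extra_nuclei > 0) {
    mid <- expand.grid(x = cx + pitch / 2, y = cy + pitch / 2)
    mid <- mid[mid$x < width - 12 & mid$y < height - 12, , drop = FALSE]
    if (nrow(mid) < n_extra_nuclei) stop("too many extracellular nuclei for grid")
    mid <- mid[sample(nrow(mid), n_extra_nuclei), , drop = FALSE]
    data.frame(x = mid$x + stats::runif(n_extra_nuclei, -4, 4),
               y = mid$y + stats::runif(n_extra_nuclei, -4, 4),
               r = stats::runif(n_extra_nuclei, 4, 5))
  } else data.frame(x = numeric(0), y = numeric(0), r = numeric(0))

  structure(list(
    width = width, height = height, pixel_size = pixel_size,
    somata = somata, neurites = neurites,
    puncta_soma = if (length(puncta_soma)) do.call(rbind, puncta_soma) else
      data.frame(soma = integer(0), x = numeric(0), y = numeric(0), r = numeric(0)),
    puncta_neurite = if (length(puncta_neurite)) do.call(rbind, puncta_neurite) else
      data.frame(neurite = integer(0), frac = numeric(0), r = numeric(0)),
    extra_nuclei = extra,
    noise_sd = noise_sd, background = background,
    background_gradient = background_gradient, seed = as.integer(seed)),
    class = "culture_scene")
}

# --- rendering primitives (matrices indexed [x, y]) ------------------------

draw_disk <- function(img, cx, cy, r, val) {
  xs <- max(1, floor(cx - r)):min(nrow(img), ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(ncol(img), ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(img)
  d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
  sub <- img[xs, ys, drop = FALSE]
  sub[d2 <= r^2] <- pmax(sub[d2 <= r^2], val)
  img[xs, ys] <- sub
  img
}

draw_segment <- function(img, x0, y0, x1, y1, thickness, val) {
  hw <- thickness / 2
  xs <- max(1, floor(min(x0, x1) - hw)):min(nrow(img), ceiling(max(x0, x1) + hw))
  ys <- max(1, floor(min(y0, y1) - hw)):min(ncol(img), ceiling(max(y0, y1) + hw))
  if (!length(xs) || !length(ys)) return(img)
  px <- matrix(xs, length(xs), length(ys))
  py <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  dx <- x1 - x0; dy <- y1 - y0
  L2 <- dx^2 + dy^2
  t <- if (L2 == 0) matrix(0, length(xs), length(ys)) else
    pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / L2))
  d2 <- (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
  sub <- img[xs, ys, drop = FALSE]
  sel <- d2 <= hw^2
  sub[sel] <- pmax(sub[sel], val)
  img[xs, ys] <- sub
  img
}

# truncated geometry of one neurite at a given injury level
neurite_geometry <- function(nrec, soma, length_factor, thickness_factor) {
  dirv <- c(cos(nrec$angle), sin(nrec$angle))
  lf <- nrec$length * length_factor
  start <- c(soma$x, soma$y)
  tip <- start + (soma$r + lf) * dirv
  th <- max(1.4, nrec$thickness * thickness_factor)
  segs <- list(rbind(c(start, 0), c(tip, soma$r + lf)))  # x, y, dist-from-center
  branch_included <- FALSE
  bsegs <- NULL
  if (nrec$branch && nrec$branch_frac * nrec$length < lf) {
    bp <- start + (soma$r + nrec$branch_frac * nrec$length) * dirv
    bang <- nrec$angle + nrec$branch_angle
    bl <- nrec$branch_len * length_factor
    bend <- bp + bl * c(cos(bang), sin(bang))
    bsegs <- rbind(c(bp, 0), c(bend, bl))
    branch_included <- TRUE
    blen <- bl
  } else blen <- 0
  list(start = start, tip = tip, thickness = th,
       main_len = lf, branch_included = branch_included,
       branch_len = blen, branch_seg = bsegs, dir = dirv,
       total_len = lf + blen)
}

#' Render fluorescence channels from a culture scene at a given injury level
#'
#' Produces four grayscale channels in [0, 1] -- nuclear (Hoechst), viability
#' (calcein AM), MAP2 and synaptophysin -- together with the scene's ground
#' truth at this injury level. Increasing injury shortens and thins neurites,
#' activates bead slots, and converts cells to calcein-negative (nucleus
#' present, no viability signal) in a fixed per-scene death order. Channels
#' are blurred with a Gaussian point-spread (sigma 1 px), then receive the
#' scene's background, optional illumination gradient and additive Gaussian
#' noise.
#'
#' @param scene a \code{\link{culture_scene}}.
#' @param injury_level dimensionless injury severity in [0, 1].
#' @return list with \code{channels} (named list of matrices: nuclear,
#'   viability, map2, synaptophysin) and \code{truth} (viable/dead counts,
#'   total neurite length in microns, process and branch counts, binary
#'   compartment masks, puncta counts per compartment, per-cell records).
#' @export
gen_culture_image <- function(scene, injury_level = 0) {
  stopifnot(inherits(scene, "culture_scene"),
            injury_level >= 0, injury_level <= 1)
  W <- scene$width; H <- scene$height
  blank <- function() matrix(0, W, H)
  nuclear <- blank(); viability <- blank(); map2 <- blank(); syn <- blank()
  soma_mask <- blank(); neurite_mask <- blank(); cell_mask <- blank()

  length_factor <- 1 - 0.6 * injury_level
  thickness_factor <- 1 - 0.5 * injury_level
  dead_fraction <- 0.6 * injury_level
  so <- scene$somata
  viable <- so$death_u >= dead_fraction
  if (injury_level == 0) viable[] <- TRUE

  geoms <- vector("list", length(scene$neurites))
  for (k in seq_along(scene$neurites)) {
    nrec <- scene$neurites[[k]]
    geoms[[k]] <- neurite_geometry(nrec, so[nrec$soma, ], length_factor,
                                   thickness_factor)
  }

  # nuclear channel: all nuclei, dead or alive, plus extracellular nuclei
  for (i in seq_len(nrow(so))) if (so$has_nucleus[i])
    nuclear <- draw_disk(nuclear, so$x[i], so$y[i], so$nucleus_r[i], 0.9)
  en <- scene$extra_nuclei
  for (i in seq_len(nrow(en)))
    nuclear <- draw_disk(nuclear, en$x[i], en$y[i], en$r[i], 0.9)

  # viability channel: viable somata + their neurites + active beads
  total_len_px <- 0; n_processes <- 0L; n_branches <- 0L
  for (i in which(viable))
    viability <- draw_disk(viability, so$x[i], so$y[i], so$r[i], 0.85)
  for (k in seq_along(geoms)) {
    g <- geoms[[k]]; nrec <- scene$neurites[[k]]
    if (!viable[nrec$soma]) next
    viability <- draw_segment(viability, g$start[1], g$start[2],
                              g$tip[1], g$tip[2], g$thickness, 0.7)
    if (g$branch_included)
      viability <- draw_segment(viability, g$branch_seg[1, 1], g$branch_seg[1, 2],
                                g$branch_seg[2, 1], g$branch_seg[2, 2],
                                g$thickness, 0.7)
    n_active <- round(injury_level * length(nrec$bead_fracs))
    if (n_active > 0) {
      act <- seq_len(n_active)
      for (b in act) {
        fr <- nrec$bead_fracs[b]
        if (fr * nrec$length >= g$main_len) next  # slot beyond truncation
        pos <- g$start + (so$r[nrec$soma] + fr * nrec$length) * g$dir
        viability <- draw_disk(viability, pos[1], pos[2], nrec$bead_r[b], 0.8)
      }
    }
    total_len_px <- total_len_px + g$total_len
    n_processes <- n_processes + 1L
    n_branches <- n_branches + as.integer(g$branch_included)
  }

  # MAP2 channel: full cell geometry of every cell (fixed-cell stain)
  for (i in seq_len(nrow(so)))
    map2 <- draw_disk(map2, so$x[i], so$y[i], so$r[i], 0.8)
  for (k in seq_along(geoms)) {
    g <- geoms[[k]]
    map2 <- draw_segment(map2, g$start[1], g$start[2], g$tip[1], g$tip[2],
                         g$thickness, 0.65)
    if (g$branch_included)
      map2 <- draw_segment(map2, g$branch_seg[1, 1], g$branch_seg[1, 2],
                           g$branch_seg[2, 1], g$branch_seg[2, 2],
                           g$thickness, 0.65)
  }

  # ground-truth masks (pre-blur, viable cells for live imaging)
  for (i in which(viable))
    soma_mask <- draw_disk(soma_mask, so$x[i], so$y[i], so$r[i], 1)
  for (k in seq_along(geoms)) {
    g <- geoms[[k]]
    if (!viable[scene$neurites[[k]]$soma]) next
    neurite_mask <- draw_segment(neurite_mask, g$start[1], g$start[2],
                                 g$tip[1], g$tip[2], g$thickness, 1)
    if (g$branch_included)
      neurite_mask <- draw_segment(neurite_mask, g$branch_seg[1, 1],
                                   g$branch_seg[1, 2], g$branch_seg[2, 1],
                                   g$branch_seg[2, 2], g$thickness, 1)
  }
  neurite_mask[soma_mask > 0] <- 0
  cell_mask <- pmax(soma_mask, neurite_mask)

  # synaptophysin channel: puncta in somata and along (truncated) neurites
  n_puncta_soma <- 0L; n_puncta_neurite <- 0L
  ps <- scene$puncta_soma
  for (i in seq_len(nrow(ps))) {
    syn <- draw_disk(syn, ps$x[i], ps$y[i], ps$r[i], 0.9)
    n_puncta_soma <- n_puncta_soma + 1L
  }
  pn <- scene$puncta_neurite
  for (i in seq_len(nrow(pn))) {
    k <- pn$neurite[i]; g <- geoms[[k]]; nrec <- scene$neurites[[k]]
    if (pn$frac[i] * nrec$length >= g$main_len) next
    pos <- g$start + (so$r[nrec$soma] + pn$frac[i] * nrec$length) * g$dir
    syn <- draw_disk(syn, pos[1], pos[2], pn$r[i], 0.9)
    n_puncta_neurite <- n_puncta_neurite + 1L
  }

  finish <- function(img) {
    img <- ebi_mat(EBImage::gblur(EBImage::Image(img), sigma = 1))
    grad <- if (scene$background_gradient != 0)
      scene$background_gradient * (row(img) - 1) / (nrow(img) - 1) else 0
    img <- img + scene$background + grad +
      stats::rnorm(length(img), 0, scene$noise_sd)
    clip01(img)
  }
  set.seed((scene$seed %% 100000L) * 101L + round(100 * injury_level))
  channels <- list(nuclear = finish(nuclear), viability = finish(viability),
                   map2 = finish(map2), synaptophysin = finish(syn))

  truth <- list(
    viable_count = sum(viable),
    dead_count = sum(!viable) + nrow(en),
    total_neurite_length_um = total_len_px * scene$pixel_size,
    total_processes = n_processes,
    total_branches = n_branches,
    soma_mask = soma_mask > 0, neurite_mask = neurite_mask > 0,
    cell_mask = cell_mask > 0,
    n_puncta_soma = n_puncta_soma, n_puncta_neurite = n_puncta_neurite,
    viable = viable,
    injury_level = injury_level)
  list(channels = channels, truth = truth, scene = scene)
}
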