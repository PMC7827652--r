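#' Per-nucleus features from a 3-channel confocal stack and a label mask
#'
#' Computes, for every labeled nucleus, the feature vector the classification
#' chain consumes: z-centroid as a fraction of stack depth, voxel-count size,
#' elongation (square root of the ratio of the two largest principal-axis
#' variances of the mask voxel coordinates), mean counterstain brightness, and
#' per-channel focus intensity — the mean of the top-`top_q` brightest in-mask
#' voxels of that channel, which captures bright intranuclear transcription
#' foci rather than diffuse background.
#'
#' @param stack A list with 3D arrays `counterstain`, `e1` (green, Homer1a)
#'   and `e2` (orange/red, Arc), dimensions `(nx, ny, nz)`.
#' @param masks Integer 3D array of the same dimensions; 0 = background,
#'   positive integers label nuclei.
#' @param top_q Fraction of brightest in-mask voxels averaged for the focus
#'   intensity (at least one voxel).
#' @param animal_id,treatment,environment,region,slide_id Metadata attached
#'   to every record.
#' @return A tibble of nucleus records compatible with [select_mid_z()] and
#'   the rest of the chain (exemplar flags initialized to `FALSE`). Labels
#'   present in `seq_len(max(masks))` but absent from the mask are skipped
#'   with a warning.
#' @export
extract_features_from_stack <- function(stack, masks, top_q = 0.01,
                                        animal_id = "a1", treatment = "control",
                                        environment = "A1A2", region = "CA1",
                                        slide_id = "slide01") {
  for (ch in c("counterstain", "e1", "e2")) {
    if (is.null(stack[[ch]]) || !identical(dim(stack[[ch]]), dim(masks))) {
      abort(sprintf("Channel `%s` missing or its dimensions differ from the mask.", ch),
            class = "checkfish_data_error")
    }
  }
  stopifnot_scalar_number(top_q, "top_q", min = 1e-9, max = 1)
  nz <- dim(masks)[3]
  max_label <- max(masks)
  if (max_label < 1) {
    abort("Mask contains no labeled nucleus.", class = "checkfish_data_error")
  }
  rows <- list()
  for (lab in seq_len(max_label)) {
    idx <- which(masks == lab)
    if (!length(idx)) {
      warn(sprintf("Label %d is empty; skipped.", lab))
      next
    }
    coords <- arrayInd(idx, dim(masks))
    size <- length(idx)
    zf <- (mean(coords[, 3]) - 0.5) / nz
    elong <- if (size < 3) 1 else {
      ev <- sort(eigen(stats::cov(coords), symmetric = TRUE,
                       only.values = TRUE)$values, decreasing = TRUE)
      sqrt(max(ev[1], 0) / max(ev[2], 1e-9))
    }
    focus <- function(channel) {
      v <- sort(channel[idx], decreasing = TRUE)
      mean(v[seq_len(max(1L, ceiling(top_q * size)))])
    }
    rows[[length(rows) + 1L]] <- tibble(
      animal_id = animal_id, treatment = treatment, environment = environment,
      region = region, slide_id = slide_id, nucleus_label = lab,
      z_centroid_fraction = zf, size = size, elongation = elong,
      counterstain_brightness = mean(stack$counterstain[idx]),
      intensity_e1_channel = focus(stack$e1),
      intensity_e2_channel = focus(stack$e2),
      exemplar_weakest_e1 = FALSE, exemplar_weakest_e2 = FALSE)
  }
  dplyr::bind_rows(rows)
}

#' Simulate a geometric two-channel nucleus phantom stack
#'
#' Builds a small synthetic confocal stack: ellipsoidal nuclei on a grid with
#' a labeled mask, uniform counterstain inside each nucleus, low background in
#' both IEG channels, and — for nuclei flagged active — one bright planted
#' focus of known value in the corresponding channel. A geometric phantom for
#' testing feature extraction, not a photorealistic microscopy simulation.
#'
#' @param n_nuclei Number of nuclei (placed on a non-overlapping grid).
#' @param dims Stack dimensions `c(nx, ny, nz)`.
#' @param radius Nucleus semi-axis in x/y, voxels.
#' @param z_semi Nucleus semi-axis in z, voxels.
#' @param active_e1,active_e2 Logical vectors (recycled) marking which nuclei
#'   get a planted focus in each channel.
#' @param focus_value Intensity of the planted focus.
#' @param background Background intensity of the IEG channels.
#' @param counterstain_value In-nucleus counterstain intensity.
#' @param seed Seed for the jittered nucleus centers.
#' @return A list: `stack` (channel list), `masks`, and `truth` (tibble of
#'   centers and planted activity).
#' @export
simulate_nucleus_stack <- function(n_nuclei = 4, dims = c(48, 48, 21),
                                   radius = 5, z_semi = 3,
                                   active_e1 = FALSE, active_e2 = FALSE,
                                   focus_value = 200, background = 5,
                                   counterstain_value = 100, seed = 1L) {
  n_nuclei <- stopifnot_count(n_nuclei, "n_nuclei")
  active_e1 <- rep_len(active_e1, n_nuclei)
  active_e2 <- rep_len(active_e2, n_nuclei)
  per_row <- ceiling(sqrt(n_nuclei))
  pitch_x <- dims[1] / per_row
  pitch_y <- dims[2] / ceiling(n_nuclei / per_row)
  if (min(pitch_x, pitch_y) < 2 * radius + 2) {
    abort("Stack too small for that many non-overlapping nuclei.",
          class = "checkfish_config_error")
  }
  masks <- array(0L, dims)
  ch <- function() array(background * stats::runif(prod(dims)), dims)
  with_seed(seed, {
    e1 <- ch(); e2 <- ch()
    counterstain <- array(stats::runif(prod(dims), 0, 5), dims)
    centers <- matrix(NA_real_, n_nuclei, 3)
    for (k in seq_len(n_nuclei)) {
      gx <- (k - 1) %% per_row
      gy <- (k - 1) %/% per_row
      cx <- (gx + 0.5) * pitch_x + stats::runif(1, -1, 1)
      cy <- (gy + 0.5) * pitch_y + stats::runif(1, -1, 1)
      cz <- stats::runif(1, z_semi + 1, dims[3] - z_semi)
      centers[k, ] <- c(cx, cy, cz)
      xr <- max(1, floor(cx - radius)):min(dims[1], ceiling(cx + radius))
      yr <- max(1, floor(cy - radius)):min(dims[2], ceiling(cy + radius))
      zr <- max(1, floor(cz - z_semi)):min(dims[3], ceiling(cz + z_semi))
      grid <- expand.grid(x = xr, y = yr, z = zr)
      inside <- ((grid$x - cx) / radius)^2 + ((grid$y - cy) / radius)^2 +
        ((grid$z - cz) / z_semi)^2 <= 1
      vox <- cbind(grid$x, grid$y, grid$z)[inside, , drop = FALSE]
      masks[vox] <- k
      counterstain[vox] <- counterstain_value +
        stats::rnorm(nrow(vox), 0, 2)
      # planted focus: the voxel block nearest the center
      n_focus <- min(4L, nrow(vox))
      focus_vox <- vox[order(rowSums(sweep(vox, 2, centers[k, ])^2))[seq_len(n_focus)], ,
                       drop = FALSE]
      if (active_e1[k]) e1[focus_vox] <- focus_value
      if (active_e2[k]) e2[focus_vox] <- focus_value
    }
    list(stack = list(counterstain = counterstain, e1 = e1, e2 = e2),
         masks = masks,
         truth = tibble(nucleus_label = seq_len(n_nuclei),
                        center_x = centers[, 1], center_y = centers[, 2],
                        center_z = centers[, 3],
                        active_e1 = active_e1, active_e2 = active_e2))
  })
}

#' Write / read a stack and label mask as multi-page TIFF
#'
#' Thin wrappers over the `tiff` package for the optional on-disk stack
#' format: one multi-page float TIFF per channel plus one for the mask.
#' Intensities are stored as 32-bit floats scaled by `scale` into `[0, 1]`.
#'
#' @param stack,masks As in [extract_features_from_stack()].
#' @param dir Output directory.
#' @param scale Intensity divisor used for storage.
#' @return `write_stack_tiff` returns the directory invisibly;
#'   `read_stack_tiff` returns `list(stack, masks)`.
#' @export
write_stack_tiff <- function(stack, masks, dir, scale = 256) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("The `tiff` package is needed for TIFF stack I/O.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  as_pages <- function(a) lapply(seq_len(dim(a)[3]), function(z) a[, , z] / scale)
  for (ch in c("counterstain", "e1", "e2")) {
    tiff::writeTIFF(as_pages(stack[[ch]]), file.path(dir, paste0(ch, ".tiff")),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  tiff::writeTIFF(as_pages(masks * 1.0), file.path(dir, "masks.tiff"),
                  bits.per.sample = 32L, reduce = FALSE)
  invisible(dir)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(dir, scale = 256) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("The `tiff` package is needed for TIFF stack I/O.")
  }
  rd <- function(f) {
    pages <- tiff::readTIFF(file.path(dir, f), all = TRUE)
    array(unlist(pages), c(dim(pages[[1]]), length(pages))) * scale
  }
  list(stack = list(counterstain = rd("counterstain.tiff"),
                    e1 = rd("e1.tiff"), e2 = rd("e2.tiff")),
       masks = array(as.integer(round(rd("masks.tiff"))),
                     dim = dim(rd("masks.tiff"))))
}
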