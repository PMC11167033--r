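#' Segment cells by nuclei and nearest-nucleus cytoplasm partition
#'
#' Nuclei are thresholded (Otsu), hole-filled and labeled; the cytoplasm
#' foreground (Otsu on the cytoplasm channel, union nuclei) is then
#' partitioned among the nuclei by a nearest-seed propagation, giving one
#' label per nucleus.
#'
#' @param nuclei Nucleus channel (2-D matrix).
#' @param cytoplasm Cytoplasm channel (2-D matrix).
#' @return Integer label matrix (0 = background).
#' @export
segment_cells <- function(nuclei, cytoplasm) {
  assert_image(nuclei, "nuclei")
  assert_image(cytoplasm, "cytoplasm")
  if (!all(dim(nuclei) == dim(cytoplasm))) {
    abort("nuclei and cytoplasm channels must have the same shape")
  }
  if (diff(range(nuclei)) == 0) abort("no nuclei found")
  nuc_mask <- segment_fluorescence(nuclei)$mask
  nuc_mask <- cleanup_mask(nuc_mask, fill_holes = TRUE, min_object_px = 9L)
  seeds <- as.matrix(EBImage::bwlabel(matrix(as.integer(nuc_mask),
                                             nrow(nuc_mask), ncol(nuc_mask))))
  if (max(seeds) == 0) abort("no nuclei found")
  cyto_mask <- if (diff(range(cytoplasm)) == 0) {
    nuc_mask
  } else {
    segment_fluorescence(cytoplasm)$mask | nuc_mask
  }
  lab <- EBImage::propagate(EBImage::Image(cytoplasm), EBImage::Image(seeds),
                            mask = cyto_mask)
  matrix(as.integer(lab), nrow(nuclei), ncol(nuclei))
}

#' Count fluorescent puncta per cell
#'
#' Detects punctum-scale blobs (default diameter 0.8 µm, far below the
#' cell diameter) in a channel and assigns each punctum to the cell whose
#' label contains its center; puncta outside every label are dropped. The
#' quality threshold is relative — `rel_quality` times the strongest
#' punctum response in the image — so counts are invariant to a global
#' intensity gain.
#'
#' @param channel Punctum channel (LC3, p62, Lamp-1, ...), 2-D matrix.
#' @param labels Integer label matrix from [segment_cells()].
#' @param diameter_um Punctum diameter (µm).
#' @param rel_quality Fraction of the maximal response retained (0-1).
#' @param pixel_size_um Pixel size (µm/px).
#' @param channel_name Label copied into the output.
#' @return One row per cell: `cell_id`, `channel`, `puncta_count`,
#'   `cell_area_px`.
#' @export
count_puncta_per_cell <- function(channel, labels, diameter_um = 0.8,
                                  rel_quality = 0.25, pixel_size_um = 0.2,
                                  channel_name = "puncta") {
  assert_image(channel)
  if (!all(dim(channel) == dim(labels))) {
    abort("labels must have the same shape as the channel")
  }
  if (rel_quality <= 0 || rel_quality > 1) abort("rel_quality must be in (0, 1]")
  cell_ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  areas <- tabulate(labels[labels > 0])
  base <- tibble(cell_id = cell_ids, channel = channel_name,
                 puncta_count = 0L,
                 cell_area_px = as.integer(areas[cell_ids]))
  if (length(cell_ids) == 0L || diff(range(channel)) == 0) return(base)
  cand <- detect_spots(channel, detection_params(diameter_um, -Inf),
                       pixel_size_um)
  if (nrow(cand) == 0L) return(base)
  cand <- filter(cand, .data$quality >= rel_quality * max(.data$quality))
  idx <- coord_to_index(cand$x_px, cand$y_px, dim(channel))
  owner <- labels[idx]
  counts <- table(factor(owner[owner > 0], levels = cell_ids))
  base$puncta_count <- as.integer(counts)
  base
}
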