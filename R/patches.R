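# Grid patches: non-overlapping tiles on a stride-(patch size) cartesian
# grid anchored at the colony's mask bounding box. Each tile carries the
# coral portion p (fraction of its pixels covered by the colony's mask
# label); tiles with p < 0.1 are discarded everywhere, and mask-background
# pixels inside a tile are zeroed to (0, 0, 0).

.coral_label <- function(coral) {
  switch(coral, C_r = 1L, C_b = 2L, stop("unknown coral '", coral, "'"))
}

.empty_patchset <- function(patch_size = 128L) {
  new("PatchSet",
      info = data.frame(patch_id = character(), image_id = character(),
                        coral = character(), x = integer(), y = integer(),
                        p = numeric(), k = integer(), k_hat = integer(),
                        mask_origin = character()),
      pixels = list(), patch_size = as.integer(patch_size))
}

#' Cut grid patches for one colony from one image
#'
#' Tiles the colony's mask bounding box with non-overlapping
#' `patch_size` x `patch_size` tiles (stride = patch size, anchored at the
#' box's top-left corner; every mask pixel of the colony lies in exactly
#' one tile). Tiles extending past the image are zero-padded. The coral
#' portion p is the fraction of tile pixels carrying the colony's label;
#' tiles with p below `p_min` (0.1) are discarded, and background pixels of
#' kept tiles are zeroed.
#'
#' @param image an [ImageRecord-class].
#' @param mask a [LabelMask-class] at native image resolution (ground truth
#'   for dataset building, predicted at inference).
#' @param coral `"C_r"` or `"C_b"`.
#' @param patch_size tile side length (default 128).
#' @param p_min eligibility threshold on the coral portion (default 0.1).
#' @return a [PatchSet-class].
#' @export
extractPatches <- function(image, mask, coral = "C_r", patch_size = 128L,
                           p_min = 0.1) {
  d <- dim(image@pixels)
  if (!identical(dim(mask@labels), d[1:2]))
    stop("mask and image sizes differ")
  lab <- .coral_label(coral)
  hit <- which(mask@labels == lab, arr.ind = TRUE)
  S <- as.integer(patch_size)
  if (!nrow(hit)) return(.empty_patchset(S))
  # 0-based bounding box top-left anchor
  y0 <- min(hit[, 1]) - 1L; x0 <- min(hit[, 2]) - 1L
  y1 <- max(hit[, 1]) - 1L; x1 <- max(hit[, 2]) - 1L
  xs <- seq(x0, x1, by = S)
  ys <- seq(y0, y1, by = S)
  info <- list(); pix <- list(); n <- 0L
  for (gy in ys) {
    for (gx in xs) {
      rows <- (gy + 1L):min(gy + S, d[1])
      cols <- (gx + 1L):min(gx + S, d[2])
      sub <- mask@labels[rows, cols, drop = FALSE]
      p <- sum(sub == lab) / (S * S)
      if (p < p_min) next
      tile <- array(0, c(S, S, 3))
      keep <- sub == lab
      img_sub <- image@pixels[rows, cols, , drop = FALSE]
      for (ch in 1:3) {
        layer <- matrix(0, S, S)
        layer[seq_along(rows), seq_along(cols)] <-
          img_sub[, , ch] * keep
        tile[, , ch] <- layer
      }
      n <- n + 1L
      info[[n]] <- data.frame(
        patch_id = sprintf("%s_%s_%d_%d", image@image_id, coral, gx, gy),
        image_id = image@image_id, coral = coral, x = gx, y = gy, p = p,
        k = NA_integer_, k_hat = NA_integer_, mask_origin = mask@origin)
      pix[[n]] <- tile
    }
  }
  if (!n) return(.empty_patchset(S))
  new("PatchSet", info = do.call(rbind, info), pixels = pix, patch_size = S)
}

#' Subset a PatchSet
#'
#' @param ps a [PatchSet-class].
#' @param idx logical or integer row index.
#' @return a [PatchSet-class].
#' @export
patchSubset <- function(ps, idx) {
  info <- ps@info[idx, , drop = FALSE]
  rownames(info) <- NULL
  new("PatchSet", info = info, pixels = ps@pixels[idx],
      patch_size = ps@patch_size)
}

#' Concatenate PatchSets
#'
#' @param ... [PatchSet-class] objects with equal patch size.
#' @return a [PatchSet-class].
#' @export
combinePatchSets <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, function(s) nrow(s@info) > 0, NA)]
  if (!length(sets)) return(.empty_patchset())
  sz <- unique(vapply(sets, function(s) s@patch_size, 0L))
  if (length(sz) != 1L) stop("patch sizes differ")
  info <- do.call(rbind, lapply(sets, function(s) s@info))
  rownames(info) <- NULL
  new("PatchSet", info = info,
      pixels = do.call(c, lapply(sets, function(s) s@pixels)),
      patch_size = sz)
}

#' Attach human activity labels to patches
#'
#' The class-label rule is an annotation rule: a patch is labeled 1 when
#' more than 20% of its visible polyps are extended, and a label may only
#' exist for an eligible patch (coral portion p >= 0.1). Labels referring
#' to patches that were filtered out (or never existed) are a validation
#' error.
#'
#' @param patches a [PatchSet-class] (all members satisfy p >= 0.1).
#' @param label_table data.frame with columns patch_id and k (0 or 1).
#' @return the [PatchSet-class] with true classes attached.
#' @export
ingestPatchLabels <- function(patches, label_table) {
  if (!all(c("patch_id", "k") %in% names(label_table)))
    stop("label table needs columns patch_id and k")
  if (!all(label_table$k %in% 0:1)) stop("labels must be 0 or 1")
  missing <- setdiff(label_table$patch_id, patches@info$patch_id)
  if (length(missing))
    stop("labels exist for filtered or unknown patch(es): ",
         paste(head(missing, 5), collapse = ", "))
  m <- match(patches@info$patch_id, label_table$patch_id)
  patches@info$k <- as.integer(label_table$k[m])
  patches
}

#' Label synthetic patches from the rendered polyp-state map
#'
#' For synthetic fixtures the renderer's per-cell state map replaces the
#' human annotator: a patch gets class 1 exactly when more than
#' `threshold` (20%) of the polyp surface cells lying in the tile were
#' rendered extended (patches in a [PatchSet-class] already satisfy
#' p >= 0.1). Tiles containing no surface cell stay unlabeled.
#'
#' @param patches a [PatchSet-class].
#' @param states state map from [renderScene()] / [simulateCampaign()]
#'   scenes (columns coral, cell_x, cell_y, extended).
#' @param cell_size renderer cell size in pixels.
#' @param threshold extended-cell fraction above which the label is 1.
#' @return the [PatchSet-class] with true classes attached.
#' @export
labelPatchesFromStates <- function(patches, states, cell_size = 16L,
                                   threshold = 0.2) {
  info <- patches@info
  S <- patches@patch_size
  for (i in seq_len(nrow(info))) {
    st <- states[states$coral == info$coral[i], , drop = FALSE]
    if (!nrow(st)) next
    ccx <- st$cell_x * cell_size + cell_size / 2
    ccy <- st$cell_y * cell_size + cell_size / 2
    inside <- ccx >= info$x[i] & ccx < info$x[i] + S &
      ccy >= info$y[i] & ccy < info$y[i] + S
    if (!any(inside)) next
    info$k[i] <- as.integer(mean(st$extended[inside]) > threshold)
  }
  patches@info <- info
  patches
}

#' Build per-split labeled patch datasets from a campaign
#'
#' Extracts and labels patches for one coral from every image, then
#' assigns each patch to train/val/test according to the assignment of its
#' source image: a patch always inherits its image's split, so no patch
#' information leaks across splits. An image assigned to two splits is an
#' error.
#'
#' @param scenes list with `$image`, `$mask`, `$states` per element (e.g.
#'   [simulateCampaign()] scenes).
#' @param split list of image-id vectors `train`, `val`, `test` (see
#'   [seededSplit()]).
#' @param coral `"C_r"` or `"C_b"`.
#' @param patch_size,p_min,cell_size see [extractPatches()] and
#'   [labelPatchesFromStates()].
#' @return list of labeled [PatchSet-class] objects keyed train/val/test.
#' @export
buildPatchDatasets <- function(scenes, split, coral = "C_r",
                               patch_size = 128L, p_min = 0.1,
                               cell_size = 16L) {
  ids <- unlist(split)
  if (anyDuplicated(ids))
    stop("image(s) assigned to more than one split: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- list()
  for (nm in c("train", "val", "test")) {
    sets <- lapply(scenes, function(sc) {
      if (!sc$image@image_id %in% split[[nm]]) return(NULL)
      ps <- extractPatches(sc$image, sc$mask, coral, patch_size, p_min)
      if (nrow(ps@info)) labelPatchesFromStates(ps, sc$states, cell_size)
      else ps
    })
    sets <- Filter(Negate(is.null), sets)
    out[[nm]] <- if (length(sets)) do.call(combinePatchSets, sets)
    else .empty_patchset(patch_size)
  }
  out
}
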