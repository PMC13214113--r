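# Candidate-set and montage presets: the 21 left-central channels and the
# 21 bilateral fronto-parietal parcels used for subject-specific feature
# selection, plus the desk-scale synthetic montage.

#' Left-central candidate channel list
#'
#' The 21-entry printed list of left central electrodes (C3 and neighbours
#' on a 128-channel montage). The printed list repeats "D18", so it
#' contains 20 unique channels; [candidate_preset()] de-duplicates on use.
#'
#' @return character vector as printed (21 entries, one duplicate).
#' @export
left_central_channels <- function() {
  c("D1", "D15", "D16", "D2", "D14", "D13", "D18", "D17", "D19", "D20",
    "D12", "D18", "D28", "D27", "D11", "D10", "D21", "D26", "D29", "A6", "A7")
}

#' Bilateral fronto-parietal candidate parcel list
#'
#' Ten bilateral Desikan-Killiany parcels plus right precentral: 21 parcels
#' in total, matching the count of the left-central channel subset. The
#' left precentral parcel is excluded because it is the coherence seed.
#'
#' @return character vector of 21 parcel names with `-lh`/`-rh` suffixes.
#' @export
dk_frontoparietal_parcels <- function() {
  bilateral <- c("precuneus", "superiorparietal", "inferiorparietal",
                 "supramarginal", "postcentral", "superiorfrontal",
                 "caudalmiddlefrontal", "rostralmiddlefrontal",
                 "parsopercularis", "parstriangularis")
  c(as.vector(t(outer(bilateral, c("-lh", "-rh"), paste0))), "precentral-rh")
}

#' Resolve a named candidate set
#'
#' @param name `"left-central-21"`, `"fronto-parietal-21"`, or
#'   `"all-channels"` (the latter resolves to all units of the tensor it is
#'   applied to).
#' @param available optional vector of available unit ids to intersect
#'   with; unavailable members are dropped with a warning.
#' @return character vector of unit ids (de-duplicated), or `NULL` for
#'   `"all-channels"`.
#' @export
candidate_preset <- function(name, available = NULL) {
  ids <- switch(name,
    "left-central-21"    = unique(left_central_channels()),
    "fronto-parietal-21" = dk_frontoparietal_parcels(),
    "all-channels"       = NULL,
    stop("candidate_preset: unknown preset '", name, "'")
  )
  if (!is.null(ids) && !is.null(available)) {
    missing <- setdiff(ids, available)
    if (length(missing) > 0)
      warning("candidate_preset: dropping unavailable units: ",
              paste(missing, collapse = ", "))
    ids <- intersect(ids, available)
  }
  ids
}

#' Desk-scale synthetic montage
#'
#' 32 channels laid out on a planar grid with 0.015-unit spacing (so the
#' 0.02 adjacency radius connects lattice neighbours), named so that the
#' left-central candidate subset is present; C3-equivalent "D19" sits in
#' the left-central part of the grid.
#'
#' @return list with `channel_ids` and a 32 x 2 `positions` matrix.
#' @export
default_montage <- function() {
  ids <- c(unique(left_central_channels()),           # 20
           paste0("A", c(1:5, 8:14)))                 # 12 fillers
  gx <- rep(seq_len(6), times = 6)[1:32]
  gy <- rep(seq_len(6), each = 6)[1:32]
  pos <- cbind(x = (gx - 3.5) * 0.015, y = (gy - 3.5) * 0.015)
  rownames(pos) <- ids
  list(channel_ids = ids, positions = pos)
}
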