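#' Track aggregates between two label masks by pixel overlap
#'
#' Builds the bipartite overlap graph between the particles of two
#' consecutive frames and classifies each particle's fate. An edge
#' `(A, B)` is kept when the overlap is at least `min_overlap_frac`
#' of the smaller of the two areas — robust to centroid drift of a few
#' pixels per frame. A frame-1 particle with two or more kept
#' successors `split`; a frame-2 particle with two or more kept
#' predecessors is a `merge` (and its predecessors are labelled
#' `merge`); a one-to-one correspondence in both directions is
#' `intact`; a particle with no kept edge `disappear`s (frame 1) or
#' `appear`s (frame 2).
#'
#' @param mask_a,mask_b integer label masks of the same shape
#'   (consecutive frames).
#' @param min_overlap_frac overlap threshold as a fraction of the
#'   smaller particle's area.
#' @return List of class `track_graph`:
#'   \describe{
#'     \item{edges}{data frame `from`, `to`, `overlap` (px) of kept
#'       edges.}
#'     \item{events_a}{data frame `label`, `event` for frame-1
#'       particles (`intact`/`split`/`merge`/`disappear`).}
#'     \item{events_b}{same for frame-2 particles
#'       (`intact`/`split`/`merge`/`appear`); a split child is labelled
#'       `split`.}
#'   }
#' @export
track_aggregates <- function(mask_a, mask_b, min_overlap_frac = 0.3) {
  if (!all(dim(mask_a) == dim(mask_b)))
    stopf("masks must have the same shape")
  la <- sort(setdiff(unique(as.integer(mask_a)), 0L))
  lb <- sort(setdiff(unique(as.integer(mask_b)), 0L))
  area_a <- setNames(tabulate(mask_a, nbins = max(mask_a, 1))[la], la)
  area_b <- setNames(tabulate(mask_b, nbins = max(mask_b, 1))[lb], lb)
  both <- mask_a > 0 & mask_b > 0
  edges <- data.frame(from = integer(0), to = integer(0), overlap = integer(0))
  if (any(both)) {
    ov <- table(from = mask_a[both], to = mask_b[both])
    ovdf <- as.data.frame(ov, stringsAsFactors = FALSE)
    ovdf <- ovdf[ovdf$Freq > 0, , drop = FALSE]
    ovdf$from <- as.integer(ovdf$from); ovdf$to <- as.integer(ovdf$to)
    keep <- ovdf$Freq >= min_overlap_frac *
      pmin(area_a[as.character(ovdf$from)], area_b[as.character(ovdf$to)])
    edges <- data.frame(from = ovdf$from[keep], to = ovdf$to[keep],
                        overlap = ovdf$Freq[keep])
  }
  n_succ <- setNames(tabulate(factor(edges$from, levels = la)), la)
  n_pred <- setNames(tabulate(factor(edges$to, levels = lb)), lb)

  ev_a <- vapply(as.character(la), function(l) {
    if (n_succ[l] == 0) return("disappear")
    if (n_succ[l] >= 2) return("split")
    succ <- edges$to[edges$from == as.integer(l)]
    if (n_pred[as.character(succ)] >= 2) "merge" else "intact"
  }, character(1))
  ev_b <- vapply(as.character(lb), function(l) {
    if (n_pred[l] == 0) return("appear")
    if (n_pred[l] >= 2) return("merge")
    pred <- edges$from[edges$to == as.integer(l)]
    if (n_succ[as.character(pred)] >= 2) "split" else "intact"
  }, character(1))

  structure(list(edges = edges,
                 events_a = data.frame(label = la, event = unname(ev_a)),
                 events_b = data.frame(label = lb, event = unname(ev_b))),
            class = "track_graph")
}

#' Track a whole mask sequence and tabulate per-transition events
#'
#' Applies [track_aggregates()] to each consecutive pair of masks and
#' returns one row per frame-1-side particle per transition, which is
#' directly comparable to a scripted scene's ground-truth event log.
#'
#' @param masks list of label masks (e.g. `scene_sim$masks`).
#' @param min_overlap_frac passed to [track_aggregates()].
#' @return Data frame: `frame_from`, `frame_to`, `label`, `event`.
#' @export
track_mask_sequence <- function(masks, min_overlap_frac = 0.3) {
  out <- lapply(seq_len(length(masks) - 1), function(f) {
    tg <- track_aggregates(masks[[f]], masks[[f + 1]], min_overlap_frac)
    cbind(frame_from = f, frame_to = f + 1, tg$events_a)
  })
  do.call(rbind, out)
}
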