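#' Specification for a scripted aggregate time-lapse scene
#'
#' Describes a synthetic label-mask movie of developing aggregates:
#' elliptical blobs that drift a few pixels per frame and, on scripted
#' frames, split into two children, merge with a partner, or remain
#' intact. The script is the ground truth the tracking stage is tested
#' against.
#'
#' Script rows are `(frame, id, type, partner)`: the event happens on
#' the transition from `frame` to `frame + 1`; `partner` is required for
#' `merge` and ignored otherwise. Aggregates without a scripted event
#' drift. Merge partners are placed adjacent at scene setup so a merged
#' ellipse can cover both footprints.
#'
#' @param frame_shape integer (rows, cols) of each mask.
#' @param n_frames number of frames.
#' @param n_aggregates number of aggregates at frame 1.
#' @param event_script data frame with columns `frame`, `id`, `type`
#'   (one of `"split"`, `"merge"`, `"intact"`, `"drift"`) and optionally
#'   `partner`; may be `NULL` for a drift-only scene.
#' @param axis_range range of ellipse semi-major axes, px; semi-minor is
#'   drawn as a fraction in `flatten_range` of the semi-major.
#' @param flatten_range range of semi-minor / semi-major ratios.
#' @param drift_max maximum per-axis centroid translation per frame, px
#'   (kept at or below 5 so overlap tracking stays well-posed).
#' @param seed integer seed.
#' @return An object of class `scene_sim_spec`.
#' @export
scene_sim_spec <- function(frame_shape = c(240, 240),
                           n_frames = 5,
                           n_aggregates = 4,
                           event_script = NULL,
                           axis_range = c(10, 18),
                           flatten_range = c(0.5, 1),
                           drift_max = 3,
                           seed = 1L) {
  if (drift_max > 5) stopf("drift_max above 5 px/frame breaks overlap tracking")
  if (is.null(event_script)) {
    event_script <- data.frame(frame = integer(0), id = integer(0),
                               type = character(0), partner = integer(0))
  }
  if (!"partner" %in% names(event_script)) event_script$partner <- NA_integer_
  bad <- setdiff(event_script$type, c("split", "merge", "intact", "drift"))
  if (length(bad)) stopf("unknown event type(s): %s", paste(bad, collapse = ", "))
  if (any(event_script$type == "merge" & is.na(event_script$partner)))
    stopf("merge events need a 'partner' id")
  if (any(event_script$frame >= n_frames))
    stopf("events must be scripted before the last frame")
  structure(list(frame_shape = as.integer(frame_shape),
                 n_frames = as.integer(n_frames),
                 n_aggregates = as.integer(n_aggregates),
                 event_script = event_script, axis_range = axis_range,
                 flatten_range = flatten_range, drift_max = drift_max,
                 seed = as.integer(seed)),
            class = "scene_sim_spec")
}

# Rasterize one ellipse into a label mask (in place); errors on overlap
# with an already-drawn aggregate or on touching the image border.
rasterize_ellipse <- function(mask, cx, cy, a, b, theta, label) {
  nr <- nrow(mask); nc <- ncol(mask)
  rr <- max(1L, floor(cy - a)):min(nr, ceiling(cy + a))
  cc <- max(1L, floor(cx - a)):min(nc, ceiling(cx + a))
  X <- outer(rep(1, length(rr)), cc) - cx
  Y <- outer(rr, rep(1, length(cc))) - cy
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (any(inside & (row(inside) + min(rr) - 1L) %in% c(1L, nr)) ||
      any(inside & (col(inside) + min(cc) - 1L) %in% c(1L, nc)) ||
      cy - a < 1 || cy + a > nr || cx - a < 1 || cx + a > nc)
    stopf("aggregate %d touches the image border", label)
  sub <- mask[rr, cc]
  if (any(sub[inside] != 0L))
    stopf("aggregates overlap in one frame (label %d)", label)
  sub[inside] <- label
  mask[rr, cc] <- sub
  mask
}

#' Simulate a scripted aggregate time-lapse as label masks
#'
#' Renders the scene described by a [scene_sim_spec()] frame by frame.
#' Splits replace a parent with two children inside the parent's
#' footprint; merges replace two adjacent parents with one ellipse
#' spanning both. Every frame is an integer label mask with background
#' 0 and labels renumbered consecutively from 1.
#'
#' @param spec a [scene_sim_spec()].
#' @return A list of class `scene_sim` with elements
#'   \describe{
#'     \item{masks}{list of integer matrices, one per frame.}
#'     \item{events}{data frame ground-truth log: `frame_from`,
#'       `frame_to`, `parents` and `children` (frame-local labels,
#'       `;`-joined), `type`.}
#'     \item{spec}{the input spec.}
#'   }
#' @examples
#' sc <- simulate_aggregate_timeseries(scene_sim_spec(
#'   n_frames = 3, n_aggregates = 2,
#'   event_script = data.frame(frame = 1, id = 1, type = "split")))
#' length(unique(sc$masks[[2]])) - 1  # components after the split
#' @export
simulate_aggregate_timeseries <- function(spec) {
  stopifnot(inherits(spec, "scene_sim_spec"))
  with_seed(derive_seed(spec$seed, "scene"), {
    nr <- spec$frame_shape[1]; nc <- spec$frame_shape[2]
    n0 <- spec$n_aggregates
    script <- spec$event_script

    # place initial aggregates on a jittered grid; merge partners adjacent
    a <- runif(n0, spec$axis_range[1], spec$axis_range[2])
    b <- a * runif(n0, spec$flatten_range[1], spec$flatten_range[2])
    theta <- runif(n0, 0, pi)
    ncol_grid <- ceiling(sqrt(n0))
    nrow_grid <- ceiling(n0 / ncol_grid)
    gx <- ((seq_len(n0) - 1) %% ncol_grid + 0.5) * (nc / ncol_grid)
    gy <- (floor((seq_len(n0) - 1) / ncol_grid) + 0.5) * (nr / nrow_grid)
    cx <- gx + runif(n0, -3, 3); cy <- gy + runif(n0, -3, 3)
    merge_rows <- script[script$type == "merge", , drop = FALSE]
    for (k in seq_len(nrow(merge_rows))) {
      i <- merge_rows$id[k]; j <- merge_rows$partner[k]
      gap <- a[i] + a[j] + 6
      dir <- if (cx[i] < nc / 2) 1 else -1   # toward the image centre
      cx[j] <- cx[i] + dir * gap; cy[j] <- cy[i]
    }

    agg <- data.frame(id = seq_len(n0), cx = cx, cy = cy, a = a, b = b,
                      theta = theta, alive = TRUE)
    next_id <- n0 + 1L
    # merge-destined aggregates hold position so the adjacency that makes
    # the merge geometrically realizable is not eroded by drift
    frozen <- unique(c(merge_rows$id, merge_rows$partner))

    render <- function(agg) {
      live <- agg[agg$alive, , drop = FALSE]
      live <- live[order(live$id), , drop = FALSE]
      mask <- matrix(0L, nr, nc)
      lab <- setNames(seq_len(nrow(live)), live$id)
      for (i in seq_len(nrow(live)))
        mask <- rasterize_ellipse(mask, live$cx[i], live$cy[i], live$a[i],
                                  live$b[i], live$theta[i], unname(lab[i]))
      list(mask = mask, labels = lab)   # labels: persistent id -> frame label
    }

    frames <- vector("list", spec$n_frames)
    fr1 <- render(agg)
    frames[[1]] <- fr1
    events <- NULL
    for (f in seq_len(spec$n_frames - 1)) {
      prev_labels <- frames[[f]]$labels
      sc_f <- script[script$frame == f, , drop = FALSE]
      trans <- list()
      handled <- integer(0)
      born_now <- integer(0)   # children created this transition do not drift
      for (k in seq_len(nrow(sc_f))) {
        ev <- sc_f[k, ]
        i <- which(agg$id == ev$id & agg$alive)
        if (!length(i)) stopf("event at frame %d targets missing aggregate %d",
                              ev$frame, ev$id)
        if (ev$type == "split") {
          p <- agg[i, ]
          ux <- cos(p$theta); uy <- sin(p$theta)
          kids <- data.frame(
            id = c(next_id, next_id + 1L),
            cx = p$cx + c(-1, 1) * 0.5 * p$a * ux,
            cy = p$cy + c(-1, 1) * 0.5 * p$a * uy,
            a = rep(0.45 * p$a, 2), b = rep(pmin(0.9 * p$b, 0.45 * p$a), 2),
            theta = rep(p$theta, 2), alive = TRUE)
          agg$alive[i] <- FALSE
          agg <- rbind(agg, kids)
          trans[[length(trans) + 1]] <- list(parents = p$id, children = kids$id,
                                             type = "split")
          next_id <- next_id + 2L
          handled <- c(handled, p$id)
          born_now <- c(born_now, kids$id)
        } else if (ev$type == "merge") {
          j <- which(agg$id == ev$partner & agg$alive)
          if (!length(j)) stopf("merge partner %d missing at frame %d",
                                ev$partner, ev$frame)
          p1 <- agg[i, ]; p2 <- agg[j, ]
          d <- sqrt((p1$cx - p2$cx)^2 + (p1$cy - p2$cy)^2)
          child <- data.frame(
            id = next_id, cx = (p1$cx + p2$cx) / 2, cy = (p1$cy + p2$cy) / 2,
            a = d / 2 + max(p1$a, p2$a), b = max(p1$b, p2$b),
            theta = atan2(p2$cy - p1$cy, p2$cx - p1$cx), alive = TRUE)
          agg$alive[c(i, j)] <- FALSE
          agg <- rbind(agg, child)
          trans[[length(trans) + 1]] <- list(parents = c(p1$id, p2$id),
                                             children = child$id, type = "merge")
          next_id <- next_id + 1L
          handled <- c(handled, p1$id, p2$id)
          born_now <- c(born_now, child$id)
        } else {
          # intact: hold position; drift handled below with everyone else
          if (ev$type == "intact") handled <- c(handled, ev$id)
          trans[[length(trans) + 1]] <- list(parents = ev$id, children = ev$id,
                                             type = "intact")
        }
      }
      stayers <- agg$alive & !(agg$id %in% c(handled, born_now))
      drifters <- which(stayers & !(agg$id %in% frozen))
      for (i in drifters) {
        # greedy frame-by-frame validation: a drift step that would bring
        # two aggregates into contact (or touch the border) is skipped
        nx <- agg$cx[i] + runif(1, -spec$drift_max, spec$drift_max)
        ny <- agg$cy[i] + runif(1, -spec$drift_max, spec$drift_max)
        others <- which(agg$alive)
        others <- others[others != i]
        clear <- all(sqrt((agg$cx[others] - nx)^2 + (agg$cy[others] - ny)^2) >
                       agg$a[others] + agg$a[i] + 2) &&
          nx - agg$a[i] > 2 && nx + agg$a[i] < nc - 2 &&
          ny - agg$a[i] > 2 && ny + agg$a[i] < nr - 2
        if (clear) {
          agg$cx[i] <- nx; agg$cy[i] <- ny
        }
      }
      for (id in agg$id[stayers])
        trans[[length(trans) + 1]] <- list(parents = id, children = id,
                                           type = "intact")
      frames[[f + 1]] <- render(agg)
      new_labels <- frames[[f + 1]]$labels
      ev_rows <- lapply(trans, function(tr) {
        data.frame(frame_from = f, frame_to = f + 1L,
                   parents = paste(unname(prev_labels[as.character(tr$parents)]),
                                   collapse = ";"),
                   children = paste(unname(new_labels[as.character(tr$children)]),
                                    collapse = ";"),
                   type = tr$type)
      })
      events <- rbind(events, do.call(rbind, ev_rows))
    }

    structure(list(masks = lapply(frames, `[[`, "mask"),
                   events = events %||% data.frame(frame_from = integer(0),
                                                   frame_to = integer(0),
                                                   parents = character(0),
                                                   children = character(0),
                                                   type = character(0)),
                   spec = spec),
              class = "scene_sim")
  })
}
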