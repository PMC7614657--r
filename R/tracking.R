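# Frame-to-frame nuclear tracking with an intensity-conservation invariant,
# merge/split repair, and mitosis detection.
#
# Total nuclear H2B signal is treated as a conserved quantity: links whose
# signal changes by more than `signal_tolerance` are not accepted directly
# but flagged for merge/split review; divisions are recognized as one track
# ending with two new tracks appearing nearby whose summed signal matches
# the parent's.

#' Link two frames of cell observations by mutual nearest neighbours
#'
#' @param prev,curr data frames of observations with columns `x`, `y`,
#'   `total` (one row per object).
#' @param max_dist_px maximum linking distance.
#' @param signal_tolerance maximum fractional change of total signal for an
#'   accepted link; candidate links beyond it are flagged for merge/split
#'   review.
#' @return list: `matches` (data frame `prev`, `curr` row indices, `dist`,
#'   `signal_ratio`, `flagged`), `unmatched_prev`, `unmatched_curr` (row
#'   indices).
#' @export
link_frames <- function(prev, curr, max_dist_px, signal_tolerance = 0.25) {
  if (max_dist_px <= 0) stopf("max_dist_px must be > 0")
  np <- nrow(prev); nc <- nrow(curr)
  empty <- data.frame(prev = integer(), curr = integer(), dist = numeric(),
                      signal_ratio = numeric(), flagged = logical())
  if (np == 0 || nc == 0)
    return(list(matches = empty, unmatched_prev = seq_len(np),
                unmatched_curr = seq_len(nc)))
  d <- sqrt(outer(prev$x, curr$x, `-`)^2 + outer(prev$y, curr$y, `-`)^2)
  # nearest neighbour each way; ties by distance then |signal change|
  nn_pc <- apply(d, 1, which.min)
  nn_cp <- apply(d, 2, which.min)
  mutual <- which(nn_cp[nn_pc] == seq_len(np) & d[cbind(seq_len(np), nn_pc)] <= max_dist_px)
  m <- data.frame(prev = mutual, curr = nn_pc[mutual],
                  dist = d[cbind(mutual, nn_pc[mutual])])
  m$signal_ratio <- curr$total[m$curr] / prev$total[m$prev]
  m$flagged <- abs(m$signal_ratio - 1) > signal_tolerance
  list(matches = m,
       unmatched_prev = setdiff(seq_len(np), m$prev),
       unmatched_curr = setdiff(seq_len(nc), m$curr))
}

#' Detect mitosis events in a set of tracks
#'
#' A division is recorded when a track ends and two new parentless tracks
#' begin on the next frame within `vicinity_px` of its last centroid, with
#' the daughters' summed total nuclear signal within `signal_tolerance` of
#' the parent's.
#'
#' @param tracks a `"cell_tracks"` object (see [build_tracks()]) or a list
#'   with `tracks` and `observations` data frames.
#' @param vicinity_px search radius around the ended track's last centroid.
#' @param signal_tolerance fractional tolerance on the daughter signal sum.
#' @return data frame of events: `parent`, `daughter1`, `daughter2`,
#'   `division_frame`.
#' @export
detect_mitosis <- function(tracks, vicinity_px, signal_tolerance = 0.3) {
  if (!(signal_tolerance > 0 && signal_tolerance < 0.5))
    stopf("signal_tolerance must lie in (0, 0.5)")
  tr <- tracks$tracks; obs <- tracks$observations
  ev <- list()
  for (i in seq_len(nrow(tr))) {
    f_end <- tr$end_frame[i]
    last <- obs[obs$track_id == tr$track_id[i] & obs$frame == f_end, ]
    starters <- tr[tr$start_frame == f_end + 1L & tr$track_id != tr$track_id[i], ]
    if (nrow(starters) < 2) next
    first_obs <- obs[obs$track_id %in% starters$track_id &
                       obs$frame == f_end + 1L, ]
    dd <- sqrt((first_obs$x - last$x)^2 + (first_obs$y - last$y)^2)
    near <- first_obs[dd <= vicinity_px, ]
    if (nrow(near) < 2) next
    near <- near[order(dd[dd <= vicinity_px]), ][1:2, ]
    if (abs(sum(near$total) - last$total) / last$total <= signal_tolerance)
      ev[[length(ev) + 1L]] <- data.frame(
        parent = tr$track_id[i],
        daughter1 = near$track_id[1], daughter2 = near$track_id[2],
        division_frame = f_end)
  }
  if (length(ev) == 0)
    return(data.frame(parent = integer(), daughter1 = integer(),
                      daughter2 = integer(), division_frame = integer()))
  do.call(rbind, ev)
}

#' Repair flagged merge/split links between two frames
#'
#' A current-frame object whose signal matches the sum of a flagged link's
#' predecessor and a second, lost predecessor is treated as a one-frame
#' segmentation merge: the observation is split in two at the predecessors'
#' carried-forward centroids with the signal apportioned proportionally.
#'
#' @param link result of [link_frames()].
#' @param prev,curr the observation data frames given to [link_frames()].
#' @param signal_tolerance fractional tolerance on the signal sum.
#' @param max_dist_px search radius for the lost second predecessor.
#' @return list: `assignments` data frame (`prev`, `curr`, `split` logical),
#'   `curr_repaired` (curr with split observations replacing merged ones),
#'   `unmatched_prev`, `unmatched_curr`.
#' @export
repair_merge_split <- function(link, prev, curr, signal_tolerance = 0.3,
                               max_dist_px = 15) {
  m <- link$matches
  up <- link$unmatched_prev
  repaired <- curr
  extra <- list()
  resolved <- data.frame(prev = integer(), curr = integer(), split = logical())
  for (i in which(m$flagged & m$signal_ratio > 1 + signal_tolerance)) {
    ci <- m$curr[i]; p1 <- m$prev[i]
    if (length(up) == 0) break
    d2 <- sqrt((prev$x[up] - curr$x[ci])^2 + (prev$y[up] - curr$y[ci])^2)
    cand <- up[d2 <= max_dist_px]
    if (length(cand) == 0) next
    p2 <- cand[which.min(abs(curr$total[ci] -
                               (prev$total[p1] + prev$total[cand])))]
    sum_sig <- prev$total[p1] + prev$total[p2]
    if (abs(curr$total[ci] - sum_sig) / sum_sig > signal_tolerance) next
    # split the merged observation at the carried-forward centroids
    shift <- c(curr$x[ci] - (prev$x[p1] * prev$total[p1] +
                               prev$x[p2] * prev$total[p2]) / sum_sig,
               curr$y[ci] - (prev$y[p1] * prev$total[p1] +
                               prev$y[p2] * prev$total[p2]) / sum_sig)
    scale <- curr$total[ci] / sum_sig
    frac1 <- prev$total[p1] / sum_sig
    o1 <- curr[ci, , drop = FALSE]
    o1$x <- prev$x[p1] + shift[1]; o1$y <- prev$y[p1] + shift[2]
    o2 <- curr[ci, , drop = FALSE]
    o2$x <- prev$x[p2] + shift[1]; o2$y <- prev$y[p2] + shift[2]
    # apportion every extensive quantity (signal totals, areas) between the
    # two tracks in proportion to their pre-merge signals
    ext_cols <- intersect(names(curr),
                          c("total", "area_px", "puncta_area_px",
                            grep("_total$", names(curr), value = TRUE)))
    for (cn in ext_cols) {
      o1[[cn]] <- curr[[cn]][ci] * frac1
      o2[[cn]] <- curr[[cn]][ci] * (1 - frac1)
    }
    repaired[ci, ] <- o1
    extra[[length(extra) + 1L]] <- list(obs = o2, prev = p2, merged_curr = ci)
    resolved <- rbind(resolved,
                      data.frame(prev = c(p1, p2),
                                 curr = c(ci, nrow(curr) + length(extra)),
                                 split = TRUE))
    up <- setdiff(up, p2)
    m$flagged[i] <- FALSE
  }
  for (e in extra) repaired <- rbind(repaired, e$obs)
  list(matches = m, resolved = resolved, curr_repaired = repaired,
       unmatched_prev = up, unmatched_curr = link$unmatched_curr)
}

#' Build lineage-resolved tracks from per-frame observations
#'
#' Orchestrates [link_frames()], merge/split repair and division detection
#' frame by frame. Accepted links extend tracks; flagged links are reviewed:
#' one-frame segmentation merges are split back into their two contributing
#' tracks (a merge persisting `k_frames` frames ends the weaker track as
#' `"lost"`), and a track ending with two new tracks nearby whose signals sum
#' to the parent's becomes a division, with daughters carrying
#' `parent_track_id`.
#'
#' @param frames list of per-frame observation data frames (columns `frame`,
#'   `x`, `y`, `total`, optionally `area_px`, `label` and signal columns).
#' @param params list: `max_dist_px` (default 10), `signal_tolerance` (0.25),
#'   `division_tolerance` (0.3), `vicinity_px` (30), `k_frames` (3).
#' @return object of class `"cell_tracks"`: list with `tracks` (track_id,
#'   parent_track_id, start_frame, end_frame, division_frame, end_reason)
#'   and `observations` (all input observations plus `track_id`).
#' @export
build_tracks <- function(frames, params = list()) {
  p <- utils::modifyList(list(max_dist_px = 10, signal_tolerance = 0.25,
                              division_tolerance = 0.3, vicinity_px = 30,
                              k_frames = 3L), params)
  frames <- Filter(function(f) !is.null(f), frames)
  if (length(frames) == 0)
    return(structure(list(
      tracks = data.frame(track_id = integer(), parent_track_id = integer(),
                          start_frame = integer(), end_frame = integer(),
                          division_frame = integer(), end_reason = character()),
      observations = data.frame()), class = "cell_tracks"))

  frame_ids <- vapply(frames, function(f) f$frame[1], 0)
  ord <- order(frame_ids)
  frames <- frames[ord]; frame_ids <- frame_ids[ord]

  next_id <- 1L
  tracks <- list()   # per id: list(rows, parent, status, merged_with, merge_run)
  new_track <- function(obs_row, parent = NA_integer_) {
    id <- next_id; next_id <<- next_id + 1L
    obs_row$track_id <- id
    tracks[[id]] <<- list(rows = obs_row, parent = parent,
                          status = "active", end_reason = NA_character_,
                          division_frame = NA_integer_,
                          merge_run = 0L, merge_partner = NA_integer_)
    id
  }
  active <- integer(0)
  f0 <- frames[[1]]
  for (i in seq_len(nrow(f0))) active <- c(active, new_track(f0[i, , drop = FALSE]))

  for (fi in seq_along(frames)[-1]) {
    curr <- frames[[fi]]
    f_now <- frame_ids[fi]
    prev <- do.call(rbind, lapply(active, function(id) {
      r <- tracks[[id]]$rows
      r[nrow(r), , drop = FALSE]
    }))
    lk <- link_frames(prev, curr, p$max_dist_px, p$signal_tolerance)

    linked_curr <- integer(0); linked_prev <- integer(0)

    # 1) tracks in a merged state: when the merged object separates into two
    #    objects again, assign the fragments by signal similarity (totals
    #    were apportioned at the pre-merge ratio, so they identify the cells)
    partnered <- which(vapply(active, function(id)
      !is.na(tracks[[id]][["merge_partner"]] %||% NA_integer_), TRUE))
    handled_pairs <- list()
    for (pr1 in partnered) {
      id1 <- active[pr1]
      id2 <- tracks[[id1]][["merge_partner"]]
      pr2 <- match(id2, active)
      if (is.na(pr2) || pr2 < pr1) next
      # candidate objects near either carried position
      dd1 <- sqrt((curr$x - prev$x[pr1])^2 + (curr$y - prev$y[pr1])^2)
      dd2 <- sqrt((curr$x - prev$x[pr2])^2 + (curr$y - prev$y[pr2])^2)
      cand <- setdiff(which(pmin(dd1, dd2) <= p$max_dist_px), linked_curr)
      if (length(cand) < 2) next     # still merged (or lost): repair below
      cand <- cand[order(pmin(dd1, dd2)[cand])][1:2]
      # two assignments; pick the one with the smaller signal mismatch
      mis <- function(a, b) abs(log(curr$total[a] / prev$total[pr1])) +
        abs(log(curr$total[b] / prev$total[pr2]))
      pick <- if (mis(cand[1], cand[2]) <= mis(cand[2], cand[1]))
        c(cand[1], cand[2]) else c(cand[2], cand[1])
      for (q in 1:2) {
        id <- c(id1, id2)[q]
        row <- curr[pick[q], , drop = FALSE]; row$track_id <- id
        tracks[[id]]$rows <- rbind(tracks[[id]]$rows, row)
        tracks[[id]]$merge_run <- 0L
        tracks[[id]]$merge_partner <- NA_integer_
      }
      linked_curr <- c(linked_curr, pick)
      linked_prev <- c(linked_prev, pr1, pr2)
    }

    lk$matches <- lk$matches[!(lk$matches$prev %in% linked_prev |
                                 lk$matches$curr %in% linked_curr), ,
                             drop = FALSE]
    lk$unmatched_prev <- setdiff(lk$unmatched_prev, linked_prev)
    lk$unmatched_curr <- setdiff(lk$unmatched_curr, linked_curr)

    # 2) merged objects: split the observation between the two contributing
    #    tracks; the pair stays alive for as long as the merge lasts
    rp <- repair_merge_split(lk, prev, curr,
                             signal_tolerance = p$division_tolerance,
                             max_dist_px = p$max_dist_px)
    curr <- rp$curr_repaired
    m <- rp$matches
    if (nrow(rp$resolved)) {
      for (j in seq(1L, nrow(rp$resolved), by = 2L)) {
        pr1 <- rp$resolved$prev[j]; cu1 <- rp$resolved$curr[j]
        pr2 <- rp$resolved$prev[j + 1L]; cu2 <- rp$resolved$curr[j + 1L]
        id1 <- active[pr1]; id2 <- active[pr2]
        run <- max(tracks[[id1]]$merge_run, tracks[[id2]]$merge_run) + 1L
        for (pair in list(list(id = id1, pr = pr1, cu = cu1, other = id2),
                          list(id = id2, pr = pr2, cu = cu2, other = id1))) {
          tracks[[pair$id]]$merge_run <- run
          tracks[[pair$id]]$merge_partner <- pair$other
          row <- curr[pair$cu, , drop = FALSE]; row$track_id <- pair$id
          tracks[[pair$id]]$rows <- rbind(tracks[[pair$id]]$rows, row)
        }
        linked_curr <- c(linked_curr, cu1, cu2)
        linked_prev <- c(linked_prev, pr1, pr2)
      }
    }

    # 3) ordinary accepted links
    for (j in seq_len(nrow(m))) {
      if (m$flagged[j]) next
      if (m$prev[j] %in% linked_prev || m$curr[j] %in% linked_curr) next
      id <- active[m$prev[j]]
      row <- curr[m$curr[j], , drop = FALSE]; row$track_id <- id
      tracks[[id]]$rows <- rbind(tracks[[id]]$rows, row)
      tracks[[id]]$merge_run <- 0L
      tracks[[id]]$merge_partner <- NA_integer_
      linked_curr <- c(linked_curr, m$curr[j]); linked_prev <- c(linked_prev, m$prev[j])
    }
    ended_prev <- setdiff(seq_len(nrow(prev)), linked_prev)
    new_curr <- setdiff(seq_len(nrow(curr)), linked_curr)

    # division detection: ended track + two new objects nearby
    used_curr <- integer(0)
    survivors <- integer(0)
    for (pe in ended_prev) {
      id <- active[pe]
      if (!is.na(tracks[[id]][["merge_partner"]] %||% NA_integer_)) {
        # a track inside an unresolved merge does not divide; it is lost
        tracks[[id]]$status <- "ended"
        tracks[[id]]$end_reason <- "lost"
        next
      }
      cand <- setdiff(new_curr, used_curr)
      if (length(cand) >= 2) {
        dd <- sqrt((curr$x[cand] - prev$x[pe])^2 + (curr$y[cand] - prev$y[pe])^2)
        near <- cand[dd <= p$vicinity_px][order(dd[dd <= p$vicinity_px])]
        if (length(near) >= 2) {
          two <- near[1:2]
          if (abs(sum(curr$total[two]) - prev$total[pe]) / prev$total[pe] <=
              p$division_tolerance) {
            tracks[[id]]$status <- "ended"
            tracks[[id]]$end_reason <- "divided"
            tracks[[id]]$division_frame <- as.integer(frame_ids[fi - 1L])
            for (cu in two) {
              did <- new_track(curr[cu, , drop = FALSE], parent = id)
              survivors <- c(survivors, did)
            }
            used_curr <- c(used_curr, two)
            next
          }
        }
      }
      if (tracks[[id]]$status == "active") {
        tracks[[id]]$status <- "ended"
        tracks[[id]]$end_reason <- "lost"
      }
    }
    for (cu in setdiff(new_curr, used_curr))
      survivors <- c(survivors, new_track(curr[cu, , drop = FALSE]))
    still <- active[vapply(active, function(id) tracks[[id]]$status == "active", TRUE)]
    active <- c(still, survivors)
  }
  for (id in active) {
    tracks[[id]]$status <- "ended"
    tracks[[id]]$end_reason <- "movie_end"
  }
  # pairs still merged at movie end after a persistent run: the weaker
  # member is declared lost (its identity cannot be confirmed again)
  for (id in seq_along(tracks)) {
    pid <- tracks[[id]][["merge_partner"]] %||% NA_integer_
    if (is.na(pid) || pid < id) next
    if (max(tracks[[id]]$merge_run, tracks[[pid]]$merge_run) < p$k_frames)
      next
    t1 <- tracks[[id]]$rows$total[nrow(tracks[[id]]$rows)]
    t2 <- tracks[[pid]]$rows$total[nrow(tracks[[pid]]$rows)]
    lose <- if (t1 < t2) id else pid
    if (identical(tracks[[lose]]$end_reason, "movie_end"))
      tracks[[lose]]$end_reason <- "lost"
  }

  tracks <- stitch_spurious_divisions(tracks, p$k_frames)
  obs <- do.call(rbind, lapply(seq_along(tracks), function(id) tracks[[id]]$rows))
  tr <- data.frame(
    track_id = seq_along(tracks),
    parent_track_id = vapply(tracks, function(t) t$parent, 1L),
    start_frame = vapply(tracks, function(t)
      if (nrow(t$rows)) as.integer(t$rows$frame[1]) else NA_integer_, 1L),
    end_frame = vapply(tracks, function(t)
      if (nrow(t$rows)) as.integer(t$rows$frame[nrow(t$rows)]) else NA_integer_, 1L),
    division_frame = vapply(tracks, function(t) t$division_frame, 1L),
    end_reason = vapply(tracks, function(t) t$end_reason, "")
  )
  # drop tracks absorbed by stitching
  keep <- !vapply(tracks, function(t) isTRUE(t[["stitched_away"]]), TRUE)
  tr <- tr[keep, , drop = FALSE]
  structure(list(tracks = tr, observations = obs), class = "cell_tracks")
}

# A division whose daughter pair re-merges within k frames (one daughter lost
# after <= k + 1 frames while its sibling persists) is a spurious
# segmentation split, not a mitosis: merge the pair back into the parent
# track, which continues through the surviving branch.
stitch_spurious_divisions <- function(tracks, k_frames) {
  parents <- which(vapply(tracks, function(t)
    identical(t$end_reason, "divided"), TRUE))
  for (pid in parents) {
    kids <- which(vapply(tracks, function(t)
      identical(t$parent, pid), TRUE))
    if (length(kids) != 2) next
    len <- vapply(kids, function(id) nrow(tracks[[id]]$rows), 0L)
    short <- kids[which.min(len)]; long <- kids[which.max(len)]
    if (short == long) next
    if (!(tracks[[short]]$end_reason == "lost" &&
          nrow(tracks[[short]]$rows) <= k_frames + 1L)) next
    # combine the daughters' overlapping frames back into one observation
    rs <- tracks[[short]]$rows; rl <- tracks[[long]]$rows
    comb <- rl
    for (i in seq_len(nrow(comb))) {
      j <- which(rs$frame == comb$frame[i])
      if (length(j) == 1) {
        w <- c(comb$total[i], rs$total[j])
        comb$x[i] <- sum(c(comb$x[i], rs$x[j]) * w) / sum(w)
        comb$y[i] <- sum(c(comb$y[i], rs$y[j]) * w) / sum(w)
        comb$total[i] <- sum(w)
        if ("area_px" %in% names(comb))
          comb$area_px[i] <- comb$area_px[i] + rs$area_px[j]
      }
    }
    comb$track_id <- pid
    tracks[[pid]]$rows <- rbind(tracks[[pid]]$rows, comb)
    tracks[[pid]]$status <- tracks[[long]]$status
    tracks[[pid]]$end_reason <- tracks[[long]]$end_reason
    tracks[[pid]]$division_frame <- tracks[[long]]$division_frame
    tracks[[short]]$rows <- tracks[[short]]$rows[0, , drop = FALSE]
    tracks[[long]]$rows <- tracks[[long]]$rows[0, , drop = FALSE]
    tracks[[short]]$stitched_away <- TRUE
    tracks[[long]]$stitched_away <- TRUE
    for (q in seq_along(tracks))
      if (identical(tracks[[q]]$parent, long)) tracks[[q]]$parent <- pid
  }
  tracks
}

#' @export
print.cell_tracks <- function(x, ...) {
  cat(sprintf("cell_tracks: %d tracks, %d observations, frames %d..%d\n",
              nrow(x$tracks), nrow(x$observations),
              min(x$tracks$start_frame), max(x$tracks$end_frame)))
  cat("end reasons:\n")
  print(table(x$tracks$end_reason))
  invisible(x)
}
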