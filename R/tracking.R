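#' Link per-frame defect detections into trajectories
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames,
#' restricted to charge-matched pairs within `max_disp` (minimal-image
#' distance on the periodic box).  Unmatched detections open (birth) or close
#' (death) trajectories; births/deaths of a (+1/2, -1/2) pair within
#' `pair_dist` of each other in the same frame are recorded as pair-creation
#' / annihilation events.
#'
#' @param detections Tibble with columns `frame`, `time`, `x`, `y`, `charge`
#'   (typically per-frame [detect_defects()] output with frame/time added).
#' @param grid A [grid_spec()] (for periodic wrapping).
#' @param max_disp Maximum per-frame displacement (default `4 * dx`).
#' @param pair_dist Pair-event radius (default 3, in units of \eqn{\xi}).
#' @return A list of class `defect_trajectories`: `trajectories` (the input
#'   tibble with an `id` column) and `events` (tibble with `kind` in
#'   creation/annihilation/birth/death, `frame`, `time`, `id`, `partner`).
#' @export
link_trajectories <- function(detections, grid, max_disp = 4 * grid$dx,
                              pair_dist = 3) {
  stopifnot(all(c("frame", "time", "x", "y", "charge") %in% names(detections)))
  det <- dplyr::arrange(detections, .data$frame)
  frames <- sort(unique(det$frame))
  det$id <- NA_integer_
  next_id <- 1L
  events <- list()
  rows_of <- function(f) which(det$frame == f)
  prev <- rows_of(frames[1])
  det$id[prev] <- seq_len(length(prev))
  next_id <- length(prev) + 1L
  if (length(frames) > 1) for (fi in 2:length(frames)) {
    cur <- rows_of(frames[fi])
    linked_cur <- rep(FALSE, length(cur))
    linked_prev <- rep(FALSE, length(prev))
    if (length(prev) && length(cur)) {
      dmat <- outer(seq_along(prev), seq_along(cur), function(a, b) {
        sqrt(wrap_delta(det$x[prev[a]] - det$x[cur[b]], grid$Lx)^2 +
             wrap_delta(det$y[prev[a]] - det$y[cur[b]], grid$Ly)^2)
      })
      dmat[outer(det$charge[prev], det$charge[cur], `!=`)] <- Inf
      dmat[dmat > max_disp] <- Inf
      for (a in seq_along(prev)) {
        if (all(is.infinite(dmat[a, ]))) next
        b <- which.min(dmat[a, ])
        if (which.min(dmat[, b]) == a) {   # mutual nearest neighbours
          det$id[cur[b]] <- det$id[prev[a]]
          linked_cur[b] <- TRUE; linked_prev[a] <- TRUE
          dmat[a, ] <- Inf; dmat[, b] <- Inf
        }
      }
    }
    born <- cur[!linked_cur]
    if (length(born)) {
      det$id[born] <- next_id + seq_along(born) - 1L
      next_id <- next_id + length(born)
    }
    died <- prev[!linked_prev]
    events <- c(events,
                pair_events(det, born, "creation", grid, pair_dist),
                pair_events(det, died, "annihilation", grid, pair_dist))
    prev <- cur
  }
  ev <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(kind = character(0), frame = integer(0),
                   time = numeric(0), id = integer(0), partner = integer(0))
  structure(list(trajectories = tibble::as_tibble(det), events = ev),
            class = "defect_trajectories")
}

pair_events <- function(det, rows, kind, grid, pair_dist) {
  if (length(rows) < 2) return(list())
  out <- list()
  used <- rep(FALSE, length(rows))
  for (a in seq_along(rows)) {
    if (used[a]) next
    for (b in seq_along(rows)) {
      if (b <= a || used[b]) next
      ra <- rows[a]; rb <- rows[b]
      if (det$charge[ra] * det$charge[rb] >= 0) next
      d <- sqrt(wrap_delta(det$x[ra] - det$x[rb], grid$Lx)^2 +
                wrap_delta(det$y[ra] - det$y[rb], grid$Ly)^2)
      if (d <= pair_dist) {
        out[[length(out) + 1]] <- tibble::tibble(
          kind = kind, frame = det$frame[ra], time = det$time[ra],
          id = det$id[ra], partner = det$id[rb])
        used[a] <- used[b] <- TRUE
        break
      }
    }
  }
  out
}

#' @export
print.defect_trajectories <- function(x, ...) {
  cat(sprintf("<defect_trajectories> %d detections, %d tracks, %d events\n",
              nrow(x$trajectories), length(unique(x$trajectories$id)),
              nrow(x$events)))
  invisible(x)
}

#' Track defects over a simulation run
#'
#' Convenience wrapper: runs [detect_defects()] on every stored snapshot of
#' an `nd_run` (or on callback results that are defect tables) and links the
#' frames.
#'
#' @param run An `nd_run` from [run_protocol()] with either stored fields or
#'   defect-table callback results.
#' @param grid The [grid_spec()].
#' @param ... Passed to [link_trajectories()].
#' @return A `defect_trajectories` object.
#' @export
track_run <- function(run, grid, ...) {
  tabs <- if (!is.null(run$snapshots)) {
    lapply(seq_along(run$snapshots), function(i) {
      s <- run$snapshots[[i]]
      d <- detect_defects(s$q, flow = state_flow(s))
      d$frame <- i; d$time <- s$time
      d
    })
  } else if (length(run$callback_results)) {
    lapply(seq_along(run$callback_results), function(i) {
      d <- run$callback_results[[i]]
      stopifnot(is.data.frame(d))
      d$frame <- i; d$time <- run$times[i]
      d
    })
  } else stop("run has neither snapshots nor defect-table callback results")
  link_trajectories(dplyr::bind_rows(tabs), grid, ...)
}

#' Export trajectories to CSV
#'
#' Writes the documented column set: frame, time, id, charge, x, y, ex, ey,
#' re_theta3, im_theta3, u0x, u0y, omega0, event.
#'
#' @param traj A `defect_trajectories` object.
#' @param path Output CSV path.
#' @return The written tibble, invisibly.
#' @export
write_trajectories_csv <- function(traj, path) {
  df <- traj$trajectories
  for (col in c("ex", "ey", "re_theta3", "im_theta3", "u0x", "u0y", "omega0"))
    if (!col %in% names(df)) df[[col]] <- NA_real_
  ev <- traj$events
  df$event <- ""
  if (nrow(ev)) for (k in seq_len(nrow(ev))) {
    sel <- df$id == ev$id[k] & df$frame == ev$frame[k]
    df$event[sel] <- paste0(ev$kind[k], ":", ev$partner[k])
  }
  out <- df[, c("frame", "time", "id", "charge", "x", "y", "ex", "ey",
                "re_theta3", "im_theta3", "u0x", "u0y", "omega0", "event")]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
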