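#' Write trajectory, centre-of-mass and event tables as CSV
#'
#' Writes up to three files into `dir`: `trajectories.csv` with columns
#' `(replicate, timestep, agent_index, x)`, `com.csv` with
#' `(replicate, timestep, com)` and `events.csv` with
#' `(replicate, timestep, agent_index, proposal, accepted)`.  A single
#' trajectory is written as replicate 1.
#'
#' @param x a `cohesim_trajectory` or `cohesim_ensemble`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
write_trajectory_csv <- function(x, dir) {
  trajs <- if (inherits(x, "cohesim_ensemble")) x$trajectories
           else if (inherits(x, "cohesim_trajectory")) list(x)
           else stop("'x' must be a cohesim_trajectory or cohesim_ensemble")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pos <- do.call(rbind, lapply(seq_along(trajs), function(k) {
    tr <- trajs[[k]]
    n <- ncol(tr$positions)
    data.frame(replicate = k,
               timestep = rep(tr$time, times = n),
               agent_index = rep(seq_len(n), each = length(tr$time)),
               x = as.vector(tr$positions))
  }))
  com <- do.call(rbind, lapply(seq_along(trajs), function(k) {
    tr <- trajs[[k]]
    data.frame(replicate = k, timestep = tr$time, com = tr$com)
  }))
  ev <- do.call(rbind, lapply(seq_along(trajs), function(k) {
    tr <- trajs[[k]]
    if (!nrow(tr$events)) return(NULL)
    data.frame(replicate = k, timestep = tr$events$timestep,
               agent_index = tr$events$agent,
               proposal = tr$events$proposal,
               accepted = tr$events$accepted)
  }))
  paths <- file.path(dir, c("trajectories.csv", "com.csv", "events.csv"))
  write.csv(pos, paths[1], row.names = FALSE)
  write.csv(com, paths[2], row.names = FALSE)
  write.csv(if (is.null(ev)) data.frame(replicate = integer(0),
                                        timestep = integer(0),
                                        agent_index = integer(0),
                                        proposal = numeric(0),
                                        accepted = logical(0)) else ev,
            paths[3], row.names = FALSE)
  invisible(paths)
}

#' Write an analysis summary as JSON
#'
#' @param speed a [estimate_speed()] result.
#' @param msd optionally, a fitted [fit_msd()] result.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_summary_json <- function(speed, msd = NULL, path) {
  out <- list(mean_speed_mr_per_tau = speed$mean_mr_per_tau,
              stderr = speed$stderr_mr_per_tau,
              n_replicates = speed$n_replicates)
  if (!is.null(msd)) {
    out$msd <- list(order = msd$fit_order,
                    coefficients = as.list(msd$coefficients),
                    r_squared = msd$r_squared)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
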