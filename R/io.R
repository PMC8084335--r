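#' @title Trajectory tables, configuration files, and dataset analysis
#'
#' @description Trajectory datasets travel as plain delimited text with one
#' row per time sample and columns `participant`, `condition`, `phase`,
#' `trial`, `t_s`, `x_m`, `y_m`, `vx_ms`, `vy_ms` (optionally `fx_N`,
#' `fy_N`), SI units internally and millimeters only at reporting
#' boundaries. Configuration files are YAML with the same keys as the
#' configuration constructors.
#' @name trajectory-io
NULL

TRAJ_REQUIRED_COLS <- c("participant", "condition", "phase", "trial",
                        "t_s", "x_m", "y_m", "vx_ms", "vy_ms")

#' Validate a trajectory table
#'
#' Checks the column contract, uniqueness of
#' (participant, condition, trial, t_s) and strictly increasing time within
#' each trial; names the offending row on failure.
#'
#' @param df Trajectory table.
#' @return `df`, invisibly, on success.
#' @export
validate_trajectory_table <- function(df) {
  missing_cols <- setdiff(TRAJ_REQUIRED_COLS, names(df))
  if (length(missing_cols))
    stop("trajectory table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  key <- interaction(df$participant, df$condition, df$phase, df$trial,
                     drop = TRUE)
  bad <- unlist(lapply(split(seq_len(nrow(df)), key), function(i) {
    d <- diff(df$t_s[i])
    i[which(d <= 0) + 1L]
  }), use.names = FALSE)
  if (length(bad))
    stop(sprintf("time not strictly increasing within trial at row %d",
                 bad[1L]))
  invisible(df)
}

#' Write a trajectory table
#'
#' Tab-delimited text with a header; values round-trip through
#' [read_trajectory_table()] at full precision.
#'
#' @param df Trajectory table.
#' @param path Output file.
#' @export
write_trajectory_table <- function(df, path) {
  validate_trajectory_table(df)
  utils::write.table(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory table
#'
#' @param path Delimited text file written by [write_trajectory_table()]
#'   (or any tab-separated file with the standard columns).
#' @return Validated trajectory data frame.
#' @export
read_trajectory_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_trajectory_table(df)
  df
}

#' Read a simulation/analysis configuration file
#'
#' YAML keys are passed to the matching constructor ([ofc_config()],
#' [vs_config()], [gen_config()], [field_spec()], [channel_spec()])
#' depending on `what`.
#'
#' @param path YAML file.
#' @param what One of `"ofc"`, `"vs"`, `"gen"`, `"field"`, `"channel"`.
#' @return The corresponding configuration object.
#' @export
read_config <- function(path, what = c("ofc", "vs", "gen", "field",
                                       "channel")) {
  what <- match.arg(what)
  vals <- yaml::read_yaml(path)
  ctor <- switch(what, ofc = ofc_config, vs = vs_config, gen = gen_config,
                 field = field_spec, channel = channel_spec)
  do.call(ctor, vals)
}

#' Per-trial metrics and epoch summaries of a trajectory dataset
#'
#' Applies the behavioral measures to every trial of a trajectory table:
#' target error, lateral deviation and reach distance per trial, exclusion
#' of short reaches (< 75 mm), and means over the six canonical epochs per
#' participant and condition.
#'
#' @param df Trajectory table (see [validate_trajectory_table()]).
#' @return List with `trials` (one row per trial: `participant`,
#'   `condition`, `phase`, `trial`, `TE_mm`, `LD_mm`, `reach_mm`, `valid`)
#'   and `epochs` (one row per participant x condition x epoch with mean
#'   `TE_mm`, `LD_mm` over valid trials).
#' @export
analyze_trajectories <- function(df) {
  validate_trajectory_table(df)
  key <- interaction(df$participant, df$condition, df$phase, df$trial,
                     drop = TRUE)
  recs <- lapply(split(df, key), function(tr) {
    tr <- tr[order(tr$t_s), ]
    m <- trial_metrics(tr)
    data.frame(participant = tr$participant[1L],
               condition = tr$condition[1L], phase = tr$phase[1L],
               trial = tr$trial[1L], TE_mm = m$TE_mm, LD_mm = m$LD_mm,
               reach_mm = m$reach_mm, valid = m$valid)
  })
  trials <- do.call(rbind, recs)
  trials <- trials[order(trials$participant, trials$condition,
                         trials$phase, trials$trial), ]
  rownames(trials) <- NULL
  valid <- trials[trials$valid, ]
  eps <- epoch_spec()
  groups <- unique(valid[, c("participant", "condition")])
  epochs <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    sub <- valid[valid$participant == groups$participant[g] &
                 valid$condition == groups$condition[g], ]
    do.call(rbind, lapply(names(eps), function(nm) {
      e <- eps[[nm]]
      sel <- sub[sub$phase == e$phase & sub$trial %in% e$trials, ]
      data.frame(participant = groups$participant[g],
                 condition = groups$condition[g], epoch = nm,
                 TE_mm = mean(sel$TE_mm, na.rm = TRUE),
                 LD_mm = mean(sel$LD_mm, na.rm = TRUE))
    }))
  }))
  rownames(epochs) <- NULL
  list(trials = trials, epochs = epochs)
}
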