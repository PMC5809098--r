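#' Read a run configuration from YAML
#'
#' Validates the file against the known configuration fields of
#' \code{\link{session_config}} plus the reserved keys \code{seed} and
#' \code{out_dir}; unknown keys are rejected so typos cannot silently fall
#' back to defaults.
#'
#' @param path YAML file path.
#' @return List with \code{config} (a \code{session_config}), \code{seed},
#'   \code{out_dir}.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("malformed config: top level must be a mapping",
                          call. = FALSE)
  known <- names(formals(session_config))
  extra <- setdiff(names(raw), c(known, "seed", "out_dir"))
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  cfg <- do.call(session_config, raw[intersect(names(raw), known)])
  list(config = cfg, seed = raw$seed, out_dir = raw$out_dir)
}

#' Write a paired session to plain-text files
#'
#' One directory holds \code{closed.csv} and \code{replay.csv} (columns:
#' \code{time}, \code{E}, \code{B_1..B_n}; time in seconds) plus
#' \code{meta.json} with the sampling rate, gain-block start indices and
#' seed. Values round-trip through \code{\link{read_session}} to at least
#' 1e-12.
#'
#' @param session A \code{session_recording}.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(session$B_c)
  tm <- (seq_len(n) - 1) / session$fs
  wr <- function(E, B, file) {
    df <- data.frame(time = tm, E = E, B)
    names(df) <- c("time", "E", paste0("B_", seq_len(ncol(B))))
    utils::write.csv(format(df, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     file.path(dir, file), row.names = FALSE,
                     quote = FALSE)
  }
  wr(session$E_c, session$B_c, "closed.csv")
  wr(session$E_r, session$B_r, "replay.csv")
  jsonlite::write_json(list(fs = session$fs,
                            blocks = as.integer(session$blocks),
                            seed = if (is.null(session$seed)) NULL else
                              as.integer(session$seed),
                            n_cells = ncol(session$B_c),
                            n_samples = n),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a paired session written by \code{\link{write_session}}
#'
#' @param dir Directory containing \code{closed.csv}, \code{replay.csv} and
#'   \code{meta.json}.
#' @return A \code{session_recording} (without ground truth).
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) {
    stop("not a session directory (missing meta.json): ", dir,
         call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  rd <- function(file) {
    df <- utils::read.csv(file.path(dir, file))
    need <- c("time", "E", paste0("B_", seq_len(meta$n_cells)))
    if (!all(need %in% names(df))) {
      stop("malformed ", file, ": expected columns ",
           paste(need[!need %in% names(df)], collapse = ", "),
           call. = FALSE)
    }
    list(E = df$E, B = as.matrix(df[paste0("B_", seq_len(meta$n_cells))]))
  }
  cl <- rd("closed.csv"); rp <- rd("replay.csv")
  structure(list(B_c = unname(cl$B), B_r = unname(rp$B), E_c = cl$E,
                 E_r = rp$E, fs = meta$fs, blocks = meta$blocks,
                 ground_truth = NULL, seed = meta$seed),
            class = "session_recording")
}

#' Write a run manifest
#'
#' Records the resolved configuration, the root seed, the package version
#' and the produced output files, so a run can be reproduced exactly.
#'
#' @param config The configuration list/object used.
#' @param outputs Character vector of produced file paths.
#' @param path Manifest destination (JSON).
#' @param seed Root seed of the run.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(config, outputs, path, seed = NULL) {
  jsonlite::write_json(
    list(package = "loopgain",
         version = as.character(utils::packageVersion("loopgain")),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         config = unclass(config),
         outputs = as.character(outputs),
         timestamp = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Export a recording's traces as CSV
#'
#' Two-column (time, value) CSV with metadata comment lines in the header.
#'
#' @param ts A \code{loop_ts} or numeric vector.
#' @param path Output file.
#' @param dt Sample interval when \code{ts} is a bare vector.
#' @param label Condition label for the metadata header.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(ts, path, dt = NULL, label = NULL) {
  if (inherits(ts, "loop_ts")) {
    vals <- ts$values; dt <- ts$dt
    if (is.null(label)) label <- ts$label
  } else vals <- as.numeric(ts)
  stopifnot(!is.null(dt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# label: ", if (is.null(label)) "" else label),
               paste0("# dt: ", format(dt, digits = 17)),
               "time,value"), con)
  utils::write.table(
    data.frame(time = format((seq_along(vals) - 1) * dt, digits = 17,
                             trim = TRUE),
               value = format(vals, digits = 17, trim = TRUE)),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
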