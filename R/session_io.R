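session_columns <- c("subject", "session", "batch", "trial", "batch_type",
                     "target_x", "target_y", "hand_x", "hand_y",
                     "cursor_x", "cursor_y", "a", "b", "c", "d")

#' Flatten a session to a trial table
#'
#' @param x A `vm_session`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (ignored).
#' @return A data frame with one row per trial: subject, session, batch,
#'   trial, batch_type, target/hand/cursor coordinates (cm), and the true
#'   transformation elements `a`, `b`, `c`, `d`.
#' @export
as.data.frame.vm_session <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  rows <- lapply(seq_along(x$batches), function(bi) {
    b <- x$batches[[bi]]
    t4 <- vec_transform(b$transform)
    data.frame(subject = x$subject, session = x$session, batch = bi,
               trial = b$trials$trial, batch_type = b$type,
               target_x = b$trials$target_x, target_y = b$trials$target_y,
               hand_x = b$trials$hand_x, hand_y = b$trials$hand_y,
               cursor_x = b$trials$cursor_x, cursor_y = b$trials$cursor_y,
               a = t4[1], b = t4[2], c = t4[3], d = t4[4])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- as.data.frame(matrix(numeric(0), 0, length(session_columns),
                                dimnames = list(NULL, session_columns)))
  }
  out
}

#' Write a session to CSV with a JSON sidecar
#'
#' The CSV holds the trial table ([as.data.frame.vm_session()]); the
#' sidecar (same path with `.json` appended) records the generator
#' configuration, the simulation mode and observer model, the cursor noise,
#' the per-batch true transformations and hit flags, and the generating
#' prior if present, so that a written session round-trips exactly.
#'
#' @param session A `vm_session`.
#' @param path CSV file path.
#' @param sidecar Whether to write the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, sidecar = TRUE) {
  df <- as.data.frame(session)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "subject" &
    names(df) != "session" & names(df) != "batch" & names(df) != "trial"
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    side <- list(
      subject = session$subject, session = session$session,
      model = session$model, mode = session$mode,
      cursor_noise_sd = session$cursor_noise_sd,
      config = unclass(session$config),
      generating_prior = session$generating_prior,
      batches = lapply(session$batches, function(b) {
        list(type = b$type, hit = b$hit, transform = vec_transform(b$transform))
      }))
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' @param path CSV file path.
#' @param sidecar_path JSON sidecar path (default `paste0(path, ".json")`;
#'   `NULL` to reconstruct from the CSV alone).
#' @return A `vm_session`.
#' @export
read_session <- function(path, sidecar_path = paste0(path, ".json")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(session_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(session_columns, "batch_type")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0) {
      stop("non-numeric or missing values in column '", col, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  side <- if (!is.null(sidecar_path) && file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  }
  batches <- lapply(unique(df$batch), function(bi) {
    sub <- df[df$batch == bi, , drop = FALSE]
    structure(list(
      type = sub$batch_type[1],
      transform = transform_matrix(sub$a[1], sub$b[1], sub$c[1], sub$d[1]),
      hit = if (!is.null(side)) isTRUE(side$batches$hit[[bi]]) else NA,
      trials = data.frame(trial = sub$trial,
                          target_x = sub$target_x, target_y = sub$target_y,
                          hand_x = sub$hand_x, hand_y = sub$hand_y,
                          cursor_x = sub$cursor_x, cursor_y = sub$cursor_y)),
      class = "vm_batch")
  })
  cfg <- if (!is.null(side)) {
    structure(side$config, class = "vm_generator_config")
  } else {
    generator_config()
  }
  gp <- if (!is.null(side) && !is.null(side$generating_prior)) {
    matrix(unlist(side$generating_prior), 4, 4)
  }
  structure(list(batches = batches, config = cfg,
                 model = if (!is.null(side)) side$model else NA_character_,
                 mode = if (!is.null(side)) side$mode else NA_character_,
                 cursor_noise_sd = if (!is.null(side)) side$cursor_noise_sd
                 else NA_real_,
                 generating_prior = gp,
                 subject = df$subject[1], session = df$session[1]),
            class = "vm_session")
}
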