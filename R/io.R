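# Session file formats and (de)serialization.
#
# A session directory holds:
#   position.tsv          t, x, y, valid        (s / cm)
#   epochs.tsv            epoch, t_start, t_end
#   units.tsv             unit_id, width_us, spike_file
#   spikes_<id>.tsv       t, amp_1..k, f_1..d
#   lfp.dat + lfp.json    raw little-endian int16 + {fs_hz, scale, channel_id,
#                         n_samples, t0}
#   truth.json            optional ground-truth sidecar (synthetic sessions)
# Tables are tab-separated, '.' decimal, UTF-8.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", na = "")
}

read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("missing session file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("file ", basename(path), " lacks required column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Write a session bundle to a directory
#'
#' @param session a `synth_session` or compatible list with `position`,
#'   `spikes`, `lfp`, `epochs` and optionally `truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pos <- session$position
  write_tsv(data.frame(t = sprintf("%.6f", pos$t),
                       x = sprintf("%.4f", pos$x),
                       y = sprintf("%.4f", pos$y),
                       valid = as.integer(pos$valid)),
            file.path(dir, "position.tsv"))
  write_tsv(session$epochs, file.path(dir, "epochs.tsv"))
  units <- data.frame(
    unit_id = vapply(session$spikes, function(s) as.character(s$unit_id),
                     character(1)),
    width_us = vapply(session$spikes, function(s) s$width_us, numeric(1)))
  units$spike_file <- paste0("spikes_", units$unit_id, ".tsv")
  write_tsv(units, file.path(dir, "units.tsv"))
  for (s in session$spikes) {
    df <- data.frame(t = sprintf("%.6f", s$t))
    if (!is.null(s$amp)) {
      a <- as.data.frame(s$amp)
      names(a) <- paste0("amp_", seq_len(ncol(a)))
      df <- cbind(df, round(a, 4))
    }
    if (!is.null(s$features)) {
      f <- as.data.frame(s$features)
      names(f) <- paste0("f_", seq_len(ncol(f)))
      df <- cbind(df, round(f, 4))
    }
    write_tsv(df, file.path(dir, paste0("spikes_", s$unit_id, ".tsv")))
  }
  lfp <- session$lfp
  scale <- max(abs(lfp$samples), 1e-12) / 32000
  con <- file(file.path(dir, "lfp.dat"), "wb")
  writeBin(as.integer(round(lfp$samples / scale)), con, size = 2L,
           endian = "little")
  close(con)
  jsonlite::write_json(
    list(fs_hz = lfp$fs_hz, scale = scale, channel_id = lfp$channel_id,
         n_samples = length(lfp$samples), t0 = lfp$t0),
    file.path(dir, "lfp.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(session$truth))
    jsonlite::write_json(session$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read a session bundle from a directory
#'
#' Validates schemas on load: required columns, strictly increasing
#' position time, sorted spike times, and (optionally) that the LFP
#' sidecar sampling rate matches an expected value.
#'
#' @param dir session directory written by [write_session()].
#' @param expected_fs_hz optional; error if the LFP sidecar rate
#'   differs.
#' @return list with `position`, `spikes`, `lfp`, `epochs`, `truth`
#'   (NULL if absent).
#' @export
read_session <- function(dir, expected_fs_hz = NULL) {
  posdf <- read_tsv(file.path(dir, "position.tsv"),
                    required = c("t", "x", "y"))
  if (any(diff(posdf$t) <= 0))
    stop("position.tsv: time must be strictly increasing")
  pos <- position_trace(posdf$t, posdf$x, posdf$y,
                        valid = if ("valid" %in% names(posdf))
                          posdf$valid == 1 else rep(TRUE, nrow(posdf)))
  epochs <- read_tsv(file.path(dir, "epochs.tsv"),
                     required = c("epoch", "t_start", "t_end"))
  units <- read_tsv(file.path(dir, "units.tsv"),
                    required = c("unit_id", "width_us", "spike_file"))
  spikes <- lapply(seq_len(nrow(units)), function(i) {
    sdf <- read_tsv(file.path(dir, units$spike_file[i]), required = "t")
    if (is.unsorted(sdf$t))
      stop(units$spike_file[i], ": spike times must be sorted ascending")
    ac <- grep("^amp_", names(sdf), value = TRUE)
    fc <- grep("^f_", names(sdf), value = TRUE)
    spike_train(units$unit_id[i], sdf$t,
                amp = if (length(ac)) as.matrix(sdf[ac]) else NULL,
                features = if (length(fc)) as.matrix(sdf[fc]) else NULL,
                width_us = units$width_us[i])
  })
  meta <- jsonlite::read_json(file.path(dir, "lfp.json"), simplifyVector = TRUE)
  if (!is.null(expected_fs_hz) &&
      abs(meta$fs_hz - expected_fs_hz) > 1e-6 * expected_fs_hz)
    stop(sprintf("LFP sampling-rate mismatch: sidecar %.4f Hz, expected %.4f Hz",
                 meta$fs_hz, expected_fs_hz))
  con <- file(file.path(dir, "lfp.dat"), "rb")
  raw <- readBin(con, "integer", n = meta$n_samples, size = 2L,
                 endian = "little")
  close(con)
  lfp <- lfp_signal(raw * meta$scale, meta$fs_hz, meta$channel_id,
                    t0 = if (is.null(meta$t0)) 0 else meta$t0)
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  list(position = pos, spikes = spikes, lfp = lfp, epochs = epochs,
       truth = truth)
}

#' Read / write a pipeline configuration
#'
#' The configuration is a plain YAML mapping holding stage parameters
#' and, for synthetic sessions, the generator settings; it round-trips
#' losslessly through [write_config()] / [read_config()].
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param cfg named list to serialize.
#' @export
write_config <- function(cfg, path) {
  writeLines(yaml::as.yaml(cfg), path)
  invisible(path)
}
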