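#' Write / read epoched EEG as HDF5
#'
#' The container schema: datasets `/data` (trials x channels x samples),
#' `/labels` (integer codes) with `/label_names` (string table),
#' `/participants` (integer codes) with `/participant_names`, `/times`
#' (float64 seconds), `/montage/labels`, `/montage/positions`, and a root
#' attribute `sampling_rate_hz`. Write-then-read restores data, labels,
#' participants, and times bit-identically (`/data` is stored at float64
#' precision for that reason).
#'
#' @param epochs an [epochs_set()].
#' @param path HDF5 file path (overwritten if present).
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns an
#'   [epochs_set()].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epochs_set"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(epochs$data, path, "data")
  rhdf5::h5write(as.integer(epochs$labels), path, "labels")
  rhdf5::h5write(levels(epochs$labels), path, "label_names")
  rhdf5::h5write(as.integer(epochs$participants), path, "participants")
  rhdf5::h5write(levels(epochs$participants), path, "participant_names")
  rhdf5::h5write(epochs$times, path, "times")
  rhdf5::h5createGroup(path, "montage")
  rhdf5::h5write(epochs$montage$channel_labels, path, "montage/labels")
  rhdf5::h5write(epochs$montage$positions, path, "montage/positions")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(epochs$sampling_rate, fid, "sampling_rate_hz")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  present <- rhdf5::h5ls(path)
  have <- file.path(ifelse(present$group == "/", "", present$group),
                    present$name)
  have <- sub("^/", "", gsub("^//", "", have))
  need <- c("data", "labels", "label_names", "participants",
            "participant_names", "times", "montage/labels",
            "montage/positions")
  missing <- setdiff(need, have)
  if (length(missing)) {
    stopf("HDF5 epochs file is missing dataset(s): /%s",
          paste(missing, collapse = ", /"))
  }
  data <- rhdf5::h5read(path, "data")
  labels <- as.integer(rhdf5::h5read(path, "labels"))
  label_names <- as.character(rhdf5::h5read(path, "label_names"))
  pp <- as.integer(rhdf5::h5read(path, "participants"))
  pp_names <- as.character(rhdf5::h5read(path, "participant_names"))
  times <- as.numeric(rhdf5::h5read(path, "times"))
  mlab <- as.character(rhdf5::h5read(path, "montage/labels"))
  mpos <- rhdf5::h5read(path, "montage/positions")
  fid <- rhdf5::H5Fopen(path)
  att <- try(rhdf5::h5readAttributes(fid, "/"), silent = TRUE)
  rhdf5::H5Fclose(fid)
  sr <- if (!inherits(att, "try-error") && !is.null(att$sampling_rate_hz)) {
    as.numeric(att$sampling_rate_hz)
  } else {
    stopf("HDF5 epochs file is missing the sampling_rate_hz attribute")
  }
  if (length(labels) != dim(data)[1]) {
    stopf("/labels length does not match /data trial count")
  }
  epochs_set(data,
             factor(label_names[labels], levels = label_names),
             factor(pp_names[pp], levels = pp_names),
             times, montage(mlab, mpos), sampling_rate = sr)
}

#' Write / read aggregate attribution maps as HDF5
#'
#' Aggregate and per-participant maps live under
#' `/attributions/{method}/{layer}/{condition}` with datasets `aggregate`
#' (channels x samples), `per_participant` (channels x samples x
#' participants), `participants`, plus shared `/times` and `/channels`.
#'
#' @param maps nested list `maps[[method]][[layer]][[condition]]`, each an
#'   [aggregate_maps()] result.
#' @param times,channels shared axes.
#' @param path HDF5 file path.
#' @return `write_attribution_h5` returns `path` invisibly;
#'   `read_attribution_h5` the nested list (values, per_participant,
#'   participants).
#' @export
write_attribution_h5 <- function(maps, times, channels, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(times, path, "times")
  rhdf5::h5write(channels, path, "channels")
  rhdf5::h5createGroup(path, "attributions")
  for (method in names(maps)) {
    rhdf5::h5createGroup(path, file.path("attributions", method))
    for (layer in names(maps[[method]])) {
      rhdf5::h5createGroup(path, file.path("attributions", method, layer))
      for (cond in names(maps[[method]][[layer]])) {
        g <- file.path("attributions", method, layer, cond)
        rhdf5::h5createGroup(path, g)
        agg <- maps[[method]][[layer]][[cond]]
        rhdf5::h5write(agg$aggregate$values, path, file.path(g, "aggregate"))
        rhdf5::h5write(agg$per_participant, path,
                       file.path(g, "per_participant"))
        rhdf5::h5write(agg$participants, path, file.path(g, "participants"))
      }
    }
  }
  invisible(path)
}

#' @rdname write_attribution_h5
#' @export
read_attribution_h5 <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ls <- rhdf5::h5ls(path)
  out <- list(times = as.numeric(rhdf5::h5read(path, "times")),
              channels = as.character(rhdf5::h5read(path, "channels")),
              attributions = list())
  full <- paste0(ifelse(ls$group == "/", "", ls$group), "/", ls$name)
  cond_groups <- full[ls$otype == "H5I_GROUP" &
                        grepl("^/attributions/[^/]+/[^/]+/[^/]+$", full)]
  for (g in cond_groups) {
    parts <- strsplit(sub("^/attributions/", "", g), "/")[[1]]
    out$attributions[[parts[1]]][[parts[2]]][[parts[3]]] <- list(
      aggregate = rhdf5::h5read(path, file.path(g, "aggregate")),
      per_participant = rhdf5::h5read(path, file.path(g, "per_participant")),
      participants = as.character(rhdf5::h5read(path,
                                                file.path(g, "participants"))))
  }
  out
}

#' Export an attribution map to long-format CSV
#'
#' Columns: `channel`, `time_s`, `value`.
#'
#' @param map an [attribution_map()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_attribution_csv <- function(map, path) {
  stopifnot(inherits(map, "attribution_map"))
  df <- data.frame(channel = rep(map$channels, times = length(map$times)),
                   time_s = rep(map$times, each = length(map$channels)),
                   value = as.numeric(map$values))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
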