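#' Write an epoch set to disk
#'
#' Serializes epochs as a TSV (one row per trial x electrode: `trial`,
#' `electrode_id`, `condition`, `rejected`, then amplitude columns
#' `s0..sN` in microvolts) plus a JSON sidecar holding the sampling rate,
#' time axis, task label and electrode metadata.
#'
#' @param epochs an [epoch_set()].
#' @param meta electrode metadata data.frame.
#' @param path output directory (created if absent).
#' @return `path`, invisibly. Files written: `epochs.tsv`, `epochs.json`.
#' @export
write_epochs <- function(epochs, meta, path) {
  if (!inherits(epochs, "epoch_set")) stop_input("epochs must be an epoch_set")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  ids <- dimnames(epochs$data)[[2]]
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), d[1] * d[2], d[3])
  tab <- data.table::data.table(
    trial = rep(seq_len(d[1]), each = d[2]),
    electrode_id = rep(ids, d[1]),
    condition = rep(epochs$condition, each = d[2]),
    rejected = rep(epochs$rejected, each = d[2])
  )
  samp <- data.table::as.data.table(flat)
  data.table::setnames(samp, sprintf("s%d", seq_len(d[3]) - 1L))
  data.table::fwrite(cbind(tab, samp), file.path(path, "epochs.tsv"), sep = "\t")
  sidecar <- list(fs = epochs$fs, times = epochs$times, task = epochs$task,
                  phase = epochs$phase, electrodes = meta)
  jsonlite::write_json(sidecar, file.path(path, "epochs.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#'
#' Validates the file pair strictly: unknown region or hemisphere labels,
#' condition labels outside the task design, and truncated sample rows all
#' raise parse errors naming the offending field or row.
#'
#' @param path directory containing `epochs.tsv` and `epochs.json`.
#' @return list with `epochs` (an [epoch_set()]) and `meta` (data.frame).
#' @export
read_epochs <- function(path) {
  tsv <- file.path(path, "epochs.tsv"); js <- file.path(path, "epochs.json")
  if (!file.exists(tsv) || !file.exists(js))
    stop_input("missing epochs.tsv or epochs.json in ", path)
  sidecar <- jsonlite::read_json(js, simplifyVector = TRUE)
  for (f in c("fs", "times", "task", "electrodes"))
    if (is.null(sidecar[[f]])) stop_input("sidecar missing field: ", f)
  meta <- as.data.frame(sidecar$electrodes, stringsAsFactors = FALSE)
  need <- c("electrode_id", "region", "hemisphere", "patient")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop_input("electrode metadata missing field: ",
                               paste(miss, collapse = ", "))
  bad <- setdiff(unique(meta$region), c("LTC", "HIPP", "OTHER"))
  if (length(bad)) stop_input("unknown region label: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(meta$hemisphere), c("L", "R"))
  if (length(bad)) stop_input("unknown hemisphere label: ", paste(bad, collapse = ", "))
  if (anyDuplicated(meta$electrode_id))
    stop_input("duplicate electrode_id in metadata")

  tab <- data.table::fread(tsv, sep = "\t", fill = TRUE)
  head_cols <- c("trial", "electrode_id", "condition", "rejected")
  miss <- setdiff(head_cols, names(tab))
  if (length(miss)) stop_input("epochs.tsv missing column: ", paste(miss, collapse = ", "))
  n_samp <- length(sidecar$times)
  samp_cols <- sprintf("s%d", seq_len(n_samp) - 1L)
  miss <- setdiff(samp_cols, names(tab))
  if (length(miss)) stop_input("epochs.tsv missing sample column(s): ",
                               paste(utils::head(miss, 3), collapse = ", "))
  flat <- as.matrix(tab[, samp_cols, with = FALSE])
  bad_rows <- which(rowSums(!is.finite(flat)) > 0)
  if (length(bad_rows))
    stop_input("truncated or non-numeric sample data at row ", bad_rows[1],
               " of epochs.tsv")
  unk <- setdiff(unique(tab$electrode_id), meta$electrode_id)
  if (length(unk)) stop_input("electrode_id not in metadata: ", unk[1])

  trials <- sort(unique(tab$trial))
  ids <- meta$electrode_id[meta$electrode_id %in% unique(tab$electrode_id)]
  if (nrow(tab) != length(trials) * length(ids))
    stop_input("epochs.tsv is not a complete trial x electrode grid")
  data <- array(NA_real_, dim = c(length(trials), length(ids), n_samp),
                dimnames = list(NULL, ids, NULL))
  ti <- match(tab$trial, trials); ei <- match(tab$electrode_id, ids)
  for (r in seq_len(nrow(tab))) data[ti[r], ei[r], ] <- flat[r, ]

  cond <- rejected <- rep(NA, length(trials))
  first <- !duplicated(tab$trial)
  cond[match(tab$trial[first], trials)] <- as.character(tab$condition[first])
  rejected[match(tab$trial[first], trials)] <- as.logical(tab$rejected[first])
  phase <- sidecar$phase
  if (length(phase) == 0) phase <- NULL
  epochs <- epoch_set(data, as.numeric(sidecar$times), sidecar$fs, cond,
                      rejected = rejected, task = sidecar$task, phase = phase)
  list(epochs = epochs, meta = meta)
}
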