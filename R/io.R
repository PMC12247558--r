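#' Read and write trial tables as TSV
#'
#' @param table trial table data.frame.
#' @param path file path.
#' @return \code{read_trial_table} returns the data.frame.
#' @export
write_trial_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a subject's labelled series as NIfTI plus a BIDS-style events TSV
#'
#' The 4D data go to \code{<prefix>_bold.nii.gz}; one events row is
#' written per contiguous block of volumes sharing a label, with
#' \code{onset}/\code{duration} in seconds, \code{trial_type} (the volume
#' class) and \code{stimulus_id}.
#'
#' @param series labelled time series (see [simulate_fmri()]).
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_labeled_series <- function(series, prefix) {
  nii <- paste0(prefix, "_bold.nii.gz")
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(1, 1, 1, series$tr_seconds)
  RNifti::writeNifti(img, nii)
  lab <- series$volume_labels
  block_key <- paste(lab$volume_class, ifelse(is.na(lab$stimulus_id), "n/a",
                                              lab$stimulus_id))
  grp <- cumsum(c(TRUE, block_key[-1] != block_key[-length(block_key)]))
  blocks <- split(seq_len(nrow(lab)), grp)
  ev <- do.call(rbind, lapply(blocks, function(ii) {
    data.frame(onset = (ii[1] - 1) * series$tr_seconds,
               duration = length(ii) * series$tr_seconds,
               trial_type = lab$volume_class[ii[1]],
               stimulus_id = ifelse(is.na(lab$stimulus_id[ii[1]]), "n/a",
                                    lab$stimulus_id[ii[1]]))
  }))
  tsv <- paste0(prefix, "_events.tsv")
  utils::write.table(ev, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nii, tsv))
}

#' Reconstruct per-volume labels from a BIDS-style events table
#'
#' Onsets and durations (seconds) must be whole multiples of the TR;
#' stimulus presentations are aligned with volume boundaries by design.
#'
#' @param events data.frame with \code{onset}, \code{duration},
#'   \code{trial_type}, \code{stimulus_id}.
#' @param n_volumes length of the acquisition.
#' @param tr_seconds repetition time.
#' @return volume-label data.frame (\code{stimulus_id},
#'   \code{volume_class}, \code{censor}).
#' @export
labels_from_events <- function(events, n_volumes, tr_seconds) {
  off <- c(events$onset, events$duration) / tr_seconds
  if (any(abs(off - round(off)) > 1e-6)) {
    stop("event onsets/durations are not TR-aligned", call. = FALSE)
  }
  lab <- data.frame(stimulus_id = rep(NA_character_, n_volumes),
                    volume_class = rep("rest", n_volumes),
                    censor = 0L)
  for (r in seq_len(nrow(events))) {
    i0 <- round(events$onset[r] / tr_seconds) + 1
    ii <- i0:(i0 + round(events$duration[r] / tr_seconds) - 1)
    lab$volume_class[ii] <- events$trial_type[r]
    sid <- events$stimulus_id[r]
    if (!is.na(sid) && !identical(sid, "n/a")) lab$stimulus_id[ii] <- sid
  }
  lab
}

#' Read a labelled series back from NIfTI + events TSV
#'
#' @param prefix path prefix used by [write_labeled_series()].
#' @param subject_id,group metadata to attach.
#' @return labelled time series list.
#' @export
read_labeled_series <- function(prefix, subject_id = basename(prefix),
                                group = NA_character_) {
  img <- RNifti::readNifti(paste0(prefix, "_bold.nii.gz"))
  tr <- RNifti::pixdim(img)[4]
  dat <- array(as.numeric(img), dim = dim(img))
  ev <- utils::read.delim(paste0(prefix, "_events.tsv"),
                          stringsAsFactors = FALSE)
  list(data = dat, tr_seconds = tr,
       volume_labels = labels_from_events(ev, dim(dat)[4], tr),
       subject_id = subject_id, group = group)
}

#' Write a JSON sidecar recording provenance
#'
#' @param path sidecar path (.json).
#' @param config list describing the producing configuration.
#' @param seed integer seed used.
#' @export
write_sidecar <- function(path, config, seed) {
  payload <- list(
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    seed = seed,
    package_version = as.character(utils::packageVersion("curisc")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}
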