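# Readers and writers for continuous EEG (fixture format and BrainVision
# Core with ASCII data) and for epoch sets (plain-text container).

#' Write / read the plain-text continuous-EEG fixture format
#'
#' A self-describing text format: `key<TAB>value` header lines (`rate`,
#' `unit`, `labels` comma-separated, `events` as
#' `sample:trial:code` triplets separated by `;`), a line `data`, then one
#' tab-separated line per sample (multiplexed channels, microvolts).
#'
#' @param eeg A `continuous_eeg`.
#' @param path File path.
#' @return `read_eeg_fixture` returns a `continuous_eeg`; the writer returns
#'   `path` invisibly.
#' @export
write_eeg_fixture <- function(eeg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# continuous EEG fixture v1",
    paste0("rate\t", eeg$rate),
    paste0("unit\t", eeg$unit),
    paste0("labels\t", paste(eeg$labels, collapse = ",")),
    paste0("events\t", paste(sprintf("%d:%d:%s", eeg$events$sample,
                                     eeg$events$trial, eeg$events$code),
                             collapse = ";")),
    "data"), con)
  utils::write.table(t(signif(eeg$signal, 8)), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg_fixture
#' @export
read_eeg_fixture <- function(path) {
  lines <- readLines(path)
  hdr_end <- which(lines == "data")[1]
  hdr <- strsplit(lines[2:(hdr_end - 1)], "\t", fixed = TRUE)
  kv <- stats::setNames(vapply(hdr, `[`, "", 2), vapply(hdr, `[`, "", 1))
  ev <- strsplit(strsplit(kv[["events"]], ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  sig <- t(as.matrix(utils::read.table(text = lines[(hdr_end + 1):length(lines)],
                                       sep = "\t")))
  dimnames(sig) <- NULL
  eeg <- list(signal = sig,
              rate = as.numeric(kv[["rate"]]),
              labels = strsplit(kv[["labels"]], ",", fixed = TRUE)[[1]],
              events = data.frame(sample = as.integer(vapply(ev, `[`, "", 1)),
                                  trial = as.integer(vapply(ev, `[`, "", 2)),
                                  code = vapply(ev, `[`, "", 3),
                                  stringsAsFactors = FALSE),
              unit = kv[["unit"]])
  class(eeg) <- "continuous_eeg"
  eeg
}

#' Write / read BrainVision Core files (ASCII data)
#'
#' Writes the standard file triplet: `.vhdr` header, `.vmrk` marker file
#' (one stimulus marker per event) and `.eeg` data file in multiplexed ASCII
#' layout (one line per sample). Reading supports the same subset
#' (multiplexed ASCII).
#'
#' @param eeg A `continuous_eeg`.
#' @param basename Path without extension.
#' @return `read_brainvision` returns a `continuous_eeg`; the writer returns
#'   `basename` invisibly.
#' @export
write_brainvision <- function(eeg, basename) {
  nm <- basename(basename)
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "", "[Common Infos]",
           paste0("DataFile=", nm, ".eeg"),
           paste0("MarkerFile=", nm, ".vmrk"),
           "DataFormat=ASCII",
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", nrow(eeg$signal)),
           paste0("SamplingInterval=", format(1e6 / eeg$rate)),
           "", "[ASCII Infos]", "DecimalSymbol=.", "SkipLines=0", "SkipColumns=0",
           "", "[Channel Infos]",
           sprintf("Ch%d=%s,,1,µV", seq_along(eeg$labels), eeg$labels))
  writeLines(hdr, paste0(basename, ".vhdr"))
  mrk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
           "", "[Common Infos]", paste0("DataFile=", nm, ".eeg"),
           "", "[Marker Infos]",
           "Mk1=New Segment,,1,1,0,0",
           sprintf("Mk%d=Stimulus,%s,%d,1,0", seq_len(nrow(eeg$events)) + 1L,
                   eeg$events$code, eeg$events$sample))
  writeLines(mrk, paste0(basename, ".vmrk"))
  utils::write.table(t(signif(eeg$signal, 8)), paste0(basename, ".eeg"),
                     sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(basename)
}

#' @rdname write_brainvision
#' @export
read_brainvision <- function(basename) {
  vhdr <- if (grepl("\\.vhdr$", basename)) basename else paste0(basename, ".vhdr")
  stem <- sub("\\.vhdr$", "", vhdr)
  hdr <- readLines(vhdr)
  get_val <- function(key) {
    ln <- grep(paste0("^", key, "="), hdr, value = TRUE)[1]
    sub(paste0("^", key, "="), "", ln)
  }
  if (!identical(get_val("DataFormat"), "ASCII") ||
      !identical(get_val("DataOrientation"), "MULTIPLEXED")) {
    stop("only multiplexed ASCII BrainVision data is supported", call. = FALSE)
  }
  rate <- 1e6 / as.numeric(get_val("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", hdr, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",", fixed = TRUE),
                   `[`, "", 1)
  sig <- t(as.matrix(utils::read.table(file.path(dirname(vhdr), get_val("DataFile")),
                                       sep = "")))
  dimnames(sig) <- NULL
  mrk <- readLines(file.path(dirname(vhdr), sub("\\.vhdr$", ".vmrk", basename(vhdr))))
  stim <- grep("^Mk[0-9]+=Stimulus,", mrk, value = TRUE)
  parts <- strsplit(sub("^Mk[0-9]+=", "", stim), ",", fixed = TRUE)
  events <- data.frame(sample = as.integer(vapply(parts, `[`, "", 3)),
                       trial = seq_along(parts),
                       code = vapply(parts, `[`, "", 2),
                       stringsAsFactors = FALSE)
  eeg <- list(signal = sig, rate = rate, labels = labels, events = events,
              unit = "uV")
  class(eeg) <- "continuous_eeg"
  eeg
}

#' Write / read an epoch set as a plain-text container
#'
#' A directory holding `meta` (Debian-control-format metadata: rate, unit,
#' labels, baseline), `times.csv`, `trials.csv` (trial number and condition)
#' and `data.csv` (one row per trial x channel, columns = samples).
#'
#' @param epochs An `epoch_set`.
#' @param path Directory path (created if needed).
#' @return `read_epochs` returns an `epoch_set`; the writer returns `path`
#'   invisibly.
#' @export
write_epochs <- function(epochs, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  write.dcf(data.frame(rate = epochs$rate, unit = epochs$unit,
                       labels = paste(epochs$labels, collapse = ","),
                       baseline = paste(epochs$baseline, collapse = ","),
                       n_trials = d[1], n_channels = d[2], n_samples = d[3]),
            file.path(path, "meta"))
  utils::write.csv(data.frame(time = epochs$times), file.path(path, "times.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(trial = epochs$trial, condition = epochs$condition),
                   file.path(path, "trials.csv"), row.names = FALSE)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  utils::write.table(signif(flat, 8), file.path(path, "data.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- read.dcf(file.path(path, "meta"))
  d <- as.integer(meta[1, c("n_trials", "n_channels", "n_samples")])
  flat <- as.matrix(utils::read.table(file.path(path, "data.csv"), sep = ","))
  data <- aperm(array(t(flat), c(d[3], d[2], d[1])), c(3, 2, 1))
  trials <- utils::read.csv(file.path(path, "trials.csv"), stringsAsFactors = FALSE)
  ep <- list(data = data,
             times = utils::read.csv(file.path(path, "times.csv"))$time,
             rate = as.numeric(meta[1, "rate"]),
             labels = strsplit(meta[1, "labels"], ",", fixed = TRUE)[[1]],
             condition = as.character(trials$condition),
             trial = trials$trial,
             unit = unname(meta[1, "unit"]),
             baseline = as.numeric(strsplit(meta[1, "baseline"], ",")[[1]]),
             dropped = data.frame())
  class(ep) <- "epoch_set"
  ep
}

#' Write / read a trial schedule table
#'
#' @param schedule A [generate_schedule()] result.
#' @param path File path (CSV with columns index, condition, target, block,
#'   post).
#' @return `read_schedule` returns a `reach_schedule`; the writer returns
#'   `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$condition <- factor(tab$condition, levels = condition_levels)
  tab$post <- as.logical(tab$post)
  attr(tab, "post_indices") <- tab$index[tab$post]
  attr(tab, "n_pre") <- sum(tab$condition != "ADAPT")
  class(tab) <- c("reach_schedule", "data.frame")
  tab
}
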