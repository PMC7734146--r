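#' Spike-train container
#'
#' Per-neuron sorted spike times plus the population label and autapse
#' flag of each neuron. This is the common currency between the simulator,
#' the synthetic-train generator and every diagnostic.
#'
#' @param times list of numeric vectors, one strictly increasing vector of
#'   spike times (ms) per neuron; empty vectors are allowed.
#' @param labels character vector (`"excitatory"` / `"inhibitory"`), one
#'   per neuron.
#' @param autaptic logical vector, one per neuron.
#' @return An object of class `aeif_spikes`.
#' @export
aeif_spikes <- function(times, labels = NULL, autaptic = NULL) {
  stopifnot(is.list(times))
  n <- length(times)
  if (is.null(labels)) labels <- rep("excitatory", n)
  if (is.null(autaptic)) autaptic <- logical(n)
  stopifnot(length(labels) == n, length(autaptic) == n)
  for (j in seq_len(n)) {
    tj <- times[[j]]
    if (length(tj) > 1L && any(diff(tj) <= 0)) {
      stop("spike times of neuron ", j, " are not strictly increasing")
    }
  }
  structure(list(times = times, labels = labels,
                 autaptic = as.logical(autaptic)),
            class = "aeif_spikes")
}

#' @export
print.aeif_spikes <- function(x, ...) {
  n_spk <- vapply(x$times, length, integer(1))
  cat(sprintf("Spike data: %d neurons, %d spikes", length(x$times),
              sum(n_spk)))
  if (sum(n_spk) > 0) {
    cat(sprintf(" in [%.6g, %.6g] ms", min(unlist(x$times)),
                max(unlist(x$times))))
  }
  cat(sprintf("\n  %d excitatory, %d autaptic\n",
              sum(x$labels == "excitatory"), sum(x$autaptic)))
  invisible(x)
}

# index vector for a named subset of neurons
subset_neurons <- function(spikes, subset = c("all", "aut", "non",
                                              "exc", "inh")) {
  subset <- match.arg(subset)
  switch(subset,
         all = seq_along(spikes$times),
         aut = which(spikes$autaptic),
         non = which(!spikes$autaptic),
         exc = which(spikes$labels == "excitatory"),
         inh = which(spikes$labels == "inhibitory"))
}

#' Write / read spike trains as tab-separated text
#'
#' Two columns `neuron_id` and `spike_time_ms`, sorted by time, with
#' comment headers recording the neuron count, labels and autapse flags so
#' the container round-trips.
#'
#' @param spikes an [aeif_spikes()] object.
#' @param path file path.
#' @param comment optional extra comment string (e.g. a config hash or
#'   seed record) written into the header.
#' @return `write_spikes` returns `path` invisibly; `read_spikes` an
#'   `aeif_spikes` object.
#' @export
write_spikes <- function(spikes, path, comment = NULL) {
  stopifnot(inherits(spikes, "aeif_spikes"))
  n <- length(spikes$times)
  id <- rep(seq_len(n), times = vapply(spikes$times, length, integer(1)))
  t <- unlist(spikes$times, use.names = FALSE)
  o <- order(t, id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_neurons\t%d", n), con)
  writeLines(sprintf("# exc\t%s", paste(as.integer(
    spikes$labels == "excitatory"), collapse = "")), con)
  writeLines(sprintf("# aut\t%s", paste(as.integer(spikes$autaptic),
                                        collapse = "")), con)
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("neuron_id\tspike_time_ms", con)
  if (length(t)) {
    writeLines(sprintf("%d\t%.10g", id[o], t[o]), con)
  }
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  n <- as.integer(sub("# n_neurons\t", "",
                      hdr[startsWith(hdr, "# n_neurons")], fixed = TRUE))
  dig <- function(tag) {
    s <- sub(paste0("# ", tag, "\t"), "", hdr[startsWith(hdr,
                                                         paste0("# ", tag))],
             fixed = TRUE)
    as.integer(strsplit(s, "")[[1]]) == 1L
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1L] # column header
  times <- rep(list(numeric(0)), n)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    id <- as.integer(vapply(parts, `[`, "", 1L))
    t <- as.numeric(vapply(parts, `[`, "", 2L))
    sp <- split(t, factor(id, levels = seq_len(n)))
    times <- lapply(sp, function(v) sort(unname(v)))
  }
  aeif_spikes(times,
              labels = ifelse(dig("exc"), "excitatory", "inhibitory"),
              autaptic = dig("aut"))
}

#' Write / read the mean synaptic current series
#'
#' Two tab-separated columns `time_ms` and `I_chem_pA`.
#'
#' @param current data frame with columns `time` (ms) and `I_chem` (pA).
#' @param path file path.
#' @return `write_current` returns `path` invisibly; `read_current` the
#'   data frame.
#' @export
write_current <- function(current, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_ms\tI_chem_pA", con)
  writeLines(sprintf("%.10g\t%.10g", current$time, current$I_chem), con)
  invisible(path)
}

#' @rdname write_current
#' @export
read_current <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  data.frame(time = d[[1]], I_chem = d[[2]])
}
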