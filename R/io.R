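# Delimited-text I/O. The exchange schema for two-arm data is fixed:
# header row, columns time / event / group, events coded 1 = event,
# 0 = censored. Band and KM results serialize to tab-separated tables with
# metadata in '#' comment lines so they round-trip to equal objects.

.detect_sep <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (grepl("\t", l1)) "\t" else if (grepl(",", l1)) "," else ""
}

#' Read two-arm right-censored data from a delimited file
#'
#' Expects a header with columns `time`, `event`, `group` (tab-, comma- or
#' whitespace-separated); `event` is 1 for an event, 0 for censoring; the
#' two group labels are mapped to 1 (reference, first label in sorted
#' order) and 2 (test).
#'
#' @param path File path.
#' @return A data.frame `time`, `event`, `group` with
#'   `attr(, "group_labels")` recording the original labels.
#' @export
read_two_arm <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  d <- utils::read.table(path, header = TRUE, sep = .detect_sep(path),
                         stringsAsFactors = FALSE, comment.char = "#")
  need <- c("time", "event", "group")
  if (!all(need %in% names(d))) {
    stop("input must have header columns time, event, group (got: ",
         paste(names(d), collapse = ", "), ")", call. = FALSE)
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(d$time))) |
                 as.numeric(d$time) <= 0)
  if (length(bad)) {
    stop("non-positive or non-numeric time in data row ", bad[1L],
         call. = FALSE)
  }
  bad <- which(!(d$event %in% c(0, 1)))
  if (length(bad)) {
    stop("event must be 0/1; offending data row ", bad[1L], call. = FALSE)
  }
  labs <- sort(unique(d$group))
  if (length(labs) != 2L) {
    stop("exactly two groups expected, found ", length(labs), call. = FALSE)
  }
  out <- data.frame(time = as.numeric(d$time), event = as.numeric(d$event),
                    group = match(d$group, labs))
  attr(out, "group_labels") <- as.character(labs)
  out
}

#' Write a two-arm dataset in the package's exchange schema
#'
#' @param data A data.frame with columns `time`, `event`, `group`.
#' @param path Output path (tab-separated).
#' @export
write_two_arm <- function(data, path) {
  stopifnot(all(c("time", "event", "group") %in% names(data)))
  utils::write.table(data[, c("time", "event", "group")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / read pointwise bands
#'
#' Tab-separated columns `t, estimate, variance, lower, upper`, with the
#' band metadata (`contrast`, `alpha`, `method`, `n_boot`) in leading `#`
#' lines. `read_band()` reconstructs an equal `nph_band`.
#'
#' @param band An `nph_band`.
#' @param path File path.
#' @export
write_band <- function(band, path) {
  stopifnot(inherits(band, "nph_band"))
  hdr <- c(paste0("# contrast=", band$contrast),
           paste0("# alpha=", format(band$alpha, digits = 17)),
           paste0("# method=", band$method),
           paste0("# n_boot=", band$n_boot))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    format(band$band, digits = 17, trim = TRUE, scientific = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_band
#' @export
read_band <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, "="), "",
                           grep(paste0("^# ", key, "="), meta, value = TRUE))
  d <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                         sep = "\t")
  nb <- suppressWarnings(as.integer(get("n_boot")))
  .new_band(d$t, d$estimate, d$variance, as.numeric(get("alpha")),
            get("contrast"), get("method"),
            n_boot = if (length(nb) && !is.na(nb)) nb else NA_integer_)
}

#' Export a Kaplan-Meier fit
#'
#' @param km A `km_fit`.
#' @param path Output path (tab-separated columns `time, surv, var,
#'   n_risk, n_event, n_censor`).
#' @export
write_km <- function(km, path) {
  stopifnot(inherits(km, "km_fit"))
  utils::write.table(
    format(as.data.frame(km)[, c("time", "surv", "var", "n_risk", "n_event",
                                 "n_censor")], digits = 17, trim = TRUE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
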