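# Delimited-text I/O for trace and lesion tables, plus the per-lesion
# parameter manifest of the synthetic generator.

trace_columns <- c("procedure_id", "lesion_id", "time_s", "cf_g", "power_w",
                   "li_ohm", "x_mm", "y_mm", "z_mm")

#' Write a cohort of traces as delimited text
#'
#' All traces are stacked into one tab-separated table with the standard
#' columns (`procedure_id`, `lesion_id`, `time_s`, `cf_g`, `power_w`,
#' `li_ohm`, `x_mm`, `y_mm`, `z_mm`).
#'
#' @param traces list of `ablation_trace` data frames.
#' @param path destination file (TSV).
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(traces, path) {
  tab <- do.call(rbind, lapply(traces, function(tr)
    as.data.frame(tr)[, trace_columns]))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort of traces from delimited text
#'
#' @param path a TSV written by [write_trace_table()].
#' @return List of `ablation_trace` data frames, one per
#'   (procedure, lesion).
#' @export
read_trace_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(trace_columns, names(tab))
  if (length(missing_cols))
    stop("read_trace_table: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  key <- paste(tab$procedure_id, tab$lesion_id, sep = "\r")
  lapply(split(tab, factor(key, levels = unique(key))), function(block) {
    block <- block[order(block$time_s), , drop = FALSE]
    rownames(block) <- NULL
    class(block) <- c("ablation_trace", "data.frame")
    block
  })
}

#' Write the generator's per-lesion parameter manifest
#'
#' Records every lesion's true generating parameters (including the
#' analytic noiseless LI minimum) so downstream recovery tests can score
#' the pipeline against ground truth.
#'
#' @param traces list of `ablation_trace` objects carrying a `params`
#'   attribute (from [simulate_trace()]).
#' @param path destination file (TSV).
#' @return The manifest data frame, invisibly.
#' @export
write_param_manifest <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    p <- attr(tr, "params")
    if (is.null(p)) stop("write_param_manifest: trace lacks params attribute",
                         call. = FALSE)
    data.frame(procedure_id = tr$procedure_id[1L], lesion_id = tr$lesion_id[1L],
               as.data.frame(unclass(p)),
               t_min_noiseless_s = noiseless_li_minimum(p),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Write/read a lesion-summary table
#'
#' @param lesions lesion-summary data frame.
#' @param path TSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_lesion_table <- function(lesions, path) {
  utils::write.table(lesions, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lesion_table
#' @export
read_lesion_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
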