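#' Read and write the tidy delimited assay tables
#'
#' Thin tab-delimited readers/writers for the three table shapes the
#' analyses use: swelling time courses (one row per area measurement:
#' `oocyte_id`, `time`, `area`, optional `group`), long-form Ct tables
#' (`group`, `gene`, `is_reference`, `ct`, optional `sample_id`,
#' `replicate`), and wide per-bug phenotype tables (`bug_id`, `group`,
#' `w_prefeed`, `w_fed`, `wt_<hour>` columns, optional `urea_nmol`,
#' `eggs_total`). Column presence is validated on read.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return The validated data frame (readers); `path`, invisibly (writer).
#' @name assay_io
NULL

#' @rdname assay_io
#' @export
read_swelling_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("oocyte_id", "time", "area")
  if (!all(need %in% names(d)))
    stop("swelling table must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  d
}

#' @rdname assay_io
#' @export
read_ct_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if ("is_reference" %in% names(d))
    d$is_reference <- as.logical(d$is_reference)
  validate_ct_table(d)
}

#' @rdname assay_io
#' @export
read_bug_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  validate_bug_table(d, need_hours = FALSE)
}

#' @rdname assay_io
#' @export
write_assay_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
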