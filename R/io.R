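# Plain-text readers/writers for the study's table formats.

#' Write a long-format concentration table
#'
#' Tab-separated text with header columns `subject`, `condition`, `time_h`,
#' `conc_ng_ml` and (if present) `blq`.
#'
#' @param conc data.frame as returned by [simulate_pk_profiles()].
#' @param path destination file.
#' @export
write_concentration_table <- function(conc, path) {
  utils::write.table(conc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a long-format concentration table
#'
#' @param path tab- or whitespace-delimited file with header `subject`,
#'   `condition`, `time_h`, `conc_ng_ml` and optional `blq`.
#' @param loq limit of quantification used to derive `blq` when absent.
#' @return data.frame suitable for [nca_study()].
#' @export
read_concentration_table <- function(path, loq = 0.01) {
  conc <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("subject", "condition", "time_h", "conc_ng_ml")
  if (!all(need %in% names(conc))) {
    stop("concentration table needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(conc$blq)) conc$blq <- conc$conc_ng_ml < loq
  attr(conc, "loq") <- loq
  conc
}

#' Write a per-epoch artifact mask as plain text
#'
#' Two columns per channel block: `epoch_index` and one 0/1 `flag` column
#' per channel.
#'
#' @param artifacts logical matrix, epochs x channels.
#' @param path destination file.
#' @export
write_artifact_mask <- function(artifacts, path) {
  d <- data.frame(epoch_index = seq_len(nrow(artifacts)) - 1L,
                  artifacts * 1L)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-epoch artifact mask
#'
#' @param path file written by [write_artifact_mask()].
#' @return logical matrix, epochs x channels.
#' @export
read_artifact_mask <- function(path) {
  d <- utils::read.table(path, header = TRUE)
  m <- as.matrix(d[, setdiff(names(d), "epoch_index"), drop = FALSE]) == 1
  m
}
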