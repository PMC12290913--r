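# Full-precision text serialisation of numeric matrices. 17 significant
# digits round-trip IEEE doubles exactly, so save -> load is lossless.
fwrite_matrix <- function(m, path) {
  if (is.null(m)) m <- matrix(numeric(0), 0, 0)
  header <- paste(paste0("V", seq_len(ncol(m))), collapse = ",")
  if (nrow(m) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  dt <- data.table::as.data.table(
    matrix(sprintf("%.17g", m), nrow(m), ncol(m)))
  data.table::setnames(dt, paste0("V", seq_len(ncol(m))))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

fread_matrix <- function(path) {
  m <- as.matrix(data.table::fread(path, colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}
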