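# Minimal FCS list-mode support. Writes FCS 3.1 single-precision float
# files; reads FCS 3.0/3.1 float or integer list-mode data. Keyword values
# containing the TEXT delimiter are escaped by doubling, per the standard.

.fcs_delim <- "|"

.fcs_escape <- function(x) gsub(.fcs_delim, paste0(.fcs_delim, .fcs_delim),
                                x, fixed = TRUE)

#' Write events to an FCS 3.1 file
#'
#' Data are stored as little-endian single-precision floats, `$PnN` set to
#' the channel identifier and `$PnS` to the marker name. Bytes are a pure
#' function of the inputs, so identically-parameterized writes are
#' byte-identical.
#'
#' @param events `event_matrix` or numeric matrix (finite values).
#' @param path Output file path.
#' @param marker_names Optional `$PnS` labels; defaults to the column names.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path, marker_names = NULL) {
  X <- event_exprs(events)
  if (any(!is.finite(X))) cs_abort("cannot write non-finite values", "validation")
  n_par <- ncol(X); n_tot <- nrow(X)
  chan <- colnames(X)
  if (is.null(marker_names)) marker_names <- chan
  D <- .fcs_delim
  kw <- c("$BEGINANALYSIS", "0", "$BEGINDATA", "@BD@", "$BEGINSTEXT", "0",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F",
          "$ENDANALYSIS", "0", "$ENDDATA", "@ED@", "$ENDSTEXT", "0",
          "$MODE", "L", "$NEXTDATA", "0",
          "$PAR", as.character(n_par), "$TOT", as.character(n_tot))
  for (i in seq_len(n_par)) {
    kw <- c(kw,
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dN", i), .fcs_escape(chan[i]),
            sprintf("$P%dR", i), "262144",
            sprintf("$P%dS", i), .fcs_escape(marker_names[i]))
  }
  text <- paste0(D, paste(kw, collapse = D), D)
  # offsets: header is 58 bytes, TEXT follows immediately; the @BD@/@ED@
  # placeholders are replaced by fixed-width (10-digit) offsets so the TEXT
  # length is known before the offsets are.
  text_tmp <- sub("@BD@", "0000000000", sub("@ED@", "0000000000", text))
  text_start <- 58
  text_end <- text_start + nchar(text_tmp, type = "bytes") - 1
  data_start <- text_end + 1
  data_end <- data_start + 4 * n_par * n_tot - 1
  text <- sub("@BD@", sprintf("%010d", data_start), text)
  text <- sub("@ED@", sprintf("%010d", data_end), text)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end, data_start, data_end, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.vector(t(X)), con, size = 4, endian = "little")
  invisible(path)
}

# split a TEXT segment on its delimiter, honoring doubled-delimiter escapes
.fcs_tokens <- function(txt, delim) {
  parts <- strsplit(txt, delim, fixed = TRUE)[[1]]
  tokens <- character(0)
  carry <- NULL
  pending <- FALSE
  for (p in parts) {
    if (is.null(carry)) { carry <- p; next }
    if (p == "") { carry <- paste0(carry, delim); pending <- TRUE; next }
    if (pending) { carry <- paste0(carry, p); pending <- FALSE; next }
    tokens <- c(tokens, carry)
    carry <- p
  }
  if (!is.null(carry)) tokens <- c(tokens, carry)
  tokens
}

#' Read an FCS 3.0/3.1 list-mode file
#'
#' Supports float (`$DATATYPE F`, 32-bit) and integer (`$DATATYPE I`,
#' 16/32-bit) data in either byte order. Channel names come from `$PnS`
#' with `$PnN` as fallback.
#'
#' @param path Path to an FCS file.
#' @return An `event_matrix`; all FCS keywords are kept in `meta$keywords`.
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) cs_abort(paste("no such file:", path), "io")
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  if (!grepl("^FCS3\\.[01]", header)) {
    cs_abort(sprintf("not an FCS 3.0/3.1 file (header '%s', offset 0)",
                     substr(header, 1, 6)), "parse")
  }
  off <- suppressWarnings(as.numeric(trimws(
    substring(header, seq(11, 51, by = 8), seq(18, 58, by = 8)))))
  if (anyNA(off[1:2])) cs_abort("malformed header offsets (offset 10)", "parse")
  seek(con, off[1])
  txt <- rawToChar(readBin(con, "raw", off[2] - off[1] + 1))
  delim <- substr(txt, 1, 1)
  tokens <- .fcs_tokens(substring(txt, 2), delim)
  if (length(tokens) %% 2 == 1) tokens <- tokens[-length(tokens)]
  kwn <- toupper(trimws(tokens[seq(1, length(tokens), by = 2)]))
  kwv <- tokens[seq(2, length(tokens), by = 2)]
  kw <- stats::setNames(as.list(kwv), kwn)
  need <- function(k) {
    if (is.null(kw[[k]])) cs_abort(paste("missing required keyword", k), "parse")
    kw[[k]]
  }
  if (toupper(need("$MODE")) != "L") cs_abort("only list mode is supported", "format")
  dtype <- toupper(need("$DATATYPE"))
  if (!dtype %in% c("F", "I", "D")) {
    cs_abort(paste("unsupported $DATATYPE", dtype), "format")
  }
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  data_start <- off[3]
  data_end <- off[4]
  if (is.na(data_start) || data_start == 0) {
    data_start <- as.numeric(need("$BEGINDATA"))
    data_end <- as.numeric(need("$ENDDATA"))
  }
  endian <- if (startsWith(need("$BYTEORD"), "1")) "little" else "big"
  bits <- vapply(seq_len(n_par), function(i) {
    as.integer(kw[[sprintf("$P%dB", i)]] %||% "32")
  }, integer(1))
  if (dtype %in% c("F", "D")) bits[] <- if (dtype == "F") 32L else 64L
  if (length(unique(bits)) != 1) {
    cs_abort("mixed per-channel bit widths are not supported", "format")
  }
  bytes_per <- bits[1] / 8
  expected <- n_par * n_tot * bytes_per
  avail <- min(data_end, sz) - data_start + 1
  if (expected > avail) {
    cs_abort(sprintf(
      "$TOT*$PAR implies %d data bytes but segment holds %d (offset %d)",
      expected, avail, data_start), "parse")
  }
  seek(con, data_start)
  vals <- if (dtype %in% c("F", "D")) {
    readBin(con, "double", n = n_par * n_tot, size = bytes_per, endian = endian)
  } else {
    readBin(con, "integer", n = n_par * n_tot, size = bytes_per,
            endian = endian, signed = bytes_per > 2)
  }
  X <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  nm <- vapply(seq_len(n_par), function(i) {
    s <- kw[[sprintf("$P%dS", i)]]
    n <- kw[[sprintf("$P%dN", i)]]
    if (!is.null(s) && nzchar(trimws(s))) s else n %||% paste0("P", i)
  }, character(1))
  colnames(X) <- nm
  event_matrix(X, meta = list(keywords = kw, path = path))
}
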