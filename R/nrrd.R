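## Minimal NRRD0004 support for 3D scalar volumes: attached-data files,
## raw or gzip encoding, little-endian, with per-axis spacing taken from
## either "spacings" or diagonal "space directions". Covers the subset of
## the format used for segmentation volumes and masks.

nrrd_type_map <- list(
  "double" = list(what = "double", size = 8L),
  "float" = list(what = "double", size = 4L),
  "int" = list(what = "integer", size = 4L),
  "signed int" = list(what = "integer", size = 4L),
  "short" = list(what = "integer", size = 2L),
  "signed short" = list(what = "integer", size = 2L),
  "unsigned short" = list(what = "integer", size = 2L),
  "uchar" = list(what = "integer", size = 1L),
  "unsigned char" = list(what = "integer", size = 1L)
)

read_nrrd <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  ## header ends at the first blank line
  nl <- which(raw_all == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L) { hdr_end <- p; break }
    prev <- p
  }
  if (is.na(hdr_end)) stop("malformed NRRD: no end-of-header blank line")
  hdr_lines <- strsplit(rawToChar(raw_all[seq_len(hdr_end - 2L)]), "\n",
                        fixed = TRUE)[[1]]
  if (!grepl("^NRRD", hdr_lines[1])) stop("not an NRRD file: ", path)
  fields <- list()
  for (ln in hdr_lines[-1]) {
    if (grepl("^#", ln) || !grepl(":", ln, fixed = TRUE)) next
    kv <- regmatches(ln, regexpr("^[^:]+", ln))
    fields[[tolower(trimws(kv))]] <- trimws(sub("^[^:]+:=?", "", ln))
  }
  dim_n <- as.integer(fields[["dimension"]])
  if (!identical(dim_n, 3L)) stop("expected a 3D NRRD, got dimension ", dim_n)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type <- nrrd_type_map[[tolower(fields[["type"]])]]
  if (is.null(type)) stop("unsupported NRRD type: ", fields[["type"]])
  enc <- tolower(fields[["encoding"]])
  payload <- raw_all[(hdr_end + 1L):length(raw_all)]
  if (enc %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (enc != "raw") {
    stop("unsupported NRRD encoding: ", enc)
  }
  vals <- readBin(payload, what = type$what, n = prod(sizes),
                  size = type$size, endian = "little",
                  signed = !grepl("^u", tolower(fields[["type"]])) || type$size > 2L)
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(v) {
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
    }, numeric(3)))
    spacing <- sqrt(rowSums(m^2))
  }
  list(data = array(vals, sizes), spacing = spacing)
}

write_nrrd <- function(data, path, spacing = c(1, 1, 1), encoding = "gzip") {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 3L, encoding %in% c("raw", "gzip"))
  hdr <- paste0(
    "NRRD0004\n",
    "# written by the usformer package\n",
    "type: double\n",
    "dimension: 3\n",
    sprintf("sizes: %d %d %d\n", dim(data)[1], dim(data)[2], dim(data)[3]),
    sprintf("spacings: %.17g %.17g %.17g\n", spacing[1], spacing[2], spacing[3]),
    "endian: little\n",
    sprintf("encoding: %s\n", encoding),
    "\n"
  )
  payload <- writeBin(as.numeric(data), raw(), size = 8L, endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeBin(payload, con)
  invisible(path)
}
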