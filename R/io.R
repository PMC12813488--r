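#' Write an edge map to a headered TSV
#'
#' Persists an [edge_vector()] or signature map as a plain-text table with
#' commented header lines recording the schema version, parcel count, edge
#' ordering, and per-parcel network labels. The header is what later reads
#' validate before any dot product, so silent edge-order mismatches are
#' impossible.
#'
#' @param x an `edge_vector`, `neurosignature`, or `contrast_signature`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_connectome_table <- function(x, path) {
  nets <- x$networks
  vals <- if (!is.null(x$values)) list(value = x$values)
          else list(weight = x$weights,
                    haufe = if (!is.null(x$haufe)) x$haufe)
  vals <- vals[!vapply(vals, is.null, TRUE)]
  idx <- edge_index(length(nets))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#connsig_edges v1",
               paste0("#n_parcels=", length(nets)),
               "#edge_order=row-major-upper",
               paste0("#networks=", paste(nets, collapse = ","))), con)
  df <- data.frame(edge_i = idx$i, edge_j = idx$j,
                   lapply(vals, function(v) sprintf("%.17g", v)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge map written by [write_connectome_table()]
#'
#' @param path input file
#' @return an [edge_vector()] (single-value tables) or a list with
#'   `weights`, `haufe`, `networks` (signature tables)
#' @export
read_connectome_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5 || lines[1] != "#connsig_edges v1") {
    stop("not a connsig edge table (bad header at line 1): ", path)
  }
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    h <- hdr[startsWith(hdr, paste0("#", key, "="))]
    if (length(h) != 1) stop("missing header field '", key, "' in ", path)
    sub(paste0("^#", key, "="), "", h)
  }
  p <- as.integer(get("n_parcels"))
  nets <- strsplit(get("networks"), ",", fixed = TRUE)[[1]]
  if (length(nets) != p) {
    stop("parcel count (", p, ") does not match network labels (",
         length(nets), ") in ", path)
  }
  body <- lines[!startsWith(lines, "#")]
  df <- tryCatch(
    utils::read.table(text = body, header = TRUE, sep = "\t"),
    error = function(e) stop("parse error in ", path, " near line ",
                             length(hdr) + 1, ": ", conditionMessage(e))
  )
  if (nrow(df) != n_edges(p)) {
    stop("truncated edge table: ", nrow(df), " rows at line ",
         length(hdr) + 1 + nrow(df) + 1, ", expected ", n_edges(p))
  }
  idx <- edge_index(p)
  if (!all(df$edge_i == idx$i & df$edge_j == idx$j)) {
    stop("edge ordering in ", path, " is not row-major-upper")
  }
  if ("value" %in% names(df)) {
    edge_vector(df$value, nets)
  } else {
    out <- list(weights = df$weight, networks = nets)
    if ("haufe" %in% names(df)) out$haufe <- df$haufe
    out
  }
}

#' Write a JSON metadata sidecar
#'
#' @param x list of metadata (config, seed, stage outputs)
#' @param path output .json path
#' @return `path`, invisibly
#' @export
write_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
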