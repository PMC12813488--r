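#' Edge index for a parcellation
#'
#' Enumerates the upper triangle of a P x P symmetric matrix in fixed
#' row-major order (1,2), (1,3), ..., (1,P), (2,3), ... The whole package
#' relies on this single ordering: cross-dataset dot products are only
#' meaningful when both edge vectors were built against the same index.
#'
#' @param n_parcels number of parcels P (>= 2)
#' @return data.frame with integer columns `i`, `j` (i < j), one row per edge
#' @export
edge_index <- function(n_parcels) {
  stopifnot(is.numeric(n_parcels), length(n_parcels) == 1, n_parcels >= 2)
  p <- as.integer(n_parcels)
  i <- rep.int(seq_len(p - 1L), times = (p - 1L):1L)
  j <- unlist(lapply(seq_len(p - 1L), function(k) (k + 1L):p), use.names = FALSE)
  data.frame(i = i, j = j)
}

#' Number of edges for P parcels
#' @param n_parcels parcel count
#' @return P*(P-1)/2
#' @export
n_edges <- function(n_parcels) as.integer(n_parcels * (n_parcels - 1) / 2)

#' Vectorize the upper triangle of a symmetric matrix (row-major)
#'
#' @param mat symmetric numeric matrix
#' @return numeric vector of length P*(P-1)/2 in [edge_index()] order
#' @export
vec_upper <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  idx <- edge_index(nrow(mat))
  mat[cbind(idx$i, idx$j)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vec_upper()]; the round trip is lossless.
#'
#' @param values edge vector in row-major upper-triangle order
#' @param diag value placed on the diagonal (default 0)
#' @return symmetric P x P matrix
#' @export
unvec_upper <- function(values, diag = 0) {
  e <- length(values)
  p <- (1 + sqrt(1 + 8 * e)) / 2
  if (abs(p - round(p)) > 1e-8) {
    stop("length ", e, " is not P*(P-1)/2 for any integer P")
  }
  p <- as.integer(round(p))
  m <- matrix(diag, p, p)
  idx <- edge_index(p)
  m[cbind(idx$i, idx$j)] <- values
  m[cbind(idx$j, idx$i)] <- values
  m
}

#' Construct an edge vector with parcel/network metadata
#'
#' @param values numeric vector, length P*(P-1)/2, finite
#' @param networks character vector of network labels, one per parcel
#' @return object of class `edge_vector`
#' @export
edge_vector <- function(values, networks) {
  p <- length(networks)
  if (length(values) != n_edges(p)) {
    stop("edge vector length ", length(values),
         " does not match ", p, " parcels (expected ", n_edges(p), ")")
  }
  if (any(!is.finite(values))) stop("edge values must be finite")
  structure(
    list(values = as.numeric(values), networks = as.character(networks)),
    class = "edge_vector"
  )
}

#' @export
print.edge_vector <- function(x, ...) {
  cat("<edge_vector> ", length(x$networks), " parcels, ",
      length(x$values), " edges; networks: ",
      paste(unique(x$networks), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Test whether two edge maps share the same edge ordering
#'
#' Compares parcel count and the per-parcel network labels. Objects may be
#' `edge_vector`s, signatures, or anything carrying a `networks` field.
#'
#' @param a,b objects with a `networks` character vector
#' @return TRUE/FALSE
#' @export
same_edge_order <- function(a, b) {
  na <- a$networks
  nb <- b$networks
  !is.null(na) && !is.null(nb) && length(na) == length(nb) && all(na == nb)
}

#' Logical mask of within-network edges
#'
#' @param networks per-parcel network labels
#' @param network network name (e.g. "SMN"); if NULL, any shared network
#' @return logical vector over edges, TRUE where both endpoints lie in the
#'   (given) network
#' @export
within_network_edges <- function(networks, network = NULL) {
  idx <- edge_index(length(networks))
  ni <- networks[idx$i]
  nj <- networks[idx$j]
  if (is.null(network)) ni == nj else ni == network & nj == network
}
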