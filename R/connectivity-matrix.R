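#' Weighted structural connectivity matrices
#'
#' The central container of the package: a symmetric, non-negative weight
#' matrix over an ordered subset of parcellation nodes, with zero diagonal.
#' Entries count streamlines whose two endpoints fall in the two regions
#' (or run/subject means, or volume-normalized strengths).
#'
#' @param weights numeric NxN matrix.
#' @param node_labels integer label ids, in canonical parcellation order.
#' @param node_names character names, same length.
#' @param kind one of `"raw"`, `"run_mean"`, `"subject_mean"`,
#'   `"volume_normalized"`.
#' @param discards optional named numeric tally of discarded records.
#' @return Object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(weights, node_labels, node_names = NULL,
                                kind = "raw", discards = NULL) {
  weights <- as.matrix(weights)
  n <- length(node_labels)
  stopifnot(nrow(weights) == n, ncol(weights) == n)
  node_labels <- as.integer(node_labels)
  if (anyDuplicated(node_labels)) stop("node_labels must be unique")
  if (is.null(node_names)) node_names <- as.character(node_labels)
  kind <- match.arg(kind, c("raw", "run_mean", "subject_mean",
                            "volume_normalized"))
  if (any(!is.finite(weights))) stop("weights must be finite")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (max(abs(weights - t(weights))) > 1e-9 * max(1, max(abs(weights)))) {
    stop("weights must be symmetric")
  }
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) stop("diagonal must be zero")
  dimnames(weights) <- list(node_names, node_names)
  structure(list(weights = weights, node_labels = node_labels,
                 node_names = as.character(node_names), kind = kind,
                 discards = discards),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("ConnectivityMatrix [%s]: %d nodes, total weight %.4g\n",
              x$kind, length(x$node_labels), sum(x$weights)))
  invisible(x)
}

#' @export
dim.connectivity_matrix <- function(x) dim(x$weights)

stop_if_mismatched <- function(mats) {
  labs <- lapply(mats, function(m) m$node_labels)
  if (!all(vapply(labs, identical, logical(1), labs[[1]]))) {
    stop("matrices have mismatched node sets")
  }
}

#' Write or read a connectivity matrix as TSV with a JSON sidecar
#'
#' The TSV carries node names as first row and first column; the sidecar
#' (`<path>.json`) records kind, node labels, and any provenance the caller
#' supplies. Round-trips are lossless to below 1e-12; matrices asymmetric
#' beyond 1e-9 are rejected on read.
#'
#' @param cm a [connectivity_matrix].
#' @param path TSV path.
#' @param provenance optional list stored in the sidecar.
#' @export
write_matrix_tsv <- function(cm, path, provenance = NULL) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  w <- cm$weights
  header <- c("name", cm$node_names)
  lines <- c(paste(header, collapse = "\t"),
             vapply(seq_len(nrow(w)), function(i) {
               paste(c(cm$node_names[i],
                       formatC(w[i, ], format = "g", digits = 17)),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  side <- list(kind = cm$kind, node_labels = cm$node_labels,
               node_names = cm$node_names,
               discards = as.list(cm$discards %||% stats::setNames(numeric(0), character(0))),
               provenance = provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("matrix TSV too short: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]][-1]
  n <- length(header)
  w <- matrix(NA_real_, n, n)
  rown <- character(n)
  for (i in seq_len(n)) {
    row <- cells[[i + 1L]]
    if (length(row) != n + 1L) {
      stop(sprintf("line %d: expected %d fields, got %d", i + 1L, n + 1L,
                   length(row)))
    }
    rown[i] <- row[1]
    w[i, ] <- as.numeric(row[-1])
  }
  if (!identical(rown, header)) stop("row and column names disagree")
  if (anyNA(w)) stop("non-numeric matrix entry")
  if (max(abs(w - t(w))) > 1e-9 * max(1, max(abs(w)))) {
    stop("matrix is asymmetric beyond tolerance")
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    labels <- as.integer(side$node_labels)
    kind <- side$kind
    discards <- unlist(side$discards) %||% NULL
  } else {
    labels <- seq_len(n)
    kind <- "raw"
    discards <- NULL
  }
  connectivity_matrix(w, labels, header, kind = kind, discards = discards)
}
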