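#' Event-by-event similarity matrices
#'
#' A `sim_matrix` couples a symmetric event-by-event similarity matrix with a
#' boolean availability mask. The mask marks cells that carry a defined value:
#' brain matrices mask out their (ignored) diagonal and any event pair whose
#' series were too short to correlate; recalled-knowledge matrices mask out
#' pairs of events that were not jointly recalled.
#'
#' @param values square numeric matrix.
#' @param mask logical matrix of the same shape (default: all available).
#' @param kind one of `"knowledge"`, `"brain"`, `"predicted"`, `"recalled"`.
#' @return an object of class `sim_matrix`.
#' @export
sim_matrix <- function(values, mask = NULL,
                       kind = c("knowledge", "brain", "predicted", "recalled")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square")
  m <- nrow(values)
  if (is.null(mask)) mask <- matrix(TRUE, m, m)
  mask <- mask & is.finite(values)
  stopifnot(dim(mask) == dim(values))
  if (kind %in% c("knowledge", "brain", "recalled")) {
    v <- values[mask]
    if (length(v) && (min(v) < -1 - 1e-8 || max(v) > 1 + 1e-8)) {
      stop("similarity values outside [-1, 1]")
    }
  }
  sym_ok <- all(abs(values[mask & t(mask)] - t(values)[mask & t(mask)]) < 1e-8)
  if (!sym_ok) stop("similarity matrix is not symmetric where masked")
  structure(list(values = values, mask = mask, kind = kind),
            class = "sim_matrix")
}

#' @export
print.sim_matrix <- function(x, ...) {
  m <- nrow(x$values)
  lt <- lower.tri(x$values)
  avail <- sum(x$mask[lt])
  cat(sprintf("<sim_matrix> kind '%s', %d x %d, %d/%d lower-triangle cells available\n",
              x$kind, m, m, avail, sum(lt)))
  v <- x$values[x$mask & lt]
  if (length(v)) {
    cat(sprintf("  values: min %.3f, median %.3f, max %.3f\n",
                min(v), stats::median(v), max(v)))
  }
  invisible(x)
}

#' @export
as.matrix.sim_matrix <- function(x, ...) {
  out <- x$values
  out[!x$mask] <- NA_real_
  out
}

# accept either a sim_matrix or a bare matrix (full mask)
as_sim <- function(x, kind = "brain") {
  if (inherits(x, "sim_matrix")) x else sim_matrix(x, kind = kind)
}

# jointly-available strictly-lower-triangle values of two sim matrices
joint_lower <- function(a, b) {
  stopifnot(nrow(a$values) == nrow(b$values))
  lt <- lower.tri(a$values)
  keep <- lt & a$mask & b$mask
  list(a = a$values[keep], b = b$values[keep], n = sum(keep))
}

#' Write a similarity matrix (values + mask) as TSV
#'
#' @param x a [sim_matrix()].
#' @param path output path for the values TSV; the mask is written next to it
#'   with suffix `.mask.tsv`.
#' @return `path`, invisibly.
#' @export
write_sim_matrix <- function(x, path) {
  write.table(x$values, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(x$mask * 1L, paste0(path, ".mask.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
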